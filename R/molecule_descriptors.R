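#' Build the molecular graph of a linear peptide
#'
#' Joins per-residue heavy-atom templates by amide bonds with condensation
#' (one water removed per bond), a free amine at the N-terminus and a free
#' carboxylic acid at the C-terminus. Protonation states are neutral
#' (formal charges zero); charge enters the descriptor set only through the
#' net-charge count of [polar_group_descriptors()].
#'
#' @param sequence A peptide string over the 20 canonical one-letter codes.
#' @return An object of class `peptide_graph`: a list with `atoms` (tibble:
#'   `residue`, `name`, `element`, `nH`, `aromatic`, `hyb`, `ring`),
#'   `bonds` (tibble: `from`, `to` atom indices, `order` one of
#'   `"1"`, `"2"`, `"AR"`, `ring`, `amide`) and the `sequence`.
#' @examples
#' g <- build_peptide_graph("GG")
#' molecular_formula(g)   # "C4H8N2O3"
#' @export
build_peptide_graph <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1, nzchar(sequence))
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!chars %in% .AA_CODES)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Non-canonical residue code '%s' at position %d.",
      chars[[bad[[1]]]], bad[[1]]))
  }
  atoms <- vector("list", length(chars))
  bonds <- vector("list", length(chars))
  offset <- 0L
  c_index <- integer(length(chars))   # index of backbone carbonyl C
  n_index <- integer(length(chars))   # index of backbone N
  for (k in seq_along(chars)) {
    tmpl <- .AA_TEMPLATES[[chars[[k]]]]
    a <- tibble::as_tibble(tmpl$atoms)
    b <- tibble::as_tibble(tmpl$bonds)
    if (k == 1L) a$nH[a$name == "N"] <- a$nH[a$name == "N"] + 1L
    idx <- setNames(offset + seq_len(nrow(a)), a$name)
    n_index[[k]] <- idx[["N"]]
    c_index[[k]] <- idx[["C"]]
    a$residue <- k
    bonds[[k]] <- tibble::tibble(
      from = unname(idx[b$from]), to = unname(idx[b$to]),
      order = b$order, ring = b$ring)
    if (k == length(chars)) {
      a <- dplyr::bind_rows(a, tibble::tibble(
        name = "OXT", element = "O", nH = 1L, aromatic = FALSE,
        hyb = "SP3", ring = FALSE, residue = k))
      bonds[[k]] <- dplyr::bind_rows(bonds[[k]], tibble::tibble(
        from = idx[["C"]], to = offset + nrow(a), order = "1", ring = FALSE))
    }
    atoms[[k]] <- a
    offset <- offset + nrow(a)
  }
  backbone <- if (length(chars) > 1) {
    tibble::tibble(
      from = c_index[-length(chars)], to = n_index[-1],
      order = "1", ring = FALSE)
  } else NULL
  atoms <- dplyr::bind_rows(atoms)
  bonds <- dplyr::bind_rows(c(bonds, list(backbone)))
  # flag amide C-N single bonds: the carbon carries a double bond to oxygen
  has_carbonyl <- logical(nrow(atoms))
  dbl <- bonds[bonds$order == "2", , drop = FALSE]
  for (i in seq_len(nrow(dbl))) {
    f <- dbl$from[[i]]; t <- dbl$to[[i]]
    if (atoms$element[[f]] == "C" && atoms$element[[t]] == "O") has_carbonyl[[f]] <- TRUE
    if (atoms$element[[t]] == "C" && atoms$element[[f]] == "O") has_carbonyl[[t]] <- TRUE
  }
  pair_elem <- cbind(atoms$element[bonds$from], atoms$element[bonds$to])
  bonds$amide <- bonds$order == "1" & (
    (pair_elem[, 1] == "C" & pair_elem[, 2] == "N" & has_carbonyl[bonds$from]) |
    (pair_elem[, 2] == "C" & pair_elem[, 1] == "N" & has_carbonyl[bonds$to]))
  structure(list(atoms = atoms, bonds = bonds, sequence = sequence),
            class = "peptide_graph")
}

#' @export
print.peptide_graph <- function(x, ...) {
  cat(sprintf("<peptide_graph> %s: %d heavy atoms, %d bonds, formula %s\n",
              x$sequence, nrow(x$atoms), nrow(x$bonds), molecular_formula(x)))
  invisible(x)
}

#' Count atoms of one element in a peptide graph
#'
#' @param graph A [build_peptide_graph()] result.
#' @param element Element symbol; `"H"` counts attached hydrogens.
#' @return Integer count.
#' @export
element_count <- function(graph, element) {
  stopifnot(inherits(graph, "peptide_graph"))
  known <- c(unique(graph$atoms$element), "H", "C", "N", "O", "S", "Se")
  if (!element %in% known) {
    rlang::abort(sprintf("Unknown element symbol '%s'.", element))
  }
  if (element == "H") return(sum(graph$atoms$nH))
  sum(graph$atoms$element == element)
}

#' Molecular formula of a peptide graph (Hill order)
#' @param graph A [build_peptide_graph()] result.
#' @return Character scalar, e.g. `"C4H8N2O3"`.
#' @export
molecular_formula <- function(graph) {
  counts <- c(C = element_count(graph, "C"), H = element_count(graph, "H"),
              N = element_count(graph, "N"), O = element_count(graph, "O"),
              S = element_count(graph, "S"))
  counts <- counts[counts > 0]
  paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
}

# number of aromatic rings (SSSR): cyclomatic number of the aromatic
# subgraph, edges - vertices + components
.aromatic_ring_count <- function(graph) {
  e <- graph$bonds[graph$bonds$order == "AR", , drop = FALSE]
  if (nrow(e) == 0) return(0L)
  verts <- sort(unique(c(e$from, e$to)))
  parent <- seq_along(verts)
  vid <- match(c(e$from, e$to), verts)
  find <- function(i) { while (parent[[i]] != i) i <- parent[[i]]; i }
  for (k in seq_len(nrow(e))) {
    a <- find(vid[[k]]); b <- find(vid[[k + nrow(e)]])
    if (a != b) parent[[a]] <- b
  }
  comps <- length(unique(vapply(seq_along(verts), find, integer(1))))
  as.integer(nrow(e) - length(verts) + comps)
}

#' Physicochemical descriptors of a peptide graph
#'
#' Computes the structure-based descriptor block used by the feature
#' compositions, under fixed documented conventions:
#' * `MW` — average-mass molecular weight (Da; standard atomic weights);
#' * `tPSA` — topological polar surface area, the sum of Ertl fragment
#'   contributions over N/O environments (A^2);
#' * `cLogP` — Wildman-Crippen atomic-contribution logP;
#' * `Fsp3` — sp3-hybridised carbons / all carbons;
#' * `HBA` — count of N and O atoms (Lipinski-style);
#' * `HBD` — count of N or O atoms bearing at least one hydrogen;
#' * `NAR` — number of aromatic rings (SSSR);
#' * `NRB` — rotatable bonds: non-ring single bonds between two
#'   non-terminal heavy atoms, amide C-N bonds excluded.
#'
#' @param graph A [build_peptide_graph()] result.
#' @return A one-row tibble with columns `MW`, `tPSA`, `cLogP`, `Fsp3`,
#'   `HBA`, `HBD`, `NAR`, `NRB`.
#' @export
physchem_descriptors <- function(graph) {
  stopifnot(inherits(graph, "peptide_graph"))
  a <- graph$atoms
  mw <- sum(.ATOMIC_MASS[a$element]) + sum(a$nH) * .ATOMIC_MASS[["H"]]
  chars <- strsplit(graph$sequence, "")[[1]]
  if (length(chars) == 1L) {
    tpsa <- .TPSA_FREE[[chars]]
    clogp <- .CRIPPEN_FREE[[chars]]
  } else {
    inner <- chars[-c(1, length(chars))]
    tpsa <- .TPSA_CTX[chars[[1]], "nterm"] +
      sum(.TPSA_CTX[inner, "internal"]) +
      .TPSA_CTX[chars[[length(chars)]], "cterm"]
    clogp <- .CRIPPEN_CTX[chars[[1]], "nterm"] +
      sum(.CRIPPEN_CTX[inner, "internal"]) +
      .CRIPPEN_CTX[chars[[length(chars)]], "cterm"]
  }
  is_c <- a$element == "C"
  fsp3 <- sum(is_c & a$hyb == "SP3") / sum(is_c)
  hba <- sum(a$element %in% c("N", "O"))
  hbd <- sum(a$element %in% c("N", "O") & a$nH >= 1)
  deg <- tabulate(c(graph$bonds$from, graph$bonds$to), nbins = nrow(a))
  rot <- graph$bonds$order == "1" & !graph$bonds$ring & !graph$bonds$amide &
    deg[graph$bonds$from] >= 2 & deg[graph$bonds$to] >= 2
  tibble::tibble(
    MW = unname(mw), tPSA = unname(tpsa), cLogP = unname(clogp),
    Fsp3 = fsp3, HBA = hba, HBD = hbd,
    NAR = .aromatic_ring_count(graph), NRB = sum(rot))
}

#' Charged polar-group descriptors of a peptide sequence
#'
#' Counts taken from side-chain identity under a fixed pH-7-like
#' convention: `NG` guanidine groups (Arg), `NNCAA` negatively charged
#' residues (Asp + Glu), `NPA` primary amines (Lys side chains plus the
#' free N-terminal alpha-amine), and `NetC` the side-chain net charge
#' (Arg + Lys) - (Asp + Glu). His is treated as neutral. Termini cancel at
#' neutral pH and are excluded from `NetC` by default; set
#' `charged_n_terminus` / `charged_c_terminus` to count either one.
#'
#' @param sequence Canonical peptide string.
#' @param free_n_terminus Is the N-terminus a free amine (counted in
#'   `NPA`)? Default `TRUE`.
#' @param charged_n_terminus,charged_c_terminus Add +1 / -1 terminal
#'   charges to `NetC`. Default `FALSE`.
#' @return A one-row tibble with columns `NetC`, `NPA`, `NG`, `NNCAA`.
#' @examples
#' polar_group_descriptors("KKDE")  # NetC 0, NPA 3, NG 0, NNCAA 2
#' @export
polar_group_descriptors <- function(sequence, free_n_terminus = TRUE,
                                    charged_n_terminus = FALSE,
                                    charged_c_terminus = FALSE) {
  .check_canonical(sequence)
  chars <- strsplit(sequence, "")[[1]]
  cnt <- function(x) sum(chars %in% x)
  tibble::tibble(
    NetC = cnt(c("R", "K")) - cnt(c("D", "E")) +
      as.integer(charged_n_terminus) - as.integer(charged_c_terminus),
    NPA = cnt("K") + as.integer(free_n_terminus),
    NG = cnt("R"),
    NNCAA = cnt(c("D", "E")))
}

#' All structure-based descriptors for a set of peptides
#'
#' Convenience wrapper computing, per row, the graph-based physicochemical
#' block, the polar-group counts and the N / O atom counts. Descriptors are
#' computed from the sequence-built graph even when coordinates are
#' present; geometry is used only by the structural hydrophobic moment.
#'
#' @param peptides Peptide tibble with a `sequence` column.
#' @return `peptides` (id/label columns retained) with descriptor columns
#'   `MW`, `tPSA`, `NRB`, `Fsp3`, `cLogP`, `HBD`, `HBA`, `NAR`, `NetC`,
#'   `NPA`, `NG`, `NNCAA`, `N`, `O`.
#' @export
structure_descriptors <- function(peptides) {
  stopifnot(is.data.frame(peptides), "sequence" %in% names(peptides))
  keep <- intersect(c("id", "label"), names(peptides))
  desc <- purrr::map(peptides$sequence, function(s) {
    g <- build_peptide_graph(s)
    dplyr::bind_cols(
      physchem_descriptors(g),
      polar_group_descriptors(s),
      tibble::tibble(N = element_count(g, "N"), O = element_count(g, "O")))
  })
  out <- dplyr::bind_cols(peptides[, keep, drop = FALSE], dplyr::bind_rows(desc))
  out[, c(keep, "MW", "tPSA", "NRB", "Fsp3", "cLogP", "HBD", "HBA", "NAR",
          "NetC", "NPA", "NG", "NNCAA", "N", "O")]
}
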