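#' Read peptide sequences from a FASTA file
#'
#' Each FASTA entry becomes one row; sequences are uppercased and validated
#' against the 20 canonical one-letter amino-acid codes.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped, multi-record).
#' @return A tibble with columns `id` (the FASTA header up to the first
#'   whitespace) and `sequence`, in file order. An empty file yields a
#'   zero-row tibble.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "GRKKRR", ">p2", "glfga"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  if (file.size(path) == 0) {
    return(tibble::tibble(id = character(), sequence = character()))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  .check_canonical(seqs, ids)
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write peptides to a FASTA file
#'
#' @param peptides A tibble with columns `id` and `sequence`.
#' @param path Output file path.
#' @return `peptides`, invisibly.
#' @export
write_fasta <- function(peptides, path) {
  stopifnot(is.data.frame(peptides))
  set <- Biostrings::BStringSet(setNames(peptides$sequence, peptides$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(peptides)
}

#' Read a peptide structure from a PDB file
#'
#' Parses ATOM records of one model/one chain into a single peptide record:
#' the sequence from residue order, the alpha-carbon position of every
#' residue, and the side-chain centroid as the unweighted mean of side-chain
#' heavy-atom positions (absent for glycine or residues with no resolved
#' side-chain atoms). Coordinates are kept in Angstrom as stored.
#'
#' @param path Path to a PDB file containing ATOM records.
#' @param residue_map Named character vector mapping 3-letter residue codes
#'   to parent 1-letter codes. Nonstandard residues are only accepted
#'   through this map; an unmapped code is an error.
#' @param chain Chain identifier; default the first chain in the file.
#' @param model Model number; default the first model.
#' @param id Record identifier; defaults to the file name.
#' @return A one-row peptide tibble with columns `id`, `sequence` and a
#'   `residues` list column (tibble with `residue`, `ca_x`, `ca_y`, `ca_z`,
#'   `sc_x`, `sc_y`, `sc_z`; centroid columns are `NA` where no side chain
#'   is resolved).
#' @export
read_pdb <- function(path, residue_map = default_residue_map(),
                     chain = NULL, model = 1L, id = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = model > 1, verbose = FALSE)
  if (model > 1) {
    if (nrow(pdb$xyz) < model) {
      rlang::abort(sprintf("Model %d requested but file has %d model(s).",
                           model, nrow(pdb$xyz)))
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    pdb$atom$x <- xyz[, 1]; pdb$atom$y <- xyz[, 2]; pdb$atom$z <- xyz[, 3]
  }
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) rlang::abort(sprintf("No ATOM records in %s", path))
  if (is.null(chain)) chain <- at$chain[[1]]
  at <- at[at$chain %in% chain, , drop = FALSE]
  # first alternate location only
  at <- at[at$alt %in% c("", " ", NA, at$alt[[1]]), , drop = FALSE]
  key <- paste(at$resno, at$insert)
  res_order <- unique(key)
  rows <- vector("list", length(res_order))
  seq1 <- character(length(res_order))
  backbone <- c("N", "CA", "C", "O", "OXT")
  for (k in seq_along(res_order)) {
    ra <- at[key == res_order[[k]], , drop = FALSE]
    code3 <- toupper(ra$resid[[1]])
    if (!code3 %in% names(residue_map)) {
      rlang::abort(sprintf(
        "Residue code '%s' (residue %d) is not in residue_map.", code3, k))
    }
    seq1[[k]] <- residue_map[[code3]]
    ca <- ra[ra$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0) {
      rlang::abort(sprintf("Missing CA atom for residue %d (%s).", k, code3))
    }
    sc <- ra[!ra$elety %in% backbone & substr(ra$elesy, 1, 1) != "H", ,
             drop = FALSE]
    cent <- if (nrow(sc) > 0) c(mean(sc$x), mean(sc$y), mean(sc$z))
            else c(NA_real_, NA_real_, NA_real_)
    rows[[k]] <- tibble::tibble(
      residue = seq1[[k]],
      ca_x = ca$x[[1]], ca_y = ca$y[[1]], ca_z = ca$z[[1]],
      sc_x = cent[[1]], sc_y = cent[[2]], sc_z = cent[[3]])
  }
  sequence <- paste(seq1, collapse = "")
  .check_canonical(sequence, ids = basename(path))
  tibble::tibble(
    id = id %||% sub("\\.pdb$", "", basename(path), ignore.case = TRUE),
    sequence = sequence,
    residues = list(dplyr::bind_rows(rows)))
}

#' Default three-letter to one-letter residue map
#'
#' The 20 standard residues plus a few common modified forms (MSE, SEC,
#' PYL, HYP). Extend by concatenating, e.g.
#' `c(default_residue_map(), ORN = "K")`.
#' @return Named character vector.
#' @export
default_residue_map <- function() .RESIDUE_MAP_DEFAULT

#' Length-filter and deduplicate peptide records
#'
#' Keeps peptides whose length lies in `[min_len, max_len]` (both inclusive;
#' cell-penetrating peptides are 5-30 residues long, hence the defaults) and
#' collapses exact duplicate sequences to their first occurrence. Duplicates
#' with conflicting labels are an error. The operation is idempotent.
#'
#' @param peptides Peptide tibble (`id`, `sequence`, optional `label`, ...).
#' @param min_len,max_len Inclusive length bounds. Defaults 5 and 30.
#' @param quiet Suppress the drop summary message.
#' @return The filtered peptide tibble.
#' @export
preprocess_peptides <- function(peptides, min_len = 5L, max_len = 30L,
                                quiet = FALSE) {
  stopifnot(is.data.frame(peptides))
  n0 <- nrow(peptides)
  len <- nchar(peptides$sequence)
  kept <- peptides[len >= min_len & len <= max_len, , drop = FALSE]
  n_len <- n0 - nrow(kept)
  if ("label" %in% names(kept)) {
    conflicts <- kept |>
      dplyr::group_by(.data$sequence) |>
      dplyr::summarise(nlab = dplyr::n_distinct(.data$label),
                       .groups = "drop") |>
      dplyr::filter(.data$nlab > 1)
    if (nrow(conflicts) > 0) {
      rlang::abort(sprintf(
        "Duplicate sequences with conflicting labels: %s",
        paste(utils::head(conflicts$sequence, 3), collapse = ", ")))
    }
  }
  dedup <- kept[!duplicated(kept$sequence), , drop = FALSE]
  if (!quiet) {
    rlang::inform(sprintf(
      "preprocess_peptides: %d records in, %d dropped by length, %d duplicates removed, %d kept.",
      n0, n_len, nrow(kept) - nrow(dedup), nrow(dedup)))
  }
  tibble::as_tibble(dedup)
}
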