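#' Configuration of the sequence-based feature extractors
#'
#' Bundles the tunables of the pseudo amino-acid composition (PseAAC) and
#' dipeptide composition (DPC) extractors. Defaults follow Chou's type-1
#' PseAAC (`lambda = 2` sequence-order tiers so that 20 + lambda = 22
#' components, weight `w = 0.05`, and the three classical property scales:
#' hydrophobicity, hydrophilicity, side-chain mass, each standardised over
#' the 20 residues) and a 40-dipeptide catalogue containing the ten
#' uptake-motif pairs (GL, GF, LG, GA, VC, RK, RQ, KR, KK, RR).
#'
#' @param pseaac_lambda Number of sequence-order correlation tiers
#'   (integer >= 1; must be smaller than the shortest admissible peptide).
#' @param pseaac_weight Weight of the correlation tail (> 0).
#' @param pseaac_properties Named list of per-residue numeric scales.
#' @param dpc_list Character vector of 40 two-letter dipeptides.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(pseaac_lambda = 2L, pseaac_weight = 0.05,
                           pseaac_properties = .PSEAAC_SCALES,
                           dpc_list = .DPC_DEFAULT) {
  stopifnot(pseaac_lambda >= 1, pseaac_weight > 0)
  if (!all(nchar(dpc_list) == 2L)) {
    rlang::abort("dpc_list entries must be two-letter dipeptides.")
  }
  structure(list(pseaac_lambda = as.integer(pseaac_lambda),
                 pseaac_weight = pseaac_weight,
                 pseaac_properties = pseaac_properties,
                 dpc_list = dpc_list),
            class = "feature_config")
}

#' Arginine and lysine fractions
#'
#' @param sequence Canonical peptide string (non-empty).
#' @return One-row tibble with `F[ARG]` and `F[LYS]`, each in \[0, 1\].
#' @export
aac_fractions <- function(sequence) {
  .check_canonical(sequence)
  if (!nzchar(sequence)) rlang::abort("Empty sequence.")
  chars <- strsplit(sequence, "")[[1]]
  tibble::tibble(
    "F[ARG]" = mean(chars == "R"),
    "F[LYS]" = mean(chars == "K"))
}

# standardised property matrix: residues x scales, zero mean and unit
# population SD over the 20 residues per scale
.pseaac_property_matrix <- function(properties) {
  m <- vapply(properties, function(p) {
    v <- p[.AA_CODES]
    (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }, numeric(20))
  rownames(m) <- .AA_CODES
  m
}

#' Pseudo amino-acid composition (Chou type 1)
#'
#' The residue-pair correlation is the mean squared difference of the
#' standardised property scales; the tier-k factor theta_k averages it over
#' residue pairs k positions apart. The 20 + lambda components are
#' `f_c / (sum f + w sum theta)` for the residues and
#' `w theta_k / (sum f + w sum theta)` for the tail, so they sum to one.
#'
#' @param sequence Canonical peptide string, longer than `config$pseaac_lambda`.
#' @param config A [feature_config()].
#' @return One-row tibble `PseAAC_1` .. `PseAAC_{20+lambda}` (22 at defaults).
#' @export
pseaac <- function(sequence, config = feature_config()) {
  .check_canonical(sequence)
  chars <- strsplit(sequence, "")[[1]]
  lam <- config$pseaac_lambda
  if (length(chars) <= lam) {
    rlang::abort(sprintf(
      "Sequence length %d must exceed pseaac_lambda = %d.",
      length(chars), lam))
  }
  pm <- .pseaac_property_matrix(config$pseaac_properties)
  idx <- match(chars, .AA_CODES)
  theta <- vapply(seq_len(lam), function(k) {
    i <- seq_len(length(chars) - k)
    d <- pm[idx[i], , drop = FALSE] - pm[idx[i + k], , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1))
  f <- tabulate(idx, nbins = 20) / length(chars)
  denom <- sum(f) + config$pseaac_weight * sum(theta)
  comp <- c(f, config$pseaac_weight * theta) / denom
  setNames(tibble::as_tibble(as.list(comp), .name_repair = "minimal"),
           paste0("PseAAC_", seq_along(comp)))
}

#' Dipeptide composition over a fixed catalogue
#'
#' Fraction of overlapping occurrences of each listed dipeptide among the
#' L - 1 adjacent windows.
#'
#' @param sequence Canonical peptide string of length >= 2.
#' @param dpc_list Character vector of two-letter dipeptides.
#' @return One-row tibble with columns `DPC_<XY>`.
#' @export
dpc <- function(sequence, dpc_list = .DPC_DEFAULT) {
  .check_canonical(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) < 2L) rlang::abort("Sequence must have length >= 2.")
  pairs <- paste0(chars[-length(chars)], chars[-1])
  counts <- vapply(dpc_list, function(d) sum(pairs == d), numeric(1))
  setNames(tibble::as_tibble(as.list(counts / (length(chars) - 1)),
                             .name_repair = "minimal"),
           paste0("DPC_", dpc_list))
}

#' All sequence-based descriptors for a set of peptides
#'
#' Per row: Arg/Lys fractions, PseAAC components, dipeptide compositions
#' and the Eisenberg descriptor `Ho` (per-residue sequence hydrophobic
#' moment at 100 degrees per residue; see [sequence_hydrophobic_moment()]).
#'
#' @param peptides Peptide tibble with a `sequence` column.
#' @param config A [feature_config()].
#' @return Tibble of id/label columns plus the descriptor columns.
#' @export
sequence_descriptors <- function(peptides, config = feature_config()) {
  stopifnot(is.data.frame(peptides), "sequence" %in% names(peptides))
  keep <- intersect(c("id", "label"), names(peptides))
  desc <- purrr::map(peptides$sequence, function(s) {
    dplyr::bind_cols(
      aac_fractions(s),
      pseaac(s, config),
      dpc(s, config$dpc_list),
      tibble::tibble(Ho = sequence_hydrophobic_moment(s)$per_residue))
  })
  dplyr::bind_cols(peptides[, keep, drop = FALSE], dplyr::bind_rows(desc))
}
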