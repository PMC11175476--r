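# Feature compositions: named, ordered descriptor sets.
#
# Baseline compositions:
#   FC-SEQ      (64) all sequence descriptors: 2 AAC + 22 PseAAC + 40 DPC
#   FC-STR      (12) all structure descriptors
#   FC-SEQ-STR  (76) union of the two
#   FC-Kendall  (43) AAC + PseAAC + the ten motif DPCs + structure
#                    descriptors excluding tPSA, NRB, HBD
# The "+NOHo" variants add the nitrogen count, oxygen count and Eisenberg
# hydrophobicity to the structure-containing compositions and drop the
# descriptors a Kendall redundancy analysis flags against them
# (HBD and MW; F[ARG] falls in the sequence compositions), giving sizes
# 63, 13, 77 and 44.

.fc_seq_names <- function(config = feature_config()) {
  c("F[ARG]", "F[LYS]",
    paste0("PseAAC_", seq_len(20 + config$pseaac_lambda)),
    paste0("DPC_", config$dpc_list))
}

.fc_str_names <- function() {
  c("MW", "tPSA", "Fsp3", "cLogP", "HBA", "HBD",
    "NAR", "NRB", "NetC", "NPA", "NG", "NNCAA")
}

#' Assemble a named feature composition
#'
#' @param name One of `"FC-SEQ"`, `"FC-STR"`, `"FC-SEQ-STR"`, `"FC-Kendall"`.
#' @param variant `"baseline"` or `"+NOHo"` (with N, O and Ho added and the
#'   redundancy-flagged descriptors removed).
#' @param config A [feature_config()] (fixes PseAAC size and DPC catalogue).
#' @return An object of class `feature_composition`: list with `name`,
#'   `variant` and the ordered `descriptors` character vector.
#' @examples
#' length(assemble_fc("FC-STR", "+NOHo")$descriptors)  # 13
#' @export
assemble_fc <- function(name = c("FC-SEQ", "FC-STR", "FC-SEQ-STR", "FC-Kendall"),
                        variant = c("baseline", "+NOHo"),
                        config = feature_config()) {
  name <- rlang::arg_match(name)
  variant <- rlang::arg_match(variant)
  motif_dpc <- paste0("DPC_", c("GL", "GF", "LG", "GA", "VC",
                                "RK", "RQ", "KR", "KK", "RR"))
  base <- switch(name,
    "FC-SEQ" = .fc_seq_names(config),
    "FC-STR" = .fc_str_names(),
    "FC-SEQ-STR" = c(.fc_seq_names(config), .fc_str_names()),
    "FC-Kendall" = c("F[ARG]", "F[LYS]",
                     paste0("PseAAC_", seq_len(20 + config$pseaac_lambda)),
                     motif_dpc,
                     setdiff(.fc_str_names(), c("tPSA", "NRB", "HBD"))))
  desc <- base
  if (variant == "+NOHo") {
    drop <- switch(name,
      "FC-SEQ" = "F[ARG]",
      "FC-STR" = c("HBD", "MW"),
      "FC-SEQ-STR" = c("HBD", "MW"),
      "FC-Kendall" = c("F[ARG]", "MW"))
    desc <- setdiff(desc, drop)
    if (name != "FC-SEQ") desc <- c(desc, "N", "O", "Ho")
  }
  structure(list(name = name, variant = variant, descriptors = desc),
            class = "feature_composition")
}

#' @export
print.feature_composition <- function(x, ...) {
  cat(sprintf("<feature_composition> %s (%s): %d descriptors\n",
              x$name, x$variant, length(x$descriptors)))
  invisible(x)
}

#' Extract a labelled feature table for a feature composition
#'
#' Computes every needed descriptor from the sequences and returns them in
#' the composition's fixed order. This column order is also the order in
#' which descriptors are presented to the convolutional network.
#'
#' @param peptides Peptide tibble with `sequence` (and usually `id`,
#'   `label`) columns.
#' @param fc A [assemble_fc()] result, or a composition name (then built
#'   with `variant`).
#' @param variant Used when `fc` is given as a name.
#' @param config A [feature_config()].
#' @return Tibble: `id`, `label` (if present) followed by the
#'   composition's descriptor columns.
#' @export
extract_features <- function(peptides, fc = "FC-STR", variant = "+NOHo",
                             config = feature_config()) {
  if (is.character(fc)) fc <- assemble_fc(fc, variant, config)
  stopifnot(inherits(fc, "feature_composition"))
  keep <- intersect(c("id", "label"), names(peptides))
  need_seq <- any(fc$descriptors %in% setdiff(.fc_seq_names(config), "Ho")) ||
    "Ho" %in% fc$descriptors
  need_str <- any(fc$descriptors %in% c(.fc_str_names(), "N", "O"))
  parts <- list(peptides[, keep, drop = FALSE])
  if (need_seq) {
    s <- sequence_descriptors(peptides, config)
    parts <- c(parts, list(s[, setdiff(names(s), keep), drop = FALSE]))
  }
  if (need_str) {
    s <- structure_descriptors(peptides)
    parts <- c(parts, list(s[, setdiff(names(s), keep), drop = FALSE]))
  }
  all_cols <- dplyr::bind_cols(parts)
  missing <- setdiff(fc$descriptors, names(all_cols))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Descriptors not computable: %s",
                         paste(missing, collapse = ", ")))
  }
  all_cols[, c(keep, fc$descriptors)]
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between two numeric vectors of equal
#' length. Constant input on either side makes tau undefined; `NA` is
#' returned with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A number in \[-1, 1\], or `NA`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    rlang::warn("kendall_tau undefined for constant input; returning NA.")
    return(NA_real_)
  }
  stats::cor(x, y, method = "kendall")
}

#' Remove redundant features by Kendall correlation
#'
#' Computes tau-b between every pair of feature columns and removes, for
#' every pair with `|tau| >= threshold`, exactly one member. The default
#' keep policy drops the member with the larger mean absolute tau against
#' all other features (the more globally redundant one), ties broken
#' alphabetically. Deterministic given the table, threshold and policy.
#'
#' @param table Feature tibble; non-numeric columns (`id`, `label`) pass
#'   through untouched.
#' @param threshold Absolute-tau removal threshold in (0, 1\]; default 0.8.
#' @param keep_policy `"mean_abs_tau"` (default, as above) or `"first"`
#'   (keep the earlier column, drop the later one).
#' @return A list with `table` (filtered tibble) and `report`, a tibble of
#'   all pairs at or above the threshold (`feature_a`, `feature_b`, `tau`,
#'   `removed`).
#' @export
kendall_filter <- function(table, threshold = 0.8,
                           keep_policy = c("mean_abs_tau", "first")) {
  stopifnot(threshold > 0, threshold <= 1)
  keep_policy <- rlang::arg_match(keep_policy)
  meta_cols <- names(table)[!vapply(table, is.numeric, logical(1))]
  feats <- setdiff(names(table), meta_cols)
  x <- as.matrix(table[, feats, drop = FALSE])
  tau <- suppressWarnings(stats::cor(x, method = "kendall"))
  tau[is.na(tau)] <- 0
  mean_abs <- rowMeans(abs(tau) - diag(nrow(tau))) # exclude self-correlation
  names(mean_abs) <- feats
  pairs <- which(upper.tri(tau) & abs(tau) >= threshold, arr.ind = TRUE)
  removed <- character(0)
  report <- list()
  for (r in order(-abs(tau[pairs]))) {
    a <- feats[pairs[r, 1]]; b <- feats[pairs[r, 2]]
    if (a %in% removed || b %in% removed) {
      drop <- intersect(c(a, b), removed)[[1]] # pair already resolved
    } else {
      drop <- switch(keep_policy,
        first = b,
        mean_abs_tau = if (mean_abs[[a]] > mean_abs[[b]]) a
                       else if (mean_abs[[b]] > mean_abs[[a]]) b
                       else sort(c(a, b))[[2]])
      removed <- c(removed, drop)
    }
    report[[length(report) + 1]] <- tibble::tibble(
      feature_a = a, feature_b = b, tau = tau[pairs[r, 1], pairs[r, 2]],
      removed = drop)
  }
  report <- if (length(report)) dplyr::bind_rows(report)
            else tibble::tibble(feature_a = character(), feature_b = character(),
                                tau = numeric(), removed = character())
  list(table = table[, c(meta_cols, setdiff(feats, removed)), drop = FALSE],
       report = report)
}
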