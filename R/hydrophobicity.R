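#' The Eisenberg consensus hydrophobicity scale
#'
#' Per-residue consensus hydrophobicities (Eisenberg et al. 1984);
#' hydrophobic residues (Ile, Leu, Phe, Val) are positive, charged residues
#' (Arg, Lys, Asp, Glu) negative.
#' @return Named numeric vector over the 20 canonical residues.
#' @export
eisenberg_scale <- function() .EISENBERG

#' Mean Eisenberg hydrophobicity of a sequence
#'
#' @param sequence Canonical peptide string (non-empty).
#' @param scale Named per-residue hydrophobicity scale.
#' @return Numeric scalar: the arithmetic mean of the per-residue values.
#' @export
mean_hydrophobicity <- function(sequence, scale = eisenberg_scale()) {
  .check_canonical(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) == 0) rlang::abort("Empty sequence.")
  missing <- setdiff(unique(chars), names(scale))
  if (length(missing) > 0) {
    rlang::abort(sprintf("Residue '%s' missing from scale.", missing[[1]]))
  }
  mean(scale[chars])
}

#' Sequence (helical-wheel) hydrophobic moment
#'
#' Projects residues on an idealised helix with `delta` degrees of turn per
#' residue (100 for an alpha-helix) and sums the hydrophobicity-weighted
#' unit direction vectors: `mu = (sum H_n cos(n delta), sum H_n sin(n delta))`
#' for `n = 0..L-1`. A strongly amphipathic helix concentrates hydrophobic
#' residues on one face and yields a large magnitude.
#'
#' @param sequence Canonical peptide string.
#' @param scale Named per-residue hydrophobicity scale.
#' @param delta_degrees Helical turn per residue in degrees (default 100).
#' @return A list of class `moment_result`: `Ho` (raw magnitude, scale
#'   units), `per_residue` (`Ho / L`, the length-comparable default export)
#'   and `vector` (the 2-D components).
#' @examples
#' sequence_hydrophobic_moment("LKKLLKLLKKLLKL")$per_residue
#' @export
sequence_hydrophobic_moment <- function(sequence, scale = eisenberg_scale(),
                                        delta_degrees = 100) {
  .check_canonical(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) == 0) rlang::abort("Empty sequence.")
  h <- scale[chars]
  ang <- (seq_along(chars) - 1) * delta_degrees * pi / 180
  v <- c(sum(h * cos(ang)), sum(h * sin(ang)))
  ho <- sqrt(sum(v^2))
  structure(list(Ho = ho, per_residue = ho / length(chars), vector = v),
            class = "moment_result")
}

#' Structural hydrophobic moment from atomic coordinates
#'
#' When per-residue geometry is known, the moment is the magnitude of
#' `sum_n H_n S_n`, where `S_n` is the unit vector pointing from the
#' alpha-carbon to the side-chain centroid of residue n. Residues without a
#' resolved side chain (glycine) contribute zero and are reported.
#'
#' @param residues Tibble of residue geometry as produced by [read_pdb()]
#'   or [add_helix_coordinates()]: columns `residue`, `ca_x`, `ca_y`,
#'   `ca_z`, `sc_x`, `sc_y`, `sc_z`.
#' @param scale Named per-residue hydrophobicity scale.
#' @return A list of class `moment_result`: `Ho`, `per_residue`, 3-D
#'   `vector`, and `n_skipped` (residues without a defined direction).
#' @export
structural_hydrophobic_moment <- function(residues,
                                          scale = eisenberg_scale()) {
  stopifnot(is.data.frame(residues), nrow(residues) >= 1)
  need <- c("residue", "ca_x", "ca_y", "ca_z", "sc_x", "sc_y", "sc_z")
  missing_cols <- setdiff(need, names(residues))
  if (length(missing_cols) > 0) {
    rlang::abort(sprintf("Missing geometry columns: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  dirs <- cbind(residues$sc_x - residues$ca_x,
                residues$sc_y - residues$ca_y,
                residues$sc_z - residues$ca_z)
  ok <- stats::complete.cases(dirs)
  if (!any(ok)) rlang::abort("No residue has a defined side-chain direction.")
  h <- scale[residues$residue]
  v <- c(0, 0, 0)
  for (i in which(ok)) {
    s <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    v <- v + h[[i]] * s
  }
  ho <- sqrt(sum(v^2))
  structure(list(Ho = ho, per_residue = ho / nrow(residues), vector = v,
                 n_skipped = sum(!ok)),
            class = "moment_result")
}

#' @export
print.moment_result <- function(x, ...) {
  cat(sprintf("<moment_result> Ho = %.4f (%.4f per residue)\n",
              x$Ho, x$per_residue))
  invisible(x)
}
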