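# Synthetic labelled peptide sets with the distributional structure the
# classifier assumes: the CPP class is Arg/Lys-rich, cationic and
# amphipathic (hydrophobic residues concentrated on one face of an
# idealised 100-degree-per-residue helix), the non-CPP class is drawn from
# background residue frequencies. The generator encodes only these
# assumptions; it makes no claim of biological sequence realism.

# background residue frequencies (approximate proteome composition)
.BG_FREQ <- c(
  A = 0.074, R = 0.042, N = 0.044, D = 0.059, C = 0.033,
  Q = 0.037, E = 0.058, G = 0.074, H = 0.029, I = 0.038,
  L = 0.076, K = 0.072, M = 0.018, F = 0.040, P = 0.050,
  S = 0.081, T = 0.062, W = 0.013, Y = 0.033, V = 0.068)

# CPP-face pools: hydrophobic residues on the apolar face, cationic/polar
# residues (Arg/Lys elevated) elsewhere
.CPP_HYDRO <- c(L = 0.25, I = 0.15, F = 0.15, V = 0.12,
                W = 0.08, M = 0.08, A = 0.17)
.CPP_POLAR <- c(R = 0.30, K = 0.30, S = 0.07, T = 0.05, Q = 0.05,
                N = 0.05, G = 0.08, E = 0.02, D = 0.02, H = 0.03, P = 0.03)

#' Configuration of the synthetic peptide generator
#'
#' @param n_cpp,n_noncpp Records per class; defaults give the reference
#'   training scale of 300 + 300.
#' @param length_range Inclusive sequence-length bounds (default 5-30).
#' @param separation `"strong"` (fully structured CPP class), `"weak"`
#'   (each CPP position structured with probability 1/2) or `"none"`
#'   (both classes from background; classes indistinguishable).
#' @param delta_degrees Helical phase used to place the hydrophobic face.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_cpp = 300L, n_noncpp = 300L,
                             length_range = c(5L, 30L),
                             separation = c("strong", "weak", "none"),
                             delta_degrees = 100, seed = 1L) {
  separation <- rlang::arg_match(separation)
  if (n_cpp + n_noncpp <= 0) {
    rlang::abort("At least one class must have a positive count.")
  }
  stopifnot(length_range[1] >= 2, length_range[2] >= length_range[1])
  structure(list(n_cpp = as.integer(n_cpp), n_noncpp = as.integer(n_noncpp),
                 length_range = as.integer(length_range),
                 separation = separation, delta_degrees = delta_degrees,
                 seed = as.integer(seed)),
            class = "generator_config")
}

.sample_residue <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate a labelled synthetic peptide set
#'
#' @param config A [generator_config()].
#' @return Peptide tibble with `id`, `sequence`, `label`
#'   (`n_cpp + n_noncpp` rows, CPP first).
#' @examples
#' generate_peptides(generator_config(n_cpp = 3, n_noncpp = 3, seed = 7))
#' @export
generate_peptides <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, {
    lens_cpp <- sample(config$length_range[1]:config$length_range[2],
                       config$n_cpp, replace = TRUE)
    lens_non <- sample(config$length_range[1]:config$length_range[2],
                       config$n_noncpp, replace = TRUE)
    cpp <- vapply(lens_cpp, function(L) {
      if (config$separation == "none") {
        return(paste(.sample_residue(L, .BG_FREQ), collapse = ""))
      }
      ang <- (seq_len(L) - 1) * config$delta_degrees * pi / 180
      structured <- if (config$separation == "strong") rep(TRUE, L)
                    else stats::runif(L) < 0.5
      res <- character(L)
      hydro_face <- cos(ang) > 0.25
      for (i in seq_len(L)) {
        res[[i]] <- if (!structured[[i]]) .sample_residue(1, .BG_FREQ)
          else if (hydro_face[[i]]) .sample_residue(1, .CPP_HYDRO)
          else .sample_residue(1, .CPP_POLAR)
      }
      paste(res, collapse = "")
    }, character(1))
    non <- vapply(lens_non, function(L) {
      paste(.sample_residue(L, .BG_FREQ), collapse = "")
    }, character(1))
    tibble::tibble(
      id = c(sprintf("cpp_%03d", seq_len(config$n_cpp)),
             sprintf("non_%03d", seq_len(config$n_noncpp))),
      sequence = c(cpp, non),
      label = rep(c("CPP", "nonCPP"), c(config$n_cpp, config$n_noncpp)))
  })
}

#' Attach ideal alpha-helix coordinates to peptides
#'
#' Places each residue's alpha carbon on an ideal helix (rise 1.5 A,
#' 100 degrees per residue, radius 2.3 A) and the side-chain centroid
#' radially outward at +1.5 A; glycine gets no centroid. Consecutive
#' alpha carbons then sit ~3.8 A apart, and the structural hydrophobic
#' moment of these coordinates matches the helical-wheel construction.
#'
#' @param peptides Peptide tibble with a `sequence` column.
#' @param rise,radius,delta_degrees Helix geometry (A, A, degrees).
#' @return `peptides` with a `residues` list column of geometry tibbles.
#' @export
add_helix_coordinates <- function(peptides, rise = 1.5, radius = 2.3,
                                  delta_degrees = 100) {
  stopifnot(is.data.frame(peptides), "sequence" %in% names(peptides))
  peptides$residues <- purrr::map(peptides$sequence, function(s) {
    chars <- strsplit(s, "")[[1]]
    n <- seq_along(chars) - 1
    ang <- n * delta_degrees * pi / 180
    sc_r <- radius + 1.5
    gly <- chars == "G"
    tibble::tibble(
      residue = chars,
      ca_x = radius * cos(ang), ca_y = radius * sin(ang), ca_z = rise * n,
      sc_x = ifelse(gly, NA_real_, sc_r * cos(ang)),
      sc_y = ifelse(gly, NA_real_, sc_r * sin(ang)),
      sc_z = ifelse(gly, NA_real_, rise * n))
  })
  peptides
}

#' Class-separation score of a labelled peptide set
#'
#' A margin statistic used to calibrate the generator: the absolute
#' standardised difference (pooled-SD units) of the class means of the
#' combined Arg+Lys fraction and of the per-residue hydrophobic moment,
#' averaged over the two statistics. Indistinguishable classes score near
#' zero; the generator's `"strong"` setting scores well above 1.
#'
#' @param peptides Labelled peptide tibble (`sequence`, `label`).
#' @return A single non-negative number.
#' @export
class_separation_check <- function(peptides) {
  stopifnot(is.data.frame(peptides), "label" %in% names(peptides))
  if (length(unique(peptides$label)) < 2) {
    rlang::abort("Both classes must be present.")
  }
  stat <- purrr::map(peptides$sequence, function(s) {
    a <- aac_fractions(s)
    c(rk = a[["F[ARG]"]] + a[["F[LYS]"]],
      ho = sequence_hydrophobic_moment(s)$per_residue)
  })
  m <- do.call(rbind, stat)
  is_cpp <- peptides$label == "CPP"
  d <- vapply(colnames(m), function(col) {
    v1 <- m[is_cpp, col]; v2 <- m[!is_cpp, col]
    sp <- sqrt((stats::var(v1) * (length(v1) - 1) +
                stats::var(v2) * (length(v2) - 1)) /
               (length(v1) + length(v2) - 2))
    if (sp == 0) 0 else abs(mean(v1) - mean(v2)) / sp
  }, numeric(1))
  mean(d)
}
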