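test_that("the embedded consensus scale has the expected signs", {
  sc <- eisenberg_scale()
  expect_length(sc, 20)
  expect_true(all(sc[c("I", "L", "F", "V")] > 0))
  expect_true(all(sc[c("R", "K", "D", "E")] < 0))
})

test_that("mean hydrophobicity is an arithmetic mean", {
  sc <- eisenberg_scale()
  expect_equal(mean_hydrophobicity("LLLL"), sc[["L"]])
  expect_lt(mean_hydrophobicity("RKRKRK"), 0)
  s1 <- "GRK"; s2 <- "LLFAV"
  expect_equal(mean_hydrophobicity(paste0(s1, s2)),
               (3 * mean_hydrophobicity(s1) + 5 * mean_hydrophobicity(s2)) / 8)
})

test_that("sequence moment follows the helical-wheel geometry", {
  sc <- eisenberg_scale()
  expect_equal(sequence_hydrophobic_moment("A")$Ho, abs(sc[["A"]]))
  # two unit vectors 100 degrees apart: |v| = 2 cos(50 deg) * H
  expect_equal(sequence_hydrophobic_moment("AA")$Ho,
               abs(sc[["A"]]) * 2 * cos(50 * pi / 180))
  # 18 residues span exactly five turns: the vector sum vanishes
  expect_equal(sequence_hydrophobic_moment(strrep("L", 18))$Ho, 0,
               tolerance = 1e-9)
})

test_that("sequence moment matches a complex-arithmetic oracle and is
           phase-rotation invariant", {
  sc <- eisenberg_scale()
  for (s in random_peptides(10, seed = 61)) {
    chars <- strsplit(s, "")[[1]]
    n <- seq_along(chars) - 1
    for (phase in c(0, 0.7, 2.1)) {
      z <- sum(sc[chars] * exp(1i * (n * 100 * pi / 180 + phase)))
      expect_equal(sequence_hydrophobic_moment(s)$Ho, Mod(z),
                   tolerance = 1e-9)
    }
    expect_lte(sequence_hydrophobic_moment(s)$Ho,
               sum(abs(sc[chars])) + 1e-12)
  }
})

test_that("structural moment handles parallel, antiparallel and the
           frozen three-residue case", {
  geo <- function(res, ca, sc) tibble::tibble(
    residue = res, ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
    sc_x = sc[1], sc_y = sc[2], sc_z = sc[3])
  # all directions identical, H > 0: Ho = L * h
  par3 <- dplyr::bind_rows(
    geo("L", c(0, 0, 0), c(1, 0, 0)),
    geo("L", c(5, 5, 5), c(9, 5, 5)),
    geo("L", c(1, 2, 3), c(3, 2, 3)))
  expect_equal(structural_hydrophobic_moment(par3)$Ho,
               3 * eisenberg_scale()[["L"]])
  # equal H, antiparallel directions cancel
  anti <- dplyr::bind_rows(
    geo("V", c(0, 0, 0), c(1, 0, 0)),
    geo("V", c(0, 0, 0), c(-2, 0, 0)))
  expect_equal(structural_hydrophobic_moment(anti)$Ho, 0)
  # hand-computed: S = (1,0,0), (0,1,0), (0,0,1) with H(A), H(L), H(K)
  tri <- dplyr::bind_rows(
    geo("A", c(0, 0, 0), c(1, 0, 0)),
    geo("L", c(0, 0, 0), c(0, 2, 0)),
    geo("K", c(1, 1, 1), c(1, 1, 3)))
  expect_equal(structural_hydrophobic_moment(tri)$Ho, 1.9385561,
               tolerance = 1e-6)
})

test_that("structural moment is invariant under rigid motion", {
  peps <- add_helix_coordinates(
    tibble::tibble(sequence = random_peptides(5, c(6L, 20L), seed = 71)))
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(11, -4, 7)
  for (geo in peps$residues) {
    before <- structural_hydrophobic_moment(geo)$Ho
    ca <- as.matrix(geo[, c("ca_x", "ca_y", "ca_z")]) %*% t(R)
    sc <- as.matrix(geo[, c("sc_x", "sc_y", "sc_z")]) %*% t(R)
    moved <- geo
    moved[, c("ca_x", "ca_y", "ca_z")] <- sweep(ca, 2, shift, "+")
    moved[, c("sc_x", "sc_y", "sc_z")] <- sweep(sc, 2, shift, "+")
    expect_equal(structural_hydrophobic_moment(moved)$Ho, before,
                 tolerance = 1e-9)
  }
})

test_that("glycine-only geometry is rejected; glycines are skipped", {
  gly <- tibble::tibble(residue = "G", ca_x = 0, ca_y = 0, ca_z = 0,
                        sc_x = NA_real_, sc_y = NA_real_, sc_z = NA_real_)
  expect_error(structural_hydrophobic_moment(gly), "No residue")
  mix <- add_helix_coordinates(tibble::tibble(sequence = "GLGLG"))
  res <- structural_hydrophobic_moment(mix$residues[[1]])
  expect_equal(res$n_skipped, 3)
})
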