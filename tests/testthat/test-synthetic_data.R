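test_that("the generator hits the requested scale and bounds", {
  cfg <- generator_config(seed = 13)      # reference defaults: 300 + 300
  peps <- generate_peptides(cfg)
  expect_equal(nrow(peps), 600)
  expect_equal(sum(peps$label == "CPP"), 300)
  expect_true(all(nchar(peps$sequence) >= 5 & nchar(peps$sequence) <= 30))
  expect_error(generator_config(n_cpp = 0, n_noncpp = 0), "positive")
})

test_that("generation is byte-identical under one seed", {
  cfg <- generator_config(n_cpp = 25L, n_noncpp = 25L, seed = 99)
  p1 <- generate_peptides(cfg)
  p2 <- generate_peptides(cfg)
  expect_identical(p1, p2)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(p1, f1); write_fasta(p2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  p3 <- generate_peptides(generator_config(n_cpp = 25L, n_noncpp = 25L,
                                           seed = 100))
  expect_false(identical(p1$sequence, p3$sequence))
})

test_that("helix coordinates have the ideal alpha-carbon spacing", {
  peps <- add_helix_coordinates(
    tibble::tibble(sequence = random_peptides(6, c(6L, 25L), seed = 3)))
  for (geo in peps$residues) {
    d <- sqrt(diff(geo$ca_x)^2 + diff(geo$ca_y)^2 + diff(geo$ca_z)^2)
    expect_true(all(abs(d - 3.8) < 0.1))
  }
})

test_that("helix geometry reproduces the moment cancellation at 18 residues", {
  g18 <- add_helix_coordinates(tibble::tibble(sequence = strrep("L", 18)))
  expect_lt(structural_hydrophobic_moment(g18$residues[[1]])$Ho, 1e-9)
  g7 <- add_helix_coordinates(tibble::tibble(sequence = strrep("L", 7)))
  expect_gt(structural_hydrophobic_moment(g7$residues[[1]])$Ho, 0.1)
})

test_that("separation settings order the class-separation score", {
  strong <- generate_peptides(generator_config(n_cpp = 150L, n_noncpp = 150L,
                                               separation = "strong", seed = 7))
  none <- generate_peptides(generator_config(n_cpp = 150L, n_noncpp = 150L,
                                             separation = "none", seed = 7))
  s_strong <- class_separation_check(strong)
  s_none <- class_separation_check(none)
  expect_gt(s_strong, 1)          # documented calibration threshold
  expect_lt(s_none, 0.35)
  # label permutation destroys the separation
  set.seed(5)
  permuted <- strong
  permuted$label <- sample(permuted$label)
  expect_lt(class_separation_check(permuted), 0.35)
  expect_error(class_separation_check(strong[strong$label == "CPP", ]),
               "Both classes")
})

test_that("the CPP class is Arg/Lys-enriched by construction", {
  peps <- generate_peptides(generator_config(n_cpp = 100L, n_noncpp = 100L,
                                             seed = 23))
  rk <- vapply(peps$sequence, function(s) {
    a <- aac_fractions(s); a[["F[ARG]"]] + a[["F[LYS]"]]
  }, numeric(1))
  expect_gt(mean(rk[peps$label == "CPP"]), mean(rk[peps$label == "nonCPP"]))
})
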