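test_that("peptide graphs have the hand-enumerated formulas", {
  expect_equal(molecular_formula(build_peptide_graph("G")), "C2H5NO2")
  expect_equal(molecular_formula(build_peptide_graph("GG")), "C4H8N2O3")
  # free arginine C6H14N4O2
  g <- build_peptide_graph("R")
  expect_equal(molecular_formula(g), "C6H14N4O2")
  expect_equal(element_count(g, "N"), 4)
})

test_that("element counts match the GG enumeration and reject junk", {
  g <- build_peptide_graph("GG")
  expect_equal(element_count(g, "N"), 2)
  expect_equal(element_count(g, "O"), 3)
  expect_equal(element_count(g, "H"), 8)
  expect_equal(element_count(g, "Se"), 0)
  expect_error(element_count(g, "Xx"), "Unknown element")
  expect_error(build_peptide_graph("GBG"), "position 2")
})

test_that("physicochemical descriptors reproduce frozen golden values", {
  # golden MW/tPSA/cLogP computed before the build with an independent
  # cheminformatics toolkit on the same neutral linear peptides
  gold <- tibble::tribble(
    ~seq,                    ~MW,       ~tPSA,   ~cLogP,
    "GG",                    132.119,   92.42,   -1.8541,
    "GF",                    222.244,   92.42,   -0.2428,
    "KKDE",                  518.568,   277.26,  -2.5498,
    "RRGGG",                 501.549,   303.52,  -5.24176,
    "ACDEFGHIKLMNPQRSTVWY",  2395.756,  961.29,  -7.67533,
    "KPRW",                  585.710,   245.54,  -0.52483,
    "GRKKRRQRRRPPQ",         1719.047,  904.56,  -11.77168)
  for (i in seq_len(nrow(gold))) {
    d <- physchem_descriptors(build_peptide_graph(gold$seq[[i]]))
    expect_equal(d$MW, gold$MW[[i]], tolerance = 1e-5)
    expect_equal(d$tPSA, gold$tPSA[[i]], tolerance = 1e-6)
    expect_equal(d$cLogP, gold$cLogP[[i]], tolerance = 1e-4)
  }
})

test_that("hybridisation and ring descriptors follow hand assignment", {
  d <- physchem_descriptors(build_peptide_graph("GG"))
  expect_equal(d$Fsp3, 0.5)      # 2 sp3 of 4 carbons (carbonyls are sp2)
  expect_equal(d$NAR, 0)
  expect_equal(physchem_descriptors(build_peptide_graph("GF"))$NAR, 1)
  expect_equal(physchem_descriptors(build_peptide_graph("WW"))$NAR, 4)
})

test_that("polar group counts follow the side-chain convention", {
  expect_equal(polar_group_descriptors("KKDE"),
               tibble::tibble(NetC = 0L, NPA = 3L, NG = 0L, NNCAA = 2L))
  expect_equal(polar_group_descriptors("RRG")$NG, 2L)
  expect_equal(polar_group_descriptors("GGGGG"),
               tibble::tibble(NetC = 0L, NPA = 1L, NG = 0L, NNCAA = 0L))
  expect_equal(polar_group_descriptors("K", charged_n_terminus = TRUE,
                                       charged_c_terminus = TRUE)$NetC, 1L)
})

test_that("atom counts and mass are additive under condensation", {
  seqs <- random_peptides(12, c(2L, 12L), seed = 11)
  h2o <- 2 * 1.008 + 15.999
  for (i in seq(1, 11, by = 2)) {
    s1 <- seqs[[i]]; s2 <- seqs[[i + 1]]
    g1 <- build_peptide_graph(s1); g2 <- build_peptide_graph(s2)
    g12 <- build_peptide_graph(paste0(s1, s2))
    expect_equal(element_count(g12, "N"),
                 element_count(g1, "N") + element_count(g2, "N"))
    expect_equal(element_count(g12, "O"),
                 element_count(g1, "O") + element_count(g2, "O") - 1)
    expect_equal(physchem_descriptors(g12)$MW,
                 physchem_descriptors(g1)$MW + physchem_descriptors(g2)$MW -
                   h2o,
                 tolerance = 1e-6)
  }
})

test_that("HBA >= HBD and nitrogen matches the per-residue table oracle", {
  side_n <- c(A = 0, C = 0, D = 0, E = 0, F = 0, G = 0, H = 2, I = 0,
              K = 1, L = 0, M = 0, N = 1, P = 0, Q = 1, R = 3, S = 0,
              T = 0, V = 0, W = 1, Y = 0)
  for (s in random_peptides(20, seed = 21)) {
    g <- build_peptide_graph(s)
    d <- physchem_descriptors(g)
    expect_gte(d$HBA, d$HBD)
    chars <- strsplit(s, "")[[1]]
    expect_equal(element_count(g, "N"),
                 length(chars) + sum(side_n[chars]))
  }
})

test_that("the descriptor table carries the full exported column set", {
  tab <- structure_descriptors(
    tibble::tibble(id = "t", label = "CPP", sequence = "GRKKRRQRRRPPQ"))
  expect_named(tab, c("id", "label", "MW", "tPSA", "NRB", "Fsp3", "cLogP",
                      "HBD", "HBA", "NAR", "NetC", "NPA", "NG", "NNCAA",
                      "N", "O"))
  expect_equal(tab$N, 35L)  # matches formula C70H131N35O16
  expect_equal(tab$O, 16L)
})
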