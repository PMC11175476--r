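test_that("the eight composition cardinalities are exact", {
  sizes_base <- vapply(c("FC-SEQ", "FC-STR", "FC-SEQ-STR", "FC-Kendall"),
                       function(n) length(assemble_fc(n, "baseline")$descriptors),
                       integer(1))
  sizes_noho <- vapply(c("FC-SEQ", "FC-STR", "FC-SEQ-STR", "FC-Kendall"),
                       function(n) length(assemble_fc(n, "+NOHo")$descriptors),
                       integer(1))
  expect_equal(unname(sizes_base), c(64L, 12L, 76L, 43L))
  expect_equal(unname(sizes_noho), c(63L, 13L, 77L, 44L))
})

test_that("variant membership changes follow the redundancy outcomes", {
  str_noho <- assemble_fc("FC-STR", "+NOHo")$descriptors
  expect_true(all(c("N", "O", "Ho") %in% str_noho))
  expect_false(any(c("HBD", "MW") %in% str_noho))
  expect_false("F[ARG]" %in% assemble_fc("FC-SEQ", "+NOHo")$descriptors)
  kend <- assemble_fc("FC-Kendall", "+NOHo")$descriptors
  expect_false(any(c("F[ARG]", "MW") %in% kend))
  expect_true(all(c("N", "O", "Ho") %in% kend))
  # Kendall baseline: structure block without tPSA/NRB/HBD, ten motif DPCs
  kb <- assemble_fc("FC-Kendall", "baseline")$descriptors
  expect_false(any(c("tPSA", "NRB", "HBD") %in% kb))
  expect_length(grep("^DPC_", kb), 10)
  expect_error(assemble_fc("FC-NOPE"), "must be one of")
})

test_that("feature extraction returns the composition's columns in order", {
  peps <- tibble::tibble(id = c("a", "b"), label = c("CPP", "nonCPP"),
                         sequence = c("GRKKRRQRRRPPQ", "GLFGAIAGFIE"))
  ft <- extract_features(peps, "FC-STR", "+NOHo")
  expect_equal(names(ft),
               c("id", "label", assemble_fc("FC-STR", "+NOHo")$descriptors))
  ft2 <- extract_features(peps, "FC-SEQ", "baseline")
  expect_equal(ncol(ft2), 2 + 64)
})

test_that("kendall_tau is tau-b: agrees with a pair-count oracle on ties", {
  tau_oracle <- function(x, y) {
    n <- length(x); conc <- disc <- tx <- ty <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
    n0 <- n * (n - 1) / 2
    (conc - disc) / sqrt((n0 - .tiecount(x)) * (n0 - .tiecount(y)))
  }
  .tiecount <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  expect_equal(kendall_tau(1:3, 1:3), 1)
  expect_equal(kendall_tau(1:3, 3:1), -1)
  set.seed(81)
  for (rep in 1:20) {
    x <- sample(1:5, 12, replace = TRUE)
    y <- sample(1:5, 12, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y), tau_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("kendall_tau symmetry, antisymmetry and constant-input warning", {
  set.seed(91)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(kendall_tau(x, x), 1)
  expect_equal(kendall_tau(x, y), kendall_tau(y, x))
  expect_equal(kendall_tau(x, -y), -kendall_tau(x, y))
  expect_warning(out <- kendall_tau(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
})

test_that("kendall_filter removes duplicates and constructed dependences
           but keeps independent columns", {
  set.seed(101)
  n <- 200
  tab <- tibble::tibble(
    id = as.character(1:n), label = rep(c("CPP", "nonCPP"), n / 2),
    a = rnorm(n), b = rnorm(n), c = rnorm(n))
  tab$dup <- tab$a
  res <- kendall_filter(tab, threshold = 0.8)
  expect_true(xor("a" %in% names(res$table), "dup" %in% names(res$table)))
  expect_true(all(c("b", "c") %in% names(res$table)))
  expect_true(all(abs(res$report$tau) >= 0.8))

  # MW constructed as a monotone function of N + O forces tau = 1
  tab2 <- tibble::tibble(id = as.character(1:n),
                         NO = sample(10:40, n, replace = TRUE))
  tab2$MW <- 75 + 57.1 * tab2$NO
  res2 <- kendall_filter(tab2, threshold = 0.8)
  expect_equal(ncol(res2$table) - 1, 1)
  expect_equal(nrow(res2$report), 1)
  expect_equal(res2$report$tau, 1)

  # deterministic, and removed + retained partition the feature set
  res3 <- kendall_filter(tab, threshold = 0.8)
  expect_identical(res$table, res3$table)
  expect_setequal(c(setdiff(names(res$table), c("id", "label")),
                    unique(res$report$removed)),
                  c("a", "b", "c", "dup"))
})
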