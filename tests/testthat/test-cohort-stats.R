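test_that("descriptives follow their closed forms", {
  d <- describeValues(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$median, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$cv, 50)
  expect_equal(d$n, 3)

  const <- describeValues(rep(4, 5))
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_error(describeValues(numeric(0)), "empty")

  # permutation invariance; sd shift invariance
  set.seed(1)
  x <- stats::rnorm(20)
  expect_equal(describeValues(sample(x)), describeValues(x))
  expect_equal(describeValues(x + 100)$sd, describeValues(x)$sd)
})

test_that("Mann-Whitney handles separation, symmetry and ties", {
  sep <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(sep$parameter), 0)   # complete separation: U = 0
  # exact one-sided tail mass of U = 0 over the 6-choose-3 = 20 splits
  expect_equal(1 / choose(6, 3), 0.05)

  same <- mannWhitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)

  ident <- mannWhitney(rep(2, 4), rep(2, 4))
  expect_equal(ident$p.value, 1)           # zero variance convention

  # tie-corrected z matches wilcox.test's normal approximation
  set.seed(5)
  for (i in 1:20) {
    a <- sample(1:6, 12, replace = TRUE)
    b <- sample(1:6, 9, replace = TRUE)
    mw <- mannWhitney(a, b)
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = FALSE))
    expect_equal(mw$p.value, wt$p.value, tolerance = 1e-12)
  }

  # invariant under strictly monotone transforms of the pooled data
  a <- c(0.3, 1.7, 2.2, 5); b <- c(0.9, 1.1, 4)
  expect_equal(mannWhitney(exp(a), exp(b))$statistic,
               mannWhitney(a, b)$statistic)
  expect_error(mannWhitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney z matches the exact-enumeration oracle", {
  set.seed(11)
  for (i in 1:30) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    a <- sample(1:5, n1, replace = TRUE)   # heavy ties on purpose
    b <- sample(1:5, n2, replace = TRUE)
    z <- unname(mannWhitney(a, b)$statistic)
    expect_equal(z, mwEnumOracleZ(a, b), tolerance = 1e-9)
  }
})

test_that("null p-values are near-uniform at n = (10, 10)", {
  set.seed(99)
  p <- replicate(5000, mannWhitney(stats::rnorm(10), stats::rnorm(10))$p.value)
  n <- length(p); s <- sort(p)
  ks <- max(seq_len(n) / n - s, s - (seq_len(n) - 1) / n)
  expect_lt(ks, 0.05)
})

test_that("Spearman rho, t conversion and symmetry behave", {
  mono <- spearmanRank(1:10, (1:10)^3)
  expect_equal(unname(mono$estimate), 1)
  expect_true(is.infinite(unname(mono$statistic)))
  expect_equal(mono$p.value, 0)

  set.seed(3)
  x <- stats::rnorm(15); y <- stats::rnorm(15)
  xy <- spearmanRank(x, y)
  yx <- spearmanRank(y, x)
  expect_equal(xy$estimate, yx$estimate)
  expect_gte(unname(xy$estimate), -1)
  expect_lte(unname(xy$estimate), 1)
  expect_equal(unname(xy$estimate),
               unname(stats::cor.test(x, y, method = "spearman")$estimate),
               tolerance = 1e-12)
  # t reproduces rho through the closed form
  expect_equal(unname(xy$statistic),
               spearmanT(unname(xy$estimate), 15))

  expect_error(spearmanRank(1:2, 2:1), "3 pairs")
  expect_error(spearmanRank(rep(1, 5), 1:5), "zero variance")
})

test_that("2x2 chi-square matches the direct expected-counts oracle", {
  flat <- chiSquare2x2(matrix(10, 2, 2))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p.value, 1)

  diag <- chiSquare2x2(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(unname(diag$statistic), 40)

  set.seed(21)
  for (i in 1:100) {
    m <- matrix(sample(1:40, 4, replace = TRUE), 2, 2)
    got <- suppressWarnings(chiSquare2x2(m))   # small-count warnings expected
    expect_equal(unname(got$statistic), chisqOracle(m), tolerance = 1e-9)
  }
  expect_error(chiSquare2x2(matrix(c(0, 0, 3, 4), 2, 2)), "zero margin")
})

test_that("the cohort statistics block has the published tables' shape", {
  set.seed(8)
  n <- 24
  rows <- data.frame(
    subject_id = sprintf("x%02d", 1:n),
    group = rep(c("study", "control"), each = n / 2),
    bruxism_index = c(stats::runif(n / 2, 3, 9), stats::runif(n / 2, 0, 2)),
    mean_hr = stats::rnorm(n, 60, 5),
    n_total = sample(20:120, n, TRUE),
    n_tonic = sample(5:60, n, TRUE),
    n_phasic = sample(5:40, n, TRUE),
    n_mixed = sample(0:10, n, TRUE)
  )
  st <- cohortStats(rows)
  expect_named(st, c("descriptives", "correlations"))
  bi <- st$descriptives$bruxism_index
  expect_equal(bi$by_group$study$n, n / 2)
  expect_true(bi$comparison$p < 0.001)   # groups built disjoint
  expect_named(st$correlations$study, c("n_phasic", "n_tonic", "n_mixed"))
  ct <- st$correlations$control$n_tonic
  expect_equal(ct$t, spearmanT(ct$rho, n / 2), tolerance = 1e-9)
})
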