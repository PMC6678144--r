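test_that("diagnosis is strictly greater-than the 2/h cut-off", {
  expect_equal(diagnose(2.60), "positive")   # lowest published study index
  expect_equal(diagnose(2.40), "positive")   # highest published control index
  expect_equal(diagnose(2.00), "negative")   # boundary is strict
  expect_equal(diagnose(0), "negative")
  expect_error(diagnose(-1), "non-negative")

  # monotone in the index
  idx <- sort(stats::runif(50, 0, 6))
  calls <- diagnose(idx)
  expect_false(is.unsorted(rev(calls == "negative")))
})

test_that("confusion table cross-tabulates against the clinical reference", {
  device <- rep(c("positive", "negative"), c(41, 19))
  clinical <- c(rep("positive", 35), rep("negative", 6), rep("negative", 19))
  ct <- confusionTable(device, clinical)
  expect_equal(c(ct@tp, ct@fn, ct@fp, ct@tn), c(35, 0, 6, 19))

  agree <- confusionTable(c("positive", "negative"),
                          c("positive", "negative"))
  expect_equal(c(agree@fp, agree@fn), c(0, 0))

  expect_error(confusionTable("positive", c("positive", "negative")),
               "equal length")
  expect_error(confusionTable("yes", "positive"), "labels")
})

test_that("confusion table matches brute-force counting on random cohorts", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(1:40, 1)
    dev <- sample(c("positive", "negative"), n, replace = TRUE)
    cli <- sample(c("positive", "negative"), n, replace = TRUE)
    ct <- confusionTable(dev, cli)
    want <- c(tp = 0, fn = 0, fp = 0, tn = 0)
    for (j in seq_len(n)) {
      cell <- if (cli[j] == "positive") {
        if (dev[j] == "positive") "tp" else "fn"
      } else {
        if (dev[j] == "positive") "fp" else "tn"
      }
      want[cell] <- want[cell] + 1
    }
    expect_equal(c(ct@tp, ct@fn, ct@fp, ct@tn), unname(want))
  }
})

test_that("sensitivity and specificity follow their definitions", {
  ct <- function(tp, fn, fp, tn) new("ConfusionTable", tp = tp, fn = fn,
                                     fp = fp, tn = tn)
  expect_equal(sensitivity(ct(35, 0, 6, 19)), 100)
  expect_equal(specificity(ct(35, 0, 6, 19)), 76)
  expect_equal(sensitivity(ct(1, 1, 1, 1)), 50)
  expect_equal(specificity(ct(1, 1, 1, 1)), 50)
  expect_true(is.na(sensitivity(ct(0, 0, 5, 5))))
  expect_equal(specificity(ct(0, 0, 5, 5)), 50)

  # invariant under scaling all cells
  expect_equal(sensitivity(ct(3 * 35, 0, 3 * 6, 3 * 19)), 100)
  expect_equal(specificity(ct(3 * 35, 0, 3 * 6, 3 * 19)), 76)

  acc <- diagnosticAccuracy(ct(35, 0, 6, 19))
  expect_equal(sensitivity(acc), 100)
  expect_equal(specificity(acc), 76)
})

test_that("cut-off match rate counts strict exceedances", {
  control <- c(rep(2.4, 6), rep(1.0, 19))
  expect_equal(cutoffMatchRate(control, 2), 24)
  expect_equal(cutoffMatchRate(rep(3, 10), 2), 100)
  expect_equal(cutoffMatchRate(rep(0, 5), 2), 0)
  expect_error(cutoffMatchRate(numeric(0), 2), "empty")

  # non-increasing in the cut-off
  idx <- stats::runif(30, 0, 8)
  rates <- vapply(c(0, 1, 2, 4, 6), function(co) cutoffMatchRate(idx, co),
                  numeric(1))
  expect_false(is.unsorted(rev(rates)))
})
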