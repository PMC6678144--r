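## Descriptive and nonparametric cohort statistics: the per-variable
## descriptives (with coefficient of variation), tie-corrected Mann-Whitney z,
## Spearman rank correlation with its t conversion, and the 2x2 chi-square.
## Alpha is 0.05 two-sided throughout, with no multiple-testing correction
## (a documented limitation); normality screening is skipped because the
## nonparametric route is always taken.

#' Descriptive statistics of one variable
#'
#' @param values numeric vector (n >= 1; sd needs n >= 2).
#' @return one-row data.frame with `n`, `min`, `max`, `mean`, `median`,
#'   `sd` (sample, n-1) and `cv` (100 * sd / mean, %; NA when the mean is 0).
#' @export
describeValues <- function(values) {
  if (!length(values)) stop("empty input")
  s <- if (length(values) >= 2L) stats::sd(values) else NA_real_
  m <- mean(values)
  data.frame(n = length(values), min = min(values), max = max(values),
             mean = m, median = stats::median(values), sd = s,
             cv = if (!is.na(s) && m != 0) 100 * s / m else NA_real_)
}

#' Mann-Whitney two-group comparison
#'
#' U statistic with midranks for ties and the tie-corrected normal
#' approximation: `z = (U - n1 n2 / 2) / sd(U)` with
#' `var(U) = n1 n2 / 12 * (N + 1 - sum(t^3 - t) / (N (N - 1)))`,
#' no continuity correction, two-sided p. When every pooled value is
#' identical the variance is zero and z = 0, p = 1 by convention.
#'
#' @param a,b numeric samples (both non-empty).
#' @return an object of class `htest` with `statistic` (z), `parameter`
#'   (U), `p.value`, and per-group sizes in `sample.size`.
#' @export
mannWhitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tt <- table(c(a, b))
  tieCorr <- if (N > 1) sum(tt^3 - tt) / (N * (N - 1)) else 0
  v <- n1 * n2 / 12 * (N + 1 - tieCorr)
  if (v <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (U - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(
    statistic = c(z = z), parameter = c(U = U), p.value = p,
    sample.size = c(n1 = n1, n2 = n2),
    method = "Mann-Whitney test (tie-corrected normal approximation)",
    data.name = "a and b"), class = "htest")
}

#' Spearman t conversion
#'
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`, referred to a t distribution
#' with n - 2 degrees of freedom. `rho = +-1` gives an infinite t (p -> 0).
#'
#' @param rho Spearman rank correlation.
#' @param n number of pairs (>= 3).
#' @return the t statistic.
#' @export
spearmanT <- function(rho, n) {
  if (n < 3L) stop("need at least 3 pairs")
  if (abs(rho) >= 1) return(sign(rho) * Inf)
  rho * sqrt((n - 2) / (1 - rho^2))
}

#' Spearman rank correlation with t-based significance
#'
#' rho is the Pearson correlation of midranks; significance comes from the
#' [spearmanT()] conversion with n - 2 degrees of freedom, two-sided.
#'
#' @param x,y paired numeric vectors (n >= 3, non-degenerate).
#' @return an `htest` with `estimate` (rho), `statistic` (t), `parameter`
#'   (df), `p.value` and `sample.size`.
#' @export
spearmanRank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  rho <- stats::cor(x, y, method = "spearman")
  if (1 - abs(rho) < 1e-12) rho <- sign(rho)   # exact monotone ties-free case
  t <- spearmanT(rho, n)
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), df = n - 2)
  structure(list(
    estimate = c(rho = rho), statistic = c(t = t),
    parameter = c(df = n - 2), p.value = p,
    sample.size = c(n = n),
    method = "Spearman rank correlation (t approximation)",
    data.name = "x and y"), class = "htest")
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' No continuity correction, 1 degree of freedom. All expected counts must
#' be positive.
#'
#' @param table 2x2 matrix of counts.
#' @return the `htest` from [stats::chisq.test()] (correct = FALSE).
#' @export
chiSquare2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin")
  res <- stats::chisq.test(table, correct = FALSE)
  if (any(res$expected <= 0)) stop("all expected counts must be positive")
  res
}

#' Cohort statistics block
#'
#' Replicates the shape of the published cohort tables from per-subject
#' summary rows: per-variable descriptives by group with the between-group
#' Mann-Whitney comparison, and the within-group rank correlation of each
#' contraction type against the bruxism index.
#'
#' @param rows data.frame of per-subject summary rows (see
#'   [as.data.frame.SubjectSummary()]) with a `group` column.
#' @param variables summary variables to describe and compare.
#' @return a list with `descriptives` (one element per variable: per-group
#'   describe rows plus z and p) and `correlations` (per group: rho, t, p of
#'   each contraction count vs the index).
#' @export
cohortStats <- function(rows,
                        variables = c("bruxism_index", "mean_hr", "n_total",
                                      "n_phasic", "n_tonic", "n_mixed")) {
  stopifnot(is.data.frame(rows), "group" %in% names(rows))
  groups <- c("study", "control")
  desc <- list()
  for (v in intersect(variables, names(rows))) {
    byg <- lapply(groups, function(g) describeValues(rows[[v]][rows$group == g]))
    names(byg) <- groups
    cmp <- if (all(vapply(byg, function(d) d$n > 0, logical(1)))) {
      mw <- mannWhitney(rows[[v]][rows$group == "study"],
                        rows[[v]][rows$group == "control"])
      list(z = unname(mw$statistic), p = mw$p.value)
    } else NULL
    desc[[v]] <- list(by_group = byg, comparison = cmp)
  }
  cors <- list()
  for (g in groups) {
    sub <- rows[rows$group == g, , drop = FALSE]
    if (nrow(sub) < 3L) next
    cg <- list()
    for (v in intersect(c("n_phasic", "n_tonic", "n_mixed"), names(sub))) {
      res <- tryCatch(spearmanRank(sub[[v]], sub$bruxism_index),
                      error = function(e) NULL)
      if (!is.null(res))
        cg[[v]] <- list(rho = unname(res$estimate),
                        t = unname(res$statistic), p = res$p.value)
    }
    cors[[g]] <- cg
  }
  list(descriptives = desc, correlations = cors)
}
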