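# Independent brute-force oracles, deliberately naive and separate from the
# implementation they check.

# Mann-Whitney: exact permutation mean/sd of U by full enumeration of all
# choose(N, n1) group assignments of the pooled values, then the normal-
# approximation z of the observed U.
mwEnumOracleZ <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled)
  n1 <- length(a)
  r <- rank(pooled)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uObs <- uOf(seq_len(n1))
  all <- utils::combn(N, n1)
  us <- apply(all, 2, uOf)
  mu <- mean(us)
  sdev <- sqrt(mean((us - mu)^2))   # population sd of the exact null
  if (sdev == 0) return(0)
  (uObs - mu) / sdev
}

# Pearson chi-square from the definition
chisqOracle <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

# naive event grouping: transitive closure over the "gap < eventGap"
# relation between consecutive time-sorted bursts
naiveGroup <- function(bursts, eventGap = 3) {
  bursts <- bursts[order(bursts$onset), , drop = FALSE]
  n <- nrow(bursts)
  if (!n) return(list())
  groups <- list(1L)
  for (i in seq_len(n)[-1L]) {
    last <- groups[[length(groups)]]
    if (bursts$onset[i] - max(bursts$offset[last]) < eventGap) {
      groups[[length(groups)]] <- c(last, i)
    } else {
      groups[[length(groups) + 1L]] <- i
    }
  }
  groups
}

# naive classification from first principles
naiveClassify <- function(durs, tonicMin = 2, phasicBounds = c(0.25, 2),
                          phasicMin = 3) {
  hasTonic <- any(durs > tonicMin)
  nPhasic <- sum(durs >= phasicBounds[1] & durs <= phasicBounds[2])
  hasPhasic <- nPhasic >= phasicMin
  if (hasTonic && hasPhasic) return("mixed")
  if (hasTonic) return("tonic")
  if (hasPhasic) return("phasic")
  "unclassified"
}

# random non-overlapping burst set for the grouping oracle
randomBursts <- function(n, span = 120) {
  on <- sort(stats::runif(n, 0, span))
  dur <- stats::runif(n, 0.1, 3)
  off <- on + dur
  # enforce non-overlap by pushing forward
  for (i in seq_len(n)[-1L]) {
    if (on[i] < off[i - 1L]) {
      shift <- off[i - 1L] - on[i] + stats::runif(1, 0.01, 0.3)
      on[i] <- on[i] + shift
      off[i] <- off[i] + shift
    }
  }
  data.frame(onset = on, offset = off, peak = stats::runif(n, 11, 80),
             channel = "EMG_LEFT", stringsAsFactors = FALSE)
}
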