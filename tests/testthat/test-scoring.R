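test_that("burst detection applies threshold, duration and hysteresis rules", {
  cfg <- scoringConfig()

  quiet <- pctProfile(10, list())
  expect_equal(nrow(detectBursts(quiet, cfg)), 0)

  one <- pctProfile(10, list(c(3, 5.5, 40)))
  b <- detectBursts(one, cfg)
  expect_equal(nrow(b), 1)
  expect_equal(b$offset - b$onset, 2.5, tolerance = 0.1)
  expect_equal(b$peak, 40)

  spike <- pctProfile(10, list(c(3, 3.1, 50)))
  expect_equal(nrow(detectBursts(spike, cfg)), 0)

  # a dip to 8.5 %MVC stays above the 8 %MVC hysteresis level: one burst
  dip <- pctProfile(10, list(c(3, 4, 40), c(4, 4.3, 8.5), c(4.3, 5, 40)))
  expect_equal(nrow(detectBursts(dip, cfg)), 1)

  # a dip below the hysteresis level splits the burst
  split <- pctProfile(10, list(c(3, 4, 40), c(4.3, 5.3, 40)))
  expect_equal(nrow(detectBursts(split, cfg)), 2)

  # near-contiguous bursts (< 50 ms apart) merge
  merged <- pctProfile(10, list(c(3, 4, 40), c(4.03, 5, 40)), rate = 1000)
  expect_equal(nrow(detectBursts(merged, cfg)), 1)
})

test_that("event grouping splits strictly at the 3 s quiescence gap", {
  mk <- function(on, off) data.frame(onset = on, offset = off,
                                     peak = 40, channel = "EMG_LEFT")
  cfg <- scoringConfig()
  ev <- groupEvents(mk(c(0, 1.5, 3), c(0.5, 2, 3.5)), cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$nBursts, 3L)

  ev2 <- groupEvents(mk(c(0, 6), c(1, 7)), cfg)
  expect_equal(nrow(ev2), 2)

  # gap of exactly eventGap separates (strict <)
  ev3 <- groupEvents(mk(c(0, 4), c(1, 5)), cfg)
  expect_equal(nrow(ev3), 2)
  ev4 <- groupEvents(mk(c(0, 3.9), c(1, 5)), cfg)
  expect_equal(nrow(ev4), 1)
})

test_that("classification follows the tonic/phasic/mixed boundary semantics", {
  cfg <- scoringConfig()
  mkEv <- function(durs, gap = 1) {
    on <- cumsum(c(0, durs[-length(durs)] + gap))
    groupEvents(data.frame(onset = on, offset = on + durs, peak = 40,
                           channel = "EMG_LEFT"), cfg)
  }
  cases <- list(
    list(durs = 2.5, want = "tonic"),
    list(durs = c(0.5, 0.5, 0.5), want = "phasic"),
    list(durs = c(3, 0.5, 0.5, 0.5), want = "mixed"),
    list(durs = 2.0, want = "unclassified"),        # strict > 2 s
    list(durs = c(2.0, 0.5, 0.5), want = "phasic"), # 2.000 s is phasic-eligible
    list(durs = c(0.5, 0.5), want = "unclassified"),
    list(durs = c(0.2, 0.2, 0.2), want = "unclassified"),  # below bounds
    list(durs = c(2.5, 2.5, 2.5), want = "tonic")   # long bursts are not phasic
  )
  for (cs in cases) {
    ev <- classifyEvents(mkEv(cs$durs), cfg)
    expect_equal(ev$type, cs$want,
                 label = paste("durations", paste(cs$durs, collapse = ",")))
  }
})

test_that("bilateral pooling unions overlapping cross-channel bursts", {
  cfg <- scoringConfig()
  l <- data.frame(onset = c(10, 20), offset = c(11, 21), peak = c(40, 30),
                  channel = "EMG_LEFT")
  r <- data.frame(onset = c(10.5, 40), offset = c(12, 41), peak = c(50, 20),
                  channel = "EMG_RIGHT")
  p <- poolBursts(list(EMG_LEFT = l, EMG_RIGHT = r), cfg)
  expect_equal(nrow(p), 3)
  expect_equal(p$offset[1], 12)      # merged interval extends
  expect_equal(p$peak[1], 50)
  expect_equal(p$channel[1], "EMG_BOTH")

  left <- poolBursts(list(EMG_LEFT = l, EMG_RIGHT = r),
                     scoringConfig(emgPooling = "left"))
  expect_equal(nrow(left), 2)
})

test_that("surge detection opens at the interval start and freezes baseline", {
  cfg <- scoringConfig()
  flat <- heartRateSeries(beatTrain(40))
  expect_length(detectHrSurges(flat, cfg), 0)

  # one RR shortened to 0.8 s: 75 bpm = +25% over the 60 bpm baseline
  one <- heartRateSeries(beatTrain(40, overrides = list(c(20, 0.8))))
  s <- detectHrSurges(one, cfg)
  expect_length(s, 1)
  expect_equal(s, beatTrain(40)[20])   # start of the qualifying interval

  # a sustained run of fast beats is one surge, not several
  run <- heartRateSeries(beatTrain(40, overrides = list(
    c(20, 0.78), c(21, 0.78), c(22, 0.78), c(23, 0.78))))
  expect_length(detectHrSurges(run, cfg), 1)

  # +19% never crosses the 20% threshold
  sub <- heartRateSeries(beatTrain(40, overrides = list(c(20, 1 / 1.19))))
  expect_length(detectHrSurges(sub, cfg), 0)

  expect_error(detectHrSurges(heartRateSeries(c(0, 1, 2)), cfg), "short")
})

test_that("episode coupling respects the closed 1-5 s lag window", {
  cfg <- scoringConfig()
  ev <- data.frame(onset = 100, offset = 103, nBursts = 1L, type = "tonic")
  ev$bursts <- list(data.frame(onset = 100, offset = 103))
  expect_equal(scoreSbEpisodes(ev, 97, cfg)$lag, 3)
  expect_equal(nrow(scoreSbEpisodes(ev, 99.5, cfg)), 0)
  expect_equal(scoreSbEpisodes(ev, 95, cfg)$lag, 5)     # inclusive
  expect_equal(scoreSbEpisodes(ev, 99, cfg)$lag, 1)     # inclusive
  expect_equal(nrow(scoreSbEpisodes(ev, 94.9, cfg)), 0)

  uncl <- ev; uncl$type <- "unclassified"
  expect_equal(nrow(scoreSbEpisodes(uncl, 97, cfg)), 0)

  # one surge licenses at most the first qualifying event
  two <- rbind(ev, transform(ev, onset = 101.5, offset = 104))
  two$bursts <- list(ev$bursts[[1]], ev$bursts[[1]])
  eps <- scoreSbEpisodes(two, 98, cfg)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$onset, 100)
})

test_that("bruxism index is count-per-hour over the scored night", {
  expect_equal(bruxismIndex(12, 6 * 3600), 2)
  expect_equal(bruxismIndex(data.frame(), 3600), 0)
  expect_error(bruxismIndex(3, 0), "positive")
})

test_that("grouping and classification agree with the brute-force oracle", {
  cfg <- scoringConfig()
  set.seed(42)
  for (i in 1:50) {
    b <- randomBursts(sample(1:30, 1))
    got <- classifyEvents(groupEvents(b, cfg), cfg)
    want <- naiveGroup(b, cfg@eventGap)
    expect_equal(nrow(got), length(want))
    for (k in seq_along(want)) {
      idx <- want[[k]]
      expect_equal(got$onset[k], min(b$onset[idx]))
      expect_equal(got$nBursts[k], length(idx))
      expect_equal(got$type[k],
                   naiveClassify(b$offset[idx] - b$onset[idx]))
    }
  }
})

test_that("the scored chain is monotone and recovers planted structure", {
  g <- generateRecording(shortNightConfig(seed = 12, nightDuration = 1200))
  s <- summarizeSubject(g$recording)
  ev <- scoredEvents(s)
  eps <- episodes(s)
  classified <- ev[ev$type != "unclassified", ]
  expect_lte(nrow(eps), nrow(classified))
  expect_lte(nrow(classified), nrow(ev))
  expect_true(all(eps$lag >= 1 & eps$lag <= 5))
  expect_equal(s@nTotal, nrow(classified))

  truthEv <- truthEvents(g$truth)
  # every planted structure (coupled or confounder) surfaces as one scored
  # event of the planted shape
  expect_equal(nrow(ev), nrow(truthEv))
  near <- vapply(truthEv$onset, function(o) min(abs(ev$onset - o)),
                 numeric(1))
  expect_lt(max(near), 0.5)
  expect_equal(ev$type[order(ev$onset)],
               truthEv$shape[order(truthEv$onset)])

  r <- episodeRecovery(eps, g$truth)
  expect_equal(r$recall, 1)
  expect_equal(r$precision, 1)
  expect_equal(bruxismIndexOf(s), trueIndex(g$truth), tolerance = 0.1)
})

test_that("subject summary propagates upstream failures", {
  g <- generateRecording(shortNightConfig(seed = 2, nightDuration = 600))
  rec <- g$recording
  rec@channels$ECG$samples <- numeric(length(rec@channels$ECG$samples))
  expect_error(summarizeSubject(rec), "unusable ECG")
})
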