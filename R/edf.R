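## Minimal European Data Format (EDF) support: 16-bit continuous records,
## 1-second data records, no EDF+ annotations. Enough to carry overnight
## EMG/ECG nights between tools; not a general-purpose EDF library.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = "-")
}

edfNum <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 6, width = -1)
  for (d in 6:1) {
    if (nchar(s) <= width) break
    s <- formatC(x, format = "g", digits = d, width = -1)
  }
  edfPad(s, width)
}

#' Write a Recording to an EDF file
#'
#' Emits a plain EDF (not EDF+) with one-second data records and 16-bit
#' samples, so each channel's sampling rate must be a whole number of Hz and
#' the duration is padded up to whole seconds. Physical scaling is symmetric
#' around zero per channel; amplitude resolution is therefore the channel's
#' peak absolute value divided by 32767.
#'
#' @param rec a [Recording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRecordingEdf <- function(rec, path) {
  stopifnot(is(rec, "Recording"))
  labs <- channelLabels(rec)
  rates <- vapply(labs, function(l) samplingRate(rec, l), numeric(1))
  if (any(rates != round(rates)))
    stop("EDF writer requires integer sampling rates (Hz)")
  nsec <- ceiling(duration(rec))
  ns <- length(labs)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8),
    edfPad(subjectId(rec), 80),
    edfPad("bruxscore recording", 80),
    edfPad("01.01.00", 8), edfPad("00.00.00", 8),
    edfPad(256 * (1 + ns), 8),
    edfPad("", 44),
    edfPad(nsec, 8),
    edfPad("1", 8),
    edfPad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)

  physMax <- numeric(ns)
  for (i in seq_len(ns)) {
    a <- max(abs(channelSamples(rec, labs[i])), 1e-6)
    physMax[i] <- a
  }
  field <- function(f) paste(vapply(seq_len(ns), f, character(1)),
                             collapse = "")
  writeChar(paste0(
    field(function(i) edfPad(labs[i], 16)),
    field(function(i) edfPad("", 80)),
    field(function(i) edfPad("mV", 8)),
    field(function(i) edfNum(-physMax[i])),
    field(function(i) edfNum(physMax[i])),
    field(function(i) edfPad("-32767", 8)),
    field(function(i) edfPad("32767", 8)),
    field(function(i) edfPad("", 80)),
    field(function(i) edfPad(rates[i], 8)),
    field(function(i) edfPad("", 32))
  ), con, eos = NULL)

  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- channelSamples(rec, labs[i])
    need <- nsec * rates[i]
    if (length(x) < need) x <- c(x, numeric(need - length(x)))
    dig[[i]] <- as.integer(round(x / physMax[i] * 32767))
  }
  for (r in seq_len(nsec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * rates[i] + 1L):(r * rates[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

readEdfRaw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(w, as = as.integer) {
    v <- suppressWarnings(as(rd(w)))
    if (length(v) != 1L || is.na(v))
      stop("unreadable or corrupt EDF file: ", path)
    v
  }
  version <- rd(8); patient <- rd(80); recInfo <- rd(80)
  rd(8); rd(8)
  rd(8); rd(44)
  nrec <- num(8)
  recDur <- num(8, as.numeric)
  ns <- num(4)
  if (ns < 1L || nrec < 1L || recDur <= 0)
    stop("unreadable or corrupt EDF file: ", path)
  sfield <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- trimws(sfield(16)); sfield(80); dims <- trimws(sfield(8))
  physMin <- suppressWarnings(as.numeric(sfield(8)))
  physMax <- suppressWarnings(as.numeric(sfield(8)))
  digMin <- suppressWarnings(as.numeric(sfield(8)))
  digMax <- suppressWarnings(as.numeric(sfield(8)))
  sfield(80)
  spr <- suppressWarnings(as.integer(sfield(8))); sfield(32)
  if (length(spr) != ns || anyNA(spr) || anyNA(physMin) || anyNA(physMax) ||
      anyNA(digMin) || anyNA(digMax))
    stop("unreadable or corrupt EDF file: ", path)

  samples <- lapply(seq_len(ns), function(i)
    matrix(0L, nrow = spr[i], ncol = nrec))
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      v <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[i])
        stop("unreadable or corrupt EDF file (truncated records): ", path)
      samples[[i]][, r] <- v
    }
  }
  chans <- vector("list", ns)
  for (i in seq_len(ns)) {
    gain <- (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
    chans[[i]] <- list(
      label = labels[i],
      samples = (as.vector(samples[[i]]) - digMin[i]) * gain + physMin[i],
      rate = spr[i] / recDur,
      units = dims[i]
    )
  }
  list(subject = trimws(patient), channels = chans,
       duration = nrec * recDur)
}
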