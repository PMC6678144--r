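## Recording, manifest, ground-truth and report IO.

#' Default channel-label alias lists
#'
#' Token sets used to map whatever labels a file declares onto the canonical
#' `EMG_LEFT` / `EMG_RIGHT` / `ECG` labels. A label matches a channel class
#' when any of its (lower-cased, punctuation-split) tokens appears in the
#' class's token list; EMG side is resolved by the side tokens.
#'
#' @return a named list of character vectors.
#' @export
defaultChannelAliases <- function() {
  list(
    ECG = c("ecg", "ekg", "heart", "cardiac"),
    EMG = c("emg", "masseter", "sEMG", "semg"),
    LEFT = c("l", "left", "lt", "1"),
    RIGHT = c("r", "right", "rt", "2")
  )
}

labelTokens <- function(label) {
  tok <- strsplit(tolower(label), "[^a-z0-9]+")[[1]]
  tok[nzchar(tok)]
}

#' Map raw channel labels onto canonical labels
#'
#' @param labels character vector of labels as declared in a file.
#' @param aliases alias token lists, see [defaultChannelAliases()].
#' @return character vector of canonical labels (`EMG_LEFT`, `EMG_RIGHT`,
#'   `ECG`) with NA where a label is unrecognized.
#' @export
matchChannelLabels <- function(labels, aliases = defaultChannelAliases()) {
  al <- lapply(aliases, tolower)
  out <- rep(NA_character_, length(labels))
  for (i in seq_along(labels)) {
    tok <- labelTokens(labels[i])
    if (any(tok %in% al$ECG)) {
      out[i] <- "ECG"
    } else if (any(tok %in% al$EMG)) {
      if (any(tok %in% al$RIGHT) && !any(tok %in% al$LEFT)) {
        out[i] <- "EMG_RIGHT"
      } else {
        out[i] <- "EMG_LEFT"
      }
    }
  }
  ## a single sideless EMG channel defaults to EMG_LEFT; two sideless ones
  ## are taken in declared order
  emg <- which(out == "EMG_LEFT")
  if (length(emg) == 2L) out[emg[2L]] <- "EMG_RIGHT"
  out
}

#' Read an overnight recording
#'
#' Supports EDF (the de-facto standard for polysomnographic signals) and a
#' diffable CSV dialect: a header `t,<channel>,...` with a uniform time step,
#' one column per channel, from which a single shared sampling rate is
#' inferred. Channel labels are matched case-insensitively against alias
#' lists and normalized to `(EMG_LEFT, EMG_RIGHT, ECG)` order.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"edf"` or `"csv"`.
#' @param aliases channel alias lists, see [defaultChannelAliases()].
#' @param subjectId subject id override; defaults to the file's own id
#'   (EDF patient field) or the file name.
#' @return a [Recording-class].
#' @export
readRecording <- function(path, dialect = c("auto", "edf", "csv"),
                          aliases = defaultChannelAliases(),
                          subjectId = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("recording file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
               else "edf"
  }
  if (dialect == "edf") {
    raw <- readEdfRaw(path)
    labs <- vapply(raw$channels, `[[`, character(1), "label")
    canon <- matchChannelLabels(labs, aliases)
    chans <- list()
    for (i in seq_along(canon)) {
      if (is.na(canon[i])) next
      chans[[canon[i]]] <- list(samples = raw$channels[[i]]$samples,
                                rate = raw$channels[[i]]$rate)
    }
    if (!"ECG" %in% names(chans))
      stop("ECG channel required; channels found: ",
           paste(labs, collapse = ", "))
    if (!any(c("EMG_LEFT", "EMG_RIGHT") %in% names(chans)))
      stop("EMG channel required; channels found: ",
           paste(labs, collapse = ", "))
    if (is.null(subjectId))
      subjectId <- if (nzchar(raw$subject)) raw$subject
                   else sub("\\.[^.]+$", "", basename(path))
    return(Recording(subjectId, chans, duration = raw$duration))
  }

  df <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(df) || ncol(df) < 2L)
    stop("unreadable or empty CSV recording: ", path)
  tcol <- which(tolower(names(df)) %in% c("t", "time", "time_s"))[1]
  if (is.na(tcol)) stop("CSV recording needs a time column 't': ", path)
  tt <- df[[tcol]]
  step <- diff(tt)
  if (any(step <= 0) || (max(step) - min(step)) > 1e-6 * stats::median(step))
    stop("CSV recording time column must have a uniform positive step")
  rate <- 1 / stats::median(step)
  canon <- matchChannelLabels(names(df)[-tcol], aliases)
  chans <- list()
  cols <- setdiff(seq_along(df), tcol)
  for (i in seq_along(cols)) {
    if (is.na(canon[i])) next
    chans[[canon[i]]] <- list(samples = as.numeric(df[[cols[i]]]),
                              rate = rate)
  }
  if (!"ECG" %in% names(chans))
    stop("ECG channel required; channels found: ",
         paste(setdiff(names(df), names(df)[tcol]), collapse = ", "))
  if (is.null(subjectId)) subjectId <- sub("\\.[^.]+$", "", basename(path))
  Recording(subjectId, chans, duration = nrow(df) / rate)
}

#' Write a Recording in the CSV dialect
#'
#' All channels must share one sampling rate (the dialect has a single time
#' column). Values are written with enough digits for a lossless round-trip
#' at the declared precision.
#'
#' @param rec a [Recording-class].
#' @param path output path.
#' @param digits significant digits for samples.
#' @return `path`, invisibly.
#' @export
writeRecordingCsv <- function(rec, path, digits = 10) {
  labs <- channelLabels(rec)
  rates <- vapply(labs, function(l) samplingRate(rec, l), numeric(1))
  if (length(unique(rates)) != 1L)
    stop("CSV dialect requires all channels at one sampling rate")
  n <- length(channelSamples(rec, labs[1]))
  df <- data.frame(t = (seq_len(n) - 1L) / rates[1])
  cols <- c(EMG_LEFT = "emg_l", EMG_RIGHT = "emg_r", ECG = "ecg")
  for (lab in labs) df[[cols[[lab]]]] <- channelSamples(rec, lab)
  num <- vapply(df, function(col) format(col, digits = digits,
                                         scientific = FALSE, trim = TRUE),
                character(nrow(df)))
  utils::write.table(num, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = names(df))
  invisible(path)
}

MANIFEST_COLUMNS <- c("subject_id", "group", "sex", "age", "twi",
                      "symptoms_present", "self_report_positive",
                      "recording_path")

#' Read and validate a cohort manifest
#'
#' CSV with columns `subject_id, group, sex, age, twi, symptoms_present,
#' self_report_positive, recording_path`. `group` is `study`/`control`,
#' `twi` an integer tooth-wear score 0-4 (metadata only), the two report
#' flags logical.
#'
#' @param path manifest CSV path.
#' @return a validated data.frame, one row per subject.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("no subjects in manifest: ", path)
  miss <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  if (!all(df$group %in% c("study", "control")))
    stop("invalid group label(s): ",
         paste(setdiff(unique(df$group), c("study", "control")),
               collapse = ", "))
  if (!all(df$sex %in% c("female", "male")))
    stop("invalid sex label(s)")
  if (any(is.na(df$twi)) || any(df$twi != round(df$twi)) ||
      any(df$twi < 0 | df$twi > 4))
    stop("twi must be an integer in 0-4")
  for (col in c("symptoms_present", "self_report_positive")) {
    v <- df[[col]]
    if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "1", "YES")
    df[[col]] <- as.logical(v)
    if (any(is.na(df[[col]]))) stop(col, " must be logical")
  }
  df
}

#' Write a cohort manifest
#'
#' @param manifest data.frame with the manifest columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest[, MANIFEST_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

truthToList <- function(truth) {
  ev <- truthEvents(truth)
  list(
    schema = "bruxscore-truth/1",
    true_index = truth@trueIndex,
    calibration_end = truth@calibrationEnd,
    mvc_windows = unname(apply(truth@mvcWindows, 1L, c, simplify = FALSE)),
    events = lapply(seq_len(nrow(ev)), function(i) list(
      onset = ev$onset[i], offset = ev$offset[i],
      type = ev$type[i], shape = ev$shape[i],
      coupled = ev$coupled[i],
      surge_onset = if (is.na(ev$surgeOnset[i])) NULL else ev$surgeOnset[i],
      lag = if (is.na(ev$lag[i])) NULL else ev$lag[i],
      bursts = unname(apply(ev$bursts[[i]], 1L, c, simplify = FALSE))
    )),
    surges = lapply(seq_len(nrow(truth@surges)), function(i) list(
      onset = truth@surges$onset[i],
      peak_fraction = truth@surges$peakFraction[i],
      kind = truth@surges$kind[i]
    ))
  )
}

#' Write / read a ground-truth sidecar
#'
#' Ground truth travels next to its recording as `<recording>.truth.json`
#' so signal files stay standard EDF/CSV.
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON path.
#' @return `writeGroundTruth` returns `path` invisibly; `readGroundTruth`
#'   returns a [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truthToList(truth), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path)
  evl <- x$events
  grab <- function(field, default = NA_real_) vapply(evl, function(e) {
    v <- e[[field]]
    if (is.null(v)) default else v
  }, default)
  events <- data.frame(
    onset = grab("onset"), offset = grab("offset"),
    type = grab("type", NA_character_), shape = grab("shape", NA_character_),
    coupled = vapply(evl, function(e) isTRUE(e$coupled), logical(1)),
    surgeOnset = grab("surge_onset"), lag = grab("lag"),
    stringsAsFactors = FALSE
  )
  events$bursts <- lapply(evl, function(e)
    do.call(rbind, lapply(e$bursts, function(b)
      matrix(unlist(b), 1L, 2L, dimnames = list(NULL, c("onset", "offset"))))))
  if (!nrow(events)) events$bursts <- list()
  surges <- data.frame(
    onset = vapply(x$surges, function(s) s$onset, numeric(1)),
    peakFraction = vapply(x$surges, function(s) s$peak_fraction, numeric(1)),
    kind = vapply(x$surges, function(s) s$kind, character(1)),
    stringsAsFactors = FALSE
  )
  mvcW <- do.call(rbind, lapply(x$mvc_windows, unlist))
  if (is.null(mvcW)) mvcW <- matrix(numeric(0), 0L, 2L)
  colnames(mvcW) <- c("onset", "offset")
  new("GroundTruth", events = events, surges = surges, mvcWindows = mvcW,
      trueIndex = x$true_index, calibrationEnd = x$calibration_end)
}

scoringConfigToList <- function(config) {
  out <- lapply(slotNames(config), function(s) slot(config, s))
  names(out) <- slotNames(config)
  out
}

listToScoringConfig <- function(lst) {
  lst <- lst[names(lst) %in% slotNames("ScoringConfig")]
  lst <- lapply(lst, unlist)
  do.call(scoringConfig, lst)
}

accuracyToList <- function(acc) {
  if (is.null(acc)) return(NULL)
  ct <- acc@table
  list(sensitivity = acc@sensitivity, specificity = acc@specificity,
       table = list(tp = ct@tp, fn = ct@fn, fp = ct@fp, tn = ct@tn))
}

#' Write the structured cohort/subject report
#'
#' JSON report holding per-subject summaries, the screening confusion table
#' with sensitivity/specificity, cohort statistics blocks, and the scoring
#' configuration actually used (full provenance), under a schema version.
#'
#' @param summaries list of [SubjectSummary-class] (may be empty).
#' @param accuracy a [DiagnosticAccuracy-class] or NULL.
#' @param stats cohort statistics block (list) or NULL.
#' @param path output JSON path.
#' @param config the [ScoringConfig-class] used.
#' @param seed RNG seed associated with the run, if any.
#' @return `writeReport` returns `path` invisibly; `readReport` the parsed
#'   report list.
#' @export
writeReport <- function(summaries, accuracy, stats, path,
                        config = scoringConfig(), seed = NULL) {
  subj <- lapply(summaries, function(s) {
    row <- as.data.frame(s)
    as.list(row)
  })
  rep <- list(
    schema = "bruxscore-report/1",
    n_subjects = length(summaries),
    scoring_config = scoringConfigToList(config),
    seed = seed,
    subjects = subj,
    accuracy = accuracyToList(accuracy),
    stats = stats
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeReport
#' @export
readReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
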