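# CSV hypnogram dialects.
#
# Device export dialect (defined by this package; vendor apps do not publish
# a schema): header `timestamp_iso8601,stage`, one row per 1-minute epoch,
# stage in {wake, light, deep, rem} (case-insensitive).  Row gaps that are
# whole multiples of 60 s become UNSCORED epochs.
#
# PSG dialect: header containing a `stage` column, one row per 30-s epoch
# with an AASM code in {W, N1, N2, N3, REM} (case-insensitive; `R` accepted
# for REM); an optional `timestamp_iso8601` column carries absolute onsets.

DEV_CSV_STAGES <- c(wake = "WAKE", light = "LIGHT", deep = "DEEP", rem = "REM")
PSG_CSV_STAGES <- c(w = "W", n1 = "N1", n2 = "N2", n3 = "N3",
                    rem = "REM", r = "REM", unscored = "UNSCORED")

#' Read a device sleep export CSV
#'
#' Parses a 1-minute-epoch device hypnogram. The default dialect expects
#' columns `timestamp_iso8601` and `stage` with stages
#' `wake`/`light`/`deep`/`rem`; alternative column layouts can be adapted by
#' passing a `dialect` function that maps the raw `data.frame` to one with
#' those two columns.
#'
#' @param path CSV file (RFC-4180, UTF-8, header row required).
#' @param dialect `"default"` or a function `data.frame -> data.frame` with
#'   columns `timestamp_iso8601` and `stage`.
#' @return A 60-s `DEV4` [hypnogram()]; gaps between rows become
#'   `UNSCORED` epochs.
#' @export
read_device_csv <- function(path, dialect = "default") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.function(dialect)) raw <- dialect(raw)
  if (!all(c("timestamp_iso8601", "stage") %in% names(raw)))
    stop("device CSV must have columns timestamp_iso8601,stage", call. = FALSE)
  if (nrow(raw) == 0L) stop("device CSV has no epoch rows", call. = FALSE)

  ts <- as_utc_time_vec(raw$timestamp_iso8601)
  key <- tolower(trimws(raw$stage))
  bad <- which(!key %in% names(DEV_CSV_STAGES))
  if (length(bad))
    stop(sprintf("unknown device stage code '%s' at row %d", raw$stage[bad[1]],
                 bad[1]), call. = FALSE)
  steps <- diff(as.numeric(ts))
  if (any(steps <= 0))
    stop(sprintf("non-monotone timestamps at row %d", which(steps <= 0)[1] + 1L),
         call. = FALSE)
  if (any(steps %% 60 != 0))
    stop(sprintf("timestamp spacing not a multiple of 60 s at row %d",
                 which(steps %% 60 != 0)[1] + 1L), call. = FALSE)

  n <- as.integer(round(as.numeric(ts[length(ts)] - ts[1], units = "secs") / 60)) + 1L
  stages <- rep(UNSCORED, n)
  at <- as.integer(round(as.numeric(ts - ts[1], units = "secs") / 60)) + 1L
  stages[at] <- unname(DEV_CSV_STAGES[key])
  hypnogram(stages, ts[1], 60, "DEV4")
}

#' Read a manually scored PSG stage CSV
#'
#' One row per 30-second epoch with an AASM stage code (`W`, `N1`, `N2`,
#' `N3`, `REM`; case-insensitive, `R` accepted for `REM`).
#'
#' @param path CSV file with a `stage` column and optionally a
#'   `timestamp_iso8601` column.
#' @param start Start time used when the file has no timestamp column.
#' @return A 30-s `AASM5` [hypnogram()].
#' @export
read_psg_stage_csv <- function(path, start = "2000-01-01 00:00:00") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"stage" %in% names(raw))
    stop("PSG CSV must have a 'stage' column", call. = FALSE)
  if (nrow(raw) == 0L) stop("PSG CSV has no epoch rows", call. = FALSE)
  key <- tolower(trimws(raw$stage))
  bad <- which(!key %in% names(PSG_CSV_STAGES))
  if (length(bad))
    stop(sprintf("unknown PSG stage code '%s' at row %d", raw$stage[bad[1]],
                 bad[1]), call. = FALSE)
  if ("timestamp_iso8601" %in% names(raw)) {
    ts <- as_utc_time_vec(raw$timestamp_iso8601)
    if (any(diff(as.numeric(ts)) != 30))
      stop("PSG CSV timestamps must increase by exactly 30 s", call. = FALSE)
    start <- ts[1]
  }
  hypnogram(unname(PSG_CSV_STAGES[key]), start, 30, "AASM5")
}

#' Write a hypnogram as CSV
#'
#' Inverse of [read_device_csv()] / [read_psg_stage_csv()]: one row per
#' scored epoch with columns `timestamp_iso8601,stage`. `UNSCORED` epochs are
#' omitted (they are gaps in the export).
#'
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  keep <- hyp$stages != UNSCORED
  stage_out <- if (hyp$vocabulary == "DEV4")
    tolower(hyp$stages[keep]) else hyp$stages[keep]
  utils::write.csv(
    data.frame(
      timestamp_iso8601 = format(epoch_onsets(hyp)[keep], "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC"),
      stage = stage_out,
      stringsAsFactors = FALSE
    ),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

as_utc_time_vec <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", "", x)
  out <- as.POSIXct(x, tz = "UTC")
  if (anyNA(out))
    stop("unparseable timestamp: ", x[which(is.na(out))[1]], call. = FALSE)
  .POSIXct(round(as.numeric(out)), tz = "UTC")
}
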