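# Core containers: hypnogram and recording_markers.
#
# A hypnogram is an epoch-indexed stage sequence with a constant epoch
# duration, an absolute start time and a declared vocabulary.  Epochs are
# half-open intervals [onset, onset + epoch_s) on a regular grid anchored at
# `start`.  Timestamps are POSIXct (UTC) at 1-second precision.

#' Construct a hypnogram
#'
#' An epoch-indexed sequence of sleep-stage labels with a fixed epoch
#' duration and absolute start time. Epochs are half-open intervals
#' `[onset, onset + epoch_s)` tiling the recording contiguously.
#'
#' @param stages Character vector of stage codes from `vocabulary`
#'   (or `"UNSCORED"`). May be empty.
#' @param start Absolute start time (`POSIXct`, or a string parseable as
#'   UTC date-time).
#' @param epoch_s Epoch duration in seconds (30 for AASM-scored PSG,
#'   60 for the device export).
#' @param vocabulary `"AASM5"` or `"DEV4"`.
#' @return An object of class `hypnogram`.
#' @seealso [recording_markers()], [split_epochs()], [merge_stages()]
#' @examples
#' hypnogram(c("W", "N1", "N2"), start = "2023-01-01 23:00:00", epoch_s = 30,
#'           vocabulary = "AASM5")
#' @export
hypnogram <- function(stages, start, epoch_s, vocabulary) {
  vocabulary <- match.arg(vocabulary, c("AASM5", "DEV4"))
  stages <- as.character(stages)
  check_stages(stages, vocabulary)
  if (!(is.numeric(epoch_s) && length(epoch_s) == 1L && epoch_s > 0))
    stop("epoch_s must be a single positive number", call. = FALSE)
  structure(
    list(
      start = as_utc_time(start),
      epoch_s = as.numeric(epoch_s),
      stages = stages,
      vocabulary = vocabulary
    ),
    class = "hypnogram"
  )
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %s, %d epochs x %gs, start %s\n",
              x$vocabulary, length(x$stages), x$epoch_s,
              format(x$start, "%Y-%m-%d %H:%M:%S", tz = "UTC")))
  tab <- table(factor(x$stages, levels = c(vocab_levels(x$vocabulary), UNSCORED)))
  tab <- tab[tab > 0]
  if (length(tab))
    cat("  minutes:", paste(sprintf("%s=%.1f", names(tab), tab * x$epoch_s / 60),
                            collapse = " "), "\n")
  invisible(x)
}

#' @export
length.hypnogram <- function(x) length(x$stages)

#' @export
as.data.frame.hypnogram <- function(x, ...) {
  data.frame(
    onset = epoch_onsets(x),
    stage = x$stages,
    stringsAsFactors = FALSE
  )
}

#' Epoch onset times of a hypnogram
#'
#' @param hyp A [hypnogram()].
#' @return `POSIXct` vector of epoch start times (length `length(hyp)`).
#' @export
epoch_onsets <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  hyp$start + hyp$epoch_s * (seq_along(hyp$stages) - 1L)
}

#' End time of a hypnogram
#'
#' @param hyp A [hypnogram()].
#' @return `POSIXct` end of the last epoch (equal to `start` when empty).
#' @export
hypnogram_end <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  hyp$start + hyp$epoch_s * length(hyp$stages)
}

#' Recording markers
#'
#' Absolute timestamps delimiting a night: recording start/end and the
#' lights-off/lights-on markers that define the time-in-bed (TIB) analysis
#' window. Invariant: `start_time <= lights_off < lights_on <= end_time`.
#'
#' @param lights_off,lights_on TIB window boundaries (`POSIXct` or string).
#' @param start_time,end_time Recording boundaries; default to the lights
#'   markers.
#' @return An object of class `recording_markers`.
#' @export
recording_markers <- function(lights_off, lights_on,
                              start_time = lights_off, end_time = lights_on) {
  m <- structure(
    list(
      start_time = as_utc_time(start_time),
      lights_off = as_utc_time(lights_off),
      lights_on  = as_utc_time(lights_on),
      end_time   = as_utc_time(end_time)
    ),
    class = "recording_markers"
  )
  if (!(m$start_time <= m$lights_off && m$lights_off < m$lights_on &&
        m$lights_on <= m$end_time))
    stop("markers must satisfy start_time <= lights_off < lights_on <= end_time",
         call. = FALSE)
  m
}

#' @export
print.recording_markers <- function(x, ...) {
  fmt <- function(t) format(t, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  cat(sprintf("<recording_markers> lights off %s -> lights on %s (TIB %.1f min)\n",
              fmt(x$lights_off), fmt(x$lights_on),
              as.numeric(difftime(x$lights_on, x$lights_off, units = "mins"))))
  invisible(x)
}

#' Time in bed, in minutes
#'
#' @param markers A [recording_markers()].
#' @return TIB = lights_on - lights_off, in minutes.
#' @export
tib_minutes <- function(markers) {
  stopifnot(inherits(markers, "recording_markers"))
  as.numeric(difftime(markers$lights_on, markers$lights_off, units = "mins"))
}

as_utc_time <- function(x) {
  if (!inherits(x, "POSIXct")) {
    x <- as.POSIXct(x, tz = "UTC")
    if (is.na(x)) stop("unparseable timestamp", call. = FALSE)
  }
  # 1-s precision, POSIXct (round.POSIXt returns POSIXlt)
  .POSIXct(round(as.numeric(x)), tz = "UTC")
}
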