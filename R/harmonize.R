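# Harmonization: common grid, common vocabulary, common window.
#
# The device reports 1-minute epochs over 4 stages; the reference is scored
# in 30-second epochs over 5 AASM stages.  Epoch-by-epoch comparison
# requires: (1) splitting device minutes into two 30-s epochs sharing the
# stage, (2) merging reference N1/N2 into the device's light-sleep class,
# (3) scoring the un-exported parts of the time-in-bed (TIB) window as wake
# (the device only reports between its detected sleep onset and offset), and
# (4) restricting both series to TIB and pairing them by timestamp.

#' Split 1-minute epochs into 30-second epochs
#'
#' Each 60-s epoch becomes two consecutive 30-s epochs sharing its stage, so
#' total recorded duration and per-stage minutes are conserved.
#'
#' @param hyp A [hypnogram()] with `epoch_s = 60`.
#' @return The same hypnogram on a 30-s grid (length doubles).
#' @export
split_epochs <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (hyp$epoch_s != 60)
    stop("split_epochs expects 60-s epochs, got ", hyp$epoch_s, " s",
         call. = FALSE)
  hypnogram(rep(hyp$stages, each = 2L), hyp$start, 30, hyp$vocabulary)
}

#' Merge AASM stages into the 4-stage device vocabulary
#'
#' `W -> WAKE`, `N1 -> LIGHT`, `N2 -> LIGHT`, `N3 -> DEEP`, `REM -> REM`;
#' `UNSCORED` is preserved. Epoch duration and length are unchanged.
#'
#' @param hyp An `AASM5` [hypnogram()].
#' @return A `DEV4` hypnogram.
#' @export
merge_stages <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (hyp$vocabulary != "AASM5")
    stop("merge_stages expects an AASM5 hypnogram, got ", hyp$vocabulary,
         call. = FALSE)
  hypnogram(unname(MERGE_AASM5_TO_DEV4[hyp$stages]), hyp$start, hyp$epoch_s,
            "DEV4")
}

#' Snap a TIB window onto the 30-s epoch grid
#'
#' Markers are snapped to the nearest 30-s boundary, widening the window on
#' ties (`lights_off` floors, `lights_on` ceils), so scored sleep at the
#' boundary is never discarded. Boundaries are absolute times on the 30-s
#' grid of `anchor` (default: the epoch, so clock times at :00/:30 are
#' already boundaries).
#'
#' @param markers A [recording_markers()].
#' @param anchor `POSIXct` phase reference for the 30-s grid.
#' @return `recording_markers` with snapped lights_off/lights_on; a message
#'   is logged when snapping moved a marker.
#' @export
snap_markers <- function(markers, anchor = as.POSIXct("1970-01-01", tz = "UTC")) {
  stopifnot(inherits(markers, "recording_markers"))
  off_rel <- as.numeric(difftime(markers$lights_off, anchor, units = "secs"))
  on_rel  <- as.numeric(difftime(markers$lights_on, anchor, units = "secs"))
  off_snap <- floor(off_rel / 30) * 30
  on_snap  <- ceiling(on_rel / 30) * 30
  if (off_snap != off_rel || on_snap != on_rel)
    message(sprintf("snapped TIB window by (%+g, %+g) s to the 30-s grid",
                    off_snap - off_rel, on_snap - on_rel))
  recording_markers(
    lights_off = anchor + off_snap, lights_on = anchor + on_snap,
    start_time = min(markers$start_time, anchor + off_snap),
    end_time = max(markers$end_time, anchor + on_snap)
  )
}

#' Score un-exported TIB time as wake
#'
#' The device only reports between its detected sleep onset and offset;
#' periods of the TIB window before the first exported epoch, after the
#' last, and any unscored gaps are scored as wakefulness. Exported epochs
#' outside the window are dropped (an epoch straddling a boundary keeps its
#' in-window part).
#'
#' @param hyp A `DEV4` [hypnogram()] (30-s or 60-s epochs).
#' @param window [recording_markers()]; boundaries are snapped to the 30-s
#'   grid via [snap_markers()].
#' @return A 30-s `DEV4` hypnogram tiling `[lights_off, lights_on)` exactly,
#'   with no `UNSCORED` epochs.
#' @export
pad_device_wake <- function(hyp, window) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(window, "recording_markers"))
  if (hyp$vocabulary != "DEV4")
    stop("pad_device_wake expects a DEV4 hypnogram", call. = FALSE)
  window <- snap_markers(window)
  if (hypnogram_end(hyp) <= window$lights_off || hyp$start >= window$lights_on)
    stop("device export lies entirely outside the TIB window ",
         "(synchronization fault?)", call. = FALSE)
  n_out <- as.integer(round(tib_minutes(window) * 2))
  onsets <- window$lights_off + 30 * (seq_len(n_out) - 1L)
  midpoints <- onsets + 15
  # device stage covering each output epoch's midpoint, else padded WAKE
  idx <- floor(as.numeric(difftime(midpoints, hyp$start, units = "secs")) /
                 hyp$epoch_s) + 1
  stages <- rep("WAKE", n_out)
  inside <- idx >= 1 & idx <= length(hyp$stages)
  stages[inside] <- hyp$stages[idx[inside]]
  stages[stages == UNSCORED] <- "WAKE"
  hypnogram(stages, window$lights_off, 30, "DEV4")
}

#' Restrict a hypnogram to the TIB window
#'
#' Keeps epochs whose interval lies within `[lights_off, lights_on)` (after
#' snapping the markers to the 30-s grid).
#'
#' @param hyp A [hypnogram()] covering the window.
#' @param window [recording_markers()].
#' @return The windowed hypnogram.
#' @export
restrict_to_tib <- function(hyp, window) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(window, "recording_markers"))
  window <- snap_markers(window)
  if (hyp$start > window$lights_off || hypnogram_end(hyp) < window$lights_on)
    stop("hypnogram does not cover the TIB window", call. = FALSE)
  onsets <- epoch_onsets(hyp)
  keep <- onsets >= window$lights_off &
    (onsets + hyp$epoch_s) <= window$lights_on
  hypnogram(hyp$stages[keep], onsets[keep][1], hyp$epoch_s, hyp$vocabulary)
}

#' Pair two harmonized hypnograms epoch by epoch
#'
#' Pairs a 30-s `DEV4` reference (the merged PSG) with a 30-s `DEV4` device
#' hypnogram by timestamp, restricted to the TIB window. Pairs in which
#' either member is `UNSCORED` are dropped with a logged count.
#'
#' @param ref,dev 30-s `DEV4` [hypnogram()]s covering the window.
#' @param window [recording_markers()].
#' @return An object of class `epoch_pairs`: list with `n`, `ref`, `dev`
#'   (character stage vectors), `onsets`, `window`.
#' @export
align_pair <- function(ref, dev, window) {
  stopifnot(inherits(ref, "hypnogram"), inherits(dev, "hypnogram"))
  if (ref$epoch_s != 30 || dev$epoch_s != 30)
    stop("align_pair expects 30-s hypnograms; run split_epochs first",
         call. = FALSE)
  if (ref$vocabulary != "DEV4" || dev$vocabulary != "DEV4")
    stop("align_pair expects DEV4-vocabulary hypnograms; run merge_stages first",
         call. = FALSE)
  offset <- as.numeric(difftime(dev$start, ref$start, units = "secs")) %% 30
  if (offset != 0)
    stop("epoch grids are offset by ", offset,
         " s (not a multiple of 30 s); cannot align", call. = FALSE)
  window <- snap_markers(window)
  # clip each series to its in-window epochs; partial coverage is allowed
  # here (the timestamp intersection below defines the common span)
  clip <- function(h) {
    on <- as.numeric(epoch_onsets(h))
    on[on >= as.numeric(window$lights_off) &
         on + h$epoch_s <= as.numeric(window$lights_on)]
  }
  ref_on <- clip(ref)
  dev_on <- clip(dev)
  common <- intersect(ref_on, dev_on)
  if (length(common) == 0L)
    stop("hypnograms share no epochs within the window", call. = FALSE)
  r <- ref$stages[match(common, as.numeric(epoch_onsets(ref)))]
  d <- dev$stages[match(common, as.numeric(epoch_onsets(dev)))]
  drop <- r == UNSCORED | d == UNSCORED
  if (any(drop))
    message(sum(drop), " epoch pair(s) dropped (UNSCORED)")
  structure(
    list(
      n = sum(!drop),
      ref = r[!drop],
      dev = d[!drop],
      onsets = as.POSIXct(common[!drop], origin = "1970-01-01", tz = "UTC"),
      window = window
    ),
    class = "epoch_pairs"
  )
}

#' @export
print.epoch_pairs <- function(x, ...) {
  cat(sprintf("<epoch_pairs> %d aligned 30-s epochs, agreement %.1f%%\n",
              x$n, 100 * mean(x$ref == x$dev)))
  invisible(x)
}
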