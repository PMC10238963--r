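# Per-night sleep summary parameters.
#
# All parameters are derived from a harmonized 30-s DEV4 hypnogram tiling
# the TIB window.  Definitions (in minutes unless noted):
#   TIB   = lights_on - lights_off
#   SOL   = lights_off -> first sleep epoch (sleep = LIGHT/DEEP/REM)
#   TSPD  = first sleep epoch -> end of last sleep epoch
#   TST   = total sleep-epoch minutes
#   WASO  = wake minutes strictly inside the sleep period
#   SE    = 100 * TST / TIB  (%)
#   awake = TIB - TST  (all wake in TIB, including SOL and terminal wake)
#   awakenings = wake bouts > 5.0 min inside the sleep period (>= 11 epochs;
#                a bout of exactly 5 min does not count)
# These choices make TST = light + deep + REM and TSPD = TST + WASO exact
# identities on every night.

#' Compute per-night sleep summary parameters
#'
#' @param hyp A 30-s `DEV4` [hypnogram()] tiling the TIB window, with no
#'   `UNSCORED` epochs (see [pad_device_wake()] / [restrict_to_tib()]).
#' @param window [recording_markers()] defining TIB.
#' @param awakening_threshold_min Minimal duration (strict, minutes) for a
#'   wake bout inside the sleep period to count as an awakening.
#' @return An object of class `sleep_parameters`: a list with fields
#'   `tib_min`, `tspd_min`, `tst_min`, `waso_min`, `awakenings_n`, `sol_min`,
#'   `se_pct`, `light_min`, `deep_min`, `rem_min`, `awake_min`,
#'   `initial_sleep_onset` (`POSIXct` or `NA`), `no_sleep` (flag).
#' @examples
#' w <- recording_markers("2023-03-01 23:00:00", "2023-03-02 07:00:00")
#' hyp <- hypnogram(rep(c("WAKE", "LIGHT"), c(20, 940)),
#'                  "2023-03-01 23:00:00", 30, "DEV4")
#' compute_sleep_parameters(hyp, w)
#' @export
compute_sleep_parameters <- function(hyp, window, awakening_threshold_min = 5) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(window, "recording_markers"))
  if (hyp$epoch_s != 30 || hyp$vocabulary != "DEV4")
    stop("compute_sleep_parameters expects a harmonized 30-s DEV4 hypnogram",
         call. = FALSE)
  if (any(hyp$stages == UNSCORED))
    stop("hypnogram contains UNSCORED epochs; harmonize first", call. = FALSE)
  window <- snap_markers(window)
  if (!isTRUE(all.equal(as.numeric(hyp$start), as.numeric(window$lights_off))) ||
      !isTRUE(all.equal(as.numeric(hypnogram_end(hyp)),
                        as.numeric(window$lights_on))))
    stop("hypnogram must tile the TIB window exactly", call. = FALSE)

  ep_min <- hyp$epoch_s / 60
  tib <- tib_minutes(window)
  is_sleep <- hyp$stages %in% DEV4_SLEEP
  stage_min <- function(s) sum(hyp$stages == s) * ep_min

  if (!any(is_sleep)) {
    out <- list(
      tib_min = tib, tspd_min = 0, tst_min = 0, waso_min = 0,
      awakenings_n = 0L, sol_min = tib, se_pct = 0,
      light_min = 0, deep_min = 0, rem_min = 0, awake_min = tib,
      initial_sleep_onset = as.POSIXct(NA), no_sleep = TRUE
    )
    class(out) <- "sleep_parameters"
    return(out)
  }

  first_sleep <- which(is_sleep)[1]
  last_sleep <- max(which(is_sleep))
  tst <- sum(is_sleep) * ep_min
  onset_time <- hyp$start + (first_sleep - 1L) * hyp$epoch_s
  sol <- (first_sleep - 1L) * ep_min
  tspd <- (last_sleep - first_sleep + 1L) * ep_min
  inside <- seq.int(first_sleep, last_sleep)
  waso <- sum(!is_sleep[inside]) * ep_min

  # maximal wake runs inside the sleep period, counted when strictly longer
  # than the threshold
  r <- rle(!is_sleep[inside])
  awakenings <- sum(r$values & r$lengths * ep_min > awakening_threshold_min)

  out <- list(
    tib_min = tib,
    tspd_min = tspd,
    tst_min = tst,
    waso_min = waso,
    awakenings_n = as.integer(awakenings),
    sol_min = sol,
    se_pct = 100 * tst / tib,
    light_min = stage_min("LIGHT"),
    deep_min = stage_min("DEEP"),
    rem_min = stage_min("REM"),
    awake_min = tib - tst,
    initial_sleep_onset = onset_time,
    no_sleep = FALSE
  )
  class(out) <- "sleep_parameters"
  out
}

#' @export
print.sleep_parameters <- function(x, ...) {
  cat(sprintf(paste0(
    "<sleep_parameters> TIB %.1f  TST %.1f  WASO %.1f  SOL %.1f  SE %.2f%%\n",
    "  TSPD %.1f  light %.1f  deep %.1f  REM %.1f  awake %.1f  awakenings %d%s\n"),
    x$tib_min, x$tst_min, x$waso_min, x$sol_min, x$se_pct,
    x$tspd_min, x$light_min, x$deep_min, x$rem_min, x$awake_min,
    x$awakenings_n, if (isTRUE(x$no_sleep)) "  [no sleep]" else ""))
  invisible(x)
}

#' @export
as.data.frame.sleep_parameters <- function(x, ...) {
  data.frame(
    tib_min = x$tib_min, tspd_min = x$tspd_min, tst_min = x$tst_min,
    waso_min = x$waso_min, awakenings_n = x$awakenings_n, sol_min = x$sol_min,
    se_pct = x$se_pct, light_min = x$light_min, deep_min = x$deep_min,
    rem_min = x$rem_min, awake_min = x$awake_min,
    initial_sleep_onset = format_or_na(x$initial_sleep_onset),
    no_sleep = isTRUE(x$no_sleep),
    stringsAsFactors = FALSE
  )
}

format_or_na <- function(t) {
  if (length(t) == 0L || is.na(t)) NA_character_
  else format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}
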