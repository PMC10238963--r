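# Synthetic paired-hypnogram cohorts.
#
# The generator is a first-order Markov chain over the AASM stages at 30-s
# resolution (the minimal model with controllable stage occupancy and bout
# structure), started in wake at lights-off, with time in bed drawn from a
# truncated normal.  The device is modelled on top of the true hypnogram:
# merge to the 4-stage vocabulary, coarsen to 1-minute frames (majority
# vote, ties to the earlier epoch), then emit a device stage per frame from
# a stage-conditional emission matrix P(device | reference).  The default
# emission is the row-normalised pooled 4-way confusion observed for a
# wrist-worn tracker validated against PSG, so synthetic cohorts reproduce
# the qualitative error structure of real devices (sleep called during
# reference wake, REM called light).  The device record is truncated to
# [first emitted sleep frame + onset delay, lights_on - offset advance],
# emulating exports that only start at detected sleep onset.

#' Default device emission matrix
#'
#' Row-stochastic 4x4 matrix `P(device stage | reference merged stage)`
#' applied per 1-minute frame, row-normalised from the pooled 4-way epoch
#' confusion counts of a consumer tracker validated against PSG.
#'
#' @return 4x4 matrix with `DEV4` row/column names.
#' @export
default_device_emission <- function() {
  counts <- matrix(c(
    3019, 3957, 1020,  548,
    2236, 11366, 3468, 2274,
     537, 2653, 1775,  494,
     465, 4044,  519, 1193
  ), nrow = 4, byrow = TRUE, dimnames = list(DEV4, DEV4))
  counts / rowSums(counts)
}

#' PSG generative model parameters
#'
#' @param transition 5x5 row-stochastic stage-transition matrix over
#'   `AASM5` (order `W, N1, N2, N3, REM`), one step per 30-s epoch.
#' @param initial Initial stage distribution at lights-off (default: all
#'   mass on `W`).
#' @param tib_mean_min,tib_sd_min Mean and SD (minutes) of the truncated
#'   normal time-in-bed distribution; defaults match a clinical cohort of
#'   ~8-hour nights.
#' @param tib_floor_min Lower truncation bound (minutes).
#' @return An object of class `psg_model_params`.
#' @export
psg_model_params <- function(transition,
                             initial = c(1, 0, 0, 0, 0),
                             tib_mean_min = 443.58, tib_sd_min = 44.98,
                             tib_floor_min = 240) {
  transition <- as.matrix(transition)
  if (!all(dim(transition) == c(5L, 5L)))
    stop("transition must be 5x5 over the AASM5 stages", call. = FALSE)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-12))
    stop("transition rows must be non-negative and sum to 1", call. = FALSE)
  if (length(initial) != 5L || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-12)
    stop("initial must be a probability vector of length 5", call. = FALSE)
  if (tib_mean_min <= 0) stop("tib_mean_min must be positive", call. = FALSE)
  dimnames(transition) <- list(AASM5, AASM5)
  structure(
    list(transition = transition, initial = stats::setNames(initial, AASM5),
         tib_mean_min = tib_mean_min, tib_sd_min = tib_sd_min,
         tib_floor_min = tib_floor_min),
    class = "psg_model_params"
  )
}

#' Group presets for the PSG generator
#'
#' Stage-transition presets for nights without (`"no_sdis"`) and with
#' (`"sdis"`) sleep disorders. The disorder preset has higher wake-entry
#' rates (more fragmentation) and lower N3 occupancy, so cohort-mean stage
#' minutes land near the occupancies reported for clinical validation
#' cohorts (total TST ~345 min with deep sleep lower in the disorder
#' group).
#'
#' @param group `"no_sdis"` or `"sdis"`.
#' @param ... Overrides passed to [psg_model_params()].
#' @return A `psg_model_params` object.
#' @export
psg_preset <- function(group = c("no_sdis", "sdis"), ...) {
  group <- match.arg(group)
  tr <- if (group == "no_sdis") {
    matrix(c(
      # W      N1     N2     N3     REM
      0.950, 0.045, 0.005, 0.000, 0.000,  # W
      0.020, 0.850, 0.123, 0.000, 0.007,  # N1
      0.009, 0.012, 0.944, 0.021, 0.014,  # N2
      0.003, 0.000, 0.045, 0.950, 0.002,  # N3
      0.010, 0.008, 0.019, 0.000, 0.963   # REM
    ), nrow = 5, byrow = TRUE)
  } else {
    matrix(c(
      0.945, 0.050, 0.005, 0.000, 0.000,
      0.030, 0.845, 0.115, 0.000, 0.010,
      0.016, 0.020, 0.930, 0.019, 0.015,
      0.007, 0.000, 0.048, 0.943, 0.002,
      0.020, 0.012, 0.018, 0.000, 0.950
    ), nrow = 5, byrow = TRUE)
  }
  psg_model_params(transition = tr, ...)
}

#' Device generative model parameters
#'
#' @param emission 4x4 row-stochastic matrix `P(device | reference)` over
#'   `DEV4`, applied per 1-minute frame.
#' @param onset_delay_min Minutes of device record dropped after the first
#'   emitted sleep frame (>= 0).
#' @param offset_advance_min Minutes before lights-on at which the device
#'   record ends (>= 0).
#' @return An object of class `device_model_params`.
#' @export
device_model_params <- function(emission = default_device_emission(),
                                onset_delay_min = 0, offset_advance_min = 0) {
  emission <- as.matrix(emission)
  if (!all(dim(emission) == c(4L, 4L)))
    stop("emission must be 4x4 over the DEV4 stages", call. = FALSE)
  if (any(emission < 0) || any(abs(rowSums(emission) - 1) > 1e-12))
    stop("emission rows must be non-negative and sum to 1", call. = FALSE)
  if (onset_delay_min < 0 || offset_advance_min < 0)
    stop("delays must be >= 0", call. = FALSE)
  dimnames(emission) <- list(DEV4, DEV4)
  structure(
    list(emission = emission, onset_delay_min = onset_delay_min,
         offset_advance_min = offset_advance_min),
    class = "device_model_params"
  )
}

#' Simulate a PSG night
#'
#' Draws time in bed from the truncated normal, rounded to whole minutes,
#' and runs the stage-transition chain from lights-off.
#'
#' @param params [psg_model_params()].
#' @param seed Integer seed; identical seeds give identical nights.
#' @param lights_off Absolute lights-off time.
#' @return List with `hypnogram` (30-s `AASM5`) and `markers`
#'   ([recording_markers()]; recording pads 5 min around the TIB window).
#' @export
simulate_psg_hypnogram <- function(params, seed,
                                   lights_off = "2023-03-01 23:36:00") {
  stopifnot(inherits(params, "psg_model_params"))
  set.seed(as.integer(seed))
  tib_min <- round(rtruncnorm1(params$tib_mean_min, params$tib_sd_min,
                               params$tib_floor_min))
  n <- as.integer(tib_min * 2)  # whole minutes -> even number of 30-s epochs
  stages <- character(n)
  state <- sample.int(5L, 1L, prob = params$initial)
  for (i in seq_len(n)) {
    stages[i] <- AASM5[state]
    state <- sample.int(5L, 1L, prob = params$transition[state, ])
  }
  lights_off <- as_utc_time(lights_off)
  lights_on <- lights_off + tib_min * 60
  list(
    hypnogram = hypnogram(stages, lights_off, 30, "AASM5"),
    markers = recording_markers(lights_off, lights_on,
                                start_time = lights_off - 300,
                                end_time = lights_on + 300)
  )
}

rtruncnorm1 <- function(mean, sd, lower) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower) return(x)
  }
}

# Reference label of each 1-minute frame: majority vote over its two 30-s
# epochs with ties resolved to the earlier epoch -- which, for two epochs,
# is the first epoch's stage.
frame_reference_labels <- function(psg_dev4) {
  n_frames <- length(psg_dev4$stages) %/% 2L
  psg_dev4$stages[2L * seq_len(n_frames) - 1L]
}

#' Simulate a device hypnogram from a true PSG night
#'
#' Merges the PSG to the 4-stage vocabulary, coarsens to 1-minute frames
#' (majority vote, tie to the earlier epoch), emits one device stage per
#' frame from the emission row of the frame's reference stage, and
#' truncates the record to span from the first emitted sleep frame plus the
#' onset delay until lights-on minus the offset advance.
#'
#' @param psg A 30-s `AASM5` [hypnogram()] tiling the TIB window.
#' @param markers [recording_markers()].
#' @param params [device_model_params()].
#' @param seed Integer seed.
#' @return A 60-s `DEV4` [hypnogram()] (zero-length, with a warning, if the
#'   device never detects sleep).
#' @export
simulate_device_hypnogram <- function(psg, markers, params, seed) {
  stopifnot(inherits(psg, "hypnogram"), inherits(params, "device_model_params"))
  if (psg$epoch_s != 30)
    stop("simulate_device_hypnogram expects a 30-s PSG hypnogram", call. = FALSE)
  set.seed(as.integer(seed))
  ref <- frame_reference_labels(merge_stages(psg))
  n_frames <- length(ref)
  emitted <- vapply(ref, function(s) {
    sample(DEV4, 1L, prob = params$emission[s, ])
  }, character(1), USE.NAMES = FALSE)

  sleep_idx <- which(emitted %in% DEV4_SLEEP)
  if (length(sleep_idx) == 0L) {
    warning("device detected no sleep; returning an empty export", call. = FALSE)
    return(hypnogram(character(0), psg$start, 60, "DEV4"))
  }
  from <- min(sleep_idx) + as.integer(params$onset_delay_min)
  to <- n_frames - as.integer(params$offset_advance_min)
  if (from > to)
    stop("truncation removed the whole device record", call. = FALSE)
  hypnogram(emitted[from:to], psg$start + (from - 1L) * 60, 60, "DEV4")
}

#' Simulate a paired-hypnogram cohort
#'
#' Draws per-participant nights with group-specific PSG presets and a
#' shared device error model. Deterministic given `seed`.
#'
#' @param n_no_sdis,n_sdis Group sizes (defaults 20 and 25, the composition
#'   of the validation cohort the generator emulates).
#' @param presets Named list with `psg_model_params` for `no_sdis` and
#'   `sdis`.
#' @param device_params [device_model_params()].
#' @param seed Master integer seed; per-participant seeds are derived from
#'   it.
#' @return List of cohort records; each record is a list with
#'   `participant_id`, `group` (`"NoSDis"`/`"SDis"`), `psg_hyp`, `dev_hyp`,
#'   `markers`, `truth` (the generating parameters and seeds).
#' @export
simulate_cohort <- function(n_no_sdis = 20, n_sdis = 25,
                            presets = list(no_sdis = psg_preset("no_sdis"),
                                           sdis = psg_preset("sdis")),
                            device_params = device_model_params(),
                            seed = 1) {
  stopifnot(n_no_sdis >= 0, n_sdis >= 0)
  set.seed(as.integer(seed))
  n <- n_no_sdis + n_sdis
  if (n == 0L) return(list())
  part_seeds <- sample.int(.Machine$integer.max %/% 2L, 2L * n)
  groups <- rep(c("NoSDis", "SDis"), c(n_no_sdis, n_sdis))
  lapply(seq_len(n), function(i) {
    preset <- if (groups[i] == "NoSDis") presets$no_sdis else presets$sdis
    night <- simulate_psg_hypnogram(preset, part_seeds[2L * i - 1L],
                                    lights_off = as.POSIXct("2023-03-01 23:36:00",
                                                            tz = "UTC"))
    dev <- simulate_device_hypnogram(night$hypnogram, night$markers,
                                     device_params, part_seeds[2L * i])
    list(
      participant_id = sprintf("P%03d", i),
      group = groups[i],
      psg_hyp = night$hypnogram,
      dev_hyp = dev,
      markers = night$markers,
      truth = list(psg_seed = part_seeds[2L * i - 1L],
                   dev_seed = part_seeds[2L * i],
                   preset = preset, device_params = device_params)
    )
  })
}

#' Recover the device emission matrix from a cohort
#'
#' Parameter-recovery estimator: for each night, recomputes the 1-minute
#' frame reference labels the emission was applied to and cross-tabulates
#' them against the device's emitted frames over the device record's span;
#' pooled counts are row-normalised. The first frame of each record is
#' excluded: the record starts at the first emitted sleep frame, so that
#' frame's emission is conditioned on being sleep and would bias the
#' estimate. The remaining frames' emissions are independent of the
#' truncation, making the estimator unbiased for the generating emission
#' (unlike the pipeline's 30-s pooled confusion, which mixes frames at
#' stage transitions).
#'
#' @param cohort A list of records from [simulate_cohort()].
#' @return Row-normalised 4x4 matrix over `DEV4`.
#' @export
estimate_emission <- function(cohort) {
  counts <- matrix(0, 4, 4, dimnames = list(DEV4, DEV4))
  for (rec in cohort) {
    ref <- frame_reference_labels(merge_stages(rec$psg_hyp))
    dev <- rec$dev_hyp
    if (length(dev$stages) < 2L) next
    offset <- as.numeric(difftime(dev$start, rec$psg_hyp$start, units = "secs"))
    from <- as.integer(round(offset / 60)) + 1L
    idx <- from:(from + length(dev$stages) - 1L)
    keep <- idx >= 1L & idx <= length(ref)
    keep[1L] <- FALSE  # record start is conditioned on an emitted sleep frame
    counts <- counts + table(factor(ref[idx[keep]], levels = DEV4),
                             factor(dev$stages[keep], levels = DEV4))
  }
  counts / rowSums(counts)
}

#' Write a cohort as fixture files
#'
#' One EDF+ PSG file and one device CSV per participant, plus a group
#' manifest (`participant_id,group`) and a `truth.json` with the generating
#' seeds. Identical seeds give byte-identical files.
#'
#' @param cohort From [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_fixtures <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(participant_id = character(0), group = character(0))
  truth <- list()
  for (rec in cohort) {
    write_edfplus_hypnogram(rec$psg_hyp, rec$markers,
                            file.path(dir, paste0(rec$participant_id, "_psg.edf")))
    write_hypnogram_csv(rec$dev_hyp,
                        file.path(dir, paste0(rec$participant_id, "_device.csv")))
    manifest <- rbind(manifest, data.frame(participant_id = rec$participant_id,
                                           group = rec$group))
    truth[[rec$participant_id]] <- list(psg_seed = rec$truth$psg_seed,
                                        dev_seed = rec$truth$dev_seed,
                                        group = rec$group)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
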