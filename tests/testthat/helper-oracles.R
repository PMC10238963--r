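# Shared fixture builders and independent oracles.

T0 <- as.POSIXct("2023-03-01 23:00:00", tz = "UTC")

hyp30 <- function(stages, vocabulary = "DEV4", start = T0) {
  hypnogram(stages, start, 30, vocabulary)
}

window_for <- function(hyp) {
  recording_markers(hyp$start, hypnogram_end(hyp))
}

# random DEV4 hypnogram tiling its own window (no UNSCORED)
random_dev4_night <- function(n_epochs, start = T0,
                              probs = c(0.2, 0.45, 0.15, 0.2)) {
  hyp30(sample(DEV4, n_epochs, replace = TRUE, prob = probs), start = start)
}

# Brute-force sleep-parameter oracle: explicit per-epoch scan and run
# counting, independent of compute_sleep_parameters' vectorised path.
oracle_sleep_params <- function(stages, tib_min) {
  sleep <- stages %in% c("LIGHT", "DEEP", "REM")
  out <- list(tib = tib_min, tst = sum(sleep) / 2,
              light = sum(stages == "LIGHT") / 2,
              deep = sum(stages == "DEEP") / 2,
              rem = sum(stages == "REM") / 2)
  if (!any(sleep)) {
    out <- c(out, list(sol = tib_min, tspd = 0, waso = 0, awakenings = 0,
                       se = 0, awake = tib_min))
    return(out)
  }
  i1 <- min(which(sleep)); i2 <- max(which(sleep))
  waso <- 0; awakenings <- 0; run <- 0
  for (k in i1:i2) {
    if (!sleep[k]) {
      waso <- waso + 0.5
      run <- run + 1
    } else {
      if (run * 0.5 > 5) awakenings <- awakenings + 1
      run <- 0
    }
  }
  c(out, list(sol = (i1 - 1) * 0.5, tspd = (i2 - i1 + 1) * 0.5, waso = waso,
              awakenings = awakenings, se = 100 * sum(sleep) / 2 / tib_min,
              awake = tib_min - sum(sleep) / 2))
}

# Naive per-epoch counting oracle for agreement metrics.
oracle_metrics <- function(ref, dev) {
  both_sleep <- function(x) ifelse(x %in% c("LIGHT", "DEEP", "REM"), "SLEEP", x)
  r2 <- both_sleep(ref); d2 <- both_sleep(dev)
  n <- length(ref)
  list(
    accuracy2 = sum(r2 == d2) / n,
    sens = sum(r2 == "SLEEP" & d2 == "SLEEP") / sum(r2 == "SLEEP"),
    spec = sum(r2 == "WAKE" & d2 == "WAKE") / sum(r2 == "WAKE"),
    accuracy4 = sum(ref == dev) / n,
    kappa2 = oracle_kappa(r2, d2, c("WAKE", "SLEEP")),
    kappa4 = oracle_kappa(ref, dev, DEV4)
  )
}

oracle_kappa <- function(a, b, classes) {
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (c1 in classes) pe <- pe + sum(a == c1) / n * sum(b == c1) / n
  (po - pe) / (1 - pe)
}

# Exact finite-horizon expected stage minutes of the generator's chain:
# mean over epochs of the state distribution, times horizon (matrix-power
# recursion, independent of the simulation path).
expected_stage_minutes <- function(params, n_epochs) {
  v <- params$initial
  total <- numeric(5)
  for (i in seq_len(n_epochs)) {
    total <- total + v
    v <- as.vector(v %*% params$transition)
  }
  stats::setNames(total / n_epochs * n_epochs / 2, AASM5)
}
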