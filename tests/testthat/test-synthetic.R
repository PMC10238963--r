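test_that("generator parameter objects validate their inputs", {
  expect_error(psg_model_params(matrix(1, 4, 4)), "5x5")
  bad <- diag(5); bad[1, 1] <- 0.5
  expect_error(psg_model_params(bad), "sum to 1")
  expect_error(device_model_params(matrix(0.25, 4, 5)), "4x4")
  expect_error(device_model_params(onset_delay_min = -1), ">= 0")
  expect_equal(unname(rowSums(default_device_emission())), rep(1, 4))
})

test_that("simulation is deterministic given the seed", {
  p <- psg_preset("sdis")
  a <- simulate_psg_hypnogram(p, seed = 123)
  b <- simulate_psg_hypnogram(p, seed = 123)
  expect_identical(a$hypnogram$stages, b$hypnogram$stages)
  expect_equal(a$markers$lights_on, b$markers$lights_on)
  c2 <- simulate_psg_hypnogram(p, seed = 124)
  expect_false(identical(a$hypnogram$stages, c2$hypnogram$stages))

  d1 <- simulate_device_hypnogram(a$hypnogram, a$markers, device_model_params(), 5)
  d2 <- simulate_device_hypnogram(a$hypnogram, a$markers, device_model_params(), 5)
  expect_identical(d1$stages, d2$stages)

  co1 <- simulate_cohort(2, 3, seed = 9)
  co2 <- simulate_cohort(2, 3, seed = 9)
  expect_identical(lapply(co1, `[[`, "psg_hyp"), lapply(co2, `[[`, "psg_hyp"))
  expect_identical(vapply(co1, `[[`, character(1), "group"),
                   rep(c("NoSDis", "SDis"), c(2, 3)))
})

test_that("identical seeds give byte-identical fixture files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort_fixtures(simulate_cohort(1, 1, seed = 4), d1)
  write_cohort_fixtures(simulate_cohort(1, 1, seed = 4), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("an absorbing all-wake chain yields an all-wake night", {
  p <- psg_model_params(diag(5), tib_sd_min = 0)
  night <- simulate_psg_hypnogram(p, seed = 1)
  expect_true(all(night$hypnogram$stages == "W"))
})

test_that("simulated stage minutes match the chain's finite-horizon expectation", {
  # fixed TIB so the analytic matrix-power expectation is exact
  for (g in c("no_sdis", "sdis")) {
    p <- psg_preset(g, tib_sd_min = 0)
    n_epochs <- round(p$tib_mean_min) * 2
    expected <- expected_stage_minutes(p, n_epochs)
    sims <- vapply(1:400, function(s) {
      h <- simulate_psg_hypnogram(p, seed = 10000 + s)$hypnogram
      vapply(AASM5, function(st) sum(h$stages == st) / 2, numeric(1))
    }, numeric(5))
    mean_min <- rowMeans(sims)
    tst_sim <- sum(mean_min[c("N1", "N2", "N3", "REM")])
    tst_exp <- sum(expected[c("N1", "N2", "N3", "REM")])
    expect_lt(abs(tst_sim - tst_exp), 10)
    expect_lt(max(abs(mean_min - expected)), 10)
  }
})

test_that("noiseless device (identity emission, zero delays) reproduces the night", {
  # frame-aligned truth: stages constant within each minute, so the
  # majority-vote coarsening is lossless
  set.seed(55)
  minute_stages <- sample(c("W", "N2", "N3", "REM"), 240, replace = TRUE,
                          prob = c(0.15, 0.5, 0.15, 0.2))
  psg <- hypnogram(rep(minute_stages, each = 2), T0, 30, "AASM5")
  w <- window_for(psg)
  dev <- simulate_device_hypnogram(psg, w,
                                   device_model_params(emission = diag(4)),
                                   seed = 8)
  res <- process_record(psg, dev, w)
  expect_equal(as.numeric(cohens_kappa(res$cm4)), 1)
  expect_equal(res$params_ref$tst_min, res$params_dev$tst_min)
  expect_equal(res$params_ref$light_min, res$params_dev$light_min)
  expect_equal(res$params_ref$deep_min, res$params_dev$deep_min)
  expect_equal(res$params_ref$rem_min, res$params_dev$rem_min)
})

test_that("all-light emission makes 4-way accuracy equal the LIGHT prevalence", {
  p <- psg_preset("no_sdis", tib_sd_min = 0)
  night <- simulate_psg_hypnogram(p, seed = 77)
  em <- matrix(rep(c(0, 1, 0, 0), each = 4), 4)  # every row emits LIGHT
  dev <- simulate_device_hypnogram(night$hypnogram, night$markers,
                                   device_model_params(emission = em), seed = 3)
  expect_true(all(dev$stages == "LIGHT"))
  res <- process_record(night$hypnogram, dev, night$markers)
  m4 <- multiclass_metrics(res$cm4)
  ref_light_prev <- mean(res$pairs$ref == "LIGHT")
  expect_equal(m4$accuracy, ref_light_prev)
})

test_that("device record truncation conserves TIB coverage", {
  p <- psg_preset("no_sdis", tib_sd_min = 0)
  night <- simulate_psg_hypnogram(p, seed = 13)
  dp <- device_model_params(onset_delay_min = 7, offset_advance_min = 5)
  dev <- simulate_device_hypnogram(night$hypnogram, night$markers, dp, seed = 13)
  tib <- tib_minutes(night$markers)
  truncated <- as.numeric(difftime(dev$start, night$markers$lights_off,
                                   units = "mins")) +
    as.numeric(difftime(night$markers$lights_on, hypnogram_end(dev),
                        units = "mins"))
  expect_equal(length(dev) + truncated, tib)
  # padded wake fills exactly the truncated minutes
  padded <- pad_device_wake(dev, night$markers)
  expect_equal(length(padded) / 2, tib)
})

test_that("default cohort reproduces the qualitative validation findings", {
  cohort <- simulate_cohort(seed = 11)
  expect_length(cohort, 45)
  rep <- suppressMessages(run_validation(cohort))
  pooled <- rep$agreement$total$two_way$pooled
  # sleep sensitivity far exceeds wake specificity
  expect_gt(pooled$sensitivity_sleep, pooled$specificity_wake + 0.3)
  # emission favours sleep for reference-wake frames -> negative TST bias
  tst_row <- rep$comparisons[rep$comparisons$grouping == "total" &
                               rep$comparisons$parameter == "tst_min", ]
  expect_lt(tst_row$bias, 0)
})

test_that("empty cohort and no-sleep device edge cases error cleanly", {
  expect_length(simulate_cohort(0, 0, seed = 1), 0)
  expect_error(run_validation(list()), "no analysable")

  p <- psg_model_params(diag(5), tib_sd_min = 0)  # all-wake night
  night <- simulate_psg_hypnogram(p, seed = 2)
  em <- matrix(rep(c(1, 0, 0, 0), each = 4), 4)  # device always says wake
  expect_warning(
    dev <- simulate_device_hypnogram(night$hypnogram, night$markers,
                                     device_model_params(emission = em),
                                     seed = 2),
    "no sleep"
  )
  expect_length(dev, 0)
})
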