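test_that("normality gate routes by Shapiro-Wilk over repeated draws", {
  t_hits <- 0; w_hits <- 0
  for (s in 1:100) {
    set.seed(s)
    if (normality_gate(stats::rnorm(45, 0, 70)) == "t") t_hits <- t_hits + 1
    set.seed(s)
    if (normality_gate(stats::rexp(45) * 60) == "wilcoxon") w_hits <- w_hits + 1
  }
  expect_gte(t_hits, 90)
  expect_gte(w_hits, 90)

  g <- normality_gate(rep(3.5, 45))
  expect_identical(as.character(g), "wilcoxon")
  expect_true(attr(g, "degenerate"))
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("paired Cohen's d reproduces published bias/SD cross-checks", {
  # d is fully determined by mean and SD of the differences; synthesise a
  # 3-point set with exactly the published moments
  diffs_with <- function(m, s) m + s * c(-1, 0, 1)
  d1 <- cohens_d_paired(diffs_with(-29.54, 72.54))
  expect_equal(round(d1$d, 3), -0.407)
  expect_identical(d1$label, "small")
  d2 <- cohens_d_paired(diffs_with(2.95, 2.57))
  expect_equal(round(d2$d, 2), 1.15)
  expect_identical(d2$label, "large")

  const <- cohens_d_paired(rep(2, 10))
  expect_true(const$undefined)

  # label boundaries
  expect_identical(cohens_d_paired(0.19 + c(-1, 0, 1))$label, "negligible")
  expect_identical(cohens_d_paired(0.5 + c(-1, 0, 1))$label, "moderate")
})

test_that("paired_compare runs the gated test and fills the comparison", {
  set.seed(7)
  ref <- stats::rnorm(45, 344, 80)
  dev <- ref + stats::rnorm(45, 29.5, 72.5)
  pc <- paired_compare(ref, dev, parameter = "tst_min")
  expect_identical(pc$test_used, "t")
  expect_equal(pc$n, 45)
  expect_equal(pc$cohens_d, mean(ref - dev) / stats::sd(ref - dev))
  # cross-check statistic and p against stats::t.test directly
  tt <- stats::t.test(ref - dev)
  expect_equal(pc$statistic, unname(tt$statistic))
  expect_equal(pc$p_value, tt$p.value)

  ident <- paired_compare(ref, ref)
  expect_equal(ident$p_value, 1)
  expect_equal(ident$cohens_d, 0)

  expect_error(paired_compare(1:5, 1:4), "equal length")
})

test_that("wilcoxon branch z and p agree with stats::wilcox.test", {
  set.seed(12)
  diffs <- stats::rexp(45) * 60 - 10
  ref <- stats::rnorm(45, 300, 50)
  dev <- ref - diffs
  pc <- paired_compare(ref, dev)
  expect_identical(pc$test_used, "wilcoxon")
  wt <- suppressWarnings(stats::wilcox.test(ref, dev, paired = TRUE,
                                            correct = TRUE, exact = FALSE))
  expect_equal(pc$p_value, wt$p.value, tolerance = 1e-10)
  # z consistent with the two-sided normal p
  expect_equal(2 * stats::pnorm(-abs(pc$statistic)), pc$p_value)
})

test_that("rejection rate of the gated paired test matches paired-t power", {
  n <- 45; bias <- 30; sdd <- 70; alpha <- 0.05
  ncp <- sqrt(n) * bias / sdd
  crit <- stats::qt(1 - alpha / 2, n - 1)
  power <- 1 - stats::pt(crit, n - 1, ncp) + stats::pt(-crit, n - 1, ncp)
  set.seed(2024)
  rejections <- mean(replicate(400, {
    d <- stats::rnorm(n, bias, sdd)
    ref <- stats::rnorm(n, 350, 60)
    paired_compare(ref, ref - d)$p_value < alpha
  }))
  expect_lt(abs(rejections - power), 3 * sqrt(power * (1 - power) / 400))
})

test_that("bland_altman computes bias, limits, CI and exceedance", {
  # identity
  x <- stats::rnorm(20, 100, 10)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)
  expect_equal(ba0$n_exceeding, 0L, ignore_attr = TRUE)

  # hand computation for differences {-1, +1}
  ba <- bland_altman(c(9, 11), c(10, 10))
  expect_equal(ba$bias, 0)
  expect_equal(round(ba$sd, 3), 1.414)
  expect_equal(round(ba$loa_high, 3), 2.772)
  expect_equal(round(ba$loa_low, 3), -2.772)
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * ba$sd)
  expect_equal(ba$ci95[2] - ba$ci95[1],
               2 * stats::qt(0.975, 1) * ba$sd / sqrt(2))

  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("bland_altman recovers parameters with ~5% exceedance at large n", {
  set.seed(99)
  n <- 20000
  ref <- stats::rnorm(n, 350, 60)
  dev <- ref - stats::rnorm(n, -29.54, 72.54)
  ba <- bland_altman(ref, dev)
  expect_lt(abs(ba$bias - (-29.54)), 2)
  expect_lt(abs(ba$sd - 72.54), 2)
  expect_lt(abs(ba$n_exceeding / n - 0.05), 0.01)
})

test_that("bland_altman sign convention and translation equivariance", {
  ref <- c(300, 320, 350, 400)
  dev <- ref + 25  # device uniformly larger -> overestimation -> bias < 0
  ba <- bland_altman(ref, dev)
  expect_lt(ba$bias, 0)

  shift <- bland_altman(ref, dev + 7)
  expect_equal(shift$bias, ba$bias - 7)
  expect_equal(shift$sd, ba$sd)
  expect_equal(shift$loa_low, ba$loa_low - 7)
  expect_equal(shift$loa_high, ba$loa_high - 7)
})

test_that("comparison_table produces per-parameter rows for all groupings", {
  set.seed(3)
  n <- 12
  mk <- function() data.frame(
    tspd_min = stats::rnorm(n, 400, 40), tst_min = stats::rnorm(n, 350, 50),
    waso_min = stats::rexp(n, 1 / 50), awakenings_n = stats::rpois(n, 3),
    sol_min = stats::rexp(n, 1 / 30), se_pct = stats::runif(n, 60, 95),
    light_min = stats::rnorm(n, 215, 40), deep_min = stats::rnorm(n, 60, 20),
    rem_min = stats::rnorm(n, 70, 25), awake_min = stats::rexp(n, 1 / 90)
  )
  grp <- rep(c("NoSDis", "SDis"), each = 6)
  tab <- comparison_table(mk(), mk(), group = grp)
  expect_equal(sort(unique(tab$grouping)), c("NoSDis", "SDis", "total"))
  expect_equal(nrow(tab), 30)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1, na.rm = TRUE))
  expect_true(all(tab$loa_high >= tab$loa_low, na.rm = TRUE))

  # subgroup with n < 3 gets no inferential columns
  tiny <- comparison_table(mk()[1:4, ], mk()[1:4, ],
                           group = c("A", "A", "B", "B"))
  expect_true(all(is.na(tiny$p_value[tiny$grouping %in% c("A", "B")])))
  expect_false(anyNA(tiny$bias))

  same <- mk()
  allsame <- comparison_table(same, same)
  expect_true(all(allsame$bias == 0))
})
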