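# Parameter-level comparison between the device and the reference.
#
# For each summary parameter the per-participant reference-minus-device
# differences are tested with a paired two-tailed t test when the
# Shapiro-Wilk test does not reject normality (alpha 0.05), and with the
# Wilcoxon signed-rank test otherwise (z via the normal approximation with
# tie correction and continuity correction).  Effect size is the paired
# Cohen's d = mean(diff)/SD(diff) (sample SD).  Method agreement per
# parameter uses Bland-Altman bias and 95% limits of agreement.
# Sign convention: differences are reference - device, so a positive bias
# means the device underestimates the parameter and a negative bias means
# it overestimates it.

#' Choose the paired test by a Shapiro-Wilk normality gate
#'
#' @param diffs Per-participant paired differences (n >= 3).
#' @param alpha Gate level; Shapiro-Wilk p >= alpha selects the t test.
#' @return `"t"` or `"wilcoxon"`. Constant differences (Shapiro-Wilk
#'   undefined) route to `"wilcoxon"` with attribute `degenerate = TRUE`.
#' @export
normality_gate <- function(diffs, alpha = 0.05) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 3L)
    stop("normality gate needs at least 3 differences", call. = FALSE)
  if (stats::sd(diffs) == 0)
    return(structure("wilcoxon", degenerate = TRUE))
  p <- stats::shapiro.test(diffs)$p.value
  if (p >= alpha) "t" else "wilcoxon"
}

#' Paired comparison of a parameter between methods
#'
#' Runs the normality-gated two-sided paired test on `ref - dev` and
#' reports the statistic, p-value and paired Cohen's d.
#'
#' @param ref,dev Equal-length per-participant parameter vectors
#'   (reference and device), pairwise complete, n >= 3.
#' @param parameter Optional parameter name carried into the result.
#' @param alpha Normality-gate level.
#' @return An object of class `paired_comparison`: list with `parameter`,
#'   `n`, `mean_ref`, `mean_dev`, `sd_ref`, `sd_dev`, `test_used`,
#'   `statistic`, `p_value`, `cohens_d`, `d_label`.
#' @export
paired_compare <- function(ref, dev, parameter = NULL, alpha = 0.05) {
  ref <- as.numeric(ref); dev <- as.numeric(dev)
  if (length(ref) != length(dev))
    stop("ref and dev must have equal length", call. = FALSE)
  if (anyNA(ref) || anyNA(dev))
    stop("paired_compare requires pairwise-complete data", call. = FALSE)
  diffs <- ref - dev
  test <- normality_gate(diffs, alpha)
  if (test == "t") {
    fit <- stats::t.test(ref, dev, paired = TRUE)
    statistic <- unname(fit$statistic)
    p <- fit$p.value
  } else if (stats::sd(diffs) == 0) {
    statistic <- NA_real_
    p <- if (all(diffs == 0)) 1 else NA_real_
  } else {
    sr <- signed_rank_z(diffs)
    statistic <- sr$z
    p <- sr$p
  }
  d <- cohens_d_paired(diffs)
  structure(
    list(
      parameter = parameter, n = length(diffs),
      mean_ref = mean(ref), mean_dev = mean(dev),
      sd_ref = stats::sd(ref), sd_dev = stats::sd(dev),
      test_used = as.character(test), statistic = statistic, p_value = p,
      cohens_d = d$d, d_label = d$label
    ),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison>%s n=%d  ref %.2f (%.2f) vs dev %.2f (%.2f)\n  %s test: statistic %.3f, p %.4g, d %.3f (%s)\n",
    if (is.null(x$parameter)) "" else paste0(" ", x$parameter),
    x$n, x$mean_ref, x$sd_ref, x$mean_dev, x$sd_dev,
    x$test_used, x$statistic, x$p_value, x$cohens_d, x$d_label))
  invisible(x)
}

# Wilcoxon signed-rank statistic with normal approximation:
# z = (W+ - n'(n'+1)/4 -/+ 0.5) / sqrt(var), tie-corrected variance, zeros
# dropped (Wilcoxon's convention, as stats::wilcox.test does).
signed_rank_z <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) return(list(z = NA_real_, p = 1, w = NA_real_))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(w - mu) * 0.5
  z <- if (v > 0) (w - mu - cc) / sqrt(v) else 0
  list(z = z, p = 2 * stats::pnorm(-abs(z)), w = w)
}

#' Paired Cohen's d with ordinal label
#'
#' `d = mean(diffs) / SD(diffs)` (sample SD, n-1). Magnitude labels:
#' negligible (<0.2), small (0.2-0.5), moderate (0.5-0.8), large (>=0.8).
#'
#' @param diffs Paired differences, n >= 2.
#' @return List with `d`, `label`, and `undefined = TRUE` when SD is 0.
#' @export
cohens_d_paired <- function(diffs) {
  diffs <- as.numeric(diffs)
  if (length(diffs) < 2L)
    stop("cohens_d_paired needs at least 2 differences", call. = FALSE)
  s <- stats::sd(diffs)
  if (s == 0)
    return(list(d = 0, label = "negligible", undefined = TRUE))
  d <- mean(diffs) / s
  a <- abs(d)
  label <- if (a < 0.2) "negligible" else if (a < 0.5) "small"
           else if (a < 0.8) "moderate" else "large"
  list(d = d, label = label)
}

#' Bland-Altman method agreement
#'
#' Bias = mean(ref - dev); 95% limits of agreement = bias +/- 1.96 * SD of
#' the differences (sample SD); 95% CI of the bias uses the t distribution.
#' A positive bias means the device underestimates the parameter; a
#' negative bias means it overestimates it.
#'
#' @param ref,dev Equal-length paired parameter vectors (n >= 2).
#' @param parameter Optional parameter name carried into the result.
#' @return An object of class `bland_altman`: list with `parameter`, `n`,
#'   `bias`, `sd`, `ci95` (length-2), `loa_low`, `loa_high`, `n_exceeding`
#'   (differences strictly outside the limits), plus the `means` and
#'   `diffs` vectors for plotting.
#' @export
bland_altman <- function(ref, dev, parameter = NULL) {
  ref <- as.numeric(ref); dev <- as.numeric(dev)
  if (length(ref) != length(dev))
    stop("ref and dev must have equal length", call. = FALSE)
  n <- length(ref)
  if (n < 2L) stop("bland_altman needs n >= 2", call. = FALSE)
  diffs <- ref - dev
  bias <- mean(diffs)
  s <- stats::sd(diffs)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  loa <- bias + c(-1, 1) * 1.96 * s
  structure(
    list(
      parameter = parameter, n = n, bias = bias, sd = s,
      ci95 = bias + c(-half, half),
      loa_low = loa[1], loa_high = loa[2],
      n_exceeding = sum(diffs < loa[1] | diffs > loa[2]),
      means = (ref + dev) / 2, diffs = diffs
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman>%s n=%d  bias %.2f (SD %.2f; 95%% CI %.2f to %.2f)\n  limits %.2f to %.2f, %d exceeding\n",
    if (is.null(x$parameter)) "" else paste0(" ", x$parameter),
    x$n, x$bias, x$sd, x$ci95[1], x$ci95[2],
    x$loa_low, x$loa_high, x$n_exceeding))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Per-participant differences against means with bias and 95% limits of
#' agreement as dashed lines.
#'
#' @param x A [bland_altman()] object.
#' @param group Optional factor for plotting symbols (e.g. sleep-disorder
#'   group; circles/triangles).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, group = NULL, ...) {
  pch <- if (is.null(group)) 19 else c(1, 2)[as.integer(factor(group))]
  graphics::plot(x$means, x$diffs, pch = pch,
                 xlab = "Mean of methods", ylab = "Reference - device",
                 main = if (is.null(x$parameter)) "" else x$parameter, ...)
  graphics::abline(h = 0, col = "grey60")
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Parameter comparison table for a cohort
#'
#' For every sleep parameter, runs [paired_compare()] and [bland_altman()]
#' on the per-participant reference and device values, for the total sample
#' and optionally per group. Subgroups with n < 3 get no inferential
#' columns.
#'
#' @param params_ref,params_dev `data.frame`s of per-participant parameters
#'   (rows = participants, columns as in
#'   [as.data.frame.sleep_parameters()]), aligned row-wise.
#' @param group Optional per-participant group factor.
#' @param parameters Character vector of parameter columns to compare.
#' @param alpha Normality-gate level.
#' @return A `data.frame` with one row per parameter x grouping: means/SDs,
#'   test used, statistic, p, Cohen's d, Bland-Altman bias/SD/CI/limits and
#'   exceedance count.
#' @export
comparison_table <- function(params_ref, params_dev, group = NULL,
                             parameters = c("tspd_min", "tst_min", "waso_min",
                                            "awakenings_n", "sol_min", "se_pct",
                                            "light_min", "deep_min", "rem_min",
                                            "awake_min"),
                             alpha = 0.05) {
  stopifnot(nrow(params_ref) == nrow(params_dev))
  groupings <- list(total = rep(TRUE, nrow(params_ref)))
  if (!is.null(group)) {
    group <- as.factor(group)
    for (g in levels(group)) groupings[[g]] <- group == g
  }
  rows <- list()
  for (gname in names(groupings)) {
    sel <- groupings[[gname]]
    for (p in parameters) {
      ref <- params_ref[[p]][sel]
      dev <- params_dev[[p]][sel]
      n <- sum(sel)
      ba <- if (n >= 2) bland_altman(ref, dev, p) else NULL
      pc <- if (n >= 3) paired_compare(ref, dev, p, alpha) else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        grouping = gname, parameter = p, n = n,
        mean_ref = mean(ref), sd_ref = stats::sd(ref),
        mean_dev = mean(dev), sd_dev = stats::sd(dev),
        test_used = if (is.null(pc)) NA_character_ else pc$test_used,
        statistic = if (is.null(pc)) NA_real_ else pc$statistic,
        p_value = if (is.null(pc)) NA_real_ else pc$p_value,
        cohens_d = if (is.null(pc)) NA_real_ else pc$cohens_d,
        d_label = if (is.null(pc)) NA_character_ else pc$d_label,
        bias = if (is.null(ba)) NA_real_ else ba$bias,
        diff_sd = if (is.null(ba)) NA_real_ else ba$sd,
        ci95_low = if (is.null(ba)) NA_real_ else ba$ci95[1],
        ci95_high = if (is.null(ba)) NA_real_ else ba$ci95[2],
        loa_low = if (is.null(ba)) NA_real_ else ba$loa_low,
        loa_high = if (is.null(ba)) NA_real_ else ba$loa_high,
        n_exceeding = if (is.null(ba)) NA_integer_ else ba$n_exceeding,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
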