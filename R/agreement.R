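# Epoch-by-epoch agreement, per the consumer-sleep-technology evaluation
# framework's two compliance levels:
#   level 1: 2-way sleep/wake classification (accuracy, sensitivity for the
#            sleep class, specificity for the wake class, Cohen's kappa);
#   level 2: 4-way stage classification (overall accuracy, per-class recall
#            and PPV, Cohen's kappa).
# Reference (PSG) labels index rows; device labels index columns.  Metrics
# are computed both pooled (matrices summed over participants) and as
# per-participant mean (SD), which differ and are reported separately.

TWO_WAY_CLASSES <- c("WAKE", "SLEEP")

#' Epoch cross-tabulation of an aligned pair series
#'
#' @param pairs An `epoch_pairs` object from [align_pair()], or a list with
#'   character vectors `ref` and `dev` over the `DEV4` labels.
#' @param mode `"two_way"` collapses `LIGHT`/`DEEP`/`REM` into `SLEEP` on
#'   both sides; `"four_way"` keeps `WAKE`/`LIGHT`/`DEEP`/`REM`.
#' @return A `confusion_matrix`: integer matrix (reference rows, device
#'   columns) with attributes `classes` and `n`.
#' @export
confusion_matrix <- function(pairs, mode = c("two_way", "four_way")) {
  mode <- match.arg(mode)
  if (length(pairs$ref) == 0L)
    stop("empty pair series", call. = FALSE)
  ref <- pairs$ref
  dev <- pairs$dev
  if (mode == "two_way") {
    ref <- ifelse(ref %in% DEV4_SLEEP, "SLEEP", ref)
    dev <- ifelse(dev %in% DEV4_SLEEP, "SLEEP", dev)
    classes <- TWO_WAY_CLASSES
  } else {
    classes <- DEV4
  }
  counts <- table(factor(ref, levels = classes), factor(dev, levels = classes))
  as_confusion_matrix(unclass(counts), classes)
}

#' Build a confusion matrix from counts
#'
#' @param counts Square numeric matrix, reference rows x device columns.
#' @param classes Ordered class labels.
#' @return A `confusion_matrix` object.
#' @export
as_confusion_matrix <- function(counts, classes = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  dimnames(counts) <- list(reference = classes, device = classes)
  structure(counts, class = c("confusion_matrix", "matrix"),
            classes = classes, n = sum(counts))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, n = %d epochs\n",
              nrow(x), as.integer(sum(x))))
  print(unclass(x)[,])
  invisible(x)
}

#' 2-way sleep/wake agreement metrics
#'
#' Accuracy, sensitivity of sleep detection (reference-sleep epochs called
#' sleep) and specificity of wake detection (reference-wake epochs called
#' wake). A metric whose reference class is empty is `NA`, not 0.
#'
#' @param cm A 2x2 `confusion_matrix` with classes `(WAKE, SLEEP)`.
#' @return List with `accuracy`, `sensitivity_sleep`, `specificity_wake`,
#'   `kappa`, `kappa_label`, `n`.
#' @export
binary_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (!identical(attr(cm, "classes"), TWO_WAY_CLASSES))
    stop("binary_metrics expects classes (WAKE, SLEEP)", call. = FALSE)
  n <- sum(cm)
  wake_n <- sum(cm["WAKE", ])
  sleep_n <- sum(cm["SLEEP", ])
  k <- cohens_kappa(cm)
  list(
    accuracy = (cm["WAKE", "WAKE"] + cm["SLEEP", "SLEEP"]) / n,
    sensitivity_sleep = if (sleep_n > 0) cm["SLEEP", "SLEEP"] / sleep_n else NA_real_,
    specificity_wake = if (wake_n > 0) cm["WAKE", "WAKE"] / wake_n else NA_real_,
    kappa = k,
    kappa_label = kappa_label(k),
    n = as.integer(n)
  )
}

#' 4-way stage agreement metrics
#'
#' Overall accuracy plus two per-class families: recall (row-wise, reference
#' epochs of a class detected as that class) and positive predictive value
#' (column-wise, device calls of a class that are correct). Both are
#' reported because pooled per-class "agreement" figures in the validation
#' literature mix the two.
#'
#' @param cm A k x k `confusion_matrix` (typically 4-way).
#' @return List with `accuracy`, `per_class_recall`, `per_class_ppv`,
#'   `kappa`, `kappa_label`, `n`. Empty rows/columns yield `NA` entries.
#' @export
multiclass_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- sum(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  k <- cohens_kappa(cm)
  list(
    accuracy = sum(diag(cm)) / n,
    per_class_recall = ifelse(rs > 0, diag(cm) / rs, NA_real_),
    per_class_ppv = ifelse(cs > 0, diag(cm) / cs, NA_real_),
    kappa = k,
    kappa_label = kappa_label(k),
    n = as.integer(n)
  )
}

#' Cohen's chance-corrected agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace/n` and expected agreement
#' `p_e = sum_c rowsum_c * colsum_c / n^2`. In the degenerate single-class
#' case (`p_e = 1`) kappa is reported as 1 if `p_o = 1` and 0 otherwise,
#' with attribute `degenerate = TRUE`.
#'
#' @param cm A `confusion_matrix` (or square count matrix) with `n > 0`.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  counts <- as.matrix(cm)
  n <- sum(counts)
  if (n <= 0) stop("cohens_kappa requires n > 0", call. = FALSE)
  p_o <- sum(diag(counts)) / n
  p_e <- sum(rowSums(counts) * colSums(counts)) / n^2
  if (1 - p_e < .Machine$double.eps^0.5) {
    k <- if (isTRUE(all.equal(p_o, 1))) 1 else 0
    return(structure(k, degenerate = TRUE))
  }
  (p_o - p_e) / (1 - p_e)
}

#' Ordinal label for a kappa value
#'
#' Standard bins: slight (0-0.2), fair (0.21-0.40), moderate (0.41-0.60),
#' substantial (0.61-0.80), almost perfect (>0.80); negative values are
#' labelled `"poor"`. Because the published bin edges are given to 2
#' decimals, boundaries are placed at 0.205, 0.405, 0.605, 0.805 so that a
#' value printed as 0.20 and one printed as 0.21 fall in adjacent bins.
#'
#' @param kappa Value in `[-1, 1]`.
#' @return One of `"poor"`, `"slight"`, `"fair"`, `"moderate"`,
#'   `"substantial"`, `"almost perfect"`.
#' @export
kappa_label <- function(kappa) {
  kappa <- as.numeric(kappa)
  if (is.na(kappa) || kappa < -1 - 1e-9 || kappa > 1 + 1e-9)
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  if (kappa < 0) "poor"
  else if (kappa < 0.205) "slight"
  else if (kappa < 0.405) "fair"
  else if (kappa < 0.605) "moderate"
  else if (kappa < 0.805) "substantial"
  else "almost perfect"
}

#' Cohort-level agreement: pooled and per-participant
#'
#' Pools the per-participant confusion matrices (cellwise sum) and also
#' summarises per-participant metrics as mean (sample SD). Participants for
#' whom a metric is undefined (empty reference class) are excluded from that
#' metric's mean with a logged count.
#'
#' @param cms List of `confusion_matrix` objects, one per participant, all
#'   with the same classes.
#' @return List with `pooled` (the summed `confusion_matrix` plus its
#'   metrics) and `per_participant` (`mean`, `sd`, `n_used` per metric, and
#'   the per-participant metric `table`).
#' @export
cohort_agreement <- function(cms) {
  stopifnot(length(cms) >= 1L)
  classes <- attr(cms[[1]], "classes")
  two_way <- identical(classes, TWO_WAY_CLASSES)
  pooled_counts <- Reduce(`+`, lapply(cms, function(m) as.matrix(m)[,]))
  pooled_cm <- as_confusion_matrix(pooled_counts, classes)
  metric_fun <- if (two_way) binary_metrics else multiclass_metrics

  per <- lapply(cms, function(m) {
    met <- metric_fun(m)
    c(accuracy = met$accuracy, kappa = as.numeric(met$kappa),
      if (two_way) c(sensitivity_sleep = met$sensitivity_sleep,
                     specificity_wake = met$specificity_wake))
  })
  tab <- do.call(rbind, per)
  n_dropped <- colSums(is.na(tab))
  if (any(n_dropped > 0))
    message("participants excluded from per-participant means (undefined metric): ",
            paste(sprintf("%s=%d", names(n_dropped)[n_dropped > 0],
                          n_dropped[n_dropped > 0]), collapse = ", "))
  list(
    pooled = c(list(cm = pooled_cm), metric_fun(pooled_cm)),
    per_participant = list(
      mean = colMeans(tab, na.rm = TRUE),
      sd = apply(tab, 2, stats::sd, na.rm = TRUE),
      n_used = colSums(!is.na(tab)),
      table = tab
    )
  )
}
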