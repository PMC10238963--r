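# Cohort orchestration: harmonize -> parameters -> agreement -> statistics.

#' Harmonize one participant's paired hypnograms
#'
#' Runs the full preprocessing for a night: merges the PSG to the 4-stage
#' vocabulary and restricts it to TIB; pads/windows the device export to
#' TIB with un-exported time scored as wake; aligns the two 30-s series;
#' and computes per-method sleep parameters and 2-way/4-way confusion
#' matrices.
#'
#' @param psg_hyp 30-s `AASM5` [hypnogram()] covering the TIB window.
#' @param dev_hyp `DEV4` [hypnogram()] (1-min export or 30-s).
#' @param markers [recording_markers()].
#' @return List with `pairs`, `params_ref`, `params_dev`, `cm2`, `cm4`.
#' @export
process_record <- function(psg_hyp, dev_hyp, markers) {
  ref30 <- restrict_to_tib(merge_stages(psg_hyp), markers)
  dev30 <- pad_device_wake(dev_hyp, markers)
  pairs <- align_pair(ref30, dev30, markers)
  list(
    pairs = pairs,
    params_ref = compute_sleep_parameters(ref30, markers),
    params_dev = compute_sleep_parameters(dev30, markers),
    cm2 = confusion_matrix(pairs, "two_way"),
    cm4 = confusion_matrix(pairs, "four_way")
  )
}

#' Read a cohort directory
#'
#' Layout: a `manifest.csv` with columns `participant_id,group`, plus per
#' participant `<id>_psg.edf` (EDF+ annotations) and `<id>_device.csv`
#' (device export dialect). Participants with a missing file are skipped
#' and listed under `attrition`.
#'
#' @param dir Cohort directory.
#' @param manifest Path to the manifest (default `dir/manifest.csv`).
#' @return List with `records` (as in [simulate_cohort()]) and `attrition`
#'   (`data.frame` of skipped participants and reasons).
#' @export
read_cohort_dir <- function(dir, manifest = file.path(dir, "manifest.csv")) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("participant_id", "group") %in% names(man)))
  records <- list()
  attrition <- data.frame(participant_id = character(0), reason = character(0))
  for (i in seq_len(nrow(man))) {
    id <- man$participant_id[i]
    psg_path <- file.path(dir, paste0(id, "_psg.edf"))
    dev_path <- file.path(dir, paste0(id, "_device.csv"))
    missing <- c(if (!file.exists(psg_path)) "PSG EDF+",
                 if (!file.exists(dev_path)) "device CSV")
    if (length(missing)) {
      attrition <- rbind(attrition, data.frame(
        participant_id = id, reason = paste("missing", paste(missing, collapse = " and "))))
      next
    }
    psg <- read_edfplus_hypnogram(psg_path)
    records[[length(records) + 1L]] <- list(
      participant_id = id, group = man$group[i],
      psg_hyp = psg$hypnogram, dev_hyp = read_device_csv(dev_path),
      markers = psg$markers
    )
  }
  list(records = records, attrition = attrition)
}

#' Run the full validation analysis over a cohort
#'
#' For every participant: harmonization, per-method sleep parameters and
#' epoch confusion matrices. Then, over the cohort: paired parameter
#' comparisons with Bland-Altman agreement (total sample and per group) and
#' pooled plus per-participant epoch agreement (2-way and 4-way).
#'
#' @param records List of cohort records (see [simulate_cohort()] /
#'   [read_cohort_dir()]): each holds `participant_id`, `group`, `psg_hyp`,
#'   `dev_hyp`, `markers`.
#' @param alpha Normality-gate level for the paired tests.
#' @param out_dir Optional directory; when given, the bundle is written as
#'   `report.json` plus CSV tables.
#' @return A `validation_report`: list with `participants` (per-night
#'   parameter `data.frame`, both methods), `comparisons` (parameter table,
#'   total + per group), `agreement` (per grouping: pooled and
#'   per-participant 2-way/4-way metrics), `attrition`, `n`.
#' @export
run_validation <- function(records, alpha = 0.05, out_dir = NULL) {
  attrition <- data.frame(participant_id = character(0), reason = character(0))
  processed <- list()
  for (rec in records) {
    res <- tryCatch(
      process_record(rec$psg_hyp, rec$dev_hyp, rec$markers),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      message("skipping ", rec$participant_id, ": ", conditionMessage(res))
      attrition <- rbind(attrition, data.frame(
        participant_id = rec$participant_id, reason = conditionMessage(res)))
      next
    }
    res$participant_id <- rec$participant_id
    res$group <- rec$group
    processed[[length(processed) + 1L]] <- res
  }
  if (length(processed) == 0L)
    stop("no analysable participants in the cohort", call. = FALSE)

  ids <- vapply(processed, `[[`, character(1), "participant_id")
  groups <- vapply(processed, `[[`, character(1), "group")
  p_ref <- do.call(rbind, lapply(processed, function(r) as.data.frame(r$params_ref)))
  p_dev <- do.call(rbind, lapply(processed, function(r) as.data.frame(r$params_dev)))
  participants <- rbind(
    cbind(participant_id = ids, group = groups, method = "psg", p_ref),
    cbind(participant_id = ids, group = groups, method = "device", p_dev)
  )

  comparisons <- comparison_table(p_ref, p_dev,
                                  group = if (length(unique(groups)) > 1) groups,
                                  alpha = alpha)

  groupings <- c(list(total = rep(TRUE, length(processed))),
                 lapply(split(seq_along(processed), groups), function(i)
                   seq_along(processed) %in% i))
  agreement <- lapply(groupings, function(sel) {
    list(
      two_way = cohort_agreement(lapply(processed[sel], `[[`, "cm2")),
      four_way = cohort_agreement(lapply(processed[sel], `[[`, "cm4"))
    )
  })

  report <- structure(
    list(participants = participants, comparisons = comparisons,
         agreement = agreement, attrition = attrition,
         n = length(processed), alpha = alpha),
    class = "validation_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.validation_report <- function(x, ...) {
  a2 <- x$agreement$total$two_way$pooled
  a4 <- x$agreement$total$four_way$pooled
  cat(sprintf(paste0(
    "<validation_report> %d participants (%d skipped)\n",
    "  2-way pooled: accuracy %.4f, sensitivity %.4f, specificity %.4f, kappa %.3f (%s)\n",
    "  4-way pooled: accuracy %.4f, kappa %.3f (%s)\n"),
    x$n, nrow(x$attrition),
    a2$accuracy, a2$sensitivity_sleep, a2$specificity_wake, a2$kappa, a2$kappa_label,
    a4$accuracy, a4$kappa, a4$kappa_label))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$participants, file.path(out_dir, "participants.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons, file.path(out_dir, "comparisons.csv"),
                   row.names = FALSE)
  for (g in names(report$agreement)) {
    for (m in c("two_way", "four_way")) {
      cm <- report$agreement[[g]][[m]]$pooled$cm
      utils::write.csv(as.data.frame(unclass(cm)[,]),
                       file.path(out_dir, sprintf("confusion_%s_%s.csv", g, m)))
    }
  }
  json <- list(
    n = report$n,
    attrition = report$attrition,
    comparisons = report$comparisons,
    agreement = lapply(report$agreement, function(g) lapply(g, function(m) {
      list(pooled = c(list(counts = unclass(m$pooled$cm)[,]),
                      m$pooled[setdiff(names(m$pooled), "cm")]),
           per_participant = m$per_participant[c("mean", "sd", "n_used")])
    }))
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Load the packaged published confusion-matrix fixtures
#'
#' @param mode `"two_way"` or `"four_way"`.
#' @return Named list of `confusion_matrix` objects (`total`, `no_sdis`,
#'   `sdis`) encoding the published pooled epoch counts.
#' @export
published_confusions <- function(mode = c("two_way", "four_way")) {
  mode <- match.arg(mode)
  path <- system.file("extdata",
                      if (mode == "two_way") "confusion_2way.csv" else "confusion_4way.csv",
                      package = "hypnoval", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  classes <- if (mode == "two_way") TWO_WAY_CLASSES else DEV4
  out <- lapply(split(raw, raw$group), function(d) {
    m <- matrix(0, length(classes), length(classes),
                dimnames = list(classes, classes))
    m[cbind(d$ref, d$dev)] <- d$count
    as_confusion_matrix(m, classes)
  })
  out[c("total", "no_sdis", "sdis")]
}

#' Load the packaged published parameter summary fixture
#'
#' Per-parameter published means/SDs for both methods plus the published
#' paired effect size and Bland-Altman bias/SD (total sample).
#'
#' @return A `data.frame`, one row per parameter.
#' @export
published_parameters <- function() {
  utils::read.csv(system.file("extdata", "parameter_summary.csv",
                              package = "hypnoval", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Recompute the published epoch-agreement results from packaged fixtures
#'
#' Re-derives, from the packaged pooled confusion counts and parameter
#' summaries, the published agreement percentages and internal identities,
#' and checks each against its printed value at printed precision.
#'
#' @return A `data.frame` with columns `target`, `value`, `expected`,
#'   `tol`, `pass`; attribute `all_pass`.
#' @export
verify_fixtures <- function() {
  cm2 <- published_confusions("two_way")
  cm4 <- published_confusions("four_way")
  pp <- published_parameters()
  row <- function(p) pp[pp$parameter == p, ]

  b_tot <- binary_metrics(cm2$total)
  b_no <- binary_metrics(cm2$no_sdis)
  b_sd <- binary_metrics(cm2$sdis)
  m_tot <- multiclass_metrics(cm4$total)

  targets <- list(
    list("accuracy_2way_pct", 100 * b_tot$accuracy, 77.85, 0.005),
    list("sensitivity_sleep_pct", 100 * b_tot$sensitivity_sleep, 89.56, 0.005),
    list("specificity_wake_pct", 100 * b_tot$specificity_wake, 35.33, 0.005),
    list("accuracy_2way_no_sdis", b_no$accuracy, 0.80, 0.005),
    list("accuracy_2way_sdis", b_sd$accuracy, 0.76, 0.005),
    list("specificity_wake_no_sdis", b_no$specificity_wake, 0.38, 0.005),
    list("specificity_wake_sdis", b_sd$specificity_wake, 0.33, 0.005),
    list("accuracy_4way", m_tot$accuracy, 0.44, 0.005),
    list("wake_as_light_pct",
         100 * cm4$total["WAKE", "LIGHT"] / sum(cm4$total["WAKE", ]), 46.31, 0.005),
    list("rem_as_light_pct",
         100 * cm4$total["REM", "LIGHT"] / sum(cm4$total["REM", ]), 65.01, 0.005),
    list("rem_as_light_sdis_pct",
         100 * cm4$sdis["REM", "LIGHT"] / sum(cm4$sdis["REM", ]), 64.31, 0.005),
    list("psg_tst_stage_sum",
         row("light_min")$mean_psg + row("deep_min")$mean_psg +
           row("rem_min")$mean_psg, row("tst_min")$mean_psg, 0.005),
    list("dev_tspd_tst_waso_sum",
         row("tst_min")$mean_dev + row("waso_min")$mean_dev,
         row("tspd_min")$mean_dev, 0.005),
    list("d_tst_from_bias", row("tst_min")$bias / row("tst_min")$bias_sd,
         row("tst_min")$cohens_d, 0.005),
    list("d_awakenings_from_bias",
         row("awakenings_n")$bias / row("awakenings_n")$bias_sd,
         row("awakenings_n")$cohens_d, 0.005)
  )
  out <- do.call(rbind, lapply(targets, function(t) data.frame(
    target = t[[1]], value = t[[2]], expected = t[[3]], tol = t[[4]],
    stringsAsFactors = FALSE
  )))
  # printed values are rounded, so compare at printed precision: tolerance
  # is half an ulp of the printed value plus slack for the rounding itself
  out$pass <- abs(round(out$value, 4) - out$expected) <=
    pmax(out$tol, 0.5 * 10^(-decimals(out$expected)))
  rownames(out) <- NULL
  structure(out, all_pass = all(out$pass))
}

decimals <- function(x) {
  s <- sub("0+$", "", sub(".*\\.", "", format(x, scientific = FALSE)))
  ifelse(grepl("\\.", format(x, scientific = FALSE)), nchar(s), 0L)
}
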