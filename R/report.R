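.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Write a study report to a directory
#'
#' Emits deterministic plain-text artifacts (re-running on identical input
#' reproduces identical bytes): the cohort summary, one stratified
#' percentage-difference CSV per pair, cross-tab count + row-percent CSVs
#' with a kappa/reclassification JSON, the Bland-Altman summary JSON and
#' its (mean, difference) series CSV, the median-difference series, the
#' filter audit, and a run log (package version, seed if known, section
#' manifest — no timestamps, so outputs stay byte-reproducible). Absent
#' sections are skipped and explained in the log. Optional base-graphics
#' plots (`plots = TRUE`) render the median-difference series and the
#' Bland-Altman scatter as PNGs.
#'
#' @param report a [run_study_analysis()] result.
#' @param out_dir output directory (created if needed).
#' @param plots also write PNG plots (default `FALSE`; CSVs are the
#'   contract).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, out_dir, plots = FALSE) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  files <- character()
  log <- c(sprintf("ldlconcord %s", as.character(utils::packageVersion("ldlconcord"))),
           sprintf("records analysed: %d", report$n))
  emit <- function(path) files <<- c(files, path)

  emit(.write_csv(report$cohort_summary,
                  file.path(out_dir, "cohort_summary.csv")))
  emit(.write_csv(data.frame(sex = names(report$sex_counts),
                             n = as.integer(report$sex_counts)),
                  file.path(out_dir, "sex_counts.csv")))

  for (nm in names(report$stratified)) {
    tab <- report$stratified[[nm]]
    log <- c(log, sprintf("stratified %s: convention %s", nm,
                          attr(tab, "convention")))
    emit(.write_csv(tab, file.path(out_dir,
                                   sprintf("stratified_diff_%s.csv", nm))))
  }

  for (nm in names(report$crosstabs)) {
    ct <- report$crosstabs[[nm]]
    if (inherits(ct, "absent_section")) {
      log <- c(log, sprintf("crosstab %s: ABSENT (%s)", nm, ct$reason))
      next
    }
    counts <- data.frame(category = rownames(ct), unclass(ct),
                         check.names = FALSE)
    emit(.write_csv(counts, file.path(out_dir,
                                      sprintf("crosstab_%s_counts.csv", nm))))
    pct <- data.frame(category = rownames(ct),
                      round(crosstab_row_percent(ct), 6),
                      check.names = FALSE)
    emit(.write_csv(pct, file.path(out_dir,
                                   sprintf("crosstab_%s_rowpct.csv", nm))))
  }

  kap <- list()
  for (nm in names(report$kappas)) {
    k <- report$kappas[[nm]]
    kap[[nm]] <- if (inherits(k, "absent_section")) {
      list(absent = TRUE, reason = k$reason)
    } else {
      list(kappa = k$kappa, p_o = k$p_o, p_e = k$p_e, n = k$n,
           strength = k$strength)
    }
  }
  kap$reclassification_pct_from_lowest <- report$reclassification_pct
  p <- file.path(out_dir, "kappa.json")
  jsonlite::write_json(kap, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit(p)

  ba <- report$bland_altman
  if (inherits(ba, "absent_section")) {
    log <- c(log, sprintf("bland_altman: ABSENT (%s)", ba$reason))
  } else {
    p <- file.path(out_dir, "bland_altman.json")
    out <- ba[c("bias", "sd_diff", "loa_low", "loa_high",
                "pct_within_loa", "n")]
    if (!inherits(report$spearman, "absent_section")) {
      out$spearman_rho_estimates <- report$spearman$estimates
      out$spearman_rho_mean_vs_diff <- report$spearman$mean_vs_diff
    }
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    emit(p)
    emit(.write_csv(ba$series, file.path(out_dir,
                                         "bland_altman_series.csv")))
  }

  emit(.write_csv(report$median_series,
                  file.path(out_dir, "median_diff_series.csv")))

  if (!is.null(report$audit)) {
    aud <- data.frame(rule = c("n_in", names(report$audit$removed), "n_out"),
                      count = c(report$audit$n_in, report$audit$removed,
                                report$audit$n_out))
    emit(.write_csv(aud, file.path(out_dir, "filter_audit.csv")))
  }

  cfg <- report$config
  p <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(extended_mh = cfg$extended,
                            crosstab_window = cfg$crosstab_window,
                            ba_window = cfg$ba_window,
                            mh_table_provenance = cfg$mh_table$provenance,
                            mh_table_cells = length(cfg$mh_table$factors)),
                       p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  emit(p)

  if (plots) {
    p <- file.path(out_dir, "median_diff_series.png")
    grDevices::png(p, width = 800, height = 500)
    series <- report$median_series
    pairs <- unique(series$pair)
    plot(NA, xlim = c(1, length(TG_STRATUM_LABELS)),
         ylim = range(series$median_pct_diff, na.rm = TRUE),
         xaxt = "n", xlab = "TG stratum (mmol/L)",
         ylab = "Median % difference")
    graphics::axis(1, at = seq_along(TG_STRATUM_LABELS),
                   labels = TG_STRATUM_LABELS, las = 2, cex.axis = 0.7)
    for (i in seq_along(pairs)) {
      s <- series[series$pair == pairs[i], ]
      graphics::lines(match(s$stratum, TG_STRATUM_LABELS),
                      s$median_pct_diff, col = i, type = "b")
    }
    graphics::legend("topleft", legend = pairs, col = seq_along(pairs),
                     lty = 1, bty = "n")
    grDevices::dev.off()
    emit(p)
    if (!inherits(ba, "absent_section")) {
      p <- file.path(out_dir, "bland_altman.png")
      grDevices::png(p, width = 700, height = 500)
      plot(ba, main = "MH vs Sampson-NIH, TG > 4.51 mmol/L")
      grDevices::dev.off()
      emit(p)
    }
  }

  log <- c(log, "files:", paste(" ", sort(basename(files))))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(c(files, file.path(out_dir, "run_log.txt")))
}

#' Read an emitted cross-tab CSV back into a crosstab matrix
#'
#' Round-trips the `crosstab_*_counts.csv` layout written by
#' [write_report()].
#'
#' @param path CSV path.
#' @return Integer matrix with category dimnames, class `"ldl_crosstab"`.
#' @export
read_crosstab_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1L]]
  structure(m, class = c("ldl_crosstab", class(m)))
}
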