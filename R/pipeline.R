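#' Read lipid-panel records from CSV
#'
#' Required columns: `patient_id`, `visit_date`, `age`, `sex`, `tc`, `hdl`,
#' `tg`, `units` (per-row, `mmol_per_L` or `mg_per_dL`). All concentrations
#' are normalized to mmol/L. Malformed rows (non-numeric, non-positive or
#' missing concentrations; bad units flag; unparseable date) are collected
#' into a reject table with a reason column rather than failing the run.
#' Leading `#` comment lines (e.g. the generator's seed line) are skipped.
#'
#' @param path CSV file path.
#' @param default_units units flag applied when the file has no `units`
#'   column (`NULL`, the default, makes the column required).
#' @return List with `records` (clean, mmol/L, `units` column dropped) and
#'   `rejects` (offending rows with a `reject_reason` column).
#' @export
read_panels <- function(path, default_units = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("patient_id", "visit_date", "age", "sex", "tc", "hdl",
                "tg", "units")
  if (!"units" %in% names(raw) && !is.null(default_units)) {
    raw$units <- .check_units(default_units)
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  tc <- num(raw$tc); hdl <- num(raw$hdl); tg <- num(raw$tg)
  date <- as.Date(raw$visit_date, format = "%Y-%m-%d")
  age <- num(raw$age)

  reason <- rep(NA_character_, nrow(raw))
  bad_units <- !raw$units %in% .UNITS
  bad_num <- is.na(tc) | is.na(hdl) | is.na(tg)
  bad_pos <- !bad_num & (tc <= 0 | hdl <= 0 | tg <= 0)
  bad_date <- is.na(date)
  bad_age <- is.na(age)
  reason[bad_age] <- "MISSING_AGE"
  reason[bad_date] <- "BAD_DATE"
  reason[bad_units] <- "BAD_UNITS"
  reason[bad_num] <- "MISSING_VALUE"
  reason[bad_pos] <- "NONPOSITIVE_VALUE"

  keep <- is.na(reason)
  rejects <- raw[!keep, , drop = FALSE]
  if (nrow(rejects)) rejects$reject_reason <- reason[!keep]

  rec <- raw[keep, , drop = FALSE]
  tc <- tc[keep]; hdl <- hdl[keep]; tg <- tg[keep]
  to_mg <- rec$units == "mg_per_dL"
  tc[to_mg] <- tc[to_mg] / MGDL_PER_MMOL_CHOL
  hdl[to_mg] <- hdl[to_mg] / MGDL_PER_MMOL_CHOL
  tg[to_mg] <- tg[to_mg] / MGDL_PER_MMOL_TG
  records <- data.frame(patient_id = as.character(rec$patient_id),
                        visit_date = date[keep], age = age[keep],
                        sex = normalize_sex(rec$sex),
                        tc = tc, hdl = hdl, tg = tg,
                        stringsAsFactors = FALSE)
  list(records = records, rejects = rejects)
}

#' Normalize sex encodings
#'
#' Maps common encodings (F/M, f/m, female/male, FEMALE/MALE) to
#' `"female"`/`"male"`; anything else becomes `"unknown"` (retained in the
#' cohort, excluded from per-sex summaries).
#'
#' @param x character vector.
#' @return Character vector of `"female"`, `"male"`, `"unknown"`.
#' @export
normalize_sex <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[lx %in% c("f", "female", "w", "woman")] <- "female"
  out[lx %in% c("m", "male", "man")] <- "male"
  out
}

#' Apply the study's record filters
#'
#' Rules in documented order, each record attributed to its first failing
#' rule: (1) keep ages 18-75 inclusive; (2) keep the earliest-dated record
#' per patient (same-date ties: first by stable input order); (3) drop
#' TG > 9.04 mmol/L. Conservation: `n_in = n_out + sum(removals)`.
#'
#' @param records parsed records (mmol/L) from [read_panels()] or a
#'   synthetic cohort.
#' @return List with `records` (survivors, original order) and `audit`
#'   (list: `n_in`, `n_out`, `removed` named vector over
#'   `age_window`, `repeat_visit`, `tg_excluded`).
#' @export
apply_study_filters <- function(records) {
  n_in <- nrow(records)
  keep <- rep(TRUE, n_in)
  removed <- c(age_window = 0L, repeat_visit = 0L, tg_excluded = 0L)

  bad_age <- is.na(records$age) | records$age < 18 | records$age > 75
  removed["age_window"] <- sum(bad_age)
  keep <- keep & !bad_age

  idx <- which(keep)
  if (length(idx)) {
    sub <- records[idx, ]
    ord <- order(sub$patient_id, sub$visit_date, seq_along(idx))
    first <- !duplicated(sub$patient_id[ord])
    dup_idx <- idx[ord][!first]
    removed["repeat_visit"] <- length(dup_idx)
    keep[dup_idx] <- FALSE
  }

  bad_tg <- keep & records$tg > TG_EXCLUSION_LIMIT
  removed["tg_excluded"] <- sum(bad_tg)
  keep <- keep & !bad_tg

  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out,
       audit = list(n_in = n_in, n_out = nrow(out), removed = removed))
}

#' Study analysis configuration
#'
#' Windows and equation options for [run_study_analysis()]: the cross-tab
#' TG window is the closed interval `[1.69, 4.51]` mmol/L and the
#' Bland-Altman window the half-open `(4.51, 9.04]`, exactly as the printed
#' ranges imply.
#'
#' @param mh_table factor table for Martin-Hopkins.
#' @param extended use the extended MH validity range.
#' @param crosstab_window,ba_window TG windows, mmol/L.
#' @param pairs list of character(2) equation pairs for the stratified
#'   difference tables.
#' @return List of class `"study_config"`.
#' @export
study_config <- function(mh_table = mh_table_default(), extended = TRUE,
                         crosstab_window = c(1.69, 4.51),
                         ba_window = c(4.51, 9.04),
                         pairs = list(c("ff", "mh"), c("ff", "sampson"),
                                      c("mh", "sampson"))) {
  structure(list(mh_table = mh_table, extended = extended,
                 crosstab_window = crosstab_window, ba_window = ba_window,
                 pairs = pairs),
            class = "study_config")
}

.summary_row <- function(x, label) {
  mi <- tryCatch(median_iqr(x), error = function(e) list(median = NA_real_,
                                                         iqr = NA_real_))
  data.frame(variable = label, n = sum(!is.na(x)),
             median = mi$median, iqr = mi$iqr)
}

#' Run the full equation-comparison analysis
#'
#' On filtered records (mmol/L): computes all three estimates per record,
#' then the cohort summary (per-sex and overall analyte medians/IQRs and
#' per-equation LDL medians), TG-stratified percentage-difference tables
#' for each configured pair, the clinical-category cross-tab + kappa for
#' FF-vs-MH and FF-vs-Sampson inside the cross-tab TG window plus
#' MH-vs-Sampson above it, upward-reclassification rates from the lowest
#' category, the MH-vs-Sampson Bland-Altman above 4.51 mmol/L with both
#' rank correlations (estimate-vs-estimate and mean-vs-difference), and
#' the median-difference-by-stratum series. Sections with too few records
#' are reported absent with a reason rather than failing the run.
#' Deterministic given its input.
#'
#' @param records filtered records (columns `sex`, `tc`, `hdl`, `tg`, ...).
#' @param config a [study_config()].
#' @param audit optional filter audit to embed in the report.
#' @return A list of class `"study_report"`.
#' @export
run_study_analysis <- function(records, config = study_config(),
                               audit = NULL) {
  panel <- lipid_panel(records$tc, records$hdl, records$tg)
  est <- compute_all(panel, config$mh_table, extended = config$extended)
  tg <- records$tg

  cohort <- do.call(rbind, c(
    lapply(c("tc", "hdl", "tg"), function(v) {
      rbind(.summary_row(records[[v]], paste0(v, "_overall")),
            .summary_row(records[[v]][records$sex == "female"],
                         paste0(v, "_female")),
            .summary_row(records[[v]][records$sex == "male"],
                         paste0(v, "_male")))
    }),
    lapply(c("ff", "mh", "sampson"), function(eq) {
      .summary_row(est[[eq]][tg < FF_TG_LIMIT],
                   paste0("ldl_", eq, "_tg_lt_4.52"))
    })))
  sex_counts <- table(factor(records$sex,
                             levels = c("female", "male", "unknown")))

  strat <- lapply(config$pairs, function(p) {
    stratified_difference_summary(est, tg, pair = p)
  })
  names(strat) <- vapply(config$pairs, paste, "", collapse = "_vs_")

  section <- function(expr) {
    tryCatch(expr, error = function(e) {
      structure(list(reason = conditionMessage(e)), class = "absent_section")
    })
  }
  win <- config$crosstab_window
  crosstabs <- list(
    ff_vs_mh = section(category_crosstab(est, tg, c("ff", "mh"), win)),
    ff_vs_sampson = section(category_crosstab(est, tg, c("ff", "sampson"),
                                              win)),
    mh_vs_sampson_high_tg = section(
      category_crosstab(est, tg, c("mh", "sampson"),
                        c(config$ba_window[1L] + 1e-9, config$ba_window[2L]))))
  kappas <- lapply(crosstabs, function(ct) {
    if (inherits(ct, "absent_section")) ct else section(cohen_kappa(ct))
  })
  reclass <- lapply(crosstabs[c("ff_vs_mh", "ff_vs_sampson")], function(ct) {
    if (inherits(ct, "absent_section")) NA_real_
    else upward_reclassification(ct, 1L)
  })

  hi <- !is.na(tg) & tg > config$ba_window[1L] & tg <= config$ba_window[2L] &
    !is.na(est$mh) & !is.na(est$sampson)
  ba <- section({
    if (sum(hi) < 2L) stop("insufficient records with TG > ",
                           config$ba_window[1L], " mmol/L")
    bland_altman(est$mh[hi], est$sampson[hi])
  })
  rho <- section({
    list(estimates = spearman_rho(est$mh[hi], est$sampson[hi]),
         mean_vs_diff = spearman_rho((est$mh[hi] + est$sampson[hi]) / 2,
                                     est$mh[hi] - est$sampson[hi]))
  })

  medians_series <- do.call(rbind, lapply(names(strat), function(nm) {
    data.frame(pair = nm, stratum = strat[[nm]]$stratum,
               median_pct_diff = strat[[nm]]$median)
  }))

  structure(list(n = nrow(records), sex_counts = sex_counts,
                 cohort_summary = cohort, estimates = est,
                 stratified = strat, crosstabs = crosstabs,
                 kappas = kappas, reclassification_pct = reclass,
                 bland_altman = ba, spearman = rho,
                 median_series = medians_series,
                 audit = audit, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> n =", x$n, "records\n")
  cat("  pairs:", paste(names(x$stratified), collapse = ", "), "\n")
  for (nm in names(x$kappas)) {
    k <- x$kappas[[nm]]
    if (inherits(k, "absent_section")) {
      cat("  kappa ", nm, ": absent (", k$reason, ")\n", sep = "")
    } else {
      cat(sprintf("  kappa %s: %.3f (%s)\n", nm, k$kappa, k$strength))
    }
  }
  invisible(x)
}
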