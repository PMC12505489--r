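#' Log-normal parameters from a median and IQR
#'
#' Lipid analytes are right-skewed and positive, and routine reports give
#' medians and one-number IQRs; the generator therefore uses log-normal
#' marginals. For `X ~ lognormal(mu, sigma)`: median `exp(mu)` and
#' `Q3 - Q1 = exp(mu) * (exp(z*sigma) - exp(-z*sigma))` with
#' `z = qnorm(0.75)`, which inverts in closed form to
#' `sigma = asinh(iqr / (2*median)) / z`. `iqr = 0` yields the degenerate
#' point mass at the median.
#'
#' @param median target median, > 0.
#' @param iqr target interquartile width Q3 - Q1, >= 0.
#' @return List with `meanlog`, `sdlog`.
#' @examples
#' p <- lognormal_params_from_median_iqr(3.10, 1.42)
#' exp(p$meanlog) # 3.10
#' @export
lognormal_params_from_median_iqr <- function(median, iqr) {
  if (!is.finite(median) || median <= 0) {
    stop("median must be positive", call. = FALSE)
  }
  if (!is.finite(iqr) || iqr < 0) stop("iqr must be >= 0", call. = FALSE)
  list(meanlog = log(median),
       sdlog = asinh(iqr / (2 * median)) / stats::qnorm(0.75))
}

#' Synthetic lipid-cohort configuration
#'
#' The stated world the generator emulates: the source cohort's sex split
#' and per-sex TG/HDL medians and IQRs (mmol/L), its calculated-LDL
#' distribution, its age-band frequencies, and a physiologic TG:VLDL-C
#' ratio that ramps linearly from `r_min` at `tg_lo_mgdl` to `r_max` at
#' `tg_hi_mgdl` (clamped outside). Measurement noise is multiplicative
#' log-normal with the given coefficient of variation (default 0: the
#' noiseless world used by the oracle tests). Artifact rates feed
#' [inject_artifacts()].
#'
#' @param n number of base records.
#' @param female_fraction proportion of women.
#' @param tg_median,tg_iqr,hdl_median,hdl_iqr named numeric vectors with
#'   elements `female` and `male`, mmol/L.
#' @param ldl_median,ldl_iqr true-LDL distribution targets, mmol/L.
#' @param r_min,r_max,tg_lo_mgdl,tg_hi_mgdl ratio-ramp parameters
#'   (dimensionless ratio; TG knots in mg/dL).
#' @param noise_cv per-analyte multiplicative noise CV (single number
#'   applied to TC, HDL, TG).
#' @param age_band_prob 6 x 2 matrix (bands x female/male) of age-band
#'   probabilities; defaults to the source cohort's band frequencies.
#' @param repeat_rate,age_out_rate,tg_out_rate artifact injection rates in
#'   `[0, 1]`.
#' @param date_range study window for visit dates.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 20000,
                          female_fraction = 0.4305,
                          tg_median = c(female = 0.89, male = 1.02),
                          tg_iqr = c(female = 0.54, male = 0.71),
                          hdl_median = c(female = 1.45, male = 1.24),
                          hdl_iqr = c(female = 0.46, male = 0.39),
                          ldl_median = 3.10,
                          ldl_iqr = 1.42,
                          r_min = 5, r_max = 9,
                          tg_lo_mgdl = 100, tg_hi_mgdl = 400,
                          noise_cv = 0,
                          age_band_prob = NULL,
                          repeat_rate = 0.10,
                          age_out_rate = 0.02,
                          tg_out_rate = 0.01,
                          date_range = c("2019-01-01", "2023-12-31")) {
  if (is.null(age_band_prob)) {
    # per-sex age-band counts of the source cohort (18-24 ... 65-75)
    f <- c(167, 724, 1714, 1990, 2139, 1500)
    m <- c(196, 812, 2419, 2849, 2741, 1875)
    age_band_prob <- cbind(female = f / sum(f), male = m / sum(m))
  }
  cfg <- list(n = as.integer(n), female_fraction = female_fraction,
              tg_median = tg_median, tg_iqr = tg_iqr,
              hdl_median = hdl_median, hdl_iqr = hdl_iqr,
              ldl_median = ldl_median, ldl_iqr = ldl_iqr,
              r_min = r_min, r_max = r_max,
              tg_lo_mgdl = tg_lo_mgdl, tg_hi_mgdl = tg_hi_mgdl,
              noise_cv = noise_cv, age_band_prob = age_band_prob,
              repeat_rate = repeat_rate, age_out_rate = age_out_rate,
              tg_out_rate = tg_out_rate,
              date_range = as.Date(date_range))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    stopifnot(n >= 0,
              female_fraction >= 0, female_fraction <= 1,
              all(c("female", "male") %in% names(tg_median)),
              all(tg_median > 0), all(hdl_median > 0), ldl_median > 0,
              all(tg_iqr >= 0), all(hdl_iqr >= 0), ldl_iqr >= 0,
              r_min > 0, r_min <= r_max, tg_lo_mgdl < tg_hi_mgdl,
              noise_cv >= 0,
              nrow(age_band_prob) == 6L, ncol(age_band_prob) == 2L,
              all(age_band_prob >= 0),
              repeat_rate >= 0, repeat_rate <= 1,
              age_out_rate >= 0, age_out_rate <= 1,
              tg_out_rate >= 0, tg_out_rate <= 1)
  })
  invisible(cfg)
}

.AGE_BANDS <- cbind(lo = c(18, 25, 35, 45, 55, 65),
                    hi = c(24, 34, 44, 54, 64, 75))

.rlnorm_target <- function(n, median, iqr) {
  p <- lognormal_params_from_median_iqr(median, iqr)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

#' TG:VLDL-C ratio ramp
#'
#' `r = r_min + (r_max - r_min) * clamp((tg_mgdl - tg_lo) / (tg_hi - tg_lo),
#' 0, 1)`: the physiologic ratio of triglycerides to VLDL cholesterol,
#' fixed at 5 by Friedewald but observed to vary between about 5 and 9,
#' rising with TG as large triglyceride-rich VLDL1 particles come to
#' dominate.
#'
#' @param tg_mgdl triglycerides in mg/dL.
#' @param config a [cohort_config()] (only the ramp fields are used).
#' @return Numeric vector of ratios in `[r_min, r_max]`.
#' @export
tg_vldl_ratio <- function(tg_mgdl, config = cohort_config(n = 0)) {
  frac <- (tg_mgdl - config$tg_lo_mgdl) /
    (config$tg_hi_mgdl - config$tg_lo_mgdl)
  config$r_min + (config$r_max - config$r_min) * pmin(pmax(frac, 0), 1)
}

#' Generate a synthetic lipid cohort with known ground truth
#'
#' Per record: sex drawn by `female_fraction`; TG and HDL drawn log-normal
#' per sex (independent within sex); the TG:VLDL-C ratio `r` from
#' [tg_vldl_ratio()]; true VLDL-C = TG/r computed in mg/dL and converted;
#' true LDL drawn log-normal; TC composed as the *exact* sum
#' LDL + HDL + VLDL-C before noise; optional multiplicative log-normal
#' noise (mean 1, CV `noise_cv`) applied to the measured TC/HDL/TG columns.
#' Ages come from the configured band frequencies (uniform within band),
#' visit dates uniform over the study window. Deterministic given
#' `config` + `seed`.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; recorded in the output's `seed` attribute.
#' @return `data.frame` with columns `patient_id`, `visit_date`, `age`,
#'   `sex`, `tc`, `hdl`, `tg` (measured, mmol/L) and ground-truth columns
#'   `true_ldl`, `true_vldl`, `true_ratio`, `true_tc`, `true_hdl`,
#'   `true_tg`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  n <- config$n
  empty <- data.frame(patient_id = character(), visit_date = as.Date(character()),
                      age = integer(), sex = character(),
                      tc = numeric(), hdl = numeric(), tg = numeric(),
                      true_ldl = numeric(), true_vldl = numeric(),
                      true_ratio = numeric(), true_tc = numeric(),
                      true_hdl = numeric(), true_tg = numeric())
  if (n == 0L) return(structure(empty, seed = seed))
  set.seed(seed)
  sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
  tg <- hdl <- numeric(n)
  for (s in c("female", "male")) {
    idx <- sex == s
    tg[idx] <- .rlnorm_target(sum(idx), config$tg_median[[s]],
                              config$tg_iqr[[s]])
    hdl[idx] <- .rlnorm_target(sum(idx), config$hdl_median[[s]],
                               config$hdl_iqr[[s]])
  }
  tg_mg <- tg * MGDL_PER_MMOL_TG
  r <- tg_vldl_ratio(tg_mg, config)
  vldl <- (tg_mg / r) / MGDL_PER_MMOL_CHOL
  ldl <- .rlnorm_target(n, config$ldl_median, config$ldl_iqr)
  tc <- ldl + hdl + vldl

  band <- integer(n)
  for (s in c("female", "male")) {
    idx <- which(sex == s)
    band[idx] <- sample.int(6L, length(idx), replace = TRUE,
                            prob = config$age_band_prob[, s])
  }
  age <- .AGE_BANDS[band, "lo"] +
    floor(stats::runif(n) * (.AGE_BANDS[band, "hi"] - .AGE_BANDS[band, "lo"] + 1))
  span <- as.integer(diff(config$date_range)) + 1L
  visit <- config$date_range[1L] + floor(stats::runif(n) * span)

  noise <- function(x) {
    if (config$noise_cv == 0) return(x)
    sdlog <- sqrt(log(1 + config$noise_cv^2))
    x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
  }
  out <- data.frame(patient_id = sprintf("P%06d", seq_len(n)),
                    visit_date = visit, age = as.integer(age), sex = sex,
                    tc = noise(tc), hdl = noise(hdl), tg = noise(tg),
                    true_ldl = ldl, true_vldl = vldl, true_ratio = r,
                    true_tc = tc, true_hdl = hdl, true_tg = tg,
                    stringsAsFactors = FALSE)
  structure(out, seed = seed)
}

#' Inject raw-data artifacts for filter testing
#'
#' Appends (1) duplicate visits — resampled existing patients with strictly
#' later dates, (2) records with ages outside 18-75, (3) records with
#' TG > 9.04 mmol/L, at the configured rates (fractions of the base `n`,
#' counts rounded to nearest). The per-type injection counts are returned
#' so filter audits can be checked by bookkeeping.
#'
#' @param records a base cohort from [generate_cohort()].
#' @param config a [cohort_config()] (rates + date window used).
#' @param seed integer seed for the injection draws.
#' @return List with `records` (base + injected, injected rows carry an
#'   `artifact` column tag; base rows tag `"none"`) and `counts` (named
#'   integer vector: `repeat_visit`, `age_out`, `tg_out`).
#' @export
inject_artifacts <- function(records, config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  n <- nrow(records)
  records$artifact <- rep("none", n)
  counts <- c(repeat_visit = round(config$repeat_rate * n),
              age_out = round(config$age_out_rate * n),
              tg_out = round(config$tg_out_rate * n))
  if (n == 0L || sum(counts) == 0L) {
    return(list(records = records, counts = counts))
  }
  set.seed(seed)
  pieces <- list(records)

  if (counts["repeat_visit"] > 0L) {
    src <- records[sample.int(n, counts["repeat_visit"], replace = TRUE), ]
    left <- as.integer(config$date_range[2L] - src$visit_date)
    left[left < 1L] <- 1L
    src$visit_date <- src$visit_date + pmax(1L, floor(stats::runif(nrow(src)) * left))
    src$artifact <- "repeat_visit"
    pieces <- c(pieces, list(src))
  }
  if (counts["age_out"] > 0L) {
    src <- records[sample.int(n, counts["age_out"], replace = TRUE), ]
    src$patient_id <- sprintf("A%06d", seq_len(nrow(src)))
    src$age <- ifelse(stats::runif(nrow(src)) < 0.5,
                      sample(1:17, nrow(src), replace = TRUE),
                      sample(76:95, nrow(src), replace = TRUE))
    src$artifact <- "age_out"
    pieces <- c(pieces, list(src))
  }
  if (counts["tg_out"] > 0L) {
    src <- records[sample.int(n, counts["tg_out"], replace = TRUE), ]
    src$patient_id <- sprintf("T%06d", seq_len(nrow(src)))
    src$tg <- stats::runif(nrow(src), 9.05, 25)
    src$true_tg <- src$tg
    src$artifact <- "tg_out"
    pieces <- c(pieces, list(src))
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  list(records = out, counts = counts)
}

#' Write / read a cohort as CSV
#'
#' Truth columns keep their `true_` prefix so an "observed-only" input is
#' formed by dropping them. The generator seed travels in a `# seed:`
#' comment line at the top of the file.
#'
#' @param records cohort data.frame.
#' @param path file path.
#' @param truth keep ground-truth columns (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path, truth = TRUE) {
  if (!truth) {
    records <- records[, !grepl("^true_", names(records)), drop = FALSE]
  }
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(records, "seed")
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}
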