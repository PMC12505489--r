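test_that("lognormal parameters invert the quartile equations", {
  # degenerate width
  expect_equal(lognormal_params_from_median_iqr(2, 0)$sdlog, 0)
  # sdlog = 1 exactly when iqr equals the unit-lognormal quartile width
  iqr1 <- qlnorm(0.75, 0, 1) - qlnorm(0.25, 0, 1)
  p <- lognormal_params_from_median_iqr(1, iqr1)
  expect_equal(p$sdlog, 1, tolerance = 1e-12)
  expect_equal(p$meanlog, 0)
  # forward check through the distribution's own quantile function
  p <- lognormal_params_from_median_iqr(3.10, 1.42)
  expect_equal(qlnorm(0.5, p$meanlog, p$sdlog), 3.10, tolerance = 1e-12)
  expect_equal(qlnorm(0.75, p$meanlog, p$sdlog) -
                 qlnorm(0.25, p$meanlog, p$sdlog), 1.42, tolerance = 1e-12)
  expect_error(lognormal_params_from_median_iqr(-1, 1), "positive")
  expect_error(lognormal_params_from_median_iqr(1, -1), ">= 0")
})

test_that("Monte-Carlo round trip recovers median and IQR within 1%", {
  p <- lognormal_params_from_median_iqr(0.96, 0.63)
  set.seed(18)
  x <- rlnorm(1e6, p$meanlog, p$sdlog)
  expect_lt(abs(median(x) - 0.96) / 0.96, 0.01)
  expect_lt(abs(IQR(x) - 0.63) / 0.63, 0.01)
})

test_that("ratio ramp is linear in TG, clamped to [r_min, r_max]", {
  cfg <- cohort_config(n = 0)
  expect_equal(tg_vldl_ratio(c(50, 100, 250, 400, 900), cfg),
               c(5, 5, 7, 9, 9))
  expect_true(all(tg_vldl_ratio(seq(1, 1000, by = 7), cfg) >= 5))
  expect_true(all(tg_vldl_ratio(seq(1, 1000, by = 7), cfg) <= 9))
})

test_that("generated records conserve cholesterol exactly pre-noise", {
  rec <- generate_cohort(cohort_config(n = 2000), seed = 19)
  expect_identical(rec$true_tc, rec$true_ldl + rec$true_hdl + rec$true_vldl)
  # noise off: measured columns equal the truth columns
  expect_identical(rec$tc, rec$true_tc)
  expect_identical(rec$tg, rec$true_tg)
  expect_true(all(rec$true_ratio >= 5 & rec$true_ratio <= 9))
  expect_true(all(rec$age >= 18 & rec$age <= 75))
  expect_true(all(rec$visit_date >= as.Date("2019-01-01") &
                    rec$visit_date <= as.Date("2023-12-31")))
})

test_that("noise perturbs measured columns but not the truth", {
  cfg <- cohort_config(n = 500, noise_cv = 0.05)
  rec <- generate_cohort(cfg, seed = 20)
  expect_identical(rec$true_tc, rec$true_ldl + rec$true_hdl + rec$true_vldl)
  expect_false(any(rec$tc == rec$true_tc))
  # multiplicative CV ~ 5%
  expect_equal(sd(rec$tg / rec$true_tg), 0.05, tolerance = 0.2)
})

test_that("same seed reproduces bit-identical cohorts; seeds differ", {
  cfg <- cohort_config(n = 300)
  a <- generate_cohort(cfg, seed = 21)
  b <- generate_cohort(cfg, seed = 21)
  c <- generate_cohort(cfg, seed = 22)
  expect_identical(a, b)
  expect_false(identical(a$tg, c$tg))
})

test_that("n = 0 yields an empty cohort; invalid configs refuse", {
  rec <- generate_cohort(cohort_config(n = 0), seed = 1)
  expect_equal(nrow(rec), 0L)
  expect_error(cohort_config(female_fraction = 1.2))
  expect_error(cohort_config(r_min = 9, r_max = 5))
  expect_error(cohort_config(repeat_rate = -0.1))
})

test_that("artifact injection: identity at zero rates, audited construction", {
  base <- generate_cohort(cohort_config(n = 400), seed = 23)
  none <- inject_artifacts(base, cohort_config(n = 400, repeat_rate = 0,
                                               age_out_rate = 0,
                                               tg_out_rate = 0))
  expect_equal(sum(none$counts), 0)
  expect_equal(none$records[names(base)], as.data.frame(base),
               ignore_attr = TRUE)

  cfg <- cohort_config(n = 400, repeat_rate = 0.1, age_out_rate = 0.05,
                       tg_out_rate = 0.02)
  inj <- inject_artifacts(base, cfg, seed = 24)
  expect_equal(unname(inj$counts),
               c(round(0.1 * 400), round(0.05 * 400), round(0.02 * 400)))
  rep_rows <- inj$records[inj$records$artifact == "repeat_visit", ]
  # every duplicate shares a patient_id with a base row, dated strictly later
  for (i in seq_len(nrow(rep_rows))) {
    orig <- base[base$patient_id == rep_rows$patient_id[i], ]
    expect_equal(nrow(orig), 1L)
    expect_gt(as.numeric(rep_rows$visit_date[i] - orig$visit_date), 0)
  }
  expect_true(all(inj$records$tg[inj$records$artifact == "tg_out"] > 9.04))
  age_out <- inj$records$age[inj$records$artifact == "age_out"]
  expect_true(all(age_out < 18 | age_out > 75))
})

test_that("injected TG outliers equal the audited exclusion count", {
  base <- generate_cohort(cohort_config(n = 600), seed = 25)
  cfg <- cohort_config(n = 600, repeat_rate = 0.1, age_out_rate = 0.03,
                       tg_out_rate = 0.02)
  inj <- inject_artifacts(base, cfg, seed = 26)
  filt <- apply_study_filters(inj$records)
  base_tg_out <- sum(base$tg > 9.04)
  expect_equal(unname(filt$audit$removed["tg_excluded"]),
               unname(inj$counts["tg_out"]) + base_tg_out)
  expect_equal(unname(filt$audit$removed["age_window"]),
               unname(inj$counts["age_out"]))
  # audit conservation
  expect_equal(filt$audit$n_in,
               filt$audit$n_out + sum(filt$audit$removed))
})

test_that("cohort marginals track the configured targets (scaled-down run)", {
  rec <- generate_cohort(cohort_config(n = 30000), seed = 27)
  expect_equal(mean(rec$sex == "female"), 0.4305, tolerance = 0.03)
  f <- rec$sex == "female"
  expect_equal(median(rec$tg[f]), 0.89, tolerance = 0.02)
  expect_equal(median(rec$hdl[!f]), 1.24, tolerance = 0.02)
  expect_equal(median(rec$true_ldl), 3.10, tolerance = 0.02)
  # age bands roughly at Table-1 frequencies: the 35-64 share dominates
  expect_equal(mean(rec$age >= 35 & rec$age <= 64), 0.7242,
               tolerance = 0.05)
})

test_that("cohort CSV round trip, with and without truth columns", {
  rec <- generate_cohort(cohort_config(n = 50), seed = 28)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(rec, path)
  lines <- readLines(path, n = 1)
  expect_match(lines, "# seed: 28")
  back <- utils::read.csv(path, comment.char = "#")
  expect_true(all(c("true_ldl", "true_ratio") %in% names(back)))
  expect_equal(back$tc, rec$tc, tolerance = 1e-12)
  write_cohort_csv(rec, path, truth = FALSE)
  back <- utils::read.csv(path, comment.char = "#")
  expect_false(any(grepl("^true_", names(back))))
})
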