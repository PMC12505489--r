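# shared fixtures, built in code

# random physiologic panels; tg_max < 4.52 keeps Friedewald defined
random_panels <- function(n, seed = 1, units = "mmol_per_L", tg_max = 4.3) {
  set.seed(seed)
  lipid_panel(tc = stats::runif(n, 2.5, 9.0),
              hdl = stats::runif(n, 0.6, 2.5),
              tg = stats::runif(n, 0.2, tg_max),
              units = units)
}

# a 2x2 toy factor table: {TG<100: [4.0, 5.0]; TG>=100: [5.5, 6.5]}
# columns split at non-HDL 120 mg/dL
toy_mh_table <- function() {
  mh_factor_table(tg_breaks = c(0, 100), nonhdl_breaks = c(0, 120),
                  factors = matrix(c(4.0, 5.5, 5.0, 6.5), nrow = 2),
                  provenance = "2x2 toy")
}

# hand-traced 8-row filter fixture: removals 1 (age) + 2 (dedup) + 1 (TG)
filter_fixture <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P2", "P3", "P3", "P4", "P5", "P6"),
    visit_date = as.Date(c("2020-01-01", "2020-01-01", "2021-01-01",
                           "2020-06-01", "2019-03-01", "2020-02-02",
                           "2022-09-09", "2023-12-31")),
    age = c(17, 50, 50, 40, 40, 60, 33, 75),
    sex = c("F", "F", "F", "M", "M", "F", "M", "F"),
    tc = c(5, 5, 5, 6, 6, 7, 4.5, 5.5),
    hdl = c(1.2, 1.2, 1.2, 1.0, 1.0, 1.1, 1.3, 1.4),
    tg = c(1.0, 1.0, 1.2, 2.0, 1.8, 9.5, 0.8, 1.1),
    stringsAsFactors = FALSE)
}

write_panel_csv <- function(df, path, units = "mmol_per_L") {
  if (!"units" %in% names(df)) df$units <- units
  utils::write.csv(df, path, row.names = FALSE)
  path
}
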