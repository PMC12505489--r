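test_that("clinical category boundaries follow the half-open convention", {
  got <- assign_clinical_category(c(1.80, 1.81, 2.56, 2.57, 4.89, 4.90,
                                    10.0, -0.2, 0, NA))
  expect_identical(as.character(got),
                   c("<1.81", "1.81-2.56", "1.81-2.56", "2.57-3.34",
                     "4.12-4.89", ">=4.90", ">=4.90", "<1.81", "<1.81", NA))
})

test_that("TG strata partition (0, 9.04] with the printed rows", {
  expect_identical(as.character(assign_tg_stratum(c(0.96, 4.52, 9.04, 0.56,
                                                    0.57))),
                   c("0.57-1.12", "4.52-9.04", "4.52-9.04", "<0.57",
                     "0.57-1.12"))
  expect_error(assign_tg_stratum(9.05), "EXCLUDED_TG")
  expect_error(assign_tg_stratum(0), "positive")
})

test_that("category and stratum assignment are true partitions on a dense grid", {
  cat_bounds <- c(1.81, 2.57, 3.35, 4.12, 4.90)
  grid <- sort(c(seq(0.005, 12, by = 0.005), cat_bounds,
                 cat_bounds - 1e-9, cat_bounds + 1e-9))
  cats <- assign_clinical_category(grid)
  expect_false(anyNA(cats))
  # ordinal order matches concentration order
  expect_true(all(diff(as.integer(cats)) >= 0))

  tg_bounds <- c(0.57, 1.13, 1.69, 2.26, 2.82, 3.39, 3.95, 4.52, 9.04)
  grid <- sort(c(seq(0.005, 9.04, by = 0.005), tg_bounds,
                 tg_bounds - 1e-9))
  strata <- assign_tg_stratum(grid)
  expect_false(anyNA(strata))
  expect_true(all(diff(as.integer(strata)) >= 0))
})

test_that("percent difference: arithmetic, sign, denominators, identity", {
  expect_equal(percent_difference(2, 2), 0)
  expect_equal(percent_difference(2.2, 2.0), 10)
  expect_equal(percent_difference(1.9, 2.0), -5)
  expect_equal(percent_difference(2.2, 2.0, denominator = "first"),
               100 * 0.2 / 2.2)
  expect_equal(percent_difference(2.2, 2.0, denominator = "mean"),
               100 * 0.2 / 2.1)
  expect_error(percent_difference(1, 0), "zero denominator")
  # algebraic identity, property-swept:
  # 100(a-b)/b == -[100(b-a)/a] * (a/b)
  set.seed(8)
  a <- runif(200, 0.5, 5); b <- runif(200, 0.5, 5)
  expect_equal(percent_difference(a, b),
               -percent_difference(b, a) * a / b, tolerance = 1e-12)
})

test_that("stratified summary: hand case, identical estimates, empty strata", {
  # 3 records in one stratum with comparator-vs-reference diffs {-5, 0, 10}%
  est <- data.frame(ff = c(2, 2, 2), mh = c(1.9, 2, 2.2))
  out <- stratified_difference_summary(est, tg = c(0.3, 0.3, 0.3),
                                       pair = c("ff", "mh"))
  expect_identical(out$n, c(3L, rep(0L, 8)))
  expect_equal(out$median[1], 0)
  expect_equal(out$iqr[1], 7.5) # type-7 quartiles of {-5, 0, 10}
  expect_true(all(is.na(out$median[-1])))

  same <- data.frame(ff = c(1, 2, 3), mh = c(1, 2, 3))
  out <- stratified_difference_summary(same, tg = c(0.3, 1.0, 2.0),
                                       pair = c("ff", "mh"))
  expect_true(all(out$median[out$n > 0] == 0))
  expect_true(all(is.na(out$p))) # degenerate: no nonzero differences
  expect_match(attr(out, "convention"), "100\\*\\(mh-ff\\)/ff")
})

test_that("crosstab counts: trivial diagonal and hand-enumerated cases", {
  est <- data.frame(ff = rep(1.0, 10), mh = rep(1.2, 10))
  ct <- category_crosstab(est, tg = rep(2, 10), pair = c("ff", "mh"),
                          tg_window = c(1.69, 4.51))
  expect_equal(ct[1, 1], 10L)
  expect_equal(sum(ct), 10L)

  # 6 hand-built records with known categories (ff-cat, mh-cat):
  # (1,1) (1,2) (2,2) (3,4) (6,6) (2,2)
  est <- data.frame(ff = c(1.0, 1.5, 2.0, 3.0, 5.5, 2.4),
                    mh = c(1.2, 1.9, 2.1, 3.5, 6.0, 2.5))
  ct <- category_crosstab(est, tg = rep(2, 6), pair = c("ff", "mh"),
                          tg_window = c(1.69, 4.51))
  expect_equal(ct[1, 1], 1L); expect_equal(ct[1, 2], 1L)
  expect_equal(ct[2, 2], 2L); expect_equal(ct[3, 4], 1L)
  expect_equal(ct[6, 6], 1L); expect_equal(sum(ct), 6L)

  # window restriction and NA exclusion
  est <- data.frame(ff = c(1, 1, NA), mh = c(1, 1, 1))
  ct <- category_crosstab(est, tg = c(2, 5, 2), pair = c("ff", "mh"),
                          tg_window = c(1.69, 4.51))
  expect_equal(sum(ct), 1L)
  expect_error(category_crosstab(est, tg = c(10, 10, 10),
                                 pair = c("ff", "mh"),
                                 tg_window = c(1.69, 4.51)),
               "empty crosstab")
  # row percentages of nonempty rows sum to 100
  pct <- crosstab_row_percent(ct)
  rs <- rowSums(pct)
  expect_equal(rs[!is.na(rs)], rep(100, sum(!is.na(rs))),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("cohen_kappa: hand case, perfect, independence, invariances", {
  k <- cohen_kappa(matrix(c(20, 10, 5, 15), 2))
  expect_equal(k$p_o, 0.70)
  expect_equal(k$p_e, 0.50)
  expect_equal(k$kappa, 0.40)

  expect_equal(cohen_kappa(diag(c(3, 4, 5)))$kappa, 1)
  # counts proportional to the product of the margins -> kappa 0
  m <- outer(c(1, 2, 3), c(2, 1, 1))
  expect_equal(cohen_kappa(m)$kappa, 0)
  # invariant to scaling all counts by a positive integer
  set.seed(9)
  m <- matrix(rpois(16, 4), 4)
  expect_equal(cohen_kappa(m * 7L)$kappa, cohen_kappa(m)$kappa,
               tolerance = 1e-12)
  expect_error(cohen_kappa(matrix(c(5, 0, 0, 0), 2)), "undefined kappa")
  expect_error(cohen_kappa(matrix(0, 2, 2)), "positive")
})

test_that("cohen_kappa agrees with a brute-force double loop on random tables", {
  brute <- function(m) {
    n <- sum(m); k <- nrow(m)
    po <- 0; pe <- 0
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i == j) po <- po + m[i, j] / n
      }
      pe <- pe + (sum(m[i, ]) / n) * (sum(m[, i]) / n)
    }
    (po - pe) / (1 - pe)
  }
  set.seed(10)
  for (rep in 1:500) {
    k <- sample(2:6, 1)
    m <- matrix(rpois(k * k, 3), k)
    if (sum(m) == 0) m[1, 2] <- 1
    pe <- sum(rowSums(m) * colSums(m)) / sum(m)^2
    if (pe >= 1) m <- m + 1
    expect_equal(cohen_kappa(m)$kappa, brute(m), tolerance = 1e-12)
  }
})

test_that("kappa strength uses the Landis-Koch bands", {
  expect_identical(kappa_strength(0.715), "substantial")
  expect_identical(kappa_strength(0.81), "almost perfect")
  expect_identical(kappa_strength(0.336), "fair")
  expect_identical(kappa_strength(c(-0.5, 0, 0.2, 0.40, 0.60, 0.80, 1)),
                   c("poor", "poor", "slight", "fair", "moderate",
                     "substantial", "almost perfect"))
  expect_error(kappa_strength(1.2), "\\[-1, 1\\]")
})

test_that("upward reclassification reads the first row's off-diagonal mass", {
  m <- matrix(0L, 6, 6)
  m[1, 1] <- 165L; m[1, 2] <- 126L
  expect_equal(upward_reclassification(m), 100 * 126 / 291)
  expect_true(is.na(upward_reclassification(matrix(0L, 2, 2) + diag(0L, 2))))
})
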