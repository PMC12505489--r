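#' Guideline LDL cholesterol treatment categories (mmol/L)
#'
#' The six clinical treatment bands that drive statin initiation and
#' intensification decisions, as half-open lower-inclusive intervals:
#' `[0,1.81) [1.81,2.57) [2.57,3.35) [3.35,4.12) [4.12,4.90) [4.90,Inf)`.
#' Negative (flagged) estimates map to the lowest category; absent (`NA`)
#' estimates stay `NA` and are excluded from cross-tabulations.
#'
#' @param ldl numeric vector of LDL cholesterol estimates in mmol/L
#'   (`NA` allowed).
#' @return An ordered factor with levels `"<1.81"`, `"1.81-2.56"`,
#'   `"2.57-3.34"`, `"3.35-4.11"`, `"4.12-4.89"`, `">=4.90"`.
#' @examples
#' assign_clinical_category(c(1.80, 1.81, 4.90, -0.2, NA))
#' @export
assign_clinical_category <- function(ldl) {
  breaks <- c(1.81, 2.57, 3.35, 4.12, 4.90)
  idx <- findInterval(ldl, breaks) + 1L
  factor(CLINICAL_CATEGORY_LABELS[idx], levels = CLINICAL_CATEGORY_LABELS,
         ordered = TRUE)
}

#' @rdname assign_clinical_category
#' @export
CLINICAL_CATEGORY_LABELS <- c("<1.81", "1.81-2.56", "2.57-3.34",
                              "3.35-4.11", "4.12-4.89", ">=4.90")

#' Triglyceride strata (mmol/L)
#'
#' The nine analysis strata partition (0, 9.04]: half-open lower-inclusive
#' cells at 0.57, 1.13, 1.69, 2.26, 2.82, 3.39, 3.95 and 4.52 mmol/L, the
#' final stratum closed at 9.04. TG above 9.04 mmol/L is excluded from the
#' study and raises an error here.
#'
#' @param tg numeric vector of triglycerides in mmol/L, `0 < tg <= 9.04`
#'   (`NA` allowed, propagated).
#' @return An ordered factor with the nine stratum labels.
#' @examples
#' assign_tg_stratum(c(0.96, 4.52, 9.04))
#' @export
assign_tg_stratum <- function(tg) {
  ok <- !is.na(tg)
  if (any(tg[ok] > TG_EXCLUSION_LIMIT)) {
    stop("EXCLUDED_TG: triglycerides > 9.04 mmol/L are outside the study",
         call. = FALSE)
  }
  if (any(tg[ok] <= 0)) stop("triglycerides must be positive", call. = FALSE)
  breaks <- c(0.57, 1.13, 1.69, 2.26, 2.82, 3.39, 3.95, 4.52)
  idx <- findInterval(tg, breaks) + 1L
  factor(TG_STRATUM_LABELS[idx], levels = TG_STRATUM_LABELS, ordered = TRUE)
}

#' @rdname assign_tg_stratum
#' @export
TG_STRATUM_LABELS <- c("<0.57", "0.57-1.12", "1.13-1.68", "1.69-2.25",
                       "2.26-2.81", "2.82-3.38", "3.39-3.94", "3.95-4.51",
                       "4.52-9.04")

#' Percentage difference between two estimates
#'
#' `100 * (a - b) / denom`, negative when `a < b`. The denominator is the
#' second argument by default; `"mean"` uses `(a + b)/2`, `"first"` uses
#' `a`. The choice matters for sign-sensitive summaries and is therefore
#' explicit and documented wherever a summary reports it.
#'
#' @param a,b numeric vectors (recycled), `b` (or the chosen denominator)
#'   nonzero.
#' @param denominator `"second"` (default), `"first"` or `"mean"`.
#' @return Numeric vector of percentages.
#' @examples
#' percent_difference(2.2, 2.0) # 10
#' @export
percent_difference <- function(a, b,
                               denominator = c("second", "first", "mean")) {
  denominator <- match.arg(denominator)
  denom <- switch(denominator, second = b, first = a, mean = (a + b) / 2)
  if (any(denom == 0, na.rm = TRUE)) {
    stop("undefined percentage difference: zero denominator", call. = FALSE)
  }
  100 * (a - b) / denom
}

#' TG-stratified percentage-difference summary for an equation pair
#'
#' For each of the nine TG strata: the number of records with both
#' estimates present, and the median, IQR (Q3-Q1, linear-interpolation
#' quartiles) and Wilcoxon signed-rank p-value of the per-record percentage
#' difference. The reported difference is the *second-listed* equation
#' relative to the *first*, `100*(B-A)/A` — positive when the comparator
#' exceeds the first-listed (reference) equation, which makes the
#' Friedewald-vs-newer columns run from negative at low TG to positive at
#' high TG. Strata with no eligible pairs are emitted with `n = 0` and `NA`
#' statistics; Friedewald is structurally absent in the 4.52-9.04 stratum.
#'
#' @param estimates output of [compute_all()] (or any data.frame holding
#'   the two estimate columns), in mmol/L.
#' @param tg triglycerides in mmol/L, one per record.
#' @param pair character(2): column names of the reference and comparator
#'   equations, e.g. `c("ff", "mh")`.
#' @param convention passed to [percent_difference()] as the denominator of
#'   `100*(B-A)/denom`; default `"second"` here means "relative to the
#'   first-listed equation" because the difference is taken as B-A.
#' @return `data.frame` with columns `stratum`, `n`, `median`, `iqr`, `p`.
#' @export
stratified_difference_summary <- function(estimates, tg,
                                          pair = c("ff", "mh"),
                                          convention = "second") {
  stopifnot(length(pair) == 2L, all(pair %in% names(estimates)),
            length(tg) == nrow(estimates))
  a <- estimates[[pair[1L]]]
  b <- estimates[[pair[2L]]]
  stratum <- assign_tg_stratum(tg)
  rows <- lapply(TG_STRATUM_LABELS, function(s) {
    in_s <- !is.na(stratum) & stratum == s & !is.na(a) & !is.na(b)
    n <- sum(in_s)
    if (n == 0L) {
      return(data.frame(stratum = s, n = 0L, median = NA_real_,
                        iqr = NA_real_, p = NA_real_))
    }
    pd <- percent_difference(b[in_s], a[in_s], denominator = convention)
    mi <- median_iqr(pd)
    p <- if (n >= 2L && any(a[in_s] != b[in_s])) {
      wilcoxon_signed_rank(a[in_s], b[in_s])$p
    } else NA_real_
    data.frame(stratum = s, n = n, median = mi$median, iqr = mi$iqr, p = p)
  })
  out <- do.call(rbind, rows)
  attr(out, "pair") <- pair
  attr(out, "convention") <- sprintf("100*(%s-%s)/%s", pair[2L], pair[1L],
                                     switch(convention,
                                            second = pair[1L],
                                            first = pair[2L],
                                            mean = "mean"))
  out
}

#' Clinical-category cross-tabulation of two equations
#'
#' Counts of (A-category, B-category) pairs for records whose TG falls in
#' `tg_window` (closed interval, mmol/L) and whose two estimates are both
#' present. Rows are the first equation's categories.
#'
#' @inheritParams stratified_difference_summary
#' @param tg_window numeric(2) closed TG window in mmol/L; default the
#'   study's cross-tab window `c(1.69, 4.51)`. Use `c(0, 9.04)` for all
#'   eligible records.
#' @return A 6x6 integer matrix of class `"ldl_crosstab"` with category
#'   dimnames and attributes `pair`, `tg_window`, `n`.
#' @export
category_crosstab <- function(estimates, tg, pair = c("ff", "mh"),
                              tg_window = c(1.69, 4.51)) {
  stopifnot(length(pair) == 2L, all(pair %in% names(estimates)),
            length(tg) == nrow(estimates), length(tg_window) == 2L)
  a <- estimates[[pair[1L]]]
  b <- estimates[[pair[2L]]]
  keep <- !is.na(tg) & tg >= tg_window[1L] & tg <= tg_window[2L] &
    !is.na(a) & !is.na(b)
  if (!any(keep)) {
    stop("empty crosstab: no eligible records in the TG window",
         call. = FALSE)
  }
  ca <- assign_clinical_category(a[keep])
  cb <- assign_clinical_category(b[keep])
  counts <- table(ca, cb, dnn = pair)
  m <- matrix(as.integer(counts), nrow = nlevels(ca),
              dimnames = list(levels(ca), levels(cb)))
  structure(m, class = c("ldl_crosstab", class(m)), pair = pair,
            tg_window = tg_window, n = sum(keep))
}

#' Row percentages of a cross-tabulation
#'
#' @param crosstab a square count matrix (e.g. from [category_crosstab()]).
#' @return Matrix of row percentages; rows with zero total are `NaN`-free
#'   and returned as `NA`.
#' @export
crosstab_row_percent <- function(crosstab) {
  m <- unclass(crosstab)
  rs <- rowSums(m)
  out <- sweep(m, 1L, rs, "/") * 100
  out[rs == 0, ] <- NA_real_
  out
}

#' Cohen's kappa for a category cross-tabulation
#'
#' Unweighted chance-corrected agreement: observed agreement
#' `p_o = sum(diag)/N`, expected agreement
#' `p_e = sum(row_k * col_k)/N^2`, `kappa = (p_o - p_e)/(1 - p_e)`.
#'
#' @param crosstab square count matrix (any K >= 2), counts >= 0,
#'   positive grand total.
#' @return A list of class `"kappa_result"`: `kappa`, `p_o`, `p_e`, `n`,
#'   `strength` (Landis-Koch label).
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2))
#' @export
cohen_kappa <- function(crosstab) {
  m <- unclass(crosstab)
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(m >= 0))
  n <- sum(m)
  if (n <= 0) stop("crosstab grand total must be positive", call. = FALSE)
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (p_e >= 1) {
    stop("undefined kappa: all mass in one category of both margins",
         call. = FALSE)
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  structure(list(kappa = kappa, p_o = p_o, p_e = p_e, n = n,
                 strength = kappa_strength(kappa)),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f (%s agreement); p_o = %.4f, p_e = %.4f, n = %d\n",
              x$kappa, x$strength, x$p_o, x$p_e, x$n))
  invisible(x)
}

#' Landis-Koch strength label for a kappa value
#'
#' Bands: <= 0 poor; (0, 0.20] slight; (0.20, 0.40] fair; (0.40, 0.60]
#' moderate; (0.60, 0.80] substantial; (0.80, 1] almost perfect.
#'
#' @param kappa numeric in `[-1, 1]`.
#' @return Character vector of labels.
#' @examples
#' kappa_strength(c(0.715, 0.81, 0.336))
#' @export
kappa_strength <- function(kappa) {
  if (any(is.na(kappa)) || any(kappa < -1) || any(kappa > 1)) {
    stop("kappa must lie in [-1, 1]", call. = FALSE)
  }
  labels <- c("poor", "slight", "fair", "moderate", "substantial",
              "almost perfect")
  idx <- findInterval(kappa, c(0, 0.20, 0.40, 0.60, 0.80),
                      left.open = TRUE) + 1L
  labels[idx]
}

#' Upward reclassification fraction from a cross-tabulation
#'
#' Among records the row (reference) equation places in a given category,
#' the percentage the column (comparator) equation places in any *higher*
#' category. With `category = 1` this is the study's headline quantity:
#' the share of reference `<1.81` classifications the comparator moves
#' above 1.81 mmol/L.
#'
#' @param crosstab square count matrix with ordered categories.
#' @param category row index (default 1, the lowest band).
#' @return Percentage in `[0, 100]`, or `NA` if the row is empty.
#' @export
upward_reclassification <- function(crosstab, category = 1L) {
  m <- unclass(crosstab)
  row <- m[category, ]
  tot <- sum(row)
  if (tot == 0) return(NA_real_)
  100 * sum(row[seq_along(row) > category]) / tot
}
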