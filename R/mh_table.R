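#' Martin-Hopkins adjustable-factor table
#'
#' The Martin-Hopkins equation replaces Friedewald's fixed triglyceride
#' divisor with an "adjustable factor": the median TG:VLDL-C mass ratio
#' within cells of a two-way stratification of triglycerides (rows) by
#' non-HDL cholesterol (columns), both in mg/dL. This constructor validates
#' a user-supplied stratification; [mh_table_default()] loads the packaged
#' transcription of the published table and [mh_table_constant()] builds the
#' degenerate single-cell table (factor 5 reproduces mg/dL Friedewald).
#'
#' Cells are half-open and lower-bound inclusive; inputs beyond the last
#' boundary fall in the outermost cell (the published top strata are
#' open-ended).
#'
#' @param tg_breaks strictly increasing lower bounds of the TG strata
#'   (mg/dL); the first bound should be 0 so the table covers all inputs.
#' @param nonhdl_breaks strictly increasing lower bounds of the non-HDL-C
#'   strata (mg/dL).
#' @param factors numeric matrix of positive divisors, dimensions
#'   `length(tg_breaks) x length(nonhdl_breaks)`.
#' @param provenance free-text provenance string carried with the table.
#' @return An object of class `"mh_factor_table"`.
#' @export
mh_factor_table <- function(tg_breaks, nonhdl_breaks, factors,
                            provenance = "user-supplied") {
  tg_breaks <- as.numeric(tg_breaks)
  nonhdl_breaks <- as.numeric(nonhdl_breaks)
  factors <- as.matrix(factors)
  if (anyNA(tg_breaks) || is.unsorted(tg_breaks, strictly = TRUE)) {
    stop("tg_breaks must be strictly increasing", call. = FALSE)
  }
  if (anyNA(nonhdl_breaks) || is.unsorted(nonhdl_breaks, strictly = TRUE)) {
    stop("nonhdl_breaks must be strictly increasing", call. = FALSE)
  }
  if (!identical(dim(factors),
                 c(length(tg_breaks), length(nonhdl_breaks)))) {
    stop("factors must be a ", length(tg_breaks), " x ",
         length(nonhdl_breaks), " matrix", call. = FALSE)
  }
  if (anyNA(factors) || any(factors <= 0)) {
    stop("all factors must be positive", call. = FALSE)
  }
  structure(list(tg_breaks = tg_breaks, nonhdl_breaks = nonhdl_breaks,
                 factors = factors, provenance = provenance),
            class = "mh_factor_table")
}

#' @export
print.mh_factor_table <- function(x, ...) {
  cat("<mh_factor_table> ", length(x$tg_breaks), " TG strata x ",
      length(x$nonhdl_breaks), " non-HDL strata (",
      length(x$factors), " cells)\n", sep = "")
  cat("  factor range: [", min(x$factors), ", ", max(x$factors), "]\n",
      sep = "")
  cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' @rdname mh_factor_table
#' @param factor the single divisor of the constant table.
#' @export
mh_table_constant <- function(factor = 5) {
  mh_factor_table(0, 0, matrix(factor, 1, 1),
                  provenance = sprintf("constant factor %g", factor))
}

#' @rdname mh_factor_table
#' @details The packaged default is a 180-cell table (30 TG strata x 6
#'   non-HDL-C strata, factors 3.1-11.9) transcribed from the 2013
#'   publication of the method. The transcription has not been re-verified
#'   against the original supplement and individual cells may deviate from
#'   the published values: verify against the source before any clinical
#'   use. All package tests therefore run on synthetic or constant tables.
#' @export
mh_table_default <- function() {
  path <- system.file("extdata", "mh_factor_table_180.csv",
                      package = "ldlconcord", mustWork = TRUE)
  read_mh_table(path,
                provenance = paste("180-cell median TG:VLDL-C factor table,",
                                   "transcribed from the 2013 publication;",
                                   "unverified transcription - check cells",
                                   "against the source before clinical use"))
}

#' Read / write a factor table as a CSV matrix
#'
#' Layout: header row holds the non-HDL-C lower boundaries (mg/dL) after a
#' label cell; the first column holds the TG lower boundaries (mg/dL); the
#' body holds the factors. The loader validates boundary monotonicity.
#'
#' @param path file path.
#' @param provenance provenance string to attach on read.
#' @return [read_mh_table()] returns an `mh_factor_table`;
#'   [write_mh_table()] returns `path` invisibly.
#' @export
read_mh_table <- function(path, provenance = path) {
  raw <- utils::read.csv(path, check.names = FALSE)
  if (ncol(raw) < 2L) stop("malformed factor-table CSV", call. = FALSE)
  nonhdl <- suppressWarnings(as.numeric(names(raw)[-1L]))
  if (anyNA(nonhdl)) stop("header must hold numeric non-HDL boundaries",
                          call. = FALSE)
  mh_factor_table(raw[[1L]], nonhdl, as.matrix(raw[, -1L, drop = FALSE]),
                  provenance = provenance)
}

#' @rdname read_mh_table
#' @param table an `mh_factor_table`.
#' @export
write_mh_table <- function(table, path) {
  stopifnot(inherits(table, "mh_factor_table"))
  out <- data.frame(tg_mgdl = table$tg_breaks, table$factors,
                    check.names = FALSE)
  names(out) <- c("tg_mgdl", format(table$nonhdl_breaks, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up the Martin-Hopkins adjustable factor
#'
#' Finds the unique cell whose TG row and non-HDL-C column contain the
#' inputs (half-open cells, lower bound inclusive) and returns its factor.
#' Inputs below the first or beyond the last boundary use the outermost
#' cell. Vectorized over `tg_mgdl` / `nonhdl_mgdl`.
#'
#' @param tg_mgdl triglycerides in mg/dL, positive.
#' @param nonhdl_mgdl non-HDL cholesterol in mg/dL, positive.
#' @param table an [mh_factor_table()].
#' @return Numeric vector of divisors.
#' @examples
#' mh_factor(85, 140, mh_table_constant(5))
#' @export
mh_factor <- function(tg_mgdl, nonhdl_mgdl, table) {
  if (!inherits(table, "mh_factor_table")) {
    stop("table must be an mh_factor_table", call. = FALSE)
  }
  if (any(tg_mgdl <= 0) || any(nonhdl_mgdl <= 0)) {
    stop("tg and non-HDL must be positive", call. = FALSE)
  }
  i <- pmax(1L, findInterval(tg_mgdl, table$tg_breaks))
  j <- pmax(1L, findInterval(nonhdl_mgdl, table$nonhdl_breaks))
  table$factors[cbind(i, j)]
}
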