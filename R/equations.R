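#' Validity limits of the estimating equations (mmol/L of triglycerides)
#'
#' Friedewald is undefined at TG >= 4.52 mmol/L; the original Martin-Hopkins
#' stratification reaches TG 4.51 mmol/L and its 2021 extension, like
#' Sampson-NIH, reaches 9.04 mmol/L. Records above 9.04 mmol/L are excluded
#' from analysis altogether.
#'
#' @name tg-limits
#' @keywords internal
NULL

#' @rdname tg-limits
#' @export
FF_TG_LIMIT <- 4.52

#' @rdname tg-limits
#' @export
MH_TG_LIMIT_ORIGINAL <- 4.51

#' @rdname tg-limits
#' @export
TG_EXCLUSION_LIMIT <- 9.04

.estimate <- function(value, absent, reason) {
  flag <- ifelse(absent, reason,
                 ifelse(!is.na(value) & value < 0, "NEGATIVE_ESTIMATE", "OK"))
  data.frame(value = ifelse(absent, NA_real_, value), flag = flag,
             stringsAsFactors = FALSE)
}

.as_mmol <- function(panel) convert_panel_units(panel, "mmol_per_L")

.from_mmol <- function(value, units) {
  if (units == "mg_per_dL") value * MGDL_PER_MMOL_CHOL else value
}

#' Friedewald LDL cholesterol
#'
#' `LDL = TC - HDL - TG/2.2` in mmol/L, assuming a fixed TG:VLDL-C ratio.
#' No value is produced when TG >= 4.52 mmol/L (flag `TG_OUT_OF_RANGE`).
#' Negative estimates are returned, flagged `NEGATIVE_ESTIMATE`, never
#' clamped.
#'
#' @param panel a [lipid_panel()]; any units (converted internally to
#'   mmol/L, result returned in the panel's units).
#' @return `data.frame` with columns `value` (NA when absent) and `flag`
#'   (`"OK"`, `"NEGATIVE_ESTIMATE"` or `"TG_OUT_OF_RANGE"`), one row per
#'   record.
#' @examples
#' ldl_friedewald(lipid_panel(4.94, 1.32, 0.96))
#' @export
ldl_friedewald <- function(panel) {
  units <- panel_units(panel)
  p <- .as_mmol(panel)
  value <- p$tc - p$hdl - p$tg / 2.2
  .estimate(.from_mmol(value, units), p$tg >= FF_TG_LIMIT, "TG_OUT_OF_RANGE")
}

#' Sampson-NIH LDL cholesterol
#'
#' The bivariate quadratic estimator, in mmol/L:
#' `LDL = TC/0.948 - HDL/0.971 - (TG/3.74 + TG*nonHDL/24.16 - TG^2/79.36)
#' - 0.244`, valid for TG <= 9.04 mmol/L.
#'
#' @inheritParams ldl_friedewald
#' @inherit ldl_friedewald return
#' @examples
#' ldl_sampson(lipid_panel(4.94, 1.32, 0.96))
#' @export
ldl_sampson <- function(panel) {
  units <- panel_units(panel)
  p <- .as_mmol(panel)
  nhdl <- p$tc - p$hdl
  value <- p$tc / 0.948 - p$hdl / 0.971 -
    (p$tg / 3.74 + p$tg * nhdl / 24.16 - p$tg^2 / 79.36) - 0.244
  .estimate(.from_mmol(value, units), p$tg > TG_EXCLUSION_LIMIT,
            "TG_OUT_OF_RANGE")
}

#' Martin-Hopkins LDL cholesterol
#'
#' `LDL = TC - HDL - TG/factor` computed in mg/dL, with the divisor looked
#' up from the TG x non-HDL-C stratification in `table` (see
#' [mh_factor()]). The original mode refuses TG > 4.51 mmol/L; extended
#' (2021) mode reaches TG 9.04 mmol/L.
#'
#' @inheritParams ldl_friedewald
#' @param table an [mh_factor_table()]; defaults to the packaged
#'   transcription ([mh_table_default()]).
#' @param extended use the extended validity range (default `TRUE`).
#' @inherit ldl_friedewald return
#' @examples
#' ldl_martin_hopkins(lipid_panel(4.94, 1.32, 0.96), mh_table_constant(5))
#' @export
ldl_martin_hopkins <- function(panel, table = mh_table_default(),
                               extended = TRUE) {
  if (!inherits(table, "mh_factor_table")) {
    stop("missing or invalid Martin-Hopkins factor table", call. = FALSE)
  }
  units <- panel_units(panel)
  p <- convert_panel_units(panel, "mg_per_dL")
  nhdl <- p$tc - p$hdl
  fac <- mh_factor(p$tg, nhdl, table)
  value_mg <- p$tc - p$hdl - p$tg / fac
  value <- if (units == "mmol_per_L") value_mg / MGDL_PER_MMOL_CHOL else value_mg
  limit <- if (extended) TG_EXCLUSION_LIMIT else MH_TG_LIMIT_ORIGINAL
  tg_mmol <- .as_mmol(panel)$tg
  .estimate(value, tg_mmol > limit, "TG_OUT_OF_RANGE")
}

#' Apply all three equations to a panel
#'
#' Produces the per-record estimate set: Friedewald, Martin-Hopkins,
#' Sampson-NIH and non-HDL cholesterol, each with its validity flag.
#' Records with TG > 9.04 mmol/L are excluded from every equation (flag
#' `EXCLUDED_TG`), mirroring the study-wide exclusion rule.
#'
#' @inheritParams ldl_martin_hopkins
#' @return `data.frame` with columns `ff`, `ff_flag`, `mh`, `mh_flag`,
#'   `sampson`, `sampson_flag`, `non_hdl`, in the panel's units.
#' @examples
#' compute_all(lipid_panel(4.94, 1.32, 0.96), mh_table_constant(5))
#' @export
compute_all <- function(panel, table = mh_table_default(), extended = TRUE) {
  units <- panel_units(panel)
  ff <- ldl_friedewald(panel)
  mh <- ldl_martin_hopkins(panel, table, extended = extended)
  sa <- ldl_sampson(panel)
  out <- data.frame(ff = ff$value, ff_flag = ff$flag,
                    mh = mh$value, mh_flag = mh$flag,
                    sampson = sa$value, sampson_flag = sa$flag,
                    non_hdl = non_hdl(panel), stringsAsFactors = FALSE)
  excl <- .as_mmol(panel)$tg > TG_EXCLUSION_LIMIT
  for (col in c("ff", "mh", "sampson")) {
    out[[col]][excl] <- NA_real_
    out[[paste0(col, "_flag")]][excl] <- "EXCLUDED_TG"
  }
  attr(out, "units") <- units
  out
}
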