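#' Unit conversion constants
#'
#' Conventional molar-mass conversion factors between SI (mmol/L) and mass
#' (mg/dL) concentration units. Cholesterol (MW ~386.65 g/mol) converts at
#' 38.67 mg/dL per mmol/L; triglycerides (average MW ~885.7 g/mol) at
#' 88.57 mg/dL per mmol/L. These are the factors in routine laboratory use.
#'
#' @name unit-constants
#' @keywords internal
NULL

#' @rdname unit-constants
#' @export
MGDL_PER_MMOL_CHOL <- 38.67

#' @rdname unit-constants
#' @export
MGDL_PER_MMOL_TG <- 88.57

.UNITS <- c("mmol_per_L", "mg_per_dL")

.check_units <- function(units) {
  if (length(units) != 1L || !units %in% .UNITS) {
    stop("unknown units flag: must be one of ",
         paste(.UNITS, collapse = ", "), call. = FALSE)
  }
  units
}

#' Construct a lipid panel
#'
#' A lipid panel holds one or more records of the three measured analytes a
#' calculated LDL cholesterol needs: total cholesterol (TC), HDL cholesterol
#' and triglycerides (TG), all expressed in a single unit system. Vectors are
#' recycled to a common length the usual way for length-1 inputs.
#'
#' @param tc total cholesterol, numeric vector, strictly positive.
#' @param hdl HDL cholesterol, same length/units as `tc`.
#' @param tg triglycerides, same length/units as `tc`.
#' @param units `"mmol_per_L"` (default) or `"mg_per_dL"`; one flag for all
#'   three analytes.
#' @return A `data.frame` of class `"lipid_panel"` with columns `tc`, `hdl`,
#'   `tg` and a `units` attribute.
#' @examples
#' lipid_panel(tc = 4.94, hdl = 1.32, tg = 0.96)
#' @export
lipid_panel <- function(tc, hdl, tg, units = "mmol_per_L") {
  .check_units(units)
  n <- max(length(tc), length(hdl), length(tg))
  rec <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, n)
    if (length(x) != n) stop(nm, " has length ", length(x),
                             ", expected 1 or ", n, call. = FALSE)
    if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
      stop(nm, " must be numeric, non-missing and strictly positive",
           call. = FALSE)
    }
    as.numeric(x)
  }
  out <- data.frame(tc = rec(tc, "tc"), hdl = rec(hdl, "hdl"),
                    tg = rec(tg, "tg"))
  attr(out, "units") <- units
  class(out) <- c("lipid_panel", "data.frame")
  out
}

#' @export
print.lipid_panel <- function(x, ...) {
  cat("<lipid_panel> ", nrow(x), " record(s), units: ",
      panel_units(x), "\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Units of a lipid panel
#' @param panel a [lipid_panel()].
#' @return The units flag, `"mmol_per_L"` or `"mg_per_dL"`.
#' @export
panel_units <- function(panel) {
  u <- attr(panel, "units")
  if (is.null(u)) stop("not a lipid_panel: missing units attribute",
                       call. = FALSE)
  .check_units(u)
}

#' Convert a lipid panel between mmol/L and mg/dL
#'
#' Cholesterol fields (TC, HDL) scale by 38.67 mg/dL per mmol/L and
#' triglycerides by 88.57 mg/dL per mmol/L (or the inverse). Converting to
#' the panel's own units is the identity.
#'
#' @param panel a [lipid_panel()].
#' @param target `"mmol_per_L"` or `"mg_per_dL"`.
#' @return A `lipid_panel` in the target units.
#' @examples
#' p <- lipid_panel(tc = 1, hdl = 0.5, tg = 1)
#' convert_panel_units(p, "mg_per_dL")
#' @export
convert_panel_units <- function(panel, target) {
  from <- panel_units(panel)
  .check_units(target)
  if (from == target) return(panel)
  if (target == "mg_per_dL") {
    panel$tc <- panel$tc * MGDL_PER_MMOL_CHOL
    panel$hdl <- panel$hdl * MGDL_PER_MMOL_CHOL
    panel$tg <- panel$tg * MGDL_PER_MMOL_TG
  } else {
    panel$tc <- panel$tc / MGDL_PER_MMOL_CHOL
    panel$hdl <- panel$hdl / MGDL_PER_MMOL_CHOL
    panel$tg <- panel$tg / MGDL_PER_MMOL_TG
  }
  attr(panel, "units") <- target
  panel
}

#' Non-HDL cholesterol
#'
#' Total cholesterol minus HDL cholesterol, in the panel's own units. Non-HDL
#' cholesterol proxies the cholesterol carried by all atherogenic particles
#' and is one axis of the Martin-Hopkins factor lookup.
#'
#' @param panel a [lipid_panel()].
#' @return Numeric vector, one value per record.
#' @export
non_hdl <- function(panel) {
  panel_units(panel)
  panel$tc - panel$hdl
}
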