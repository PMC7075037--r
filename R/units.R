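#' Convert a crude rate per 100,000 to an annual per-person risk
#'
#' County health departments report disease incidence as crude rates per
#' 100,000 residents per year. The risk model works with annual per-person
#' probabilities, so a crude rate of 187.7 CHD deaths per 100,000 becomes a
#' baseline risk of 0.001877.
#'
#' @param rate Numeric vector of crude rates, cases per 100,000 per year.
#'   Must be non-negative.
#' @return Numeric vector of annual per-person risks (probabilities).
#' @examples
#' convert_rate_to_risk(187.7)
#' convert_rate_to_risk(495)
#' @export
convert_rate_to_risk <- function(rate) {
  stopifnot(is.numeric(rate))
  if (any(!is.na(rate) & rate < 0)) {
    stop("crude rates must be non-negative", call. = FALSE)
  }
  rate / 1e5
}

#' Convert NO2 concentrations between ug/m3 and ppb
#'
#' Uses the ideal-gas relation ppb = (ug/m3) * Vm / M with molar mass
#' M = 46.01 g/mol for NO2 and a default molar volume Vm = 24.45 L/mol
#' (25 degrees C, 1 atm). The molar volume is exposed as an argument because
#' reported conversions in the literature vary slightly with the assumed
#' temperature and pressure.
#'
#' @param value Numeric vector of concentrations, non-negative.
#' @param direction `"ugm3_to_ppb"` or `"ppb_to_ugm3"`.
#' @param molar_volume Molar volume of an ideal gas in L/mol; default 24.45.
#' @return Numeric vector of converted concentrations.
#' @examples
#' convert_no2_units(8.4, "ugm3_to_ppb")  # ~4.46 ppb
#' @export
convert_no2_units <- function(value,
                              direction = c("ugm3_to_ppb", "ppb_to_ugm3"),
                              molar_volume = 24.45) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(value), molar_volume > 0)
  if (any(!is.na(value) & value < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  no2_molar_mass <- 46.01
  factor <- molar_volume / no2_molar_mass
  switch(direction,
    ugm3_to_ppb = value * factor,
    ppb_to_ugm3 = value / factor
  )
}
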