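#' Gas escape fraction
#'
#' Fraction of a layer's dissolved gas that escapes to the atmosphere in
#' one day. A transparent linear air-filled-porosity model is used:
#' \code{clamp(escape_coeff * (1 - WFPS), 0, 1)} for NO and N2O --
#' saturated soil traps gas, dry soil vents it -- while N2, the inert end
#' product, always escapes fully. The per-gas coefficients are
#' configurable and the interface accepts a drop-in replacement scheme.
#'
#' @param w WFPS fraction in [0, 1]. Vectorised.
#' @param gas one of \code{"no"}, \code{"n2o"}, \code{"n2"}.
#' @param tp transport parameter block.
#' @return escape fraction in [0, 1], monotone non-increasing in
#'   \code{w}.
#' @export
escape_fraction <- function(w, gas, tp) {
  if (any(w < 0 | w > 1)) stop("wfps must lie in [0, 1]", call. = FALSE)
  coeff <- switch(gas,
                  no = tp$escape_no,
                  n2o = tp$escape_n2o,
                  n2 = return(rep(1, length(w))),
                  stop(sprintf("unknown gas '%s'", gas), call. = FALSE))
  pmin(pmax(coeff * (1 - w), 0), 1)
}

#' Partition produced gas between emission and retention
#'
#' The day's dissolved stock (carry-over plus new production) of a gas is
#' split by the escape fraction: the emitted share leaves the profile,
#' the remainder stays in the layer's dissolved pool where the next
#' day's reduction chain can consume it. Per-gas mass closure,
#' emitted + retained = carry-over + produced, holds exactly (retained
#' is the complement).
#'
#' @param dissolved carry-over dissolved gas, gN m^-2 per layer.
#' @param produced same-day production, gN m^-2, >= 0.
#' @param w WFPS fraction per layer.
#' @param gas \code{"no"}, \code{"n2o"} or \code{"n2"}.
#' @param tp transport parameter block.
#' @return list \code{emitted} and \code{retained}, gN m^-2 per layer.
#' @export
partition_and_emit <- function(dissolved, produced, w, gas, tp) {
  if (any(produced < 0) || any(dissolved < 0))
    stop("gas amounts must be >= 0", call. = FALSE)
  esc <- escape_fraction(w, gas, tp)
  stock <- dissolved + produced
  emitted <- esc * stock
  list(emitted = emitted, retained = stock - emitted)
}

#' Aggregate layer emissions to a surface flux
#'
#' @param layer_emissions per-layer emitted gas, gN m^-2 d^-1 (numeric
#'   vector, possibly empty).
#' @return list \code{g_m2} (gN m^-2 d^-1) and \code{g_ha}
#'   (gN ha^-1 d^-1; 1 gN m^-2 = 1e4 gN ha^-1).
#' @export
surface_flux <- function(layer_emissions) {
  total <- if (length(layer_emissions) == 0) 0 else sum(layer_emissions)
  list(g_m2 = total, g_ha = total * 1e4)
}
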