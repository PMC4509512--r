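#' Temperature response factor (Q10)
#'
#' Classic Q10 scaling of a microbial process rate:
#' \code{q10^((t_soil - t_ref)/10)}. Equals 1 at the reference
#' temperature and multiplies by \code{q10} for every 10 degC above it.
#'
#' @param t_soil soil temperature, degC. Vectorised.
#' @param q10 temperature sensitivity, dimensionless, > 0.
#' @param t_ref reference temperature, degC.
#' @return positive factor, monotone increasing in \code{t_soil};
#'   unbounded above (unlike the other response factors it is not
#'   restricted to [0, 1]).
#' @export
temperature_response <- function(t_soil, q10, t_ref = 20) {
  if (!is.numeric(q10) || any(q10 <= 0))
    stop("q10 must be > 0", call. = FALSE)
  q10^((t_soil - t_ref) / 10)
}

#' Water-filled pore space
#'
#' WFPS = volumetric water content / total porosity, with porosity
#' computed from bulk and particle density as \code{1 - rho_d/rho_s}.
#' Values above porosity (routine in field data, where measured theta can
#' exceed the porosity estimate) are clipped to 1 rather than rejected;
#' clipping is reported via \code{\link{ngas_log}}.
#'
#' @param theta volumetric water content, m3 m^-3 in [0, 1]. Vectorised.
#' @param rho_d dry bulk density, g cm^-3.
#' @param rho_s particle density, g cm^-3 (typically 2.65).
#' @return WFPS fraction in [0, 1].
#' @export
wfps <- function(theta, rho_d, rho_s = 2.65) {
  if (any(rho_d >= rho_s))
    stop("rho_d must be < rho_s (porosity would be <= 0)", call. = FALSE)
  if (any(theta < 0 | theta > 1))
    stop("theta must lie in [0, 1]", call. = FALSE)
  w <- theta / (1 - rho_d / rho_s)
  n_clip <- sum(w > 1)
  if (n_clip > 0)
    ngas_log("wfps: clipped %d value(s) above porosity to 1", n_clip)
  pmin(pmax(w, 0), 1)
}

#' Nitrification moisture response
#'
#' Piecewise quadratic response of nitrification to water-filled pore
#' space: inside the 0.3--0.75 WFPS window the factor is
#' \code{min(1, -11.25 w^2 + 11.75 w - 1.9)}; outside it the factor is
#' the constant 0.6. The function is deliberately discontinuous at the
#' window edges (branch values 0.6125 at 0.3 and 0.584375 at 0.75 against
#' the constant 0.6 outside); both jumps are properties of the adopted
#' form, not artefacts.
#'
#' @param w WFPS fraction in [0, 1]. Vectorised.
#' @return factor in [0, 1].
#' @export
moisture_response_nitrification <- function(w) {
  if (any(!is.finite(w) | w < 0 | w > 1))
    stop("wfps must lie in [0, 1]", call. = FALSE)
  ifelse(w >= 0.3 & w <= 0.75,
         pmin(1.0, -11.25 * w^2 + 11.75 * w - 1.9),
         0.6)
}

#' Substrate (Michaelis-Menten) response
#'
#' \code{s/(km + s)}: 0 with no substrate, 0.5 at the half-saturation
#' constant, saturating towards 1.
#'
#' @param s_con substrate concentration, g m^-3, >= 0. Vectorised.
#' @param km half-saturation constant, g m^-3, > 0.
#' @return factor in [0, 1).
#' @export
substrate_response <- function(s_con, km) {
  if (any(km <= 0)) stop("km must be > 0", call. = FALSE)
  if (any(s_con < 0)) stop("substrate concentration must be >= 0", call. = FALSE)
  s_con / (km + s_con)
}

#' Anaerobic soil fraction
#'
#' The share of a layer treated as oxygen-free (hosting denitrification)
#' as a linear ramp in WFPS between the \code{fr_lower} and
#' \code{fr_upper} thresholds: 0 below the ramp, 1 at and above the upper
#' threshold.
#'
#' @param w WFPS fraction in [0, 1]. Vectorised.
#' @param tp transport parameter block (\code{$transport} of
#'   \code{\link{default_parameters}}).
#' @return anaerobic fraction in [0, 1], monotone non-decreasing in
#'   \code{w}.
#' @export
anaerobic_fraction <- function(w, tp) {
  if (any(w < 0 | w > 1)) stop("wfps must lie in [0, 1]", call. = FALSE)
  pmin(pmax((w - tp$fr_lower) / (tp$fr_upper - tp$fr_lower), 0), 1)
}

# --- pH response curve family ----------------------------------------------

#' Default pH response curves
#'
#' The exact coefficients behind the published pH response curves are not
#' printed anywhere, so the package ships parametric defaults that honour
#' the documented qualitative constraints and keeps every coefficient
#' user-editable (via the parameter file or
#' \code{\link{load_ph_knots}}):
#' \describe{
#'   \item{nitrifier}{logistic rise (midpoint pH 5.3, slope 2.5):
#'     effectively zero at pH <= 4 -- nitrification is only detectable
#'     above pH 4 -- and >= 0.95 across the 6.6--7.5 optimum.}
#'   \item{denit_no3, denit_no2, denit_n2o}{piecewise-linear curves rising
#'     with pH; the N2O reductase curve is the most acid-sensitive,
#'     reflecting the well-known suppression of N2O reduction in acid
#'     soils.}
#'   \item{denit_no}{piecewise-linear with a broad optimum and mild
#'     decline towards alkaline pH (published reports disagree on the
#'     direction of the NO-reducer pH effect; a weakly peaked default is
#'     used).}
#' }
#' All curves are continuous on [3, 9] and evaluate into [0, 1].
#'
#' @return named list of pH curve objects (fields \code{curve_id},
#'   \code{shape}, and \code{coef} or \code{knots}).
#' @seealso \code{\link{ph_response}}
#' @export
default_ph_curves <- function() {
  pw <- function(id, ...) {
    k <- matrix(c(...), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("ph", "f")))
    list(curve_id = id, shape = "piecewise_linear", knots = k)
  }
  list(
    nitrifier = list(curve_id = "nitrifier", shape = "logistic",
                     coef = c(5.3, 2.5)),  # midpoint, slope
    denit_no3 = pw("denit_no3",
                   3, 0.10, 4, 0.30, 5, 0.60, 6, 0.85, 7, 1.00, 9, 1.00),
    denit_no2 = pw("denit_no2",
                   3, 0.05, 5, 0.40, 6, 0.70, 7, 1.00, 9, 1.00),
    denit_no  = pw("denit_no",
                   3, 0.30, 5, 0.80, 6, 1.00, 7, 1.00, 8, 0.90, 9, 0.80),
    denit_n2o = pw("denit_n2o",
                   3, 0.01, 5, 0.15, 6, 0.50, 7, 0.90, 8, 1.00, 9, 1.00)
  )
}

validate_ph_curve <- function(curve, id = curve$curve_id) {
  fail <- function(msg) stop(sprintf("invalid pH curve '%s': %s", id, msg),
                             call. = FALSE)
  if (!curve$shape %in% c("logistic", "exponential_rise", "piecewise_linear"))
    fail(sprintf("unknown shape '%s'", curve$shape))
  if (curve$shape == "piecewise_linear") {
    k <- curve$knots
    if (is.null(k) || !is.matrix(k) || ncol(k) != 2 || nrow(k) < 2)
      fail("piecewise_linear needs a knots matrix with >= 2 (ph, f) rows")
    if (is.unsorted(k[, 1], strictly = TRUE)) fail("knot pH values must increase")
  } else if (is.null(curve$coef) || length(curve$coef) < 2 ||
             !is.numeric(curve$coef)) {
    fail("parametric shapes need a numeric coefficient vector of length 2")
  }
  grid <- seq(3, 9, by = 0.05)
  v <- eval_ph_curve(grid, curve)
  if (any(!is.finite(v) | v < -1e-12 | v > 1 + 1e-12))
    fail("curve must evaluate into [0, 1] over pH 3..9")
  invisible(curve)
}

eval_ph_curve <- function(ph, curve) {
  switch(curve$shape,
    logistic = {
      m <- curve$coef[[1]]; s <- curve$coef[[2]]
      1 / (1 + exp(-s * (ph - m)))
    },
    exponential_rise = {
      p0 <- curve$coef[[1]]; r <- curve$coef[[2]]
      pmin(pmax(1 - exp(-r * (ph - p0)), 0), 1)
    },
    piecewise_linear = {
      k <- curve$knots
      stats::approx(k[, 1], k[, 2], xout = ph, rule = 2)$y
    },
    stop(sprintf("unknown pH curve shape '%s'", curve$shape), call. = FALSE)
  )
}

#' pH response factor
#'
#' Evaluates one of the configured pH response curves. pH values outside
#' [3, 9] are clamped to the nearest endpoint (and the clamp reported via
#' \code{\link{ngas_log}}): the curves are only constrained inside that
#' interval.
#'
#' @param ph soil pH. Vectorised.
#' @param curve a pH curve object, or a curve id looked up in
#'   \code{curves}.
#' @param curves named curve list (defaults to
#'   \code{\link{default_ph_curves}}); only used when \code{curve} is an
#'   id string.
#' @return factor in [0, 1].
#' @export
ph_response <- function(ph, curve, curves = default_ph_curves()) {
  if (is.character(curve)) {
    if (!curve %in% names(curves))
      stop(sprintf("unknown pH curve id '%s'", curve), call. = FALSE)
    curve <- curves[[curve]]
  }
  n_clamp <- sum(ph < 3 | ph > 9)
  if (n_clamp > 0)
    ngas_log("ph_response: clamped %d pH value(s) to [3, 9]", n_clamp)
  eval_ph_curve(pmin(pmax(ph, 3), 9), curve)
}

#' Load a pH curve from a knot table
#'
#' Reads a delimited text file with columns \code{ph} and \code{f}
#' (header required) into a piecewise-linear pH curve, so digitised
#' response curves can replace the shipped defaults.
#'
#' @param path file path.
#' @param curve_id identifier for the new curve.
#' @param sep field separator (default whitespace/CSV sniffed by
#'   \code{read.table}/\code{read.csv} on extension).
#' @return a validated pH curve object.
#' @export
load_ph_knots <- function(path, curve_id, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("knot table not found: %s", path),
                               call. = FALSE)
  tab <- if (!is.null(sep)) utils::read.table(path, header = TRUE, sep = sep)
         else if (grepl("\\.csv$", path)) utils::read.csv(path)
         else utils::read.table(path, header = TRUE)
  if (!all(c("ph", "f") %in% names(tab)))
    stop("knot table needs columns 'ph' and 'f'", call. = FALSE)
  curve <- list(curve_id = curve_id, shape = "piecewise_linear",
                knots = cbind(ph = tab$ph, f = tab$f))
  validate_ph_curve(curve)
  curve
}

# --- lightweight event log --------------------------------------------------

#' Runtime event log
#'
#' Clipping, availability caps and biomass floors are recorded through a
#' session-level log rather than raised as conditions, so long runs stay
#' quiet while stiffness or out-of-range forcing remains detectable.
#' \code{ngas_log} appends a formatted entry (and emits it as a
#' \code{message} when \code{options(soilngas.verbose = TRUE)});
#' \code{ngas_log_entries} returns entries; \code{ngas_log_clear} resets.
#'
#' @param fmt,... \code{sprintf} arguments.
#' @return \code{ngas_log_entries}: character vector of log entries.
#' @export
ngas_log <- function(fmt, ...) {
  entry <- sprintf(fmt, ...)
  .ngas_env$log <- c(.ngas_env$log, entry)
  if (isTRUE(getOption("soilngas.verbose"))) message(entry)
  invisible(entry)
}

#' @rdname ngas_log
#' @export
ngas_log_entries <- function() .ngas_env$log

#' @rdname ngas_log
#' @export
ngas_log_clear <- function() {
  .ngas_env$log <- character(0)
  invisible(NULL)
}

.ngas_env <- new.env(parent = emptyenv())
.ngas_env$log <- character(0)
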