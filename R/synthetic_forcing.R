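#' Synthetic forcing generator specification
#'
#' Parameters of the temperate-grassland weather/moisture emulator used
#' to build reproducible forcing fixtures. Defaults follow the climate
#' normals of a cool maritime lowland grassland: a sinusoidal
#' annual soil-temperature cycle between a January mean of 3.8 degC and
#' a July mean of 13.3 degC (mean 8.55, amplitude 4.75, peak mid-July),
#' and rainfall as a Bernoulli-exponential mixture tuned to an 849 mm
#' annual total (wet-day probability 0.5, mean wet-day depth 4.65 mm).
#' Soil moisture follows a single-bucket store: daily fill by rain over
#' an effective root-zone depth, first-order drainage towards the
#' residual water content, clipped to [theta_dry, theta_sat] (0.12 and
#' 0.47 by default, the wilting point and saturated water content of the
#' fixture topsoil). The default drainage constant (0.05 d^-1) is slow,
#' as befits an imperfectly drained clay loam: it keeps the soil wet for
#' most of the year (mean WFPS near 0.65) with saturated spells after
#' persistent rain, the moisture regime under which denitrification
#' matters. The annual temperature wave is damped with depth by
#' \code{exp(-z/damping_depth)}.
#'
#' @param t_mean annual mean soil temperature, degC.
#' @param t_amplitude annual half-range, degC.
#' @param phase_day day-of-year offset so the sinusoid peaks in
#'   mid-July.
#' @param t_noise_sd daily temperature noise SD, degC.
#' @param rain_prob wet-day probability, d^-1.
#' @param rain_mean mean wet-day rainfall, mm.
#' @param theta_dry,theta_sat bucket bounds, m3 m^-3.
#' @param root_depth_mm effective bucket depth converting mm rain to
#'   theta.
#' @param drainage_rate first-order drainage constant, d^-1.
#' @param damping_depth e-folding depth of the temperature wave, m.
#' @param theta0 initial bucket water content (default mid-range).
#' @param years series length.
#' @param start_date first day.
#' @param seed integer RNG seed.
#' @return an object of class \code{ngas_forcing_spec}.
#' @export
forcing_spec <- function(t_mean = 8.55, t_amplitude = 4.75, phase_day = 105,
                         t_noise_sd = 1.5, rain_prob = 0.5, rain_mean = 4.65,
                         theta_dry = 0.12, theta_sat = 0.47,
                         root_depth_mm = 300, drainage_rate = 0.05,
                         damping_depth = 1.0, theta0 = NULL,
                         years = 1, start_date = "1998-01-01", seed = 1L) {
  spec <- structure(list(
    t_mean = t_mean, t_amplitude = t_amplitude, phase_day = phase_day,
    t_noise_sd = t_noise_sd, rain_prob = rain_prob, rain_mean = rain_mean,
    theta_dry = theta_dry, theta_sat = theta_sat,
    root_depth_mm = root_depth_mm, drainage_rate = drainage_rate,
    damping_depth = damping_depth,
    theta0 = if (is.null(theta0)) (theta_dry + theta_sat) / 2 else theta0,
    years = years, start_date = as.Date(start_date), seed = as.integer(seed)
  ), class = "ngas_forcing_spec")
  validate_forcing_spec(spec)
  spec
}

validate_forcing_spec <- function(spec) {
  fail <- function(msg) stop(sprintf("invalid forcing spec: %s", msg),
                             call. = FALSE)
  if (spec$theta_dry >= spec$theta_sat || spec$theta_sat > 1)
    fail("need theta_dry < theta_sat <= 1")
  if (spec$rain_prob < 0 || spec$rain_prob > 1)
    fail("rain_prob must lie in [0, 1]")
  if (spec$rain_mean < 0 || spec$t_noise_sd < 0) fail("negative noise scale")
  if (spec$drainage_rate < 0 || spec$drainage_rate > 1)
    fail("drainage_rate must lie in [0, 1]")
  if (spec$root_depth_mm <= 0 || spec$damping_depth <= 0)
    fail("root_depth_mm and damping_depth must be > 0")
  if (spec$years < 1) fail("years must be >= 1")
  if (spec$theta0 < spec$theta_dry || spec$theta0 > spec$theta_sat)
    fail("theta0 must lie in [theta_dry, theta_sat]")
  invisible(spec)
}

#' Generate a synthetic forcing series
#'
#' Draws a daily forcing series from a \code{\link{forcing_spec}}:
#' sinusoidal-plus-noise temperature, Bernoulli-exponential rainfall and
#' a bucket soil-moisture store (see the spec documentation for the
#' model). Per-layer soil temperature is the surface series with its
#' deviation from the annual mean damped by
#' \code{exp(-z_mid/damping_depth)}; the bucket water content is applied
#' to every layer. Deterministic given \code{spec$seed}; the caller's
#' RNG state is preserved.
#'
#' @param spec an \code{ngas_forcing_spec}.
#' @param thicknesses layer thicknesses, m (default: single 0.1 m
#'   layer).
#' @return an \code{ngas_forcing} (with the realised daily rainfall
#'   attached as attribute \code{"rain_mm"}).
#' @export
generate_forcing <- function(spec, thicknesses = 0.1) {
  validate_forcing_spec(spec)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n_days <- round(spec$years * 365)
  dates <- seq(spec$start_date, by = "day", length.out = n_days)
  doy <- as.integer(format(dates, "%j"))
  t_surface <- spec$t_mean +
    spec$t_amplitude * sin(2 * pi * (doy - spec$phase_day) / 365) +
    stats::rnorm(n_days, 0, spec$t_noise_sd)

  rain <- stats::rbinom(n_days, 1, spec$rain_prob) *
    stats::rexp(n_days, rate = 1 / spec$rain_mean)
  theta <- numeric(n_days)
  th <- spec$theta0
  for (i in seq_len(n_days)) {
    th <- th + rain[i] / spec$root_depth_mm -
      spec$drainage_rate * (th - spec$theta_dry)
    th <- min(max(th, spec$theta_dry), spec$theta_sat)
    theta[i] <- th
  }

  z_bot <- cumsum(thicknesses)
  z_mid <- z_bot - thicknesses / 2
  damp <- exp(-z_mid / spec$damping_depth)
  t_soil <- outer(t_surface - spec$t_mean, damp) + spec$t_mean
  theta_m <- matrix(theta, nrow = n_days, ncol = length(thicknesses))

  f <- forcing_series(dates, t_soil, theta_m)
  attr(f, "rain_mm") <- rain
  f
}

#' kg ha^-1 to g m^-2
#'
#' The unit conversion every fertiliser schedule passes through
#' (1 ha = 10^4 m^2, 1 kg = 10^3 g, hence divide by 10). Kept as a
#' named, tested function because it is a classic silent-bug site.
#'
#' @param x amount in kg ha^-1.
#' @return amount in g m^-2.
#' @export
kg_ha_to_g_m2 <- function(x) x / 10

#' Bundled temperate-grassland fixture
#'
#' A complete, self-contained study setup for a cut grassland on an
#' imperfectly drained clay loam under a cool maritime climate: the
#' layered soil profile physical table, initial C/N pools by depth, the
#' management schedules of three treatments -- an unfertilised control,
#' ammonium nitrate (AN, 11 applications 1998-2003) and cattle slurry (9
#' applications) plus the shared sward-cut dates -- and a matching
#' synthetic forcing specification. Fertiliser rates are converted from
#' kg ha^-1 to g m^-2 via \code{\link{kg_ha_to_g_m2}}. The profile has
#' twelve layers (eight of 0.025 m, then 0.15, 0.45, 0.35 and 0.2 m);
#' pool tables cover the top 0.35 m, deeper layers start empty.
#'
#' @return list with \code{thicknesses}, \code{soil_props},
#'   \code{init_pools}, \code{management} (list \code{control},
#'   \code{an}, \code{slurry}, each an \code{ngas_events} frame
#'   including the cut dates) and \code{forcing_spec}.
#' @export
bush_fixture <- function() {
  soil_props <- data.frame(
    depth_top = c(0, 0.1, 0.3, 0.65, 0.95),
    depth_bot = c(0.1, 0.3, 0.65, 0.95, 2.0),
    rho_d = c(1.53, 1.53, 1.52, 1.52, 1.52),
    theta_res = c(0.041, 0.041, 0.041, 0.041, 0.041),
    theta_sat = c(0.47, 0.45, 0.43, 0.36, 0.30),
    theta_wilt = c(0.12, 0.12, 0.12, 0.10, 0.10),
    ph = c(4.6, 4.6, 5.0, 5.0, 5.0)
  )
  init_pools <- data.frame(
    depth_top = c(seq(0, 0.175, by = 0.025), 0.2),
    depth_bot = c(seq(0.025, 0.2, by = 0.025), 0.35),
    humus_c = c(rep(938, 4), rep(822, 4), 200),
    doc = c(rep(1.92, 8), 0),
    microbe_c = c(rep(19.16, 8), 0.4),
    litter_c = c(0, 7, 10.5, 14, 14, 20, 12, 4, 0.5),
    no3 = c(rep(0.8, 5), 0.6, 0.4, 0.4, 0.04),
    nh4 = c(rep(0.36, 5), 0.28, 0.2, 0.2, 0.04),
    humus_n = c(rep(69.8, 4), rep(74, 4), 20),
    don = c(rep(0.14, 8), 0),
    microbe_n = c(rep(0.04, 8), 0.002),
    litter_n = c(0, 0.68, 1.04, 1.4, 1.4, 2, 1.2, 0.4, 0)
  )

  dmy <- function(x) as.Date(x, format = "%d/%m/%Y")
  an <- data.frame(
    date = dmy(c("04/07/1998", "26/04/1999", "04/07/1999", "04/05/2000",
                 "15/07/2000", "26/04/2002", "19/06/2002", "27/08/2002",
                 "15/04/2003", "18/06/2003", "15/08/2003")),
    kind = "mineral_fertiliser",
    total_n = kg_ha_to_g_m2(c(rep(120, 5), rep(100, 6))),
    ammoniacal_n = kg_ha_to_g_m2(c(rep(60, 5), rep(50, 6))),
    dry_matter_pct = NA_real_
  )
  slurry <- data.frame(
    date = dmy(c("04/07/1998", "26/04/1999", "04/07/1999", "04/05/2000",
                 "15/07/2000", "26/04/2002", "19/06/2002", "15/04/2003",
                 "18/06/2003")),
    kind = "slurry",
    total_n = kg_ha_to_g_m2(c(220, 430, 190, 240, 200, 300, 170, 380, 150)),
    ammoniacal_n = kg_ha_to_g_m2(c(100, 154, 68, 113, 105, 127, 78, 181, 62)),
    dry_matter_pct = c(5.9, 10.0, 3.7, 4.2, 4.0, 9.2, 7.2, 7.2, 7.2)
  )
  cuts <- data.frame(
    date = dmy(c("21/08/1998", "23/06/1999", "30/08/1999", "29/06/2000",
                 "13/09/2000", "10/06/2002", "21/08/2002", "24/10/2002",
                 "04/06/2003", "20/08/2003", "23/10/2003", "15/06/2004",
                 "10/11/2004")),
    kind = "cut", total_n = 0, ammoniacal_n = 0, dry_matter_pct = NA_real_
  )

  list(
    thicknesses = c(rep(0.025, 8), 0.15, 0.45, 0.35, 0.2),
    soil_props = soil_props,
    init_pools = init_pools,
    management = list(
      control = management_events(cuts),
      an = management_events(rbind(an, cuts)),
      slurry = management_events(rbind(slurry, cuts))
    ),
    forcing_spec = forcing_spec()
  )
}
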