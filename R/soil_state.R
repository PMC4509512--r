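#' Build a layered soil profile
#'
#' Constructs the per-layer physical state and C/N pools of the simulated
#' profile. Physical properties are supplied as depth-interval tables
#' (bulk density, pH, ...) and are mapped onto layer midpoints by linear
#' interpolation between the interval midpoints (constant extrapolation
#' beyond the first/last interval). Initial pools are supplied as areal
#' masses per depth interval and mapped onto layers by depth-overlap
#' fraction, so total initial mass is conserved regardless of how the
#' layer grid cuts across the pool table.
#'
#' All pools are stored as areal masses per layer (gN m^-2 or gC m^-2);
#' kinetic rate laws convert to volumetric concentrations (g m^-3) by
#' dividing by layer thickness.
#'
#' Initial nitrifier and denitrifier biomasses are seeded as configurable
#' fractions (\code{soil$nitrifier_frac}, \code{soil$denitrifier_frac})
#' of the microbial C pool of each layer.
#'
#' @param thicknesses layer thicknesses, m (top down).
#' @param soil_props data frame with columns \code{depth_top},
#'   \code{depth_bot} (m) and any of \code{rho_d} (g cm^-3), \code{ph},
#'   \code{theta_sat}, \code{theta_wilt} (fractions).
#' @param init_pools data frame with columns \code{depth_top},
#'   \code{depth_bot} and any of \code{no3}, \code{nh4} (gN m^-2),
#'   \code{doc}, \code{humus_c}, \code{microbe_c}, \code{litter_c}
#'   (gC m^-2), \code{humus_n}, \code{don}, \code{microbe_n},
#'   \code{litter_n} (gN m^-2). Missing columns initialise to zero.
#' @param params an \code{ngas_params} object (particle density and
#'   microbial seeding fractions are taken from its \code{soil} block).
#' @return An object of class \code{ngas_profile}: a list of numeric
#'   vectors (one element per layer) with fields \code{z_top},
#'   \code{z_bot}, \code{thickness}, \code{rho_d}, \code{rho_s},
#'   \code{ph}, \code{theta}, \code{t_soil}, \code{wfps}, \code{f_r},
#'   N pools \code{nh4}, \code{no3}, \code{no2}, \code{no_diss},
#'   \code{n2o_diss}, \code{org_n}, C pools \code{doc}, biomasses
#'   \code{m_b} (nitrifier) and \code{b_d} (denitrifier), and the passive
#'   pools carried for bookkeeping (\code{humus_c}, \code{microbe_c},
#'   \code{litter_c}, \code{humus_n}, \code{don}, \code{microbe_n},
#'   \code{litter_n}).
#' @export
init_profile <- function(thicknesses, soil_props, init_pools,
                         params = default_parameters()) {
  if (any(thicknesses <= 0)) stop("layer thicknesses must be > 0", call. = FALSE)
  nl <- length(thicknesses)
  z_bot <- cumsum(thicknesses)
  z_top <- z_bot - thicknesses
  z_mid <- (z_top + z_bot) / 2

  need_depth <- function(tab, what) {
    if (!all(c("depth_top", "depth_bot") %in% names(tab)))
      stop(sprintf("%s needs depth_top and depth_bot columns", what),
           call. = FALSE)
    if (any(tab$depth_bot <= tab$depth_top))
      stop(sprintf("%s has empty/inverted depth intervals", what), call. = FALSE)
  }
  need_depth(soil_props, "soil_props")
  need_depth(init_pools, "init_pools")
  if (max(z_bot) > max(init_pools$depth_bot) + 1e-9) {
    # layers deeper than the pool table start empty
    ngas_log("init_profile: layers below %.3g m start with zero pools",
             max(init_pools$depth_bot))
  }

  interp_prop <- function(col, default = NA_real_) {
    if (!col %in% names(soil_props)) return(rep(default, nl))
    vals <- soil_props[[col]]
    if (length(vals) == 1) return(rep(vals, nl))
    mids <- (soil_props$depth_top + soil_props$depth_bot) / 2
    stats::approx(mids, vals, xout = z_mid, rule = 2)$y
  }
  # depth-overlap mass mapping, conserves the tabulated totals exactly
  overlap_pool <- function(col) {
    if (!col %in% names(init_pools)) return(numeric(nl))
    out <- numeric(nl)
    for (r in seq_len(nrow(init_pools))) {
      top <- init_pools$depth_top[r]; bot <- init_pools$depth_bot[r]
      ov <- pmax(0, pmin(z_bot, bot) - pmax(z_top, top))
      out <- out + init_pools[[col]][r] * ov / (bot - top)
    }
    out
  }

  rho_d <- interp_prop("rho_d")
  if (anyNA(rho_d)) stop("soil_props must provide rho_d", call. = FALSE)
  microbe_c <- overlap_pool("microbe_c")

  prof <- structure(list(
    z_top = z_top, z_bot = z_bot, thickness = thicknesses,
    rho_d = rho_d,
    rho_s = rep(params$soil$rho_s, nl),
    ph = interp_prop("ph", default = 7),
    theta_sat = interp_prop("theta_sat", default = 1),
    theta = interp_prop("theta_wilt", default = 0.2),
    t_soil = rep(10, nl),
    wfps = numeric(nl),
    f_r = numeric(nl),
    nh4 = overlap_pool("nh4"),
    no3 = overlap_pool("no3"),
    no2 = numeric(nl),
    no_diss = numeric(nl),
    n2o_diss = numeric(nl),
    org_n = numeric(nl),
    doc = overlap_pool("doc"),
    m_b = params$soil$nitrifier_frac * microbe_c,
    b_d = params$soil$denitrifier_frac * microbe_c,
    humus_c = overlap_pool("humus_c"),
    microbe_c = microbe_c,
    litter_c = overlap_pool("litter_c"),
    humus_n = overlap_pool("humus_n"),
    don = overlap_pool("don"),
    microbe_n = overlap_pool("microbe_n"),
    litter_n = overlap_pool("litter_n")
  ), class = "ngas_profile", n_layers = nl)
  prof$wfps <- wfps(prof$theta, prof$rho_d, prof$rho_s)
  prof
}

#' Number of layers of a profile
#' @param profile an \code{ngas_profile}.
#' @return integer layer count.
#' @export
n_layers <- function(profile) attr(profile, "n_layers")

# active (mobile) N pools summed for ledger/storage checks
active_n_pools <- c("nh4", "no3", "no2", "no_diss", "n2o_diss", "org_n")

#' Total mobile nitrogen in a profile
#'
#' Sum over layers of NH4+, NO3-, NO2-, dissolved NO and N2O, and the
#' slow-release organic fertiliser pool, gN m^-2. Passive organic pools
#' (humus, litter, microbe N) are constant over a run and excluded.
#'
#' @param profile an \code{ngas_profile}.
#' @return total N, gN m^-2.
#' @export
total_mobile_n <- function(profile) {
  sum(vapply(active_n_pools, function(p) sum(profile[[p]]), numeric(1)))
}

#' Partition substrate between aerobic and anaerobic fractions
#'
#' Splits a substrate pool (or any vector of pools) by the anaerobic
#' fraction \code{f_r}: \code{(1 - f_r) * pool} is available to
#' nitrification in aerobic microsites and \code{f_r * pool} to
#' denitrification in anaerobic microsites. The two shares sum to the
#' pool exactly (the anaerobic share is computed as the complement).
#'
#' @param pool substrate amount(s), any units.
#' @param f_r anaerobic fraction in [0, 1].
#' @return list with components \code{aerobic} and \code{anaerobic}.
#' @export
partition_substrates <- function(pool, f_r) {
  if (any(f_r < 0 | f_r > 1)) stop("f_r must lie in [0, 1]", call. = FALSE)
  aer <- (1 - f_r) * pool
  list(aerobic = aer, anaerobic = pool - aer)
}

# --- mass-balance ledger ----------------------------------------------------

#' Nitrogen mass-balance ledger
#'
#' Tracks every N input (fertiliser, deposition) and output (emitted NO,
#' N2O, N2, prescribed plant uptake, legacy-mode denitrified N) of a run
#' together with the initial mobile-N storage, so that closure
#' |inputs - outputs - (storage - initial storage)| can be asserted
#' after every daily step.
#'
#' @param profile the initial \code{ngas_profile}.
#' @return an environment of class \code{ngas_ledger} with numeric fields
#'   \code{fertiliser}, \code{deposition}, \code{emitted_no},
#'   \code{emitted_n2o}, \code{emitted_n2}, \code{uptake},
#'   \code{denitrified_legacy}, \code{death_sink_c}, \code{n0}.
#' @export
new_ledger <- function(profile) {
  led <- new.env(parent = emptyenv())
  led$fertiliser <- 0
  led$deposition <- 0
  led$emitted_no <- 0
  led$emitted_n2o <- 0
  led$emitted_n2 <- 0
  led$uptake <- 0
  led$denitrified_legacy <- 0
  led$death_sink_c <- 0   # carbon analogue: dead microbial biomass, gC m^-2
  led$n0 <- total_mobile_n(profile)
  class(led) <- "ngas_ledger"
  led
}

ledger_inputs <- function(led) led$fertiliser + led$deposition
ledger_outputs <- function(led) {
  led$emitted_no + led$emitted_n2o + led$emitted_n2 + led$uptake +
    led$denitrified_legacy
}

#' Ledger residual and closure check
#'
#' \code{ledger_residual} returns inputs - outputs - (current storage -
#' initial storage), gN m^-2: zero for a perfectly closed budget.
#' \code{ledger_check} errors (a hard invariant failure, with a
#' diagnostic dump of the ledger) when |residual| exceeds
#' \code{tol * max(1, inputs)}.
#'
#' @param led an \code{ngas_ledger}.
#' @param profile the current \code{ngas_profile}.
#' @param tol relative tolerance (default 1e-9).
#' @return \code{ledger_residual}: numeric. \code{ledger_check}: the
#'   residual, invisibly.
#' @export
ledger_residual <- function(led, profile) {
  ledger_inputs(led) - ledger_outputs(led) - (total_mobile_n(profile) - led$n0)
}

#' @rdname ledger_residual
#' @export
ledger_check <- function(led, profile, tol = 1e-9) {
  res <- ledger_residual(led, profile)
  if (abs(res) > tol * max(1, ledger_inputs(led))) {
    stop(sprintf(
      paste0("N mass balance violated: residual %.3e gN m^-2\n",
             "  inputs: fert %.6g + dep %.6g\n",
             "  outputs: NO %.6g + N2O %.6g + N2 %.6g + uptake %.6g + legacy denit %.6g\n",
             "  storage: now %.6g, initial %.6g"),
      res, led$fertiliser, led$deposition, led$emitted_no, led$emitted_n2o,
      led$emitted_n2, led$uptake, led$denitrified_legacy,
      total_mobile_n(profile), led$n0), call. = FALSE)
  }
  invisible(res)
}

#' Ledger snapshot as a data frame
#' @param led an \code{ngas_ledger}.
#' @return one-row data frame of all ledger fields.
#' @export
ledger_summary <- function(led) {
  data.frame(fertiliser = led$fertiliser, deposition = led$deposition,
             emitted_no = led$emitted_no, emitted_n2o = led$emitted_n2o,
             emitted_n2 = led$emitted_n2, uptake = led$uptake,
             denitrified_legacy = led$denitrified_legacy,
             death_sink_c = led$death_sink_c, n0 = led$n0)
}
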