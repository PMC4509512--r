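#' Denitrifier guild growth rate
#'
#' Growth of the reducer guild for one N oxide, by competitive
#' Michaelis-Menten kinetics:
#' \deqn{d_{g,i} = \gamma_{gd,i} f_d(DOC) f_{d,i}(N_i) f_{d,i}(pH) f(T) B_d}
#'
#' @param guild one of \code{"no3"}, \code{"no2"}, \code{"no"},
#'   \code{"n2o"}, or a guild parameter list.
#' @param f_doc,f_n,f_ph,f_t response factors (DOC, this oxide, pH,
#'   temperature), >= 0.
#' @param b_d denitrifier biomass concentration, gC m^-3, >= 0.
#' @param p denitrifier parameter block (\code{$denitrifier} of an
#'   \code{ngas_params}).
#' @return growth rate, gC m^-3 d^-1.
#' @export
guild_growth <- function(guild, f_doc, f_n, f_ph, f_t, b_d, p) {
  g <- resolve_guild(guild, p)
  if (any(b_d < 0)) stop("denitrifier biomass must be >= 0", call. = FALSE)
  if (any(c(f_doc, f_n, f_ph, f_t) < 0))
    stop("response factors must be >= 0", call. = FALSE)
  g$gamma_gd * f_doc * f_n * f_ph * f_t * b_d
}

#' N oxide consumption rate
#'
#' Consumption of the guild's oxide is the growth-linked demand plus a
#' maintenance demand weighted by the oxide's share of all N oxides (the
#' competition weighting for electron acceptors):
#' \deqn{d_{c,i} = d_{g,i}/Y_{N_i} + M_{N_i} (N_i/N_{total}) f(T) f_{d,i}(pH) B_d}
#' The biomass factor multiplies only the maintenance term because
#' \eqn{d_{g,i}} already contains it. Availability capping is applied by
#' the chain sequencer, not here.
#'
#' @param guild guild id or parameter list.
#' @param d_g_i guild growth rate, gC m^-3 d^-1.
#' @param n_i this oxide's concentration, gN m^-3.
#' @param n_total total N oxide concentration, gN m^-3 (returns 0 when
#'   zero: nothing to reduce).
#' @param f_t,f_ph response factors.
#' @param b_d denitrifier biomass concentration, gC m^-3.
#' @param p denitrifier parameter block.
#' @return consumption rate, gN m^-3 d^-1.
#' @export
oxide_consumption <- function(guild, d_g_i, n_i, n_total, f_t, f_ph, b_d, p) {
  g <- resolve_guild(guild, p)
  if (g$y_n <= 0) stop(sprintf("guild '%s' yield must be > 0", g$oxide),
                       call. = FALSE)
  if (any(n_i < 0) || any(n_total < n_i - 1e-12))
    stop("need n_total >= n_i >= 0", call. = FALSE)
  ifelse(n_total > 0,
         d_g_i / g$y_n +
           g$m_n * (n_i / pmax(n_total, .Machine$double.xmin)) * f_t * f_ph * b_d,
         0)
}

resolve_guild <- function(guild, p) {
  if (is.character(guild)) {
    if (!guild %in% names(p$guilds))
      stop(sprintf("unknown denitrifier guild '%s'", guild), call. = FALSE)
    p$guilds[[guild]]
  } else guild
}

#' Daily denitrifier biomass update
#'
#' Total growth is the sum over guilds; death and C maintenance
#' respiration follow
#' \deqn{d_{dd} = M_c Y_c B_d, \quad r_c = d_{dg}/Y_c + M_c B_d}
#' The biomass balance is \eqn{B_d' = B_d + d_{dg} - d_{dd}} (floored at
#' zero): respiration is a carbon flux, not a biomass sink. The death
#' flux is routed to the ledger's dead-biomass sink by the simulator.
#'
#' @param b_d_prev biomass, gC m^-3 (or gC m^-2 if growth given in the
#'   same basis), >= 0.
#' @param d_dg total growth rate, same basis per day.
#' @param p denitrifier parameter block.
#' @return list \code{b_d_new}, \code{d_dd}, \code{r_c}.
#' @export
denitrifier_pool_step <- function(b_d_prev, d_dg, p) {
  if (any(b_d_prev < 0)) stop("denitrifier biomass must be >= 0", call. = FALSE)
  d_dd <- p$m_c * p$y_c * b_d_prev
  r_c <- d_dg / p$y_c + p$m_c * b_d_prev
  list(b_d_new = pmax(b_d_prev + d_dg - d_dd, 0), d_dd = d_dd, r_c = r_c)
}

#' One daily pass of the reduction chain
#'
#' Runs the four-step chain NO3- -> NO2- -> NO -> N2O -> N2 over the
#' anaerobic pools of one or more layers. All growth and consumption
#' rates are computed from beginning-of-day concentrations (parallel
#' competition through the \eqn{N_i/N_{total}} weighting); the product of
#' step i feeds pool i+1 within the same day, and each step's consumption
#' is capped at its initial pool plus same-day upstream production. When
#' the cap binds, the guild's growth is scaled by the same ratio
#' (growth-linked consumption cannot exceed the oxide actually reduced);
#' caps are logged. Nitrogen is conserved exactly: the summed oxide
#' decrease equals the N2 produced.
#'
#' @param pools named list of anaerobic pool masses \code{no3},
#'   \code{no2}, \code{no}, \code{n2o}, gN m^-2 per layer (vectors over
#'   layers).
#' @param thickness layer thicknesses, m.
#' @param f_doc DOC response factor for denitrification.
#' @param f_t temperature response factor (denitrifier Q10).
#' @param ph soil pH per layer (evaluated against each guild's curve).
#' @param b_d denitrifier biomass, gC m^-2 per layer.
#' @param p denitrifier parameter block.
#' @param ph_curves pH curve list.
#' @param dt time step, d (default 1).
#' @return list with \code{consumption} (named list per oxide, gN m^-2
#'   over dt), \code{n2} produced (gN m^-2), \code{deltas} (named list of
#'   pool changes), \code{d_g} (effective per-guild growth, gC m^-3
#'   d^-1), \code{d_dg} (total, gC m^-3 d^-1), and \code{pools_new}.
#' @export
reduction_chain_step <- function(pools, thickness, f_doc, f_t, ph, b_d, p,
                                 ph_curves = default_ph_curves(), dt = 1) {
  oxides <- guild_order
  for (ox in oxides) if (any(pools[[ox]] < 0))
    stop(sprintf("negative anaerobic pool '%s'", ox), call. = FALSE)
  nl <- length(thickness)
  conc <- lapply(oxides, function(ox) pools[[ox]] / thickness)
  names(conc) <- oxides
  n_total <- Reduce(`+`, conc)
  bd_conc <- b_d / thickness

  cons <- list()      # realised consumption, gN m^-2 over dt
  d_g_eff <- list()   # effective growth, gC m^-3 d^-1
  inflow <- numeric(nl)  # same-day upstream production, gN m^-2
  n_capped <- 0L
  for (ox in oxides) {
    g <- p$guilds[[ox]]
    f_ph <- ph_response(ph, g$ph_curve, ph_curves)
    f_n <- substrate_response(conc[[ox]], g$km_n)
    d_g <- guild_growth(g, f_doc, f_n, f_ph, f_t, bd_conc, p)
    d_c <- oxide_consumption(g, d_g, conc[[ox]], n_total, f_t, f_ph, bd_conc, p)
    demand <- d_c * thickness * dt                 # gN m^-2
    avail <- pools[[ox]] + inflow
    realised <- pmin(demand, avail)
    n_capped <- n_capped + sum(demand > avail + 1e-15)
    ratio <- ifelse(demand > 0, realised / demand, 1)
    cons[[ox]] <- realised
    d_g_eff[[ox]] <- d_g * ratio
    inflow <- realised                             # feeds the next oxide
  }
  if (n_capped > 0)
    ngas_log("reduction_chain_step: consumption capped by oxide availability (%d guild-layer case(s))",
             n_capped)

  deltas <- list(
    no3 = -cons$no3,
    no2 = cons$no3 - cons$no2,
    no  = cons$no2 - cons$no,
    n2o = cons$no - cons$n2o
  )
  pools_new <- lapply(oxides, function(ox) pools[[ox]] + deltas[[ox]])
  names(pools_new) <- oxides
  for (ox in oxides) if (any(pools_new[[ox]] < -1e-12))
    stop("internal invariant failure: negative oxide pool after chain update",
         call. = FALSE)
  pools_new <- lapply(pools_new, function(x) pmax(x, 0))

  list(consumption = cons, n2 = cons$n2o, deltas = deltas,
       d_g = d_g_eff, d_dg = Reduce(`+`, d_g_eff),
       pools_new = pools_new)
}
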