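#' Daily nitrifier population step
#'
#' Advances the autotrophic nitrifier biomass one day with explicit
#' growth, death and maintenance-respiration terms:
#' \deqn{n_g = \gamma_{gn} f(T) f(W) f_n(pH) f_n(DOC) f(NO_3) M_b}
#' \deqn{n_d = d_{dn} f(T) f(W) f_n(pH) f_n(DOC) M_b}
#' \deqn{r_r = (1/\epsilon_n - 1) M_b}
#' \deqn{M_b' = M_b + n_g - n_d - r_r}
#'
#' Growth is keyed to the nitrate response as published (a configurable
#' switch, \code{growth_substrate = "nh4"}, substitutes the ammonium
#' response for users preferring the substrate reading); maintenance
#' respiration carries no environmental modifier, again as published.
#' The updated biomass is floored at zero, with the deficit logged.
#'
#' @param m_b_prev nitrifier biomass, gC m^-2, >= 0. Vectorised over
#'   layers.
#' @param f_t,f_w,f_ph,f_doc,f_nsub response factors (temperature,
#'   moisture, pH, DOC, and growth-substrate N), all >= 0.
#' @param p nitrifier parameter block (\code{$nitrifier} of an
#'   \code{ngas_params}).
#' @return list with \code{m_b_new} and the daily rates \code{n_g},
#'   \code{n_d}, \code{r_r} (gC m^-2 d^-1).
#' @export
nitrifier_step <- function(m_b_prev, f_t, f_w, f_ph, f_doc, f_nsub, p) {
  if (any(m_b_prev < 0)) stop("nitrifier biomass must be >= 0", call. = FALSE)
  if (any(c(f_t, f_w, f_ph, f_doc, f_nsub) < 0))
    stop("response factors must be >= 0", call. = FALSE)
  n_g <- p$gamma_gn * f_t * f_w * f_ph * f_doc * f_nsub * m_b_prev
  n_d <- p$d_dn * f_t * f_w * f_ph * f_doc * m_b_prev
  r_r <- (1 / p$epsilon_n - 1) * m_b_prev
  m_b_new <- m_b_prev + n_g - n_d - r_r
  n_floor <- sum(m_b_new < 0)
  if (n_floor > 0) {
    ngas_log("nitrifier_step: biomass floored at 0 in %d layer(s) (deficit %.3e gC m^-2)",
             n_floor, -sum(pmin(m_b_new, 0)))
    m_b_new <- pmax(m_b_new, 0)
  }
  list(m_b_new = m_b_new, n_g = n_g, n_d = n_d, r_r = r_r)
}

#' Daily nitrification flux
#'
#' \deqn{n_n = n_{nmax} f(T) f(W) f_n(pH) f(NH_4) M_b}
#' capped at the ammonium actually available to the aerobic fraction that
#' day (the cap is logged so stiffness is detectable).
#'
#' @param m_b nitrifier biomass, gC m^-2 (current step). Vectorised.
#' @param f_t,f_w,f_ph,f_nh4 response factors.
#' @param p nitrifier parameter block.
#' @param nh4_avail ammonium available in the aerobic fraction,
#'   gN m^-2 (default unlimited).
#' @return nitrification flux, gN m^-2 d^-1.
#' @export
nitrification_rate <- function(m_b, f_t, f_w, f_ph, f_nh4, p,
                               nh4_avail = Inf) {
  if (any(m_b < 0)) stop("nitrifier biomass must be >= 0", call. = FALSE)
  n_n <- p$n_nmax * f_t * f_w * f_ph * f_nh4 * m_b
  n_cap <- sum(n_n > nh4_avail)
  if (n_cap > 0)
    ngas_log("nitrification_rate: demand capped by NH4 availability in %d layer(s)",
             n_cap)
  pmin(n_n, nh4_avail)
}

#' Split the nitrification flux into its products
#'
#' Routes small fractions \code{phi_no} and \code{phi_n2o} of the
#' nitrified N to NO and N2O byproducts, the remainder to nitrate; the
#' three products sum to the flux exactly (nitrate is computed as the
#' complement). Both fractions default to 0: nitrification-sourced
#' NO/N2O requires configuring them.
#'
#' @param n_n nitrification flux, gN m^-2 d^-1, >= 0. Vectorised.
#' @param p nitrifier parameter block.
#' @return list \code{no}, \code{n2o}, \code{no3} (gN m^-2 d^-1).
#' @export
nitrification_byproducts <- function(n_n, p) {
  if (p$phi_no + p$phi_n2o >= 1)
    stop("phi_no + phi_n2o must be < 1", call. = FALSE)
  if (any(n_n < 0)) stop("nitrification flux must be >= 0", call. = FALSE)
  no <- p$phi_no * n_n
  n2o <- p$phi_n2o * n_n
  list(no = no, n2o = n2o, no3 = n_n - no - n2o)
}
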