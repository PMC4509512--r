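#' Model-evaluation statistic suite
#'
#' Computes the seven-statistic validation set for a paired
#' observed/simulated series, plus 95%-confidence companions when
#' per-observation confidence half-widths are supplied:
#' \describe{
#'   \item{r}{Pearson correlation (flagged \code{NA} when the
#'     observations are constant).}
#'   \item{rmse}{root mean square error as a percentage of the observed
#'     mean: \code{(100/mean(O)) * sqrt(sum((P-O)^2)/n)}.}
#'   \item{ef}{modelling efficiency
#'     \code{1 - sum((P-O)^2)/sum((O-mean(O))^2)}: 1 at a perfect fit, 0
#'     when no better than the observed mean, negative when worse.}
#'   \item{cd}{coefficient of determination
#'     \code{sum((O-mean(O))^2)/sum((P-mean(O))^2)}: observed scatter
#'     about the mean over predicted scatter about the observed mean.}
#'   \item{re}{relative error, \code{(100/n') * sum((O-P)/O)} over the
#'     n' pairs with O != 0 (zero-observation pairs are excluded and
#'     counted in \code{re_n_excluded}; the relative-error term is
#'     undefined at O = 0, frequent in flux data).}
#'   \item{md}{mean deviation \code{mean(O - P)} (negative = bias towards
#'     over-estimation), with its paired t statistic
#'     \code{t_md = md / (sd(O-P)/sqrt(n))}.}
#'   \item{me}{maximum absolute error.}
#'   \item{rmse95, re95}{computed from the supplied 95% CI half-widths
#'     \code{ci} as \code{(100/mean(O)) * sqrt(mean(ci^2))} and
#'     \code{(100/n') * sum(ci/O)}; \code{NA} when \code{ci} is absent.
#'     RMSE below rmse95 means the simulation falls within the
#'     measurement confidence band.}
#' }
#'
#' @param observed numeric vector of observations.
#' @param simulated numeric vector of model predictions, same length.
#' @param ci optional per-observation 95% CI half-widths.
#' @return an object of class \code{ngas_evalstats} (a one-row list).
#' @export
evaluate_fit <- function(observed, simulated, ci = NULL) {
  o <- as.numeric(observed); s <- as.numeric(simulated)
  n <- length(o)
  if (length(s) != n) stop("observed and simulated lengths differ", call. = FALSE)
  if (n < 2) stop("need at least 2 paired values", call. = FALSE)
  if (!is.null(ci) && length(ci) != n)
    stop("ci must match the series length", call. = FALSE)
  obar <- mean(o)
  d <- o - s
  sse <- sum((s - o)^2)
  sso <- sum((o - obar)^2)
  r <- if (sso == 0 || stats::sd(s) == 0) NA_real_ else stats::cor(o, s)
  if (sso == 0) ngas_log("evaluate_fit: observations constant, r undefined")

  nz <- o != 0
  n_nz <- sum(nz)
  re <- if (n_nz > 0) (100 / n_nz) * sum(d[nz] / o[nz]) else NA_real_
  sd_d <- stats::sd(d)
  structure(list(
    r = r,
    rmse = (100 / obar) * sqrt(sse / n),
    rmse95 = if (is.null(ci)) NA_real_
             else (100 / obar) * sqrt(mean(ci^2)),
    ef = 1 - sse / sso,
    cd = sso / sum((s - obar)^2),
    re = re,
    re95 = if (is.null(ci) || n_nz == 0) NA_real_
           else (100 / n_nz) * sum(ci[nz] / o[nz]),
    re_n_excluded = n - n_nz,
    md = mean(d),
    t_md = if (sd_d == 0) NA_real_ else mean(d) / (sd_d / sqrt(n)),
    me = max(abs(d)),
    n = n
  ), class = "ngas_evalstats")
}

#' @export
print.ngas_evalstats <- function(x, ...) {
  cat("<ngas_evalstats>\n")
  fmt <- function(v) if (is.na(v)) "NA" else format(signif(v, 4))
  cat(sprintf("  R %s | RMSE %s%% (95%%: %s) | EF %s | CD %s\n",
              fmt(x$r), fmt(x$rmse), fmt(x$rmse95), fmt(x$ef), fmt(x$cd)))
  cat(sprintf("  RE %s%% (95%%: %s; %d zero-obs excluded) | MD %s (t %s) | ME %s | n %d\n",
              fmt(x$re), fmt(x$re95), x$re_n_excluded, fmt(x$md), fmt(x$t_md),
              fmt(x$me), x$n))
  invisible(x)
}

#' Fertiliser-induced emission factor
#'
#' N2O-N emitted in excess of the unfertilised control, as a percentage
#' of the fertiliser N applied: \code{100 * (treatment - control) /
#' n_applied}. May be negative (reported as such, never clipped); the
#' IPCC default value is 1%.
#'
#' @param cum_treatment cumulative N2O-N emission of the treatment,
#'   gN m^-2.
#' @param cum_control cumulative emission of the paired control.
#' @param n_applied fertiliser N applied, gN m^-2, > 0.
#' @return emission factor, %.
#' @export
emission_factor <- function(cum_treatment, cum_control, n_applied) {
  if (n_applied <= 0) stop("n_applied must be > 0", call. = FALSE)
  100 * (cum_treatment - cum_control) / n_applied
}

#' Bounded differential evolution optimizer
#'
#' A compact rand/1/bin differential evolution minimiser with box
#' bounds, used as the default calibration engine (the harness accepts
#' any optimizer with the same signature). Deterministic given
#' \code{seed}; the caller's RNG state is left untouched. A zero
#' generation budget evaluates nothing and returns the initial point.
#'
#' @param fn objective function of a numeric parameter vector.
#' @param lower,upper bound vectors.
#' @param init optional initial point (returned unchanged when
#'   \code{n_gen = 0}; also seeded into the population).
#' @param n_pop population size (default \code{10 * n_par}, at least 8).
#' @param n_gen number of generations.
#' @param f_weight differential weight (default 0.8).
#' @param cr crossover rate (default 0.9).
#' @param seed integer seed.
#' @return list \code{par}, \code{value}, \code{trace} (data frame of
#'   best objective per generation, generation 0 = initial population).
#' @export
de_optimize <- function(fn, lower, upper, init = NULL, n_pop = NULL,
                        n_gen = 30, f_weight = 0.8, cr = 0.9, seed = 1) {
  d <- length(lower)
  if (length(upper) != d || any(upper <= lower))
    stop("need finite bounds with lower < upper", call. = FALSE)
  if (is.null(init)) init <- (lower + upper) / 2
  if (n_gen == 0)
    return(list(par = init, value = NA_real_,
                trace = data.frame(generation = integer(0), best = numeric(0))))
  if (is.null(n_pop)) n_pop <- max(8, 10 * d)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  pop <- matrix(stats::runif(n_pop * d, rep(lower, each = n_pop),
                             rep(upper, each = n_pop)), nrow = n_pop)
  pop[1, ] <- pmin(pmax(init, lower), upper)
  val <- apply(pop, 1, fn)
  if (all(!is.finite(val)))
    stop("calibration failure: objective non-finite for the entire initial population",
         call. = FALSE)
  trace <- data.frame(generation = 0L, best = min(val[is.finite(val)]))
  for (g in seq_len(n_gen)) {
    for (i in seq_len(n_pop)) {
      idx <- sample(setdiff(seq_len(n_pop), i), 3)
      mutant <- pop[idx[1], ] + f_weight * (pop[idx[2], ] - pop[idx[3], ])
      mutant <- pmin(pmax(mutant, lower), upper)
      cross <- stats::runif(d) < cr
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      tv <- fn(trial)
      if (is.finite(tv) && (!is.finite(val[i]) || tv <= val[i])) {
        pop[i, ] <- trial
        val[i] <- tv
      }
    }
    trace <- rbind(trace, data.frame(generation = g,
                                     best = min(val[is.finite(val)])))
  }
  best <- which.min(val)
  list(par = pop[best, ], value = val[best], trace = trace)
}

#' Calibrate model parameters against observations
#'
#' Minimises the root mean square error between observed daily N2O
#' fluxes and simulated fluxes from repeated model runs, over a named
#' subset of parameters within box bounds. The optimizer (default
#' \code{\link{de_optimize}}) is pluggable; the run is deterministic
#' given \code{seed}. A zero-generation budget returns the initial
#' parameter set unchanged.
#'
#' @param profile,forcing,events,mode forwarded to
#'   \code{\link{run_simulation}} for each trial.
#' @param params base \code{ngas_params}; named parameters are
#'   overridden per trial.
#' @param observed observed daily N2O flux, gN m^-2 d^-1, one value per
#'   forcing day.
#' @param parameters character vector of dotted parameter names (see
#'   \code{\link{param_get}}).
#' @param lower,upper bounds, one per parameter.
#' @param n_gen,n_pop optimizer budget.
#' @param seed integer seed for the optimizer.
#' @param optimizer optimizing function with the \code{de_optimize}
#'   signature.
#' @return list \code{params} (best-found full set), \code{par} (named
#'   best values), \code{rmse} (objective at the optimum), \code{trace}.
#' @export
calibrate <- function(profile, forcing, events = NULL,
                      params = default_parameters(), observed,
                      parameters, lower, upper, mode = "microbial",
                      n_gen = 30, n_pop = NULL, seed = 1,
                      optimizer = de_optimize) {
  if (length(parameters) != length(lower) || length(lower) != length(upper))
    stop("parameters, lower and upper must have equal length", call. = FALSE)
  if (length(observed) != length(forcing$dates))
    stop("observed must have one value per forcing day", call. = FALSE)
  for (nm in parameters) param_get(params, nm)  # existence check

  objective <- function(x) {
    p <- params
    for (k in seq_along(parameters)) p <- param_set(p, parameters[k], x[k])
    run <- tryCatch(
      run_simulation(profile, forcing, events, p, mode = mode),
      error = function(e) NULL)
    if (is.null(run)) return(Inf)
    sqrt(mean((run$fluxes$n2o_flux - observed)^2))
  }
  init <- vapply(parameters, function(nm) param_get(params, nm), numeric(1))
  fit <- optimizer(objective, lower, upper, init = init,
                   n_pop = n_pop, n_gen = n_gen, seed = seed)
  best <- params
  if (n_gen > 0)
    for (k in seq_along(parameters)) best <- param_set(best, parameters[k],
                                                       fit$par[k])
  list(params = best, par = stats::setNames(fit$par, parameters),
       rmse = fit$value, trace = fit$trace)
}
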