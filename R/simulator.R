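#' Construct and validate a forcing series
#'
#' Daily environmental drivers for a run: per-layer soil temperature and
#' volumetric water content, optional per-layer pH, and optional
#' prescribed plant N uptake and DOC input (both whole-profile daily
#' totals). Dates must be strictly increasing, daily and gap-free.
#'
#' @param dates Date vector.
#' @param t_soil numeric matrix, days x layers, degC.
#' @param theta numeric matrix, days x layers, m3 m^-3 in [0, 1].
#' @param ph optional matrix, days x layers (default: the profile's
#'   static pH is used).
#' @param uptake optional prescribed plant N uptake, gN m^-2 d^-1
#'   (default 0).
#' @param doc_input optional DOC input to the top layer, gC m^-2 d^-1
#'   (default 0).
#' @return an object of class \code{ngas_forcing}.
#' @export
forcing_series <- function(dates, t_soil, theta, ph = NULL,
                           uptake = NULL, doc_input = NULL) {
  dates <- as.Date(dates)
  nd <- length(dates)
  if (nd < 1) stop("forcing needs at least one day", call. = FALSE)
  if (nd > 1) {
    gaps <- diff(as.integer(dates))
    if (any(gaps != 1)) {
      missing_days <- dates[which(gaps != 1)]
      stop(sprintf("forcing dates must be daily and gap-free (gap after %s)",
                   paste(missing_days, collapse = ", ")), call. = FALSE)
    }
  }
  t_soil <- as.matrix(t_soil); theta <- as.matrix(theta)
  if (nrow(t_soil) != nd || nrow(theta) != nd)
    stop("t_soil/theta must have one row per date", call. = FALSE)
  if (ncol(t_soil) != ncol(theta))
    stop("t_soil and theta must agree on layer count", call. = FALSE)
  if (any(theta < 0 | theta > 1))
    stop("theta must lie in [0, 1]", call. = FALSE)
  if (!is.null(ph)) {
    ph <- as.matrix(ph)
    if (!all(dim(ph) == dim(t_soil)))
      stop("ph matrix must match t_soil dimensions", call. = FALSE)
  }
  zero <- rep(0, nd)
  structure(list(dates = dates, t_soil = t_soil, theta = theta, ph = ph,
                 uptake = if (is.null(uptake)) zero else uptake,
                 doc_input = if (is.null(doc_input)) zero else doc_input),
            class = "ngas_forcing")
}

#' Read and write forcing files
#'
#' Delimited-text representation of a forcing series: CSV with columns
#' \code{date} (ISO-8601), \code{uptake}, \code{doc_input},
#' \code{t_1..t_L}, \code{theta_1..theta_L} and optionally
#' \code{ph_1..ph_L}.
#'
#' @param f an \code{ngas_forcing}.
#' @param path file path.
#' @return \code{read_forcing}: an \code{ngas_forcing}.
#'   \code{write_forcing}: \code{path}, invisibly.
#' @export
write_forcing <- function(f, path) {
  nl <- ncol(f$t_soil)
  df <- data.frame(date = format(f$dates), uptake = f$uptake,
                   doc_input = f$doc_input)
  tm <- as.data.frame(f$t_soil); names(tm) <- paste0("t_", seq_len(nl))
  th <- as.data.frame(f$theta); names(th) <- paste0("theta_", seq_len(nl))
  df <- cbind(df, tm, th)
  if (!is.null(f$ph)) {
    pm <- as.data.frame(f$ph); names(pm) <- paste0("ph_", seq_len(nl))
    df <- cbind(df, pm)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcing
#' @export
read_forcing <- function(path) {
  if (!file.exists(path)) stop(sprintf("forcing file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  tcols <- grep("^t_[0-9]+$", names(df), value = TRUE)
  thcols <- grep("^theta_[0-9]+$", names(df), value = TRUE)
  phcols <- grep("^ph_[0-9]+$", names(df), value = TRUE)
  forcing_series(
    dates = as.Date(df$date),
    t_soil = as.matrix(df[tcols]),
    theta = as.matrix(df[thcols]),
    ph = if (length(phcols)) as.matrix(df[phcols]) else NULL,
    uptake = if ("uptake" %in% names(df)) df$uptake else NULL,
    doc_input = if ("doc_input" %in% names(df)) df$doc_input else NULL
  )
}

#' Management event schedules
#'
#' Events are held in a data frame with columns \code{date},
#' \code{kind} (\code{mineral_fertiliser}, \code{slurry} or \code{cut}),
#' \code{total_n} and \code{ammoniacal_n} (gN m^-2) and
#' \code{dry_matter_pct} (slurry only, informational).
#' \code{management_events} validates and normalises such a frame;
#' \code{read_management}/\code{write_management} are the CSV round-trip.
#'
#' @param df data frame as above (\code{date} coercible to Date).
#' @return validated data frame of class \code{ngas_events}.
#' @export
management_events <- function(df) {
  if (nrow(df) == 0) {
    df <- data.frame(date = as.Date(character(0)), kind = character(0),
                     total_n = numeric(0), ammoniacal_n = numeric(0),
                     dry_matter_pct = numeric(0))
    class(df) <- c("ngas_events", "data.frame")
    return(df)
  }
  df$date <- as.Date(df$date)
  if (!"dry_matter_pct" %in% names(df)) df$dry_matter_pct <- NA_real_
  if (!"total_n" %in% names(df)) df$total_n <- 0
  if (!"ammoniacal_n" %in% names(df)) df$ammoniacal_n <- 0
  df$total_n[is.na(df$total_n)] <- 0
  df$ammoniacal_n[is.na(df$ammoniacal_n)] <- 0
  bad <- !df$kind %in% c("mineral_fertiliser", "slurry", "cut")
  if (any(bad)) stop(sprintf("unknown event kind(s): %s",
                             paste(unique(df$kind[bad]), collapse = ", ")),
                     call. = FALSE)
  if (any(df$total_n < 0) || any(df$ammoniacal_n < 0))
    stop("event N amounts must be >= 0", call. = FALSE)
  if (any(df$ammoniacal_n > df$total_n + 1e-12))
    stop("ammoniacal_n must not exceed total_n", call. = FALSE)
  df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("ngas_events", "data.frame")
  df
}

#' @rdname management_events
#' @param events an \code{ngas_events} frame.
#' @param path file path.
#' @export
write_management <- function(events, path) {
  out <- as.data.frame(events)
  out$date <- format(out$date)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname management_events
#' @export
read_management <- function(path) {
  if (!file.exists(path)) stop(sprintf("management file not found: %s", path),
                               call. = FALSE)
  management_events(utils::read.csv(path))
}

#' Apply one management event to the profile
#'
#' Mineral fertiliser adds its ammoniacal N to the top layer's NH4+ pool
#' and the remainder to its NO3- pool. Slurry adds the ammoniacal share
#' to NH4+ and the organic remainder (total - ammoniacal) to a
#' slow-release organic pool that mineralises to NH4+ first-order at
#' \code{soil$org_n_min_rate}. A cut only resets prescribed uptake
#' (plant growth is a prescribed forcing, not modelled) and changes no
#' pool. All fertiliser N is recorded as a ledger input.
#'
#' @param profile an \code{ngas_profile}.
#' @param event one-row event (list or data-frame row with \code{kind},
#'   \code{total_n}, \code{ammoniacal_n}).
#' @param ledger an \code{ngas_ledger} (updated in place); optional.
#' @return the updated profile.
#' @export
apply_management <- function(profile, event, ledger = NULL) {
  kind <- as.character(event$kind)
  total <- as.numeric(event$total_n)
  amm <- as.numeric(event$ammoniacal_n)
  if (total < 0 || amm < 0 || amm > total + 1e-12)
    stop("invalid event amounts (need 0 <= ammoniacal_n <= total_n)",
         call. = FALSE)
  if (kind == "mineral_fertiliser") {
    profile$nh4[1] <- profile$nh4[1] + amm
    profile$no3[1] <- profile$no3[1] + (total - amm)
  } else if (kind == "slurry") {
    profile$nh4[1] <- profile$nh4[1] + amm
    profile$org_n[1] <- profile$org_n[1] + (total - amm)
  } else if (kind == "cut") {
    total <- 0  # no N input
  } else {
    stop(sprintf("unknown event kind '%s'", kind), call. = FALSE)
  }
  if (!is.null(ledger)) ledger$fertiliser <- ledger$fertiliser + total
  profile
}

#' Legacy first-order transformation rates
#'
#' The baseline (pre-microbial) formulation: single first-order rate
#' constants modified by the environmental response factors,
#' \code{nitr = k_nitr * NH4 * f(T) f(W) f(pH)} and
#' \code{denit = k_denit * NO3 * f(T) f(W) f(pH)}. The denitrified N is
#' not partitioned into gas species -- the legacy limitation this
#' package's microbial mode removes.
#'
#' @param nh4,no3 pools, gN m^-2 (vectors over layers).
#' @param f_t,f_w,f_ph response factors.
#' @param tp transport parameter block (holds \code{legacy_k_nitr},
#'   \code{legacy_k_denit}).
#' @return list \code{nitr}, \code{denit}, gN m^-2 d^-1.
#' @export
legacy_first_order_rates <- function(nh4, no3, f_t, f_w, f_ph, tp) {
  if (any(nh4 < 0) || any(no3 < 0)) stop("pools must be >= 0", call. = FALSE)
  list(nitr = tp$legacy_k_nitr * nh4 * f_t * f_w * f_ph,
       denit = tp$legacy_k_denit * no3 * f_t * f_w * f_ph)
}

#' Advance the simulation one day
#'
#' The daily operator sequence, per layer: (1) update theta, temperature
#' and pH from forcing; compute WFPS and the anaerobic fraction; (2)
#' apply management events and atmospheric deposition; (3) nitrification
#' in the aerobic fraction; (4) the reduction chain in the anaerobic
#' fraction; (5) gas partition and emission; (6) microbial biomass
#' updates; (7) prescribed uptake, slurry-N mineralisation and DOC
#' relaxation. All rates are explicit first-order updates from the state
#' at the start of each sub-step (dt = 1 d, no sub-daily iteration);
#' availability caps are logged so stiffness is detectable.
#'
#' @param profile an \code{ngas_profile}.
#' @param forcing an \code{ngas_forcing}.
#' @param day_idx index of the day within \code{forcing}.
#' @param events_today zero or more event rows dated today.
#' @param params an \code{ngas_params}.
#' @param mode \code{"microbial"} or \code{"legacy"}.
#' @param ledger an \code{ngas_ledger} updated in place.
#' @return list \code{profile} (advanced) and \code{flux} (named list:
#'   per-gas surface emissions gN m^-2 d^-1, nitrification and
#'   denitrification totals, legacy denitrified N, diagnostics).
#' @export
step_day <- function(profile, forcing, day_idx, events_today, params,
                     mode = "microbial", ledger) {
  p <- params
  nl <- n_layers(profile)
  th <- profile$thickness

  # (1) environmental state
  profile$theta <- pmin(forcing$theta[day_idx, ], profile$theta_sat)
  profile$t_soil <- forcing$t_soil[day_idx, ]
  if (!is.null(forcing$ph)) profile$ph <- forcing$ph[day_idx, ]
  profile$wfps <- wfps(profile$theta, profile$rho_d, profile$rho_s)
  profile$f_r <- anaerobic_fraction(profile$wfps, p$transport)

  # (2) management + deposition
  if (!is.null(events_today) && NROW(events_today) > 0) {
    for (r in seq_len(NROW(events_today)))
      profile <- apply_management(profile, events_today[r, ], ledger)
  }
  if (p$soil$n_deposition > 0) {
    profile$nh4[1] <- profile$nh4[1] + p$soil$n_deposition
    ledger$deposition <- ledger$deposition + p$soil$n_deposition
  }

  n_n_total <- 0
  denit_total <- 0
  legacy_denit <- 0
  flux_no <- flux_n2o <- flux_n2 <- NA_real_

  if (mode == "microbial") {
    # (3) nitrification in the aerobic fraction
    doc_conc <- profile$doc / th
    f_t_n <- temperature_response(profile$t_soil, p$nitrifier$q10, p$nitrifier$t_ref)
    f_w <- moisture_response_nitrification(profile$wfps)
    f_ph_n <- ph_response(profile$ph, "nitrifier", p$ph_curves)
    f_doc_n <- substrate_response(doc_conc, p$nitrifier$km_doc)
    f_nsub <- if (p$nitrifier$growth_substrate == "no3")
      substrate_response(profile$no3 / th, p$nitrifier$km_no3)
    else substrate_response(profile$nh4 / th, p$nitrifier$km_nh4)

    nit <- nitrifier_step(profile$m_b, f_t_n, f_w, f_ph_n, f_doc_n, f_nsub,
                          p$nitrifier)
    ledger$death_sink_c <- ledger$death_sink_c + sum(nit$n_d)
    profile$m_b <- nit$m_b_new

    f_nh4 <- substrate_response(profile$nh4 / th, p$nitrifier$km_nh4)
    nh4_aer <- partition_substrates(profile$nh4, profile$f_r)$aerobic
    n_n <- nitrification_rate(profile$m_b, f_t_n, f_w, f_ph_n, f_nh4,
                              p$nitrifier, nh4_avail = nh4_aer)
    bp <- nitrification_byproducts(n_n, p$nitrifier)
    profile$nh4 <- profile$nh4 - n_n
    profile$no3 <- profile$no3 + bp$no3
    profile$no_diss <- profile$no_diss + bp$no
    profile$n2o_diss <- profile$n2o_diss + bp$n2o
    n_n_total <- sum(n_n)

    # (4) reduction chain in the anaerobic fraction
    split_no3 <- partition_substrates(profile$no3, profile$f_r)
    split_no2 <- partition_substrates(profile$no2, profile$f_r)
    split_no  <- partition_substrates(profile$no_diss, profile$f_r)
    split_n2o <- partition_substrates(profile$n2o_diss, profile$f_r)
    f_t_d <- temperature_response(profile$t_soil, p$denitrifier$q10,
                                  p$denitrifier$t_ref)
    f_doc_d <- substrate_response(doc_conc, p$denitrifier$km_doc_denit)
    chain <- reduction_chain_step(
      pools = list(no3 = split_no3$anaerobic, no2 = split_no2$anaerobic,
                   no = split_no$anaerobic, n2o = split_n2o$anaerobic),
      thickness = th, f_doc = f_doc_d, f_t = f_t_d, ph = profile$ph,
      b_d = profile$b_d, p = p$denitrifier, ph_curves = p$ph_curves)
    profile$no3 <- split_no3$aerobic + chain$pools_new$no3
    profile$no2 <- split_no2$aerobic + chain$pools_new$no2
    profile$no_diss <- split_no$aerobic + chain$pools_new$no
    profile$n2o_diss <- split_n2o$aerobic + chain$pools_new$n2o
    n2_prod <- chain$n2
    denit_total <- sum(chain$consumption$no3)

    # (5) gas partition and emission
    em_no <- partition_and_emit(profile$no_diss, 0, profile$wfps, "no",
                                p$transport)
    em_n2o <- partition_and_emit(profile$n2o_diss, 0, profile$wfps, "n2o",
                                 p$transport)
    profile$no_diss <- em_no$retained
    profile$n2o_diss <- em_n2o$retained
    flux_no <- surface_flux(em_no$emitted)$g_m2
    flux_n2o <- surface_flux(em_n2o$emitted)$g_m2
    flux_n2 <- surface_flux(n2_prod)$g_m2    # inert end product, escapes fully
    ledger$emitted_no <- ledger$emitted_no + flux_no
    ledger$emitted_n2o <- ledger$emitted_n2o + flux_n2o
    ledger$emitted_n2 <- ledger$emitted_n2 + flux_n2

    # (6) denitrifier biomass update (nitrifier updated in step 3)
    bd <- denitrifier_pool_step(profile$b_d, chain$d_dg * th, p$denitrifier)
    ledger$death_sink_c <- ledger$death_sink_c + sum(bd$d_dd)
    if (p$soil$recycle_fraction > 0)
      profile$doc <- profile$doc + p$soil$recycle_fraction * bd$d_dd
    profile$b_d <- bd$b_d_new
  } else if (mode == "legacy") {
    f_t <- temperature_response(profile$t_soil, p$nitrifier$q10, p$nitrifier$t_ref)
    f_w <- moisture_response_nitrification(profile$wfps)
    rates <- legacy_first_order_rates(
      profile$nh4, profile$no3, f_t, f_w,
      ph_response(profile$ph, "nitrifier", p$ph_curves), p$transport)
    nitr <- pmin(rates$nitr, profile$nh4)
    profile$nh4 <- profile$nh4 - nitr
    profile$no3 <- profile$no3 + nitr
    denit <- pmin(
      p$transport$legacy_k_denit * profile$no3 * f_t * f_w *
        ph_response(profile$ph, "denit_no3", p$ph_curves),
      profile$no3)
    profile$no3 <- profile$no3 - denit
    legacy_denit <- sum(denit)
    ledger$denitrified_legacy <- ledger$denitrified_legacy + legacy_denit
    n_n_total <- sum(nitr)
  } else stop(sprintf("unknown mode '%s'", mode), call. = FALSE)

  # (7) prescribed uptake, slurry mineralisation, DOC housekeeping
  u <- forcing$uptake[day_idx]
  if (u > 0) {
    tot_no3 <- sum(profile$no3)
    take_no3 <- min(u, tot_no3)
    if (take_no3 > 0 && tot_no3 > 0)
      profile$no3 <- profile$no3 * (1 - take_no3 / tot_no3)
    rem <- u - take_no3
    tot_nh4 <- sum(profile$nh4)
    take_nh4 <- min(rem, tot_nh4)
    if (take_nh4 > 0 && tot_nh4 > 0)
      profile$nh4 <- profile$nh4 * (1 - take_nh4 / tot_nh4)
    realised <- take_no3 + take_nh4
    if (realised < u)
      ngas_log("step_day: prescribed uptake limited by mineral N (%.3g of %.3g)",
               realised, u)
    ledger$uptake <- ledger$uptake + realised
  }
  min_n <- p$soil$org_n_min_rate * profile$org_n
  profile$org_n <- profile$org_n - min_n
  profile$nh4 <- profile$nh4 + min_n
  profile$doc <- profile$doc +
    p$soil$doc_relax * (p$soil$doc_target * th - profile$doc)
  profile$doc[1] <- profile$doc[1] + forcing$doc_input[day_idx]

  flux <- list(date = forcing$dates[day_idx],
               no_flux = flux_no, n2o_flux = flux_n2o, n2_flux = flux_n2,
               denitrified_legacy = legacy_denit,
               nitrification = n_n_total, no3_reduced = denit_total,
               wfps_top = profile$wfps[1], f_r_top = profile$f_r[1],
               storage_n = total_mobile_n(profile))
  list(profile = profile, flux = flux)
}

#' Run the daily simulation loop
#'
#' Steps the profile through every day of the forcing series, applying
#' management events on their dates, checking nitrogen-mass closure after
#' every day (hard failure with a ledger dump above \code{daily_tol}),
#' and collecting the daily flux records. Deterministic: no randomness
#' is consumed.
#'
#' @param profile initial \code{ngas_profile}.
#' @param forcing an \code{ngas_forcing}.
#' @param events an \code{ngas_events} frame (or NULL for none). Events
#'   dated outside the forcing window are a validation error.
#' @param params an \code{ngas_params}.
#' @param mode \code{"microbial"} (default) or \code{"legacy"}.
#' @param daily_tol relative ledger tolerance per day.
#' @return an object of class \code{ngas_run}: list with \code{fluxes}
#'   (data frame, one row per day), \code{profile} (final state),
#'   \code{ledger}, \code{summary} (cumulative per-gas emissions,
#'   gN m^-2, plus totals) and \code{log} (events recorded during the
#'   run).
#' @export
run_simulation <- function(profile, forcing, events = NULL,
                           params = default_parameters(),
                           mode = "microbial", daily_tol = 1e-9) {
  if (!is.null(events) && NROW(events) > 0) {
    outside <- !(events$date %in% forcing$dates)
    if (any(outside))
      stop(sprintf("management event(s) outside the forcing window: %s",
                   paste(events$date[outside], collapse = ", ")), call. = FALSE)
  }
  nd <- length(forcing$dates)
  if (ncol(forcing$t_soil) != n_layers(profile))
    stop("forcing layer count does not match the profile", call. = FALSE)
  ledger <- new_ledger(profile)
  log_mark <- length(ngas_log_entries())
  rows <- vector("list", nd)
  for (i in seq_len(nd)) {
    ev <- if (is.null(events)) NULL
          else events[events$date == forcing$dates[i], , drop = FALSE]
    st <- step_day(profile, forcing, i, ev, params, mode, ledger)
    profile <- st$profile
    ledger_check(ledger, profile, tol = daily_tol)
    rows[[i]] <- st$flux
  }
  fluxes <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  summary <- list(
    cum_no = ledger$emitted_no, cum_n2o = ledger$emitted_n2o,
    cum_n2 = ledger$emitted_n2,
    cum_denitrified_legacy = ledger$denitrified_legacy,
    cum_nitrification = sum(fluxes$nitrification),
    n_applied = ledger$fertiliser, n_days = nd)
  structure(list(fluxes = fluxes, profile = profile, ledger = ledger,
                 summary = summary,
                 log = ngas_log_entries()[seq_len(length(ngas_log_entries())) >
                                            log_mark]),
            class = "ngas_run")
}

#' @export
print.ngas_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ngas_run> %d days\n", s$n_days))
  cat(sprintf("  cumulative emissions (gN m^-2): NO %.4g, N2O %.4g, N2 %.4g\n",
              s$cum_no, s$cum_n2o, s$cum_n2))
  if (s$cum_denitrified_legacy > 0)
    cat(sprintf("  legacy denitrified N: %.4g gN m^-2\n",
                s$cum_denitrified_legacy))
  cat(sprintf("  nitrified N: %.4g gN m^-2; fertiliser N applied: %.4g gN m^-2\n",
              s$cum_nitrification, s$n_applied))
  invisible(x)
}

#' Run a simulation from a configuration
#'
#' Resolves a \code{\link{load_config}} object (or path) into profile,
#' forcing and events -- falling back on the bundled grassland fixture
#' for anything unspecified -- runs \code{\link{run_simulation}} over the
#' requested window, and optionally writes the outputs.
#'
#' @param config an \code{ngas_config} or path to a config file.
#' @return an \code{ngas_run}.
#' @export
run_model <- function(config) {
  if (is.character(config)) config <- load_config(config)
  fx <- bush_fixture()
  params <- config$params
  thick <- if (!is.null(config$layer_thicknesses)) config$layer_thicknesses
           else fx$thicknesses
  soil_props <- if (!is.null(config$profile_file))
    utils::read.csv(config$profile_file) else fx$soil_props
  init_pools <- if (!is.null(config$init_pools_file))
    utils::read.csv(config$init_pools_file) else fx$init_pools
  profile <- init_profile(thick, soil_props, init_pools, params)

  if (is.null(config$forcing_file))
    stop("config must name a forcing_file (see gen-forcing)", call. = FALSE)
  forcing <- read_forcing(config$forcing_file)
  events <- if (!is.null(config$management_file))
    read_management(config$management_file) else NULL

  if (!is.null(config$run_start) || !is.null(config$run_end)) {
    from <- if (is.null(config$run_start)) min(forcing$dates) else config$run_start
    to <- if (is.null(config$run_end)) max(forcing$dates) else config$run_end
    keep <- forcing$dates >= from & forcing$dates <= to
    if (!any(keep)) stop("run window does not intersect the forcing series",
                         call. = FALSE)
    forcing <- forcing_series(forcing$dates[keep],
                              forcing$t_soil[keep, , drop = FALSE],
                              forcing$theta[keep, , drop = FALSE],
                              if (is.null(forcing$ph)) NULL
                              else forcing$ph[keep, , drop = FALSE],
                              forcing$uptake[keep], forcing$doc_input[keep])
  }
  if (!is.null(events)) {
    drop <- !(events$date %in% forcing$dates)
    if (any(drop)) {
      ngas_log("run_model: dropped %d management event(s) outside the run window",
               sum(drop))
      events <- events[!drop, , drop = FALSE]
    }
  }
  run <- run_simulation(profile, forcing, events, params, mode = config$mode)
  if (!is.null(config$out_dir)) write_outputs(run, config$out_dir)
  run
}

#' Write run outputs
#'
#' Writes the daily flux table (per-gas columns in both gN m^-2 d^-1 and
#' gN ha^-1 d^-1), the ledger summary and the run log to a directory.
#' Files are written atomically (temp file + rename).
#'
#' @param run an \code{ngas_run}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_outputs <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  atomically <- function(write_fn, path) {
    tmp <- paste0(path, ".tmp")
    write_fn(tmp)
    file.rename(tmp, path)
  }
  fl <- run$fluxes
  fl$date <- format(fl$date)
  for (g in c("no_flux", "n2o_flux", "n2_flux"))
    fl[[paste0(g, "_ha")]] <- fl[[g]] * 1e4
  atomically(function(f) utils::write.csv(fl, f, row.names = FALSE),
             file.path(dir, "daily_fluxes.csv"))
  atomically(function(f) utils::write.csv(ledger_summary(run$ledger), f,
                                          row.names = FALSE),
             file.path(dir, "ledger.csv"))
  atomically(function(f) writeLines(run$log, f), file.path(dir, "run_log.txt"))
  invisible(dir)
}
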