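#' Default model parameters
#'
#' Build the complete parameter set for the microbial nitrification /
#' denitrification simulator, with every rate constant, yield, maintenance
#' coefficient and half-saturation constant set to its calibrated default.
#'
#' The set is organised in five blocks:
#' \describe{
#'   \item{nitrifier}{autotrophic nitrifier kinetics: maximum gross growth
#'     rate \code{gamma_gn} (d^-1), maximum death rate \code{d_dn} (d^-1),
#'     assimilation factor \code{epsilon_n} (-), maximum specific
#'     nitrification rate \code{n_nmax} (d^-1), Michaelis constants
#'     \code{km_doc} (gC m^-3), \code{km_no3}, \code{km_nh4} (gN m^-3),
#'     temperature response \code{q10} and \code{t_ref} (deg C), and the
#'     fractions \code{phi_no}, \code{phi_n2o} of nitrified N released as
#'     NO and N2O byproducts (both default 0: pure NH4 -> NO3 unless
#'     configured, since no byproduct fractions are calibrated).}
#'   \item{denitrifier}{four reducer guilds in chain order
#'     (NO3- -> NO2- -> NO -> N2O), each with maximum growth rate
#'     \code{gamma_gd} (d^-1), growth yield \code{y_n} (gC g^-1 N),
#'     maintenance coefficient on its oxide \code{m_n} (gC g^-1 N d^-1),
#'     half-saturation \code{km_n} (gN m^-3) and a pH curve id; plus the
#'     shared C maintenance coefficient \code{m_c} = 0.0031 d^-1, growth
#'     yield on DOC \code{y_c} = 0.503 gC g^-1 N, \code{km_doc_denit},
#'     \code{q10} and \code{t_ref}.}
#'   \item{transport}{anaerobic-fraction ramp thresholds \code{fr_lower},
#'     \code{fr_upper} (WFPS units), per-gas escape coefficients
#'     (\code{escape_no}, \code{escape_n2o}, \code{escape_n2}; N2 always
#'     escapes fully), and the first-order rate constants of the legacy
#'     baseline mode.}
#'   \item{soil}{particle density \code{rho_s} (g cm^-3), DOC relaxation
#'     target (gC m^-3) and rate (d^-1), slurry organic-N mineralisation
#'     rate (d^-1), atmospheric N deposition (gN m^-2 d^-1), microbial
#'     recycle fraction, and the fractions of total microbial C seeded as
#'     nitrifier and denitrifier biomass.}
#'   \item{ph_curves}{the pH response curve family, see
#'     \code{\link{default_ph_curves}}.}
#' }
#'
#' @return A validated object of class \code{ngas_params}.
#' @seealso \code{\link{load_config}}, \code{\link{write_params_file}},
#'   \code{\link{param_get}}
#' @export
#' @examples
#' p <- default_parameters()
#' p$nitrifier$gamma_gn        # 4.87 d^-1
#' p$denitrifier$guilds$no2$m_n # 8.38 gC g^-1 N d^-1
default_parameters <- function() {
  p <- structure(list(
    nitrifier = list(
      gamma_gn = 4.87,
      d_dn = 1.44,
      epsilon_n = 0.67,
      n_nmax = 0.004,
      km_doc = 9.45,
      km_no3 = 16.65,
      km_nh4 = 18.53,
      q10 = 2.0,
      t_ref = 20,
      phi_no = 0.0,
      phi_n2o = 0.0,
      growth_substrate = "no3"
    ),
    denitrifier = list(
      guilds = list(
        no3 = list(oxide = "no3", gamma_gd = 13.65, y_n = 0.65, m_n = 2.16,
                   km_n = 16.65, ph_curve = "denit_no3"),
        no2 = list(oxide = "no2", gamma_gd = 7.83, y_n = 0.17, m_n = 8.38,
                   km_n = 16.65, ph_curve = "denit_no2"),
        no  = list(oxide = "no",  gamma_gd = 8.28, y_n = 0.75, m_n = 1.90,
                   km_n = 16.65, ph_curve = "denit_no"),
        n2o = list(oxide = "n2o", gamma_gd = 8.81, y_n = 0.24, m_n = 1.90,
                   km_n = 16.65, ph_curve = "denit_n2o")
      ),
      m_c = 0.0031,
      y_c = 0.503,
      km_doc_denit = 9.45,
      q10 = 2.0,
      t_ref = 20
    ),
    transport = list(
      fr_lower = 0.6,
      fr_upper = 0.9,
      escape_no = 1.0,
      escape_n2o = 1.0,
      escape_n2 = 1.0,
      legacy_k_nitr = 0.2,
      legacy_k_denit = 0.1
    ),
    soil = list(
      rho_s = 2.65,
      doc_target = 15,
      doc_relax = 0.1,
      org_n_min_rate = 0.02,
      n_deposition = 0,
      recycle_fraction = 0,
      nitrifier_frac = 0.02,
      denitrifier_frac = 0.05
    ),
    ph_curves = default_ph_curves()
  ), class = "ngas_params")
  validate_params(p)
  p
}

guild_order <- c("no3", "no2", "no", "n2o")

#' Validate a parameter set
#'
#' Checks every invariant of the parameter blocks (non-negative rates,
#' yields > 0, assimilation factor in (0, 1], byproduct fractions summing
#' below 1, anaerobic-fraction ramp ordering, escape coefficients in
#' [0, 1], exactly four denitrifier guilds in reduction order, pH curves
#' mapping [3, 9] into [0, 1]). Errors name the offending field.
#'
#' @param p an \code{ngas_params} object.
#' @return \code{p}, invisibly, if valid.
#' @export
validate_params <- function(p) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
  }
  num_pos <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0
  num_nonneg <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0

  n <- p$nitrifier
  for (f in c("gamma_gn", "d_dn", "n_nmax"))
    if (!num_nonneg(n[[f]])) fail(paste0("nitrifier.", f), "must be a non-negative rate")
  if (!num_pos(n$epsilon_n) || n$epsilon_n > 1)
    fail("nitrifier.epsilon_n", "must lie in (0, 1]")
  for (f in c("km_doc", "km_no3", "km_nh4"))
    if (!num_pos(n[[f]])) fail(paste0("nitrifier.", f), "half-saturation must be > 0")
  if (!num_pos(n$q10)) fail("nitrifier.q10", "must be > 0")
  if (!num_nonneg(n$phi_no) || !num_nonneg(n$phi_n2o) || n$phi_no + n$phi_n2o >= 1)
    fail("nitrifier.phi_no/phi_n2o", "byproduct fractions must be >= 0 and sum below 1")
  if (!n$growth_substrate %in% c("no3", "nh4"))
    fail("nitrifier.growth_substrate", "must be 'no3' or 'nh4'")

  d <- p$denitrifier
  if (!identical(names(d$guilds), guild_order))
    fail("denitrifier.guilds", "exactly four guilds required, in order no3, no2, no, n2o")
  for (g in d$guilds) {
    id <- paste0("denitrifier.guilds.", g$oxide)
    if (!num_nonneg(g$gamma_gd)) fail(paste0(id, ".gamma_gd"), "must be >= 0")
    if (!num_pos(g$y_n)) fail(paste0(id, ".y_n"), "yield must be > 0")
    if (!num_nonneg(g$m_n)) fail(paste0(id, ".m_n"), "must be >= 0")
    if (!num_pos(g$km_n)) fail(paste0(id, ".km_n"), "half-saturation must be > 0")
    if (!g$ph_curve %in% names(p$ph_curves))
      fail(paste0(id, ".ph_curve"), sprintf("unknown pH curve '%s'", g$ph_curve))
  }
  if (!num_pos(d$m_c)) fail("denitrifier.m_c", "must be > 0")
  if (!num_pos(d$y_c)) fail("denitrifier.y_c", "must be > 0")
  if (!num_pos(d$km_doc_denit)) fail("denitrifier.km_doc_denit", "must be > 0")
  if (!num_pos(d$q10)) fail("denitrifier.q10", "must be > 0")

  tr <- p$transport
  if (!num_nonneg(tr$fr_lower) || !num_pos(tr$fr_upper) ||
      tr$fr_lower >= tr$fr_upper || tr$fr_upper > 1)
    fail("transport.fr_lower/fr_upper", "need 0 <= fr_lower < fr_upper <= 1")
  for (f in c("escape_no", "escape_n2o", "escape_n2"))
    if (!num_nonneg(tr[[f]]) || tr[[f]] > 1)
      fail(paste0("transport.", f), "escape coefficient must lie in [0, 1]")
  for (f in c("legacy_k_nitr", "legacy_k_denit"))
    if (!num_nonneg(tr[[f]])) fail(paste0("transport.", f), "must be >= 0")

  s <- p$soil
  if (!num_pos(s$rho_s)) fail("soil.rho_s", "particle density must be > 0")
  for (f in c("doc_target", "doc_relax", "org_n_min_rate", "n_deposition"))
    if (!num_nonneg(s[[f]])) fail(paste0("soil.", f), "must be >= 0")
  for (f in c("recycle_fraction", "nitrifier_frac", "denitrifier_frac"))
    if (!num_nonneg(s[[f]]) || s[[f]] > 1) fail(paste0("soil.", f), "must lie in [0, 1]")

  for (id in names(p$ph_curves)) validate_ph_curve(p$ph_curves[[id]], id)
  invisible(p)
}

# --- dotted-path accessors (used by the config loader and the calibration
#     harness, e.g. "denitrifier.guilds.no3.gamma_gd") -----------------------

#' Get or set a parameter by dotted path
#'
#' @param p an \code{ngas_params} object.
#' @param name dotted path, e.g. \code{"nitrifier.gamma_gn"} or
#'   \code{"denitrifier.guilds.no3.gamma_gd"}.
#' @param value replacement value (for \code{param_set}).
#' @return \code{param_get}: the value. \code{param_set}: the modified,
#'   re-validated parameter set.
#' @export
param_get <- function(p, name) {
  path <- strsplit(name, ".", fixed = TRUE)[[1]]
  x <- p
  for (k in path) {
    if (is.null(x[[k]])) stop(sprintf("unknown parameter '%s'", name), call. = FALSE)
    x <- x[[k]]
  }
  x
}

#' @rdname param_get
#' @export
param_set <- function(p, name, value) {
  path <- strsplit(name, ".", fixed = TRUE)[[1]]
  param_get(p, name)  # existence check
  p[[path]] <- value
  validate_params(p)
  p
}

#' Enumerate the numeric leaves of a parameter set
#'
#' @param p an \code{ngas_params} object.
#' @return character vector of dotted paths to every scalar numeric
#'   parameter (pH curve coefficients excluded; see
#'   \code{\link{default_ph_curves}}).
#' @export
param_names <- function(p) {
  out <- character(0)
  walk <- function(x, prefix) {
    for (k in names(x)) {
      v <- x[[k]]
      key <- paste(c(prefix, k), collapse = ".")
      if (is.list(v)) walk(v, c(prefix, k))
      else if (is.numeric(v) && length(v) == 1) out <<- c(out, key)
    }
  }
  walk(p[c("nitrifier", "denitrifier", "transport", "soil")], character(0))
  out
}

# --- parameter file round-trip ---------------------------------------------

fmt_num <- function(x) {
  # full double precision so save/load round-trips bit-identically
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE),
         character(1))
}

#' Save and load parameter files
#'
#' Parameters are serialised as a flat, ordered \code{key: value} text
#' document (one canonical dialect; YAML-compatible scalars). Numeric
#' values are written with full double precision so that
#' \code{load_params_file(write_params_file(p))} reproduces \code{p}
#' bit-identically. pH curves are serialised as flattened coefficient /
#' knot vectors.
#'
#' @param p an \code{ngas_params} object.
#' @param path file path.
#' @return \code{write_params_file}: \code{path}, invisibly.
#'   \code{load_params_file}: the parameter set.
#' @export
write_params_file <- function(p, path) {
  lines <- character(0)
  for (nm in param_names(p)) {
    lines <- c(lines, sprintf("%s: %s", nm, fmt_num(param_get(p, nm))))
  }
  lines <- c(lines, sprintf("nitrifier.growth_substrate: %s",
                            p$nitrifier$growth_substrate))
  for (g in guild_order) {
    lines <- c(lines, sprintf("denitrifier.guilds.%s.ph_curve: %s",
                              g, p$denitrifier$guilds[[g]]$ph_curve))
  }
  for (id in names(p$ph_curves)) {
    cv <- p$ph_curves[[id]]
    vals <- if (cv$shape == "piecewise_linear") as.numeric(t(cv$knots)) else cv$coef
    lines <- c(lines, sprintf("ph_curve.%s.shape: %s", id, cv$shape),
               sprintf("ph_curve.%s.values: %s", id,
                       paste(fmt_num(vals), collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params_file
#' @export
load_params_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter file not found: %s", path),
                               call. = FALSE)
  kv <- read_flat_kv(path)
  p <- default_parameters()
  known_numeric <- param_names(p)
  for (nm in names(kv)) {
    v <- kv[[nm]]
    if (nm %in% known_numeric) {
      p <- param_set(p, nm, as.numeric(v))
    } else if (nm == "nitrifier.growth_substrate") {
      p$nitrifier$growth_substrate <- v
    } else if (grepl("^denitrifier\\.guilds\\.(no3|no2|no|n2o)\\.ph_curve$", nm)) {
      g <- strsplit(nm, ".", fixed = TRUE)[[1]][3]
      p$denitrifier$guilds[[g]]$ph_curve <- v
    } else if (grepl("^ph_curve\\.", nm)) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      id <- parts[2]; field <- parts[3]
      if (field == "shape") {
        p$ph_curves[[id]]$shape <- v
      } else if (field == "values") {
        vals <- as.numeric(strsplit(trimws(v), "\\s+")[[1]])
        if (p$ph_curves[[id]]$shape == "piecewise_linear") {
          p$ph_curves[[id]]$knots <- matrix(vals, ncol = 2, byrow = TRUE,
                                            dimnames = list(NULL, c("ph", "f")))
          p$ph_curves[[id]]$coef <- NULL
        } else {
          p$ph_curves[[id]]$coef <- vals
          p$ph_curves[[id]]$knots <- NULL
        }
      } else stop(sprintf("unknown key '%s' in %s", nm, path), call. = FALSE)
      p$ph_curves[[id]]$curve_id <- id
    } else {
      stop(sprintf("unknown key '%s' in %s", nm, path), call. = FALSE)
    }
  }
  validate_params(p)
  p
}

# flat "key: value" reader; preserves order, rejects duplicates
read_flat_kv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- regmatches(lines, regexec("^\\s*([^:]+?)\\s*:\\s*(.*?)\\s*$", lines))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad)) stop(sprintf("cannot parse line(s): %s",
                             paste(lines[bad], collapse = "; ")), call. = FALSE)
  keys <- vapply(m, `[`, character(1), 2)
  vals <- vapply(m, `[`, character(1), 3)
  if (anyDuplicated(keys))
    stop(sprintf("duplicate key(s): %s",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")),
         call. = FALSE)
  stats::setNames(as.list(vals), keys)
}

# --- run configuration ------------------------------------------------------

config_known_keys <- c(
  "forcing_file", "management_file", "params_file",
  "mode", "seed", "run_start", "run_end", "layer_thicknesses",
  "profile_file", "init_pools_file", "out_dir"
)

#' Load a simulation configuration
#'
#' Reads a flat \code{key: value} text file describing a run: file paths
#' for forcing, management and parameters, the run window, the simulation
#' mode and the random seed. Unspecified parameters take the calibrated
#' defaults; unknown keys are an error (fail fast rather than silently
#' ignore a typo). Recognised keys: \code{forcing_file},
#' \code{management_file}, \code{params_file}, \code{profile_file},
#' \code{init_pools_file}, \code{layer_thicknesses} (space-separated
#' metres), \code{mode} (\code{microbial} or \code{legacy}),
#' \code{seed}, \code{run_start}, \code{run_end} (ISO dates),
#' \code{out_dir}. Parameter overrides may be given inline with their
#' dotted names (e.g. \code{nitrifier.q10: 2.5}).
#'
#' @param path configuration file path.
#' @return An object of class \code{ngas_config}: a list with the fields
#'   above plus \code{params}, the fully-resolved \code{ngas_params}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  kv <- read_flat_kv(path)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(f) {
    if (is.null(f)) return(NULL)
    if (file.exists(f)) f else file.path(base_dir, f)
  }

  params <- default_parameters()
  if (!is.null(kv$params_file)) {
    pf <- resolve(kv$params_file)
    if (!file.exists(pf)) stop(sprintf("params_file not found: %s", kv$params_file),
                               call. = FALSE)
    params <- load_params_file(pf)
  }
  cfg_keys <- intersect(names(kv), config_known_keys)
  override_keys <- setdiff(names(kv), config_known_keys)
  known_numeric <- param_names(params)
  for (nm in override_keys) {
    if (nm %in% known_numeric) params <- param_set(params, nm, as.numeric(kv[[nm]]))
    else stop(sprintf("unknown key '%s' in %s", nm, path), call. = FALSE)
  }

  cfg <- structure(list(
    forcing_file = resolve(kv$forcing_file),
    management_file = resolve(kv$management_file),
    profile_file = resolve(kv$profile_file),
    init_pools_file = resolve(kv$init_pools_file),
    layer_thicknesses = if (!is.null(kv$layer_thicknesses))
      as.numeric(strsplit(trimws(kv$layer_thicknesses), "\\s+")[[1]]) else NULL,
    mode = if (!is.null(kv$mode)) kv$mode else "microbial",
    seed = if (!is.null(kv$seed)) as.integer(kv$seed) else 1L,
    run_start = if (!is.null(kv$run_start)) as.Date(kv$run_start) else NULL,
    run_end = if (!is.null(kv$run_end)) as.Date(kv$run_end) else NULL,
    out_dir = kv$out_dir,
    params = params
  ), class = "ngas_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!cfg$mode %in% c("microbial", "legacy"))
    stop(sprintf("invalid config `mode`: '%s' (microbial or legacy)", cfg$mode),
         call. = FALSE)
  if (!is.null(cfg$layer_thicknesses) && any(cfg$layer_thicknesses <= 0))
    stop("invalid config `layer_thicknesses`: all thicknesses must be > 0",
         call. = FALSE)
  if (!is.null(cfg$run_start) && !is.null(cfg$run_end) &&
      cfg$run_start > cfg$run_end)
    stop("invalid config `run_start`/`run_end`: start after end", call. = FALSE)
  for (f in c("forcing_file", "management_file", "profile_file", "init_pools_file"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop(sprintf("config `%s` does not resolve to a file: %s", f, cfg[[f]]),
           call. = FALSE)
  invisible(cfg)
}
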