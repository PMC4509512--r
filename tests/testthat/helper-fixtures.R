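# in-code fixtures shared across tests: a minimal uniform profile and
# constant forcing, so kinetics can be exercised with hand-settable state

tiny_profile <- function(n_lay = 1, thickness = rep(0.1, n_lay),
                         params = default_parameters(),
                         nh4 = 0, no3 = 0, doc = 0, m_b = 0, b_d = 0,
                         ph = 7, theta_sat = 0.6) {
  sp <- data.frame(depth_top = 0, depth_bot = sum(thickness),
                   rho_d = 1.53, ph = ph, theta_sat = theta_sat,
                   theta_wilt = 0.12)
  ip <- data.frame(depth_top = 0, depth_bot = sum(thickness))
  prof <- init_profile(thickness, sp, ip, params)
  n <- n_layers(prof)
  prof$nh4 <- rep(nh4, length.out = n)
  prof$no3 <- rep(no3, length.out = n)
  prof$doc <- rep(doc, length.out = n)
  prof$m_b <- rep(m_b, length.out = n)
  prof$b_d <- rep(b_d, length.out = n)
  prof
}

const_forcing <- function(profile, days, t_soil = 15, theta = 0.25,
                          start = "2000-03-01", uptake = 0, doc_input = 0) {
  nl <- n_layers(profile)
  forcing_series(
    dates = seq(as.Date(start), by = "day", length.out = days),
    t_soil = matrix(t_soil, days, nl),
    theta = matrix(theta, days, nl),
    uptake = rep(uptake, days),
    doc_input = rep(doc_input, days)
  )
}

# theta giving a requested WFPS for the tiny profile's bulk density
theta_for_wfps <- function(w, rho_d = 1.53, rho_s = 2.65) w * (1 - rho_d / rho_s)
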