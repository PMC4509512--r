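p_den <- default_parameters()$denitrifier

test_that("guild growth is the factor product with the calibrated maxima", {
  expect_equal(guild_growth("no3", 1, 1, 1, 1, 1, p_den), 13.65)
  expect_equal(guild_growth("n2o", 1, 1, 1, 1, 0.5, p_den), 8.81 * 0.5)
  expect_equal(guild_growth("no2", 0, 1, 1, 1, 1, p_den), 0)
  expect_error(guild_growth("n2o5", 1, 1, 1, 1, 1, p_den), "unknown")
  # chain-wide potential growth equals the summed maxima
  tot <- sum(vapply(names(p_den$guilds), function(g)
    guild_growth(g, 1, 1, 1, 1, 1, p_den), numeric(1)))
  expect_equal(tot, 38.57)
})

test_that("oxide consumption combines growth-linked and maintenance demand", {
  # maintenance term only, full competition weight
  expect_equal(oxide_consumption("no3", 0, 5, 5, 1, 1, 1, p_den), 2.16)
  # growth-linked term only (no oxide share -> zero maintenance weight)
  expect_equal(oxide_consumption("no3", 0.65, 0, 5, 1, 1, 1, p_den), 1.0)
  expect_equal(oxide_consumption("no2", 0, 0, 0, 1, 1, 1, p_den), 0)
  expect_error(oxide_consumption("no3", 0, 5, 3, 1, 1, 1, p_den), "n_total")
})

test_that("guild kinetics match independent evaluation at random factor draws", {
  set.seed(101)
  guilds <- names(p_den$guilds)
  for (i in 1:100) {
    g <- sample(guilds, 1)
    gp <- p_den$guilds[[g]]
    f <- stats::runif(4)           # doc, n, ph, t
    b_d <- stats::runif(1, 0, 3)
    n_i <- stats::runif(1, 0, 20)
    n_tot <- n_i + stats::runif(1, 0, 20)
    d_g <- guild_growth(g, f[1], f[2], f[3], f[4], b_d, p_den)
    expect_equal(d_g, gp$gamma_gd * f[1] * f[2] * f[3] * f[4] * b_d,
                 tolerance = 1e-10)
    d_c <- oxide_consumption(g, d_g, n_i, n_tot, f[4], f[3], b_d, p_den)
    expect_equal(d_c,
                 d_g / gp$y_n + gp$m_n * (n_i / n_tot) * f[4] * f[3] * b_d,
                 tolerance = 1e-10)
    ps <- denitrifier_pool_step(b_d, d_g, p_den)
    expect_equal(ps$d_dd, 0.0031 * 0.503 * b_d, tolerance = 1e-10)
    expect_equal(ps$r_c, d_g / 0.503 + 0.0031 * b_d, tolerance = 1e-10)
  }
})

test_that("denitrifier biomass bookkeeping follows the printed constants", {
  ps <- denitrifier_pool_step(1, 0, p_den)
  expect_equal(ps$d_dd, 0.0031 * 0.503)
  expect_equal(ps$r_c, 0.0031)
  expect_equal(ps$b_d_new, 1 - 0.0031 * 0.503)
  ps0 <- denitrifier_pool_step(0, 0, p_den)
  expect_equal(unlist(ps0), c(b_d_new = 0, d_dd = 0, r_c = 0))
})

test_that("a nitrate-only chain day matches a sequential hand computation", {
  curves <- default_ph_curves()
  th <- 0.1
  no3_conc <- 10                       # gN m^-3
  b_d <- 0.05                          # gC m^-2 -> 0.5 gC m^-3
  f_doc <- 0.4; f_t <- 0.8; ph <- 6.5
  chain <- reduction_chain_step(
    pools = list(no3 = no3_conc * th, no2 = 0, no = 0, n2o = 0),
    thickness = th, f_doc = f_doc, f_t = f_t, ph = ph, b_d = b_d,
    p = p_den, ph_curves = curves)

  # independent sequential computation of the same day
  bd_c <- b_d / th
  cons <- numeric(4); names(cons) <- c("no3", "no2", "no", "n2o")
  conc0 <- c(no3 = no3_conc, no2 = 0, no = 0, n2o = 0)
  n_total <- sum(conc0)
  inflow <- 0
  for (g in names(cons)) {
    gp <- p_den$guilds[[g]]
    f_ph <- ph_response(ph, gp$ph_curve, curves)
    f_n <- conc0[[g]] / (gp$km_n + conc0[[g]])
    d_g <- gp$gamma_gd * f_doc * f_n * f_ph * f_t * bd_c
    d_c <- d_g / gp$y_n + gp$m_n * (conc0[[g]] / n_total) * f_t * f_ph * bd_c
    cons[g] <- min(d_c * th, conc0[[g]] * th + inflow)
    inflow <- cons[g]
  }
  expect_equal(unlist(chain$consumption), cons, tolerance = 1e-12)
  expect_equal(chain$n2, cons[["n2o"]], tolerance = 1e-12)
})

test_that("the reduction chain conserves N exactly and never goes negative", {
  set.seed(202)
  for (i in 1:20) {
    th <- stats::runif(2, 0.02, 0.3)
    pools <- list(no3 = stats::runif(2, 0, 5), no2 = stats::runif(2, 0, 1),
                  no = stats::runif(2, 0, 0.5), n2o = stats::runif(2, 0, 0.5))
    chain <- reduction_chain_step(pools, th, f_doc = stats::runif(1),
                                  f_t = stats::runif(1, 0.2, 2),
                                  ph = stats::runif(2, 4, 8),
                                  b_d = stats::runif(2, 0, 1), p = p_den)
    total_before <- Reduce(`+`, pools)
    total_after <- Reduce(`+`, chain$pools_new)
    expect_equal(total_before - total_after, chain$n2, tolerance = 1e-12)
    for (ox in names(chain$pools_new))
      expect_true(all(chain$pools_new[[ox]] >= 0))
    expect_equal(chain$d_dg, Reduce(`+`, chain$d_g))
  }
})

test_that("zero biomass yields zero chain activity", {
  chain <- reduction_chain_step(list(no3 = 1, no2 = 1, no = 1, n2o = 1),
                                0.1, 0.5, 1, 7, b_d = 0, p = p_den)
  expect_equal(chain$n2, 0)
  expect_equal(unlist(chain$deltas), c(no3 = 0, no2 = 0, no = 0, n2o = 0))
})

test_that("more available carbon never slows total denitrification throughput", {
  set.seed(303)
  for (i in 1:15) {
    pools <- list(no3 = stats::runif(1, 0, 3), no2 = stats::runif(1, 0, 1),
                  no = stats::runif(1, 0, 0.5), n2o = stats::runif(1, 0, 0.5))
    f_t <- stats::runif(1, 0.3, 1.5)
    ph <- stats::runif(1, 4, 8)
    b_d <- stats::runif(1, 0, 0.5)
    f_docs <- sort(stats::runif(2))
    through <- vapply(f_docs, function(fd) {
      ch <- reduction_chain_step(pools, 0.1, fd, f_t, ph, b_d, p_den)
      sum(unlist(ch$consumption))
    }, numeric(1))
    expect_gte(through[2], through[1] - 1e-12)
  }
})
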