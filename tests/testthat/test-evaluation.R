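test_that("the statistic suite hits its analytic fixed points", {
  s <- evaluate_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s$rmse, 0)
  expect_equal(s$ef, 1)
  expect_equal(s$r, 1)
  expect_equal(s$md, 0)
  expect_equal(s$me, 0)
  # predicting the observed mean everywhere gives EF = 0 by construction
  s0 <- evaluate_fit(c(1, 2, 3), c(2, 2, 2))
  expect_equal(s0$ef, 0)
  # constant-shift example; negative MD = over-estimation
  s1 <- evaluate_fit(c(1, 2, 3), c(2, 3, 4))
  expect_equal(s1$md, -1)
  expect_equal(s1$me, 1)
  expect_equal(s1$rmse, 50)   # 100/2 * sqrt(3/3)
  expect_error(evaluate_fit(1, 1), "at least 2")
  expect_error(evaluate_fit(1:3, 1:2), "length")
})

test_that("all seven statistics match a brute-force recomputation", {
  set.seed(500)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    o <- stats::rnorm(n, 10, 4)
    o[sample(n, 1)] <- 0            # exercise the zero-observation exclusion
    s_mod <- o + stats::rnorm(n, 0, 2)
    ci <- abs(stats::rnorm(n, 2, 0.5))
    st <- evaluate_fit(o, s_mod, ci)

    obar <- sum(o) / n
    sse <- 0; sso <- 0; ssp <- 0
    for (k in seq_len(n)) {
      sse <- sse + (s_mod[k] - o[k])^2
      sso <- sso + (o[k] - obar)^2
      ssp <- ssp + (s_mod[k] - obar)^2
    }
    d <- o - s_mod
    nz <- which(o != 0)
    expect_equal(st$r, stats::cor(o, s_mod), tolerance = 1e-10)
    expect_equal(st$rmse, 100 / obar * sqrt(sse / n), tolerance = 1e-10)
    expect_equal(st$ef, 1 - sse / sso, tolerance = 1e-10)
    expect_equal(st$cd, sso / ssp, tolerance = 1e-10)
    expect_equal(st$re, 100 / length(nz) * sum(d[nz] / o[nz]), tolerance = 1e-10)
    expect_equal(st$md, sum(d) / n, tolerance = 1e-10)
    expect_equal(st$t_md, (sum(d) / n) / (stats::sd(d) / sqrt(n)),
                 tolerance = 1e-10)
    expect_equal(st$me, max(abs(d)), tolerance = 1e-10)
    expect_equal(st$rmse95, 100 / obar * sqrt(sum(ci^2) / n), tolerance = 1e-10)
    expect_equal(st$re95, 100 / length(nz) * sum(ci[nz] / o[nz]),
                 tolerance = 1e-10)
    expect_equal(st$re_n_excluded, n - length(nz))
    expect_lte(st$ef, 1)
  }
})

test_that("EF is negative exactly when the model is worse than the observed mean", {
  o <- c(1, 2, 3, 4)
  worse <- c(4, 1, 5, 0)   # sse 18 > sso 5
  better <- c(1.2, 2.1, 2.9, 4.1)
  expect_lt(evaluate_fit(o, worse)$ef, 0)
  expect_gt(evaluate_fit(o, better)$ef, 0)
})

test_that("emission factors follow the excess-over-control definition", {
  expect_equal(emission_factor(1.0, 1.0, 10), 0)
  expect_equal(emission_factor(2.0, 1.0, 10), 10)
  expect_equal(emission_factor(1.1, 1.0, 10), 1)   # the IPCC default magnitude
  expect_equal(emission_factor(0.5, 1.0, 10), -5)  # negative is reported as-is
  expect_error(emission_factor(1, 1, 0), "n_applied")
})

test_that("the DE optimizer is seeded, bounded and respects a zero budget", {
  sphere <- function(x) sum((x - c(2, -1))^2)
  f1 <- de_optimize(sphere, c(-5, -5), c(5, 5), n_gen = 40, seed = 3)
  f2 <- de_optimize(sphere, c(-5, -5), c(5, 5), n_gen = 40, seed = 3)
  expect_identical(f1$trace, f2$trace)
  expect_equal(f1$par, c(2, -1), tolerance = 1e-3)
  expect_true(all(diff(f1$trace$best) <= 0))
  f0 <- de_optimize(sphere, c(-5, -5), c(5, 5), init = c(0, 0), n_gen = 0)
  expect_equal(f0$par, c(0, 0))
  expect_equal(nrow(f0$trace), 0)
})

test_that("a zero-budget calibration returns the initial parameter set unchanged", {
  prof <- tiny_profile(no3 = 2, doc = 1, b_d = 0.02)
  f <- const_forcing(prof, 5, theta = theta_for_wfps(0.8))
  params <- default_parameters()
  fit <- calibrate(prof, f, params = params,
                   observed = rep(0.01, 5),
                   parameters = "denitrifier.guilds.no3.gamma_gd",
                   lower = 1, upper = 30, n_gen = 0)
  expect_identical(fit$params, params)
})
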