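test_that("parameter validation enforces positivity and t_l <= T", {
  expect_error(model_params(alpha = -1), "alpha")
  expect_error(model_params(tau = 0), "tau")
  expect_error(model_params(t_l = 5, T = 4), "t_l")
  expect_error(season_state(-1, 0), "s_hat")
  expect_error(update_params(model_params(), bogus = 1), "bogus")
  p <- update_params(model_params(), mu = 0.4)
  expect_equal(p$mu, 0.4)
  expect_equal(p$alpha, 3.5e-7)
})

test_that("emergence kernel is uniform on [0, t_l] and integrates to one", {
  p <- model_params(T = 4, t_l = 1)
  expect_equal(emergence_rate(0.5, p), 1)
  expect_equal(emergence_rate(1.5, p), 0)
  expect_equal(emergence_rate(c(0, 1, 1.0001, 4), p), c(1, 1, 0, 0))
  total <- integrate(function(t) emergence_rate(t, p), 0, p$T)$value
  expect_equal(total, 1, tolerance = 1e-8)
  p2 <- model_params(T = 6, t_l = 2.5)
  expect_equal(emergence_rate(1, p2), 1 / 2.5)
  expect_equal(integrate(function(t) emergence_rate(t, p2), 0, 6)$value, 1,
               tolerance = 1e-8)
  expect_error(emergence_rate(-0.1, p), "within the season")
  expect_error(emergence_rate(4.5, p), "within the season")
})

test_that("parasite-free season matches the closed-form survivor curve", {
  p <- model_params(tau = 2.8)
  traj <- within_season(p, season_state(1e4, 0))
  expect_true(all(traj$v1 == 0))
  expect_true(all(traj$v2 == 0))
  closed <- function(t) {
    u <- pmin(t, p$t_l)
    1e4 / p$t_l * (exp(-p$mu * (t - u)) - exp(-p$mu * t)) / p$mu
  }
  idx <- traj$t > 0
  expect_equal(traj$s[idx], closed(traj$t[idx]), tolerance = 1e-8)
})

test_that("v1 follows pure exponential decay and v2 is zero before tau", {
  p <- model_params(tau = 2.8)
  st <- season_state(1e4, 1e4)
  traj <- within_season(p, st)
  expect_equal(traj$v1, st$v_hat * exp(-p$delta * traj$t), tolerance = 1e-12)
  expect_true(all(traj$v2[traj$t <= p$tau] == 0))
  expect_true(all(traj$s >= 0), all(traj$v2 >= 0))
})

test_that("negligible transmission reproduces the no-infection closed form", {
  p <- model_params(alpha = 1e-30, tau = 2.8)
  st <- season_state(1e4, 1e4)
  eos <- end_of_season(p, st)
  expect_equal(eos$v2_T, 0, tolerance = 1e-15)
  closed <- 1e4 * (exp(-p$mu * (p$T - p$t_l)) - exp(-p$mu * p$T)) /
    (p$mu * p$t_l)
  expect_equal(eos$s_T, closed, tolerance = 1e-9)
})

test_that("reference-scenario season agrees with the delay-ODE oracle", {
  p <- model_params(tau = 2.8, T = 4, t_l = 1)
  st <- season_state(1e4, 1e4)
  eos <- end_of_season(p, st)
  orc <- oracle_within_season(p, st)
  n <- nrow(orc)
  expect_equal(eos$s_T, orc$s[n], tolerance = 1e-6)
  expect_equal(eos$v2_T, orc$v2[n], tolerance = 1e-6)
})

test_that("synchronous emergence (t_l = 0) is an exact code path", {
  p <- model_params(tau = 2.2, T = 4, t_l = 0)
  st <- season_state(5e3, 2e3)
  traj <- within_season(p, st)
  expect_equal(traj$s[1], 5e3)  # whole cohort present at t = 0+
  orc <- oracle_within_season(p, st)
  n <- nrow(orc)
  expect_equal(end_of_season(p, st)$s_T, orc$s[n], tolerance = 1e-6)
  expect_equal(end_of_season(p, st)$v2_T, orc$v2[n], tolerance = 1e-6)
})

test_that("no progeny are released when the delay reaches past season end", {
  p <- model_params(tau = 5, T = 4)
  eos <- end_of_season(p, season_state(1e4, 1e4))
  expect_identical(eos$v2_T, 0)
  # and v2(T) is continuous as tau crosses T from below
  near <- end_of_season(update_params(p, tau = 3.999),
                        season_state(1e4, 1e4))
  expect_lt(near$v2_T, 1)
})

test_that("hosts are conserved without parasites in the low-mortality limit", {
  p <- model_params(mu = 1e-10, tau = 2.8)
  eos <- end_of_season(p, season_state(1e4, 0))
  expect_equal(eos$s_T, 1e4, tolerance = 1e-8)
})

test_that("progeny output decreases with host mortality and parasite decay", {
  st <- season_state(1e4, 1e4)
  v2_at <- function(...) end_of_season(update_params(model_params(), ...), st)$v2_T
  mus <- c(0.1, 0.25, 0.5, 1)
  expect_true(all(diff(vapply(mus, function(m) v2_at(mu = m), 0)) < 0))
  deltas <- c(1, 2, 3, 5)
  expect_true(all(diff(vapply(deltas, function(d) v2_at(delta = d), 0)) < 0))
})

test_that("the season map saturates at sigma/rho and absorbs extinction", {
  p <- model_params(tau = 5)  # no progeny: v2(T) = 0
  st <- season_map(p, season_state(0, 0))
  expect_identical(st$s_hat, 0)
  # push an enormous cohort through: recruitment approaches sigma / rho
  big <- season_map(model_params(mu = 1e-8, tau = 5), season_state(1e12, 0))
  expect_equal(big$s_hat, p$sigma / p$rho, tolerance = 1e-3)
})

test_that("repeated parasite-free mapping finds the analytic fixed point", {
  p <- model_params(tau = 2.8)
  s <- 1e4
  for (i in 1:400) s <- season_map(p, season_state(s, 0))$s_hat
  expect_equal(s, parasite_free_equilibrium(p), tolerance = 1e-8)
  # closed form really is a fixed point
  sf <- parasite_free_equilibrium(p)
  expect_equal(season_map(p, season_state(sf, 0))$s_hat, sf,
               tolerance = 1e-10)
})
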