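test_that("a single strain reduces exactly to the single-strain season", {
  p <- model_params(tau = 2.8)
  st <- data.frame(alpha = p$alpha, beta = p$beta, delta = p$delta,
                   tau = p$tau, v_hat = 1e4)
  multi <- within_season_multistrain(p, 1e4, st)
  eos <- end_of_season(p, season_state(1e4, 1e4))
  expect_equal(multi$s_T, eos$s_T, tolerance = 1e-10)
  expect_equal(multi$v2_T[1], eos$v2_T, tolerance = 1e-10)
})

test_that("identical strains superpose: progeny split linearly", {
  p <- model_params(tau = 2.8)
  one <- data.frame(alpha = p$alpha, beta = p$beta, delta = p$delta,
                    tau = p$tau, v_hat = 1e4)
  two <- data.frame(alpha = p$alpha, beta = p$beta, delta = p$delta,
                    tau = c(p$tau, p$tau), v_hat = c(3e3, 7e3))
  r1 <- within_season_multistrain(p, 1e4, one)
  r2 <- within_season_multistrain(p, 1e4, two)
  expect_equal(sum(r2$v2_T), r1$v2_T[1], tolerance = 1e-10)
  expect_equal(r2$s_T, r1$s_T, tolerance = 1e-10)
  # and the split is proportional to the initial shares
  expect_equal(r2$v2_T[1] / r2$v2_T[2], 3 / 7, tolerance = 1e-10)
})

test_that("a neutral mutant in the resident equilibrium has unit growth", {
  p <- model_params(tau = 3.5)
  env <- map_fixed_point(p)
  st <- data.frame(alpha = p$alpha, beta = p$beta, delta = p$delta,
                   tau = c(p$tau, p$tau), v_hat = c(env$v_hat, 1))
  out <- within_season_multistrain(p, env$s_hat, st)
  expect_equal(out$v2_T[2], 1, tolerance = 1e-3)
  # quadrature route agrees
  expect_equal(invasion_fitness(env, strain_traits(p), p), 1,
               tolerance = 1e-3)
})

test_that("neutrality holds across phenological scenarios", {
  # unit invasion fitness of a resident-identical mutant is the sharpest
  # check that the located environment really is the coexistence fixed
  # point (and not, e.g., the disease-free state)
  cases <- list(c(T = 4, t_l = 1, tau = 3.5), c(T = 4, t_l = 0.5, tau = 3.4),
                c(T = 5, t_l = 2, tau = 3.5), c(T = 6, t_l = 1, tau = 4.5),
                c(T = 4, t_l = 3, tau = 2.6))
  for (cs in cases) {
    p <- model_params(T = cs[["T"]], t_l = cs[["t_l"]], tau = cs[["tau"]])
    env <- map_fixed_point(p)
    expect_gt(env$v_hat, 1)
    expect_equal(invasion_fitness(env, strain_traits(p), p,
                                  check_equilibrium = FALSE), 1,
                 tolerance = 1e-3,
                 label = sprintf("neutral fitness at T=%g t_l=%g tau=%g",
                                 cs[["T"]], cs[["t_l"]], cs[["tau"]]))
  }
})

test_that("closed-form invasion fitness matches the two-strain simulator", {
  p <- model_params(tau = 3.5)
  env <- map_fixed_point(p)
  for (tm in c(2.2, 2.7, 2.99, 3.0, 3.01, 3.3, 3.7, 3.95)) {
    Wq <- invasion_fitness(env, strain_traits(p, tau_m = tm), p)
    st <- data.frame(alpha = p$alpha, beta = p$beta, delta = p$delta,
                     tau = c(p$tau, tm), v_hat = c(env$v_hat, 1))
    Ws <- within_season_multistrain(p, env$s_hat, st)$v2_T[2]
    expect_equal(Wq, Ws, tolerance = 1e-3,
                 label = sprintf("v2m(T) at tau_m = %.2f", tm))
  }
})

test_that("invasion fitness is continuous at the regime boundary T - t_l", {
  p <- model_params(tau = 3.5, T = 4, t_l = 1)
  env <- map_fixed_point(p)
  edge <- p$T - p$t_l
  eps <- 1e-7
  left <- invasion_fitness(env, strain_traits(p, tau_m = edge - eps), p)
  right <- invasion_fitness(env, strain_traits(p, tau_m = edge + eps), p)
  expect_equal(left, right, tolerance = 1e-4)
})

test_that("mutants that cannot kill within the season have zero fitness", {
  p <- model_params(tau = 3.5)
  env <- map_fixed_point(p)
  expect_identical(invasion_fitness(env, strain_traits(p, tau_m = 4.5), p), 0)
})

test_that("a cycling-regime environment is refused with a clear error", {
  p <- model_params(tau = 3.5)
  expect_error(
    invasion_fitness(season_state(1e4, 1e4), strain_traits(p), p),
    "cycling regime; use simulation")
})

test_that("selection pushes tau toward the optimum from both sides", {
  p <- model_params()
  expect_gt(selection_gradient(update_params(p, tau = 2.5)), 0)
  expect_lt(selection_gradient(update_params(p, tau = 3.4)), 0)
})

test_that("the ESS lies inside the cycling window and is a maximum", {
  ts <- ess_tau(model_params())
  expect_gt(ts, 2.75)
  expect_lt(ts, 3.26)
  # local concavity of the fitness profile around tau*
  p <- update_params(model_params(), tau = ts)
  env <- map_fixed_point(p)
  W <- vapply(c(ts - 0.05, ts, ts + 0.05), function(tm)
    invasion_fitness(env, strain_traits(p, tau_m = tm), p,
                     check_equilibrium = FALSE), 0)
  expect_lt(W[1] + W[3] - 2 * W[2], 0)
})

test_that("more synchronous emergence selects for later host death", {
  p <- model_params()
  ts_sync <- ess_tau(update_params(p, t_l = 0.5))
  ts_ref <- ess_tau(p)
  ts_spread <- ess_tau(update_params(p, t_l = 2.5))
  expect_gt(ts_sync, ts_ref)
  expect_gt(ts_ref, ts_spread)
})

test_that("no interior ESS is reported as an explicit error", {
  # a parasite this unproductive cannot persist for any tau: the gradient
  # is undefined everywhere and no interior optimum exists
  p <- model_params(beta = 2, delta = 5)
  expect_error(ess_tau(p), "no interior ESS")
})

test_that("the constant-cohort equilibrium balances the parasite map", {
  p <- model_params(tau = 3.0)
  cohort <- parasite_free_equilibrium(p)
  env <- control_equilibrium(p, cohort)
  st <- data.frame(alpha = p$alpha, beta = p$beta, delta = p$delta,
                   tau = p$tau, v_hat = env$v_hat)
  out <- within_season_multistrain(p, cohort, st)
  expect_equal(out$v2_T[1], env$v_hat, tolerance = 1e-8)
})
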