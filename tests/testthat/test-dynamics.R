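make_series <- function(s, v) {
  out <- tibble::tibble(season = seq_along(s) - 1L, s_hat = s, v_hat = v)
  class(out) <- c("season_series", class(out))
  attr(out, "params") <- model_params()
  out
}

test_that("period and lag estimators recover a known synthetic cycle", {
  n <- 0:140
  s <- 1e4 + 1e3 * cos(2 * pi * n / 10)          # host peaks at 0, 10, ...
  v <- 1e5 + 1e4 * cos(2 * pi * (n - 3) / 10)    # parasite peaks 3 later
  cls <- classify_dynamics(make_series(s, v), burn_in = 20, window = 100)
  expect_identical(cls$label, "cycling")
  expect_equal(cls$period_estimate, 10, tolerance = 0.01)
  expect_equal(cls$host_parasite_peak_lag, 3, tolerance = 0.01)
})

test_that("constant and extinct windows classify as stated", {
  cls <- classify_dynamics(make_series(rep(1e4, 121), rep(5e7, 121)),
                           burn_in = 10, window = 100)
  expect_identical(cls$label, "endemic_equilibrium")
  expect_identical(cls$relative_amplitude, 0)
  cls0 <- classify_dynamics(make_series(rep(1e4, 121), rep(0, 121)),
                            burn_in = 10, window = 100)
  expect_identical(cls0$label, "parasite_free")
  expect_error(
    classify_dynamics(make_series(rep(1, 50), rep(1, 50)),
                      burn_in = 40, window = 100),
    "exceeds")
})

test_that("without parasites the iteration settles on the analytic cohort", {
  p <- model_params(tau = 2.8)
  ser <- iterate_seasons(p, initial = season_state(1e4, 0), n = 300)
  expect_true(all(ser$v_hat == 0))
  expect_equal(ser$s_hat[301], parasite_free_equilibrium(p),
               tolerance = 1e-6)
})

test_that("sub-unity parasite densities go extinct and stay extinct", {
  p <- model_params(tau = 3.9)  # barely any progeny released
  ser <- iterate_seasons(p, initial = season_state(1e4, 1e2), n = 100)
  expect_true(any(ser$v_hat == 0))
  first0 <- min(ser$season[ser$v_hat == 0])
  expect_true(all(ser$v_hat[ser$season >= first0] == 0))
})

test_that("reference virulence phenotypes cycle or equilibrate as expected", {
  p <- model_params(T = 4, t_l = 1)
  ser_cyc <- iterate_seasons(update_params(p, tau = 2.8), n = 1700)
  cls <- classify_dynamics(ser_cyc)
  expect_identical(cls$label, "cycling")
  # quasiperiodic: densities do not repeat on the attractor
  win <- ser_cyc$v_hat[ser_cyc$season > 800 & ser_cyc$season <= 900]
  expect_identical(anyDuplicated(win), 0L)
  # label is invariant to doubling the burn-in
  expect_identical(classify_dynamics(ser_cyc, burn_in = 1600)$label, "cycling")
  ser_eq <- iterate_seasons(update_params(p, tau = 3.5), n = 900)
  expect_identical(classify_dynamics(ser_eq)$label, "endemic_equilibrium")
})

test_that("classification is insensitive to the initial condition", {
  # any inoculum that establishes leads to the same attractor: vary host
  # cohort and parasite load over an order of magnitude above the default
  p <- update_params(model_params(), tau = 2.9)
  inits <- list(season_state(1e4, 1e2), season_state(3e4, 1e2),
                season_state(1e5, 1e3), season_state(1e4, 1e3))
  labs <- vapply(inits, function(init) {
    classify_dynamics(iterate_seasons(p, initial = init, n = 900))$label
  }, "")
  expect_true(all(labs == "cycling"))
  # too small an inoculum fails to establish: absolute-count extinction
  tiny <- iterate_seasons(p, initial = season_state(1e4, 30), n = 200)
  expect_identical(classify_dynamics(tiny, 100, 100)$label, "parasite_free")
})

test_that("the map fixed point satisfies the map and flags stability", {
  p <- model_params(tau = 3.5)
  fp <- map_fixed_point(p)
  nxt <- season_map(p, fp)
  expect_equal(nxt$s_hat, fp$s_hat, tolerance = 1e-7)
  expect_equal(nxt$v_hat, fp$v_hat, tolerance = 1e-7)
  st <- map_jacobian_stability(p, fp)
  expect_true(st$stable)
  expect_length(st$eigenvalues, 2L)
  # unstable focus inside the cycling window, complex eigenvalue pair
  p2 <- model_params(tau = 3.0)
  st2 <- map_jacobian_stability(p2, map_fixed_point(p2))
  expect_false(st2$stable)
  expect_true(all(Im(st2$eigenvalues) != 0))
  expect_error(map_jacobian_stability(p, season_state(1e4, 1e4)),
               "not a fixed point")
})

test_that("eigenvalue modulus crosses one at the cycling window edges", {
  p <- model_params()
  mod_at <- function(tau) {
    q <- update_params(p, tau = tau)
    map_jacobian_stability(q, map_fixed_point(q))$spectral_radius
  }
  # brackets the crossing within +/- 0.045 of the amplitude-based edges
  expect_lt(mod_at(2.73), 1)
  expect_gt(mod_at(2.82), 1)
  expect_gt(mod_at(3.23), 1)
  expect_lt(mod_at(3.32), 1)
})

test_that("the disease-free state is invadable by a fit parasite", {
  p <- model_params(tau = 3.0)
  sf <- parasite_free_equilibrium(p)
  st <- map_jacobian_stability(p, season_state(sf, 0))
  expect_gt(st$spectral_radius, 1)
})

test_that("a coarse bifurcation scan brackets the cycling window", {
  p <- model_params()
  scan <- bifurcation_scan(p, tau_grid = seq(2.6, 3.4, by = 0.1),
                           burn_in = 600, window = 100)
  edges <- bifurcation_edges(scan)
  expect_gt(edges$n_cycling, 0)
  expect_true(edges$tau_lower > 2.6 && edges$tau_lower < 2.9)
  expect_true(edges$tau_upper > 3.1 && edges$tau_upper < 3.4)
  # window densities at a stable tau collapse to a point
  stab <- dplyr::filter(scan, tau == 2.6)
  expect_lt(diff(range(stab$v_hat)) / mean(stab$v_hat), 1e-3)
})

test_that("phase diagram: short synchronous seasons cycle, long seasons do not", {
  p <- model_params()
  pb <- phase_boundary(c(4, 8), 1, p, burn_in = 600, window = 100)
  expect_identical(pb$label[pb$T == 4], "cycling")
  expect_identical(pb$label[pb$T == 8], "endemic_equilibrium")
  expect_true(all(is.finite(pb$tau_star)))
})
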