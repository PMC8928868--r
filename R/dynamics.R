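#' Iterate the seasonal map over many seasons
#'
#' Applies the between-season map repeatedly, recording the emerging host
#' cohort `s_hat(n)` and season-start parasite density `v_hat(n)` for each
#' season. Parasite densities are absolute counts: whenever `v_hat` falls
#' below `extinction_threshold` (one parasite, by default) the parasite is
#' considered extinct and held at zero thereafter.
#'
#' @param params A [model_params()] object.
#' @param initial A [season_state()]; defaults to `s_hat = 1e4`,
#'   `v_hat = 1e2`.
#' @param n Number of seasons to iterate (`n >= 1`).
#' @param extinction_threshold Density below which the parasite is extinct.
#' @param constant_cohort If `TRUE`, host demographic feedback is switched
#'   off: every season's emerging cohort is reset to `initial$s_hat`
#'   regardless of how many hosts reproduced. Used as the non-cycling
#'   control in evolution experiments.
#' @return A tibble of class `season_series` with columns `season` (0-based),
#'   `s_hat`, `v_hat`, carrying `params` and `initial` as attributes.
#' @examples
#' ser <- iterate_seasons(model_params(tau = 3.5), n = 200)
#' tail(ser, 3)
#' @export
iterate_seasons <- function(params, initial = season_state(1e4, 1e2), n,
                            extinction_threshold = 1,
                            constant_cohort = FALSE) {
  stopifnot(inherits(params, "model_params"), n >= 1)
  traits <- list(alpha = params$alpha, beta = params$beta,
                 delta = params$delta, tau = params$tau)
  s_hat <- numeric(n + 1L)
  v_hat <- numeric(n + 1L)
  s_hat[1L] <- initial$s_hat
  v_hat[1L] <- if (initial$v_hat < extinction_threshold) 0 else initial$v_hat
  for (i in seq_len(n)) {
    sol <- tryCatch(
      season_solve(s_hat[i], v_hat[i], traits, params$mu, params$T, params$t_l),
      error = function(e) {
        stop("season ", i, ": ", conditionMessage(e), call. = FALSE)
      }
    )
    s_hat[i + 1L] <- if (constant_cohort) initial$s_hat else
      params$sigma * sol$s_T / (1 + params$rho * sol$s_T)
    v <- sol$v2_T[1L]
    v_hat[i + 1L] <- if (v < extinction_threshold) 0 else v
  }
  out <- tibble::tibble(season = 0:n, s_hat = s_hat, v_hat = v_hat)
  class(out) <- c("season_series", class(out))
  attr(out, "params") <- params
  attr(out, "initial") <- initial
  attr(out, "constant_cohort") <- constant_cohort
  out
}

# indices of discrete local maxima; plateaus take the first index
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i < n) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) idx <- c(idx, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx
}

#' Classify the long-run dynamics of a seasonal series
#'
#' Looks at the post-burn-in window of a [iterate_seasons()] series and
#' labels the attractor:
#' * `parasite_free` — the parasite is extinct throughout the window;
#' * `endemic_equilibrium` — the parasite persists and the relative
#'   amplitude of `v_hat`, `(max - min) / mean`, is at or below
#'   `amplitude_threshold`;
#' * `cycling` — relative amplitude above the threshold (quasiperiodic
#'   parasite-host cycles).
#'
#' For cycling series the cycle period is estimated as the mean spacing of
#' local maxima of the host series, and the host-to-parasite peak lag as the
#' mean offset (modulo the period) from each host peak to the next parasite
#' peak.
#'
#' @param series A `season_series` tibble from [iterate_seasons()].
#' @param burn_in Seasons discarded as transient.
#' @param window Number of seasons examined after the burn-in.
#' @param amplitude_threshold Relative-amplitude cut separating numerical
#'   ringing from genuine cycling.
#' @return A list of class `dynamics_class` with fields `label`,
#'   `relative_amplitude`, `period_estimate`, `host_parasite_peak_lag`.
#' @examples
#' ser <- iterate_seasons(model_params(tau = 2.8), n = 900)
#' classify_dynamics(ser)
#' @export
classify_dynamics <- function(series, burn_in = 800, window = 100,
                              amplitude_threshold = 1e-3) {
  stopifnot(inherits(series, "season_series"))
  n_seasons <- max(series$season)
  if (burn_in + window > n_seasons) {
    stop("burn_in + window exceeds the number of simulated seasons",
         call. = FALSE)
  }
  idx <- which(series$season > burn_in & series$season <= burn_in + window)
  v <- series$v_hat[idx]
  s <- series$s_hat[idx]
  res <- structure(
    list(label = NA_character_, relative_amplitude = NA_real_,
         period_estimate = NA_real_, host_parasite_peak_lag = NA_real_),
    class = "dynamics_class"
  )
  if (all(v <= 0)) {
    res$label <- "parasite_free"
    res$relative_amplitude <- 0
    return(res)
  }
  if (mean(v) == 0) stop("classification window has zero mean parasite density",
                         call. = FALSE)
  amp <- (max(v) - min(v)) / mean(v)
  res$relative_amplitude <- amp
  if (amp <= amplitude_threshold) {
    res$label <- "endemic_equilibrium"
    return(res)
  }
  res$label <- "cycling"
  sp <- local_maxima(s)
  vp <- local_maxima(v)
  if (length(sp) >= 2L) {
    res$period_estimate <- mean(diff(sp))
    if (length(vp) >= 1L) {
      lags <- vapply(sp, function(i) {
        nxt <- vp[vp >= i]
        if (length(nxt)) nxt[1L] - i else NA_real_
      }, 0)
      lags <- lags[!is.na(lags)] %% res$period_estimate
      if (length(lags)) res$host_parasite_peak_lag <- mean(lags)
    }
  }
  res
}

#' @export
print.dynamics_class <- function(x, ...) {
  cat("<dynamics_class>", x$label,
      sprintf("(relative amplitude %.3g", x$relative_amplitude))
  if (x$label == "cycling") {
    cat(sprintf(", period %.2f seasons, host-to-parasite peak lag %.2f seasons",
                x$period_estimate, x$host_parasite_peak_lag))
  }
  cat(")\n")
  invisible(x)
}

#' @export
tidy.dynamics_class <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    relative_amplitude = x$relative_amplitude,
    period_estimate = x$period_estimate,
    host_parasite_peak_lag = x$host_parasite_peak_lag
  )
}

#' Bifurcation scan over the virulence trait
#'
#' For each incubation delay `tau` on a grid, iterates the seasonal map to
#' its attractor and records the end-of-season parasite densities over the
#' classification window, together with the attractor label. The sweep of
#' window densities against `tau` is the numerical bifurcation diagram of
#' the model; cycling shows up as a band of non-repeating densities.
#'
#' @param params A [model_params()] object (its own `tau` is ignored).
#' @param tau_grid Strictly positive grid of `tau` values.
#' @param burn_in,window,amplitude_threshold Passed to [classify_dynamics()].
#' @param initial Initial [season_state()].
#' @return A tibble of class `bifurcation_scan` with one row per
#'   `(tau, season)` pair in the window: columns `tau`, `season`, `v_hat`,
#'   `label`, `relative_amplitude`.
#' @examples
#' \donttest{
#' scan <- bifurcation_scan(model_params(), tau_grid = seq(2.6, 3.4, 0.1),
#'                          burn_in = 400, window = 100)
#' bifurcation_edges(scan)
#' }
#' @export
bifurcation_scan <- function(params, tau_grid, burn_in = 800, window = 100,
                             amplitude_threshold = 1e-3,
                             initial = season_state(1e4, 1e2)) {
  stopifnot(length(tau_grid) >= 1, all(tau_grid > 0))
  purrr::map_dfr(tau_grid, function(tau) {
    p <- update_params(params, tau = tau)
    ser <- iterate_seasons(p, initial = initial, n = burn_in + window)
    cls <- classify_dynamics(ser, burn_in = burn_in, window = window,
                             amplitude_threshold = amplitude_threshold)
    win <- ser$season > burn_in & ser$season <= burn_in + window
    tibble::tibble(
      tau = tau,
      season = ser$season[win],
      v_hat = ser$v_hat[win],
      label = cls$label,
      relative_amplitude = cls$relative_amplitude
    )
  }) -> out
  class(out) <- c("bifurcation_scan", class(out))
  out
}

#' Edges of the cycling window in a bifurcation scan
#'
#' Reports the lower and upper boundaries of the contiguous cycling interval
#' of `tau` found by [bifurcation_scan()]. Each edge is the midpoint between
#' the last non-cycling and the first cycling grid value (and the bare grid
#' values are returned alongside).
#'
#' @param scan A `bifurcation_scan` tibble.
#' @return A one-row tibble: `tau_lower`, `tau_upper` (midpoint edges),
#'   `tau_min_cycling`, `tau_max_cycling` (grid values), `n_cycling`.
#' @export
bifurcation_edges <- function(scan) {
  per_tau <- dplyr::distinct(dplyr::as_tibble(scan), tau, label)
  per_tau <- dplyr::arrange(per_tau, tau)
  cyc <- per_tau$tau[per_tau$label == "cycling"]
  if (!length(cyc)) {
    return(tibble::tibble(tau_lower = NA_real_, tau_upper = NA_real_,
                          tau_min_cycling = NA_real_,
                          tau_max_cycling = NA_real_, n_cycling = 0L))
  }
  lo <- min(cyc); hi <- max(cyc)
  below <- per_tau$tau[per_tau$tau < lo]
  above <- per_tau$tau[per_tau$tau > hi]
  tibble::tibble(
    tau_lower = if (length(below)) (max(below) + lo) / 2 else lo,
    tau_upper = if (length(above)) (min(above) + hi) / 2 else hi,
    tau_min_cycling = lo,
    tau_max_cycling = hi,
    n_cycling = length(cyc)
  )
}

#' Fixed point of the seasonal map
#'
#' Finds the coexistence fixed point `(s_hat*, v_hat*)` of the
#' between-season map. The within-season system is linear in the host at
#' fixed parasite pressure, so one unit-cohort season solve yields both the
#' uninfected-survivor ratio `c(v) = s(T)/s_hat` and the per-unit-cohort
#' progeny `w(v) = v2(T)/s_hat`, each strictly decreasing in `v`. The two
#' balance conditions (Beverton-Holt host balance and unit parasite
#' per-capita growth) then collapse to a single strictly decreasing
#' function of `v` whose root is found by log-scale bisection — the
#' coexistence fixed point is unique and located without any Newton
#' iteration. The fixed point need not be stable: in the cycling regime it
#' is the unstable focus the quasiperiodic orbit surrounds, but it still
#' satisfies `season_map(x) = x` to the requested tolerance.
#'
#' @param params A [model_params()] object.
#' @param initial Unused (kept for call compatibility).
#' @param tol Relative tolerance on the bisection in `v_hat`.
#' @param max_iter Maximum bisection iterations.
#' @return A [season_state()] fixed point.
#' @examples
#' \donttest{map_fixed_point(model_params(tau = 3.5))}
#' @export
map_fixed_point <- function(params, initial = NULL,
                            tol = 1e-12, max_iter = 200) {
  s_pf <- parasite_free_equilibrium(params)
  if (s_pf <= 0) {
    stop("no coexistence fixed point: the host population is not viable",
         call. = FALSE)
  }
  traits <- list(alpha = params$alpha, beta = params$beta,
                 delta = params$delta, tau = params$tau)
  # one unit-cohort season gives c(v) and w(v); extreme pressure overflows
  # the survival exponent and is certainly above balance
  season_unit <- function(v) {
    tryCatch(season_solve(1, v, traits, params$mu, params$T, params$t_l),
             error = function(e) list(s_T = 0, v2_T = 0))
  }
  balance <- function(v) {
    sol <- season_unit(v)
    cc <- sol$s_T
    if (params$sigma * cc <= 1) return(-v)      # host collapses: overshoot
    s_hat <- (params$sigma * cc - 1) / (params$rho * cc)
    s_hat * sol$v2_T[1] - v                     # parasite balance residual
  }
  lo <- 1e-2
  if (balance(lo) <= 0) {
    stop("no coexistence fixed point: the parasite cannot invade the ",
         "parasite-free host equilibrium", call. = FALSE)
  }
  hi <- lo
  while (balance(hi) > 0 && hi < 1e15) hi <- hi * 100
  if (hi >= 1e15) {
    stop("no coexistence fixed point found below v_hat = 1e15", call. = FALSE)
  }
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    if (balance(mid) > 0) lo <- mid else hi <- mid
    if (hi / lo < 1 + tol) break
  }
  v_star <- sqrt(lo * hi)
  cc <- season_unit(v_star)$s_T
  s_star <- (params$sigma * cc - 1) / (params$rho * cc)
  season_state(s_star, v_star)
}

#' Stability of a season-map fixed point
#'
#' Central-difference Jacobian of the two-dimensional seasonal map at a
#' fixed point, and its eigenvalues. The fixed point is stable when the
#' spectral radius is below one; quasiperiodic cycling arises when a
#' complex-conjugate pair crosses the unit circle (a Neimark-Sacker
#' bifurcation of the map).
#'
#' @param params A [model_params()] object.
#' @param fixed_point A [season_state()] satisfying
#'   `season_map(x) = x` to relative tolerance `1e-6` (checked).
#' @param rel_step Relative step for the central differences.
#' @return A list with `jacobian` (2x2 matrix), `eigenvalues` (complex),
#'   `spectral_radius`, and `stable` (logical).
#' @examples
#' \donttest{
#' p <- model_params(tau = 3.5)
#' fp <- map_fixed_point(p)
#' map_jacobian_stability(p, fp)$stable
#' }
#' @export
map_jacobian_stability <- function(params, fixed_point, rel_step = 1e-5) {
  x <- c(fixed_point$s_hat, fixed_point$v_hat)
  Fmap <- function(x) {
    st <- season_map(params, season_state(max(x[1], 0), max(x[2], 0)))
    c(st$s_hat, st$v_hat)
  }
  fx <- Fmap(x)
  if (any(abs(fx - x) > 1e-6 * pmax(abs(x), 1))) {
    stop("supplied state is not a fixed point of the season map ",
         "(residual exceeds 1e-6 relative); run map_fixed_point() first",
         call. = FALSE)
  }
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    h <- max(abs(x[j]), 1) * rel_step
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    J[, j] <- (Fmap(xp) - Fmap(xm)) / (2 * h)
  }
  ev <- eigen(J, only.values = TRUE)$values
  list(jacobian = J, eigenvalues = ev,
       spectral_radius = max(Mod(ev)), stable = max(Mod(ev)) < 1)
}

#' Stability phase diagram over phenological patterns
#'
#' For each `(T, t_l)` cell with `t_l <= T`, sets the virulence trait to the
#' evolutionarily stable value for that phenological environment (from
#' `ess_provider`), iterates the seasonal map, and classifies the attractor.
#' Cells where the ESS solver fails are labelled `"undetermined"` rather
#' than skipped.
#'
#' @param T_grid,t_l_grid Numeric grids of season lengths and emergence
#'   window lengths.
#' @param params A [model_params()] object supplying all other parameters.
#' @param ess_provider Function `(T, t_l) -> tau*`; defaults to [ess_tau()]
#'   on the correspondingly updated parameter set.
#' @param burn_in,window,amplitude_threshold Passed to [classify_dynamics()].
#' @return A tibble with columns `T`, `t_l`, `tau_star`, `label`.
#' @export
phase_boundary <- function(T_grid, t_l_grid, params,
                           ess_provider = NULL,
                           burn_in = 800, window = 100,
                           amplitude_threshold = 1e-3) {
  if (is.null(ess_provider)) {
    ess_provider <- function(T, t_l) {
      ess_tau(update_params(params, T = T, t_l = t_l, tau = min(0.7 * T, T - 0.1)))
    }
  }
  grid <- tidyr::expand_grid(T = T_grid, t_l = t_l_grid)
  grid <- dplyr::filter(grid, .data$t_l <= .data$T)
  purrr::pmap_dfr(grid, function(T, t_l) {
    tau_star <- tryCatch(ess_provider(T, t_l), error = function(e) NA_real_)
    if (!is.finite(tau_star)) {
      return(tibble::tibble(T = T, t_l = t_l, tau_star = NA_real_,
                            label = "undetermined"))
    }
    lab <- tryCatch({
      p <- update_params(params, T = T, t_l = t_l, tau = tau_star)
      # the diagram asks whether the endemic state of an adapted parasite is
      # stable, so seed an established host population with a modest
      # parasite inoculum rather than a colonising host cohort
      init <- season_state(parasite_free_equilibrium(p), 1e2)
      ser <- iterate_seasons(p, initial = init, n = burn_in + window)
      classify_dynamics(ser, burn_in, window, amplitude_threshold)$label
    }, error = function(e) "undetermined")
    tibble::tibble(T = T, t_l = t_l, tau_star = tau_star, label = lab)
  })
}
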