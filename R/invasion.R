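#' Trait set of a (mutant) parasite strain
#'
#' Bundles the four evolvable parasite traits. In the virulence-evolution
#' analyses all traits except the incubation delay `tau_m` are held equal
#' to the resident's; the constructor defaults do exactly that when given
#' the resident parameter set.
#'
#' @param params A [model_params()] supplying resident trait defaults.
#' @param tau_m Mutant incubation delay (inverse virulence).
#' @param alpha_m,beta_m,delta_m Mutant transmission rate, progeny count
#'   and environmental decay rate; default to the resident's values.
#' @return An object of class `strain_traits`.
#' @examples
#' strain_traits(model_params(), tau_m = 2.9)
#' @export
strain_traits <- function(params, tau_m = params$tau,
                          alpha_m = params$alpha, beta_m = params$beta,
                          delta_m = params$delta) {
  for (v in c(alpha_m, beta_m, delta_m, tau_m)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("strain traits must be single positive numbers", call. = FALSE)
  }
  structure(list(alpha_m = alpha_m, beta_m = beta_m, delta_m = delta_m,
                 tau_m = tau_m), class = "strain_traits")
}

#' Within-season dynamics with several co-circulating strains
#'
#' Generalises the single-strain season to `k` parasite strains sharing the
#' host environment: the susceptible hosts are depleted by the summed
#' infection pressure of all strains, while each strain's infecting
#' generation decays at its own rate and its progeny arise from its own
#' delayed kill term. Reduces exactly to the single-strain solver when one
#' strain is present.
#'
#' @param params A [model_params()]; supplies the shared host environment
#'   (`mu`, `sigma`, `rho`, `T`, `t_l`). Its parasite traits are ignored.
#' @param s_hat Emerging host cohort this season.
#' @param strains A data frame / tibble with one row per strain and columns
#'   `alpha`, `beta`, `delta`, `tau`, `v_hat`.
#' @return A list with `s_T` (hosts surviving uninfected to the season's
#'   end) and `v2_T` (numeric vector of per-strain progeny at `T`).
#' @examples
#' p <- model_params()
#' st <- data.frame(alpha = p$alpha, beta = p$beta, delta = p$delta,
#'                  tau = c(2.8, 2.9), v_hat = c(1e4, 1))
#' within_season_multistrain(p, 1e4, st)
#' @export
within_season_multistrain <- function(params, s_hat, strains) {
  stopifnot(inherits(params, "model_params"),
            all(c("alpha", "beta", "delta", "tau", "v_hat") %in% names(strains)),
            nrow(strains) >= 1)
  sol <- season_solve(
    s_hat = s_hat, v_hat = strains$v_hat,
    traits = list(alpha = strains$alpha, beta = strains$beta,
                  delta = strains$delta, tau = strains$tau),
    mu = params$mu, T = params$T, t_l = params$t_l
  )
  list(s_T = sol$s_T, v2_T = sol$v2_T)
}

#' Invasion fitness of a rare mutant parasite
#'
#' End-of-season progeny density `v2m(T)` of a single mutant parasite
#' (`v1m(0) = 1`) introduced into a resident environment at its seasonal
#' fixed point `(s_hat*, v_hat*)`. The mutant invades when
#' `v2m(T) >= 1`. Computed from the closed-form integrating-factor
#' solution by adaptive quadrature, split into the two delay regimes:
#' when `tau_m < T - t_l` some hosts are still emerging while the mutant's
#' kills release progeny (emergence-window piece plus a post-window piece);
#' when `tau_m >= T - t_l` all contributing infections happen during the
#' emergence window. The value is continuous across the regime boundary.
#'
#' This code path is independent of the panel-quadrature season solver:
#' the two computations of `v2m(T)` cross-validate each other.
#'
#' @param resident_env A [season_state()] holding `(s_hat*, v_hat*)`; must
#'   be a fixed point of the resident's season map to relative `1e-6`
#'   (checked), otherwise an error demands the simulation route.
#' @param mutant A [strain_traits()] object.
#' @param params The resident [model_params()].
#' @param check_equilibrium Set `FALSE` to skip the fixed-point check
#'   (used when the environment is held fixed externally, e.g. the
#'   constant-cohort control).
#' @return The scalar `v2m(T)`.
#' @examples
#' \donttest{
#' p <- model_params(tau = 3.5)
#' env <- map_fixed_point(p)
#' invasion_fitness(env, strain_traits(p), p)      # ~1: neutral mutant
#' }
#' @export
invasion_fitness <- function(resident_env, mutant, params,
                             check_equilibrium = TRUE) {
  stopifnot(inherits(mutant, "strain_traits"), inherits(params, "model_params"))
  s_star <- resident_env$s_hat
  v_star <- resident_env$v_hat
  if (check_equilibrium) {
    nxt <- season_map(params, season_state(s_star, v_star))
    if (abs(nxt$s_hat - s_star) > 1e-6 * max(s_star, 1) ||
        abs(nxt$v_hat - v_star) > 1e-6 * max(v_star, 1)) {
      stop("resident_env is not an equilibrium of the season map: ",
           "cycling regime; use simulation (within_season_multistrain)",
           call. = FALSE)
    }
  }
  am <- mutant$alpha_m; bm <- mutant$beta_m
  dm <- mutant$delta_m; tm <- mutant$tau_m
  al <- params$alpha; de <- params$delta
  mu <- params$mu; T <- params$T; t_l <- params$t_l
  if (tm >= T) return(0)

  # survival exponent of a susceptible host: background mortality plus
  # infection pressure from resident (density v_star) and the single mutant
  K <- function(t) {
    mu * t + al * v_star * (1 - exp(-de * t)) / de +
      am * 1 * (1 - exp(-dm * t)) / dm
  }
  upper <- T - tm
  if (t_l > 0) {
    C_of <- function(y) {
      stats::integrate(function(u) exp(K(u)), 0, y,
                       rel.tol = 1e-10, abs.tol = 0)$value
    }
    s_of <- function(w) {     # hosts still uninfected at time w (vectorised)
      vapply(w, function(wi) {
        (s_star / t_l) * exp(-K(wi)) * C_of(min(wi, t_l))
      }, 0)
    }
    I1 <- stats::integrate(s_of, 0, min(t_l, upper),
                           rel.tol = 1e-9, abs.tol = 0)$value
    I2 <- 0
    if (upper > t_l) {
      s_tl <- s_of(t_l)
      K_tl <- K(t_l)
      I2 <- s_tl * stats::integrate(function(u) exp(-(K(u + t_l) - K_tl)),
                                    0, upper - t_l,
                                    rel.tol = 1e-9, abs.tol = 0)$value
    }
    I <- I1 + I2
  } else {
    I <- stats::integrate(function(w) s_star * exp(-K(w)), 0, upper,
                          rel.tol = 1e-9, abs.tol = 0)$value
  }
  am * bm * exp(-mu * tm) * 1 * exp(-dm * (T - tm)) * I
}

#' Selection gradient on the incubation delay
#'
#' Central finite difference of [invasion_fitness()] in the mutant trait
#' `tau_m`, evaluated at `tau_m = tau_r` in the resident's own equilibrium
#' environment. Positive values select for longer delays (lower virulence).
#'
#' @param params Resident [model_params()] (its `tau` is the resident trait).
#' @param env Optional precomputed resident equilibrium [season_state()];
#'   computed with [map_fixed_point()] if missing.
#' @param h Finite-difference step on `tau_m`.
#' @param richardson If `TRUE`, repeat at `h/2` and return the
#'   Richardson-extrapolated gradient.
#' @return Scalar gradient `d v2m(T) / d tau_m`.
#' @export
selection_gradient <- function(params, env = NULL, h = 1e-3,
                               richardson = FALSE) {
  if (is.null(env)) env <- map_fixed_point(params)
  grad_at <- function(h) {
    wp <- invasion_fitness(env, strain_traits(params, tau_m = params$tau + h),
                           params, check_equilibrium = FALSE)
    wm <- invasion_fitness(env, strain_traits(params, tau_m = params$tau - h),
                           params, check_equilibrium = FALSE)
    (wp - wm) / (2 * h)
  }
  g <- grad_at(h)
  if (richardson) {
    g2 <- grad_at(h / 2)
    g <- (4 * g2 - g) / 3
  }
  g
}

#' Evolutionarily stable incubation delay
#'
#' Finds the uninvadable virulence trait `tau*`: the incubation delay at
#' which the selection gradient vanishes and invasion fitness is locally
#' maximal. The resident equilibrium is recomputed at every candidate
#' resident trait (the environment `tau*` is uninvadable in is the one
#' `tau*` itself creates). In phenological environments where the
#' coexistence fixed point is unstable (cycling), the fixed point still
#' exists and continues to define invasion fitness; it is located by
#' Newton iteration.
#'
#' @param params A [model_params()]; its `tau` seeds the search.
#' @param interval Search interval for `tau*`; defaults to
#'   `(0.05 T, 0.995 T)`.
#' @param tol Absolute tolerance on `tau*`.
#' @param constant_cohort If `TRUE`, the resident environment is the
#'   constant-cohort control: the emerging cohort is fixed at `cohort`
#'   and only the parasite density equilibrates.
#' @param cohort Host cohort for the constant-cohort control; defaults to
#'   the parasite-free equilibrium cohort of `params`.
#' @return `tau*` (scalar). Errors with "no interior ESS" if the gradient
#'   does not change sign on the interval.
#' @examples
#' \donttest{ess_tau(model_params())}
#' @export
ess_tau <- function(params, interval = NULL, tol = 1e-3,
                    constant_cohort = FALSE, cohort = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(interval)) interval <- c(0.05 * params$T, 0.995 * params$T)
  if (constant_cohort && is.null(cohort)) {
    cohort <- parasite_free_equilibrium(params)
    if (cohort <= 0) stop("host population not viable: no control cohort",
                          call. = FALSE)
  }
  last_env <- NULL
  grad <- function(tau_r) {
    p <- update_params(params, tau = tau_r)
    env <- if (constant_cohort) {
      control_equilibrium(p, cohort)
    } else {
      tryCatch(
        map_fixed_point(p, initial = if (is.null(last_env))
          season_state(1e4, 1e2) else last_env),
        error = function(e) map_fixed_point(p)
      )
    }
    last_env <<- env
    selection_gradient(p, env = env)
  }
  # bracket a sign change on a coarse grid, then bisect with uniroot
  taus <- seq(interval[1], interval[2], length.out = 13)
  lo <- NA_real_; hi <- NA_real_
  gprev <- NA_real_; tprev <- NA_real_
  for (i in seq_along(taus)) {
    g_i <- tryCatch(grad(taus[i]), error = function(e) NA_real_)
    if (is.finite(g_i) && is.finite(gprev) && sign(g_i) != sign(gprev)) {
      lo <- tprev; hi <- taus[i]
      break
    }
    if (is.finite(g_i)) { gprev <- g_i; tprev <- taus[i] }
  }
  if (!is.finite(lo)) {
    stop("no interior ESS: selection gradient does not change sign on (",
         signif(interval[1], 3), ", ", signif(interval[2], 3), ")",
         call. = FALSE)
  }
  root <- stats::uniroot(grad, c(lo, hi), tol = tol)$root
  # second-order condition: fitness locally concave at tau*; probe half a
  # typical mutational step away so the check rides above the noise floor
  # of the per-candidate fixed-point recomputation
  gl <- grad(max(root - 0.05, interval[1]))
  gr <- grad(min(root + 0.05, interval[2]))
  if (!(gl > 0 && gr < 0)) {
    warning("stationary point at tau* = ", signif(root, 4),
            " is not a local fitness maximum", call. = FALSE)
  }
  root
}

#' Parasite equilibrium under a constant host cohort
#'
#' In the constant-cohort control the emerging host cohort is pinned at
#' `cohort` every season, so only the parasite density evolves between
#' seasons: `v_hat(n+1) = v2(T; cohort, v_hat(n))`. This one-dimensional
#' map is iterated (with damping) to its fixed point.
#'
#' @param params A [model_params()].
#' @param cohort Fixed emerging host cohort size.
#' @param v0 Starting parasite density.
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap.
#' @return A [season_state()] with `s_hat = cohort` and the equilibrium
#'   `v_hat`.
#' @export
control_equilibrium <- function(params, cohort, v0 = 1e2, tol = 1e-10,
                                max_iter = 2000) {
  traits <- list(alpha = params$alpha, beta = params$beta,
                 delta = params$delta, tau = params$tau)
  v <- v0
  for (i in seq_len(max_iter)) {
    vn <- season_solve(cohort, v, traits, params$mu, params$T, params$t_l)$v2_T[1]
    if (vn < 1) stop("parasite not viable under the constant-cohort control",
                     call. = FALSE)
    if (abs(vn - v) <= tol * max(vn, 1)) {
      return(season_state(cohort, vn))
    }
    # damping stabilises overshooting when the map slope is < -1
    v <- if (i > 20) 0.5 * (v + vn) else vn
  }
  stop("constant-cohort parasite equilibrium did not converge", call. = FALSE)
}
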