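#' Model parameters for one parasite strain in one seasonal environment
#'
#' Constructs and validates the full parameter set of the seasonal
#' obligate-killer model: within-season transmission rates, the incubation
#' delay, between-season host demography, and the phenological constants
#' (season length and host emergence window).
#'
#' Defaults are the reference parameterisation used throughout the package:
#' `alpha = 3.5e-7`, `beta = 200`, `delta = 2`, `mu = 0.25`, `sigma = 500`,
#' `rho = 1e-4`. `tau`, `T` and `t_l` have no natural defaults (they are the
#' quantities being varied) but default here to the headline phenological
#' scenario `T = 4`, `t_l = 1`, `tau = 2.8`.
#'
#' @param alpha Transmission rate, per (parasite x time).
#' @param beta Number of parasite progeny released when an infected host is
#'   killed (dimensionless count).
#' @param delta Environmental parasite decay rate, per time.
#' @param mu Host background death rate, per time.
#' @param tau Incubation delay from infection to parasite-induced host death
#'   (inverse virulence), in time units. May exceed `T`, in which case no
#'   progeny are released before the season ends.
#' @param sigma Host fecundity multiplier (dimensionless).
#' @param rho Density-dependence parameter of host reproduction, per host.
#' @param T Season length, in time units.
#' @param t_l Length of the host emergence window, in time units;
#'   `0 <= t_l <= T`. `t_l = 0` means perfectly synchronous emergence at the
#'   start of the season.
#'
#' @return An object of class `model_params` (a named list).
#' @examples
#' p <- model_params()
#' p
#' model_params(tau = 3.1, T = 5, t_l = 2)
#' @export
model_params <- function(alpha = 3.5e-7, beta = 200, delta = 2, mu = 0.25,
                         tau = 2.8, sigma = 500, rho = 1e-4,
                         T = 4, t_l = 1) {
  p <- list(alpha = alpha, beta = beta, delta = delta, mu = mu, tau = tau,
            sigma = sigma, rho = rho, T = T, t_l = t_l)
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (k in c("alpha", "beta", "delta", "mu", "tau", "sigma", "rho", "T", "t_l")) {
    if (!num1(p[[k]])) stop("parameter '", k, "' must be a single finite number", call. = FALSE)
  }
  for (k in c("alpha", "beta", "delta", "mu", "sigma", "rho", "T")) {
    if (p[[k]] <= 0) stop("parameter '", k, "' must be strictly positive", call. = FALSE)
  }
  if (p$tau <= 0) stop("parameter 'tau' must be > 0", call. = FALSE)
  if (p$t_l < 0) stop("parameter 't_l' must be >= 0", call. = FALSE)
  if (p$t_l > p$T) stop("emergence window 't_l' cannot exceed season length 'T'", call. = FALSE)
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  transmission alpha = %g, progeny beta = %g, decay delta = %g\n",
              x$alpha, x$beta, x$delta))
  cat(sprintf("  host mortality mu = %g, incubation tau = %g\n", x$mu, x$tau))
  cat(sprintf("  reproduction sigma = %g, density-dependence rho = %g\n",
              x$sigma, x$rho))
  cat(sprintf("  season T = %g, emergence window t_l = %g\n", x$T, x$t_l))
  invisible(x)
}

#' @export
as.data.frame.model_params <- function(x, ...) {
  as.data.frame(unclass(x))
}

#' Coerce model parameters to a one-row tibble
#'
#' @param x A `model_params` object.
#' @param ... Unused.
#' @return A one-row tibble with one column per parameter.
#' @export
as_tibble.model_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Replace fields of a parameter set
#'
#' Convenience for single-parameter displacements: returns a copy of `params`
#' with the named fields replaced, re-validated.
#'
#' @param params A `model_params` object.
#' @param ... Named scalar replacements, e.g. `tau = 3.1`.
#' @return A new `model_params` object.
#' @examples
#' update_params(model_params(), mu = 0.4)
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_model_params(p)
  structure(p, class = "model_params")
}

#' Season-start state of the host cohort and parasite population
#'
#' @param s_hat Emerging host cohort size this season (hosts, absolute count).
#' @param v_hat Parasite density at the start of the season (parasites,
#'   absolute count).
#' @return An object of class `season_state`.
#' @examples
#' season_state(1e4, 1e2)
#' @export
season_state <- function(s_hat, v_hat) {
  if (!is.numeric(s_hat) || length(s_hat) != 1L || !is.finite(s_hat) || s_hat < 0)
    stop("'s_hat' must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(v_hat) || length(v_hat) != 1L || !is.finite(v_hat) || v_hat < 0)
    stop("'v_hat' must be a single finite number >= 0", call. = FALSE)
  structure(list(s_hat = s_hat, v_hat = v_hat), class = "season_state")
}

#' @export
print.season_state <- function(x, ...) {
  cat(sprintf("<season_state> s_hat = %g hosts, v_hat = %g parasites\n",
              x$s_hat, x$v_hat))
  invisible(x)
}
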