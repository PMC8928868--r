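# Internal semi-analytic solver for one season of the delay system.
#
# Within a season the system is, per parasite strain i,
#   ds/dt    = s_hat g(t, t_l) - mu s - s * sum_i alpha_i v1_i
#   dv1_i/dt = -delta_i v1_i
#   dv2_i/dt = alpha_i beta_i e^{-mu tau_i} s(t - tau_i) v1_i(t - tau_i)
#              - delta_i v2_i
# with s(0) = 0, v1_i(0) = v_hat_i, v2_i(t) = 0 for t <= tau_i.
#
# v1_i is closed form. With K(t) = mu t + sum_i alpha_i v_hat_i
# (1 - e^{-delta_i t}) / delta_i the integrating factor gives
#   s(t) = (s_hat / t_l) e^{-K(t)} C(min(t, t_l)),  C(y) = int_0^y e^{K(u)} du
# and because v1_i and v2_i share the decay rate delta_i the v2 quadrature
# collapses to a plain integral of s:
#   v2_i(t) = alpha_i beta_i e^{-mu tau_i} v_hat_i e^{-delta_i (t - tau_i)}
#             int_0^{t - tau_i} s(w) dw            (zero for t <= tau_i).
#
# All integrals are evaluated by composite 7-point Gauss-Legendre quadrature
# on a graded panel mesh. Panels never straddle the emergence kink at t_l nor
# any needed upper limit T - tau_i (these are forced panel boundaries), and
# panel lengths are graded so the survival exponent K changes by at most
# `exponent_step` per panel, which keeps both the panel quadrature and the
# degree-6 interpolatory partial sums used for C at interior nodes far below
# the 1e-8 relative error level.

.gl7_nodes <- c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972,
                0, 0.4058451513773972, 0.7415311855993945, 0.9491079123427585)
.gl7_weights <- c(0.1294849661688697, 0.2797053914892767, 0.3818300505051189,
                  0.4179591836734694, 0.3818300505051189, 0.2797053914892767,
                  0.1294849661688697)

# Partial-integration weight matrix: PW[j, k] = int_{-1}^{nodes[j]} l_k(x) dx
# for the Lagrange basis l_k on the 7 Gauss-Legendre nodes.
.gl7_partial <- local({
  n <- length(.gl7_nodes)
  V <- outer(.gl7_nodes, 0:(n - 1), `^`)
  PW <- matrix(0, n, n)
  for (k in seq_len(n)) {
    ek <- numeric(n); ek[k] <- 1
    a <- solve(V, ek)                       # basis-poly coefficients
    ai <- c(0, a / seq_len(n))              # antiderivative coefficients
    evalp <- function(x) sum(ai * x^(0:n))
    PW[, k] <- vapply(.gl7_nodes, evalp, 0) - evalp(-1)
  }
  PW
})

# Graded panel mesh over [0, T]. `fixed` are times that must be panel
# boundaries; grading keeps the change of the survival exponent K below
# `exponent_step` per panel, using the (conservative) total initial slope
# `mu + a_tot` decaying at the slowest strain rate. Meshes are memoised on
# (T, t_l/fixed points, slope bucket): the slope enters only through the
# power-of-two bucket ceiling, so a cached mesh is always at least as fine
# as the current season requires.
.mesh_cache <- new.env(parent = emptyenv())

season_mesh <- function(T, fixed, mu, a_tot, d_min,
                        exponent_step = 0.5, h_max = 0.5) {
  fixed <- fixed[fixed > 1e-12 & fixed < T - 1e-12]
  slope0 <- mu + a_tot
  bucket <- if (slope0 <= 1) 0 else ceiling(log2(slope0))
  key <- paste(format(c(T, fixed, d_min), digits = 15), collapse = ","
               ) |> paste(bucket, sep = "|")
  hit <- .mesh_cache[[key]]
  if (!is.null(hit)) return(hit)
  slope_cap <- mu + max(2^bucket, slope0)  # bucket-conservative grading
  fixed <- sort(unique(c(fixed, T)))
  keep <- c(TRUE, diff(fixed) > 1e-11)
  fixed <- fixed[keep]
  a_cap <- slope_cap - mu
  b <- numeric(256L)
  b[1L] <- 0
  nb <- 1L
  t <- 0
  nf <- length(fixed)
  fi <- 1L
  while (t < T - 1e-12) {
    slope <- mu + a_cap * exp(-d_min * t)
    h <- exponent_step / slope
    if (h > h_max) h <- h_max
    nxt <- t + h
    if (fi <= nf && nxt >= fixed[fi] - 1e-11) {
      nxt <- fixed[fi]
      fi <- fi + 1L
    }
    t <- if (nxt > T) T else nxt
    nb <- nb + 1L
    if (nb > length(b)) b <- c(b, numeric(length(b)))
    b[nb] <- t
  }
  b <- b[seq_len(nb)]
  if (length(.mesh_cache) > 500L) {
    rm(list = ls(.mesh_cache), envir = .mesh_cache)
  }
  .mesh_cache[[key]] <- b
  b
}

# Solve one season for k strains. `traits` is a list with numeric vectors
# alpha, beta, delta, tau (one entry per strain). Returns s(T), per-strain
# v2(T), and closures for trajectory evaluation at the mesh boundaries.
#
# eval_times: optional times in [0, T] at which the trajectory (s, v1_i,
# v2_i) is required; they (and their tau-shifts) become panel boundaries so
# all values come out of the same quadrature pass.
season_solve <- function(s_hat, v_hat, traits, mu, T, t_l,
                         eval_times = NULL) {
  k <- length(v_hat)
  alpha <- traits$alpha; beta <- traits$beta
  delta <- traits$delta; tau <- traits$tau
  stopifnot(length(alpha) == k, length(beta) == k,
            length(delta) == k, length(tau) == k)

  active <- v_hat > 0
  a_i <- alpha[active] * v_hat[active]
  d_i <- delta[active]

  upper <- T - tau                       # upper limits for the v2 integrals
  fixed <- c(t_l, upper[upper > 0 & upper < T])
  if (!is.null(eval_times)) {
    shifts <- as.vector(outer(eval_times, tau, `-`))
    fixed <- c(fixed, eval_times, shifts[shifts > 0 & shifts < T])
  }
  b <- season_mesh(T, fixed, mu, sum(a_i),
                   if (length(d_i)) min(d_i) else 1)
  P <- length(b) - 1L
  h <- diff(b)
  mid <- (b[-1] + b[-(P + 1L)]) / 2
  # 7 x P matrix of node times
  X <- outer(.gl7_nodes, h / 2) + rep(mid, each = 7L)

  Kfun <- function(t) {
    out <- mu * t
    for (j in seq_along(a_i)) {
      out <- out + a_i[j] * (1 - exp(-d_i[j] * t)) / d_i[j]
    }
    out
  }
  KX <- Kfun(X)
  Kb <- Kfun(b)
  if (max(KX) > 690) {
    stop("numerical overflow in the within-season survival exponent K(t) ",
         "(K exceeds 690; parasite pressure alpha*v_hat too large)",
         call. = FALSE)
  }

  find_b <- function(x) {
    i <- which.min(abs(b - x))
    if (abs(b[i] - x) > 1e-8 * max(1, T)) {
      stop("internal mesh lookup failed for t = ", x, call. = FALSE)
    }
    i
  }

  if (s_hat <= 0) {
    sb <- numeric(P + 1L)
    Sb <- numeric(P + 1L)
    s_T <- 0
  } else if (t_l > 0) {
    EX <- exp(KX)
    gk <- colSums(.gl7_weights * EX) * h / 2
    Cb <- c(0, cumsum(gk))               # C at boundaries
    i_tl <- find_b(t_l)
    C_tl <- Cb[i_tl]
    # C at interior nodes: exact within the emergence window, constant after
    Cn <- matrix(C_tl, 7L, P)
    inwin <- which(b[-1] <= t_l + 1e-11)
    if (length(inwin)) {
      Cn[, inwin] <- rep(Cb[inwin], each = 7L) +
        (.gl7_partial %*% EX[, inwin, drop = FALSE]) *
          rep(h[inwin] / 2, each = 7L)
    }
    sn <- (s_hat / t_l) * exp(-KX) * Cn
    # C at a boundary is Cb, frozen at C(t_l) beyond the emergence window
    sb <- (s_hat / t_l) * exp(-Kb) * pmin(Cb, C_tl)
    Sk <- colSums(.gl7_weights * sn) * h / 2
    Sb <- c(0, cumsum(Sk))               # int_0^b s
    s_T <- sb[P + 1L]
  } else {
    # synchronous emergence: all hosts appear at t = 0+, s(0+) = s_hat
    sn <- s_hat * exp(-KX)
    sb <- s_hat * exp(-Kb)
    Sk <- colSums(.gl7_weights * sn) * h / 2
    Sb <- c(0, cumsum(Sk))
    s_T <- sb[P + 1L]
  }

  if (!all(is.finite(Sb)) || !is.finite(s_T)) {
    stop("non-finite susceptible-host quadrature (s integral); ",
         "parameters: mu=", mu, " T=", T, " t_l=", t_l, call. = FALSE)
  }

  S_at <- function(x) {                  # int_0^x s(w) dw, x a mesh boundary
    if (x <= 1e-12) return(0)
    Sb[find_b(x)]
  }

  v2_T <- numeric(k)
  for (i in seq_len(k)) {
    if (v_hat[i] > 0 && tau[i] < T - 1e-12) {
      v2_T[i] <- alpha[i] * beta[i] * exp(-mu * tau[i]) * v_hat[i] *
        exp(-delta[i] * (T - tau[i])) * S_at(T - tau[i])
    }
  }
  if (!all(is.finite(v2_T))) {
    stop("non-finite progeny quadrature (v2 integral)", call. = FALSE)
  }

  trajectory <- NULL
  if (!is.null(eval_times)) {
    s_t <- vapply(eval_times, function(t) sb[find_b(t)], 0)
    v1 <- matrix(0, length(eval_times), k)
    v2 <- matrix(0, length(eval_times), k)
    for (i in seq_len(k)) {
      if (v_hat[i] > 0) {
        v1[, i] <- v_hat[i] * exp(-delta[i] * eval_times)
        past <- eval_times > tau[i] + 1e-12
        if (any(past)) {
          tt <- eval_times[past]
          v2[past, i] <- alpha[i] * beta[i] * exp(-mu * tau[i]) * v_hat[i] *
            exp(-delta[i] * (tt - tau[i])) *
            vapply(tt - tau[i], S_at, 0)
        }
      }
    }
    trajectory <- list(t = eval_times, s = s_t, v1 = v1, v2 = v2)
  }

  list(s_T = s_T, v2_T = v2_T, trajectory = trajectory)
}
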