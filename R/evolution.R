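# Multi-strain season iteration shared by the invasion-phase experiment and
# the adaptive walk. `strains` is a data frame with columns alpha, beta,
# delta, tau, v_hat (+ anything else, carried along); strains whose density
# drops below `extinction_threshold` at a season boundary are removed.
advance_multistrain <- function(params, s_hat, strains, n,
                                extinction_threshold = 1,
                                constant_cohort = FALSE,
                                cohort = s_hat,
                                record = NULL) {
  rec <- NULL
  if (!is.null(record)) {
    rec <- matrix(NA_real_, nrow = n, ncol = 2L,
                  dimnames = list(NULL, c("s_hat", "v_track")))
  }
  for (i in seq_len(n)) {
    if (nrow(strains) == 0L) {
      # no parasites left: host relaxes on its own demography
      surv <- survivor_fraction(params)
      for (j in i:n) {
        s_T <- s_hat * surv
        s_hat <- if (constant_cohort) cohort else
          params$sigma * s_T / (1 + params$rho * s_T)
        if (!is.null(rec)) { rec[j, 1L] <- s_hat; rec[j, 2L] <- 0 }
      }
      return(list(s_hat = s_hat, strains = strains, record = rec))
    }
    sol <- season_solve(
      s_hat, strains$v_hat,
      list(alpha = strains$alpha, beta = strains$beta,
           delta = strains$delta, tau = strains$tau),
      params$mu, params$T, params$t_l
    )
    s_hat <- if (constant_cohort) cohort else
      params$sigma * sol$s_T / (1 + params$rho * sol$s_T)
    strains$v_hat <- sol$v2_T
    if (!is.null(rec)) {
      rec[i, 1L] <- s_hat
      id <- match(record, strains$id)
      rec[i, 2L] <- if (is.na(id)) 0 else strains$v_hat[id]
    }
    strains <- strains[strains$v_hat >= extinction_threshold, , drop = FALSE]
  }
  list(s_hat = s_hat, strains = strains, record = rec)
}

#' Invasion outcome of an advantageous mutant across cycle phases
#'
#' Runs the resident parasite to its (cycling) attractor, then introduces a
#' single mutant parasite (density 1, start of season) at each of a sweep
#' of consecutive seasons — i.e. at different phases of the demographic
#' cycle — and follows the two-strain system forward. The mutant counts as
#' having invaded when it persists above the extinction threshold for at
#' least `persist_seasons` consecutive seasons and exceeds its introduction
#' density; a mutant pruned below density 1 is extinct.
#'
#' The per-phase outcome is returned together with the host and resident
#' parasite state at introduction and the sign of the host trend, making
#' the cycle-phase dependence of invasion success directly inspectable.
#'
#' @param params Resident [model_params()] (`tau` is overridden by
#'   `resident_tau`).
#' @param resident_tau Resident incubation delay.
#' @param mutant_tau Mutant incubation delay.
#' @param intro_seasons Integer offsets (seasons after the burn-in) at
#'   which to introduce the mutant; default sweeps 12 consecutive seasons,
#'   covering over two full cycles.
#' @param burn_in Seasons run before any introduction.
#' @param follow_seasons Seasons simulated after each introduction.
#' @param persist_seasons Consecutive-survival requirement for "invaded".
#' @param extinction_threshold Pruning density.
#' @param initial Initial [season_state()] for the burn-in.
#' @return A tibble of class `phase_invasion`: one row per introduction
#'   with columns `intro_season`, `s_hat_at_intro`, `v_hat_at_intro`,
#'   `host_rising`, `outcome` (`"invaded"`/`"extinct"`),
#'   `seasons_survived`, `max_mutant_density`.
#' @examples
#' \donttest{
#' pi <- phase_dependent_invasion(model_params(), 2.8, 2.81,
#'                                intro_seasons = 1:6, burn_in = 400)
#' }
#' @export
phase_dependent_invasion <- function(params, resident_tau = 2.8,
                                     mutant_tau = 2.81,
                                     intro_seasons = 1:12,
                                     burn_in = 800, follow_seasons = 250,
                                     persist_seasons = 50,
                                     extinction_threshold = 1,
                                     initial = season_state(1e4, 1e2)) {
  stopifnot(follow_seasons >= 2 * persist_seasons)
  p <- update_params(params, tau = resident_tau)
  ser <- iterate_seasons(p, initial = initial,
                         n = burn_in + max(intro_seasons),
                         extinction_threshold = extinction_threshold)
  res_traits <- c(alpha = p$alpha, beta = p$beta, delta = p$delta)
  purrr::map_dfr(intro_seasons, function(k) {
    n0 <- burn_in + k
    s0 <- ser$s_hat[ser$season == n0]
    v0 <- ser$v_hat[ser$season == n0]
    s_next <- ser$s_hat[ser$season == n0 + 1]
    host_rising <- if (length(s_next)) s_next > s0 else NA
    strains <- data.frame(
      id = c("resident", "mutant"),
      alpha = res_traits[["alpha"]], beta = res_traits[["beta"]],
      delta = res_traits[["delta"]],
      tau = c(resident_tau, mutant_tau),
      v_hat = c(v0, 1)
    )
    out <- advance_multistrain(p, s0, strains, follow_seasons,
                               extinction_threshold = extinction_threshold,
                               record = "mutant")
    vm <- out$record[, "v_track"]
    alive <- vm >= extinction_threshold
    run <- rle(alive)
    longest <- if (any(run$values)) max(run$lengths[run$values]) else 0L
    survived <- if (any(!alive)) which(!alive)[1L] - 1L else length(vm)
    invaded <- longest >= persist_seasons && max(vm, na.rm = TRUE) > 1
    tibble::tibble(
      intro_season = n0,
      s_hat_at_intro = s0,
      v_hat_at_intro = v0,
      host_rising = host_rising,
      outcome = if (invaded) "invaded" else "extinct",
      seasons_survived = survived,
      max_mutant_density = max(vm, na.rm = TRUE)
    )
  }) -> out
  class(out) <- c("phase_invasion", class(out))
  attr(out, "resident_tau") <- resident_tau
  attr(out, "mutant_tau") <- mutant_tau
  out
}

#' Stochastic adaptive walk of the virulence trait
#'
#' Simulates sequential mutation-invasion dynamics: the resident parasite
#' runs for `first_mutant_season` seasons, then a single mutant (density 1)
#' with incubation delay drawn from `Normal(dominant tau, mutation_sd)` is
#' introduced at the start of the season; every `mutant_interval` seasons
#' thereafter another mutant is introduced, its mean taken from whichever
#' strain currently has the highest density. Mutational input is decoupled
#' from population size. Strains whose density falls below
#' `extinction_threshold` at a season boundary are eliminated. Draws
#' outside `(0, T)` are redrawn (such phenotypes release no progeny and
#' would stall the walk).
#'
#' The walk terminates once the dominant trait has been within
#' `optimum_tol` of the optimum `tau_star` for `consecutive_hits`
#' successive mutant events (or at `max_events`). With
#' `constant_cohort = TRUE` the host demographic feedback is switched off —
#' the emerging cohort is pinned at `cohort` every season — giving the
#' non-cycling control in which advantageous mutants always invade.
#'
#' @param params A [model_params()] (its `tau` is ignored; see `tau0`).
#' @param tau0 Founding resident incubation delay.
#' @param seed Integer seed for the walk's RNG (recorded in the result).
#' @param tau_star Target optimum; computed via [ess_tau()] (with the
#'   matching demography) when `NULL`.
#' @param first_mutant_season Seasons before the first mutant.
#' @param mutant_interval Seasons between successive mutants.
#' @param mutation_sd Standard deviation of the mutation kernel on `tau`.
#' @param extinction_threshold Pruning density (absolute count).
#' @param optimum_tol Half-width of the "at the optimum" band on `tau`.
#' @param consecutive_hits Events the dominant trait must stay in the band.
#' @param max_events Cap on introduced mutants.
#' @param constant_cohort If `TRUE`, disable host feedback (control runs).
#' @param cohort Pinned cohort for the control; defaults to the
#'   parasite-free equilibrium cohort.
#' @param initial Initial [season_state()].
#' @return An object of class `adaptive_walk`: a list with `events`
#'   (tibble: `event_index`, `season`, `resident_tau`, `mutant_tau`,
#'   `outcome`, `dominant_tau_after`), `events_to_optimum`, `reached`,
#'   `tau_star`, `seed`, `constant_cohort`, and `status`
#'   (`"reached_optimum"`, `"max_events"`, or `"parasite_extinct"`).
#' @examples
#' \donttest{
#' w <- adaptive_walk(model_params(), tau0 = 2.5, seed = 1, tau_star = 2.976,
#'                    max_events = 10)
#' glance(w)
#' }
#' @export
adaptive_walk <- function(params, tau0, seed = NULL, tau_star = NULL,
                          first_mutant_season = 100, mutant_interval = 1000,
                          mutation_sd = 0.1, extinction_threshold = 1,
                          optimum_tol = 0.05, consecutive_hits = 3,
                          max_events = 80, constant_cohort = FALSE,
                          cohort = NULL, initial = season_state(1e4, 1e2)) {
  stopifnot(inherits(params, "model_params"), tau0 > 0, tau0 < params$T)
  if (!is.null(seed)) set.seed(seed)
  if (constant_cohort && is.null(cohort)) {
    cohort <- parasite_free_equilibrium(params)
  }
  if (is.null(tau_star)) {
    tau_star <- ess_tau(update_params(params, tau = tau0),
                        constant_cohort = constant_cohort, cohort = cohort)
  }
  p <- update_params(params, tau = tau0)
  s_hat <- if (constant_cohort) cohort else initial$s_hat
  strains <- data.frame(id = "founder", alpha = p$alpha, beta = p$beta,
                        delta = p$delta, tau = tau0, v_hat = initial$v_hat,
                        stringsAsFactors = FALSE)
  st <- advance_multistrain(p, s_hat, strains, first_mutant_season,
                            extinction_threshold = extinction_threshold,
                            constant_cohort = constant_cohort, cohort = cohort)
  s_hat <- st$s_hat; strains <- st$strains
  season <- first_mutant_season

  events <- vector("list", max_events)
  hits <- 0L
  events_to_optimum <- NA_integer_
  status <- "max_events"
  for (ev in seq_len(max_events)) {
    if (nrow(strains) == 0L) { status <- "parasite_extinct"; break }
    dom <- strains[which.max(strains$v_hat), ]
    repeat {
      tau_m <- dom$tau + stats::rnorm(1L, 0, mutation_sd)
      if (tau_m > 0 && tau_m < p$T) break
    }
    mut_id <- paste0("m", ev)
    strains <- rbind(strains,
                     data.frame(id = mut_id, alpha = p$alpha, beta = p$beta,
                                delta = p$delta, tau = tau_m, v_hat = 1,
                                stringsAsFactors = FALSE))
    st <- advance_multistrain(p, s_hat, strains, mutant_interval,
                              extinction_threshold = extinction_threshold,
                              constant_cohort = constant_cohort,
                              cohort = cohort)
    s_hat <- st$s_hat; strains <- st$strains
    season <- season + mutant_interval
    if (nrow(strains) == 0L) {
      events[[ev]] <- tibble::tibble(
        event_index = ev, season = season - mutant_interval,
        resident_tau = dom$tau, mutant_tau = tau_m,
        outcome = "extinct", dominant_tau_after = NA_real_
      )
      status <- "parasite_extinct"
      break
    }
    dom_after <- strains$tau[which.max(strains$v_hat)]
    events[[ev]] <- tibble::tibble(
      event_index = ev, season = season - mutant_interval,
      resident_tau = dom$tau, mutant_tau = tau_m,
      outcome = if (mut_id %in% strains$id) "invaded" else "extinct",
      dominant_tau_after = dom_after
    )
    if (abs(dom_after - tau_star) <= optimum_tol) {
      hits <- hits + 1L
      if (hits == 1L) events_to_optimum <- ev
      if (hits >= consecutive_hits) { status <- "reached_optimum"; break }
    } else {
      hits <- 0L
      events_to_optimum <- NA_integer_
    }
  }
  structure(
    list(events = dplyr::bind_rows(events),
         events_to_optimum = events_to_optimum,
         reached = identical(status, "reached_optimum"),
         tau_star = tau_star, tau0 = tau0, seed = seed,
         constant_cohort = constant_cohort, status = status,
         params = params),
    class = "adaptive_walk"
  )
}

#' @export
print.adaptive_walk <- function(x, ...) {
  cat("<adaptive_walk>", nrow(x$events), "mutant events;",
      if (x$reached) paste0("reached tau* = ", signif(x$tau_star, 4),
                            " after ", x$events_to_optimum, " mutants")
      else paste0("status: ", x$status),
      if (x$constant_cohort) "(constant-cohort control)" else "", "\n")
  invisible(x)
}

#' @describeIn adaptive_walk One row per mutant event.
#' @param x An `adaptive_walk` object.
#' @param ... Unused.
#' @export
tidy.adaptive_walk <- function(x, ...) x$events

#' @describeIn adaptive_walk One-row summary of the walk.
#' @export
glance.adaptive_walk <- function(x, ...) {
  tibble::tibble(
    tau0 = x$tau0,
    tau_star = x$tau_star,
    n_events = nrow(x$events),
    n_invaded = sum(x$events$outcome == "invaded"),
    events_to_optimum = x$events_to_optimum,
    reached = x$reached,
    status = x$status,
    constant_cohort = x$constant_cohort,
    dominant_tau_final = if (nrow(x$events))
      x$events$dominant_tau_after[nrow(x$events)] else NA_real_
  )
}

#' Replicated evolution-speed experiment
#'
#' Runs `n_below + n_above` independent adaptive walks, half founded below
#' and half above the optimum by `offset`, and summarises the number of
#' sequentially introduced mutants needed to reach the optimum. Run once
#' with demographic feedback (cycling regime) and once with
#' `constant_cohort = TRUE` to compare evolution speed between cycling and
#' stable systems.
#'
#' @param params A [model_params()].
#' @param seed Base RNG seed; replicate `i` uses `seed + i`.
#' @param n_below,n_above Replicates starting below/above the optimum.
#' @param offset Founding distance from `tau_star`.
#' @param tau_star Optimum; computed if `NULL` (with matching demography).
#' @param ... Passed to [adaptive_walk()].
#' @inheritParams adaptive_walk
#' @return A tibble of class `walk_ensemble`: one row per replicate
#'   ([glance()] columns plus `replicate` and `start`).
#' @export
walk_ensemble <- function(params, seed = 1, n_below = 6, n_above = 6,
                          offset = 0.5, tau_star = NULL,
                          constant_cohort = FALSE, cohort = NULL, ...) {
  if (constant_cohort && is.null(cohort)) {
    cohort <- parasite_free_equilibrium(params)
  }
  if (is.null(tau_star)) {
    tau_star <- ess_tau(params, constant_cohort = constant_cohort,
                        cohort = cohort)
  }
  starts <- c(rep(tau_star - offset, n_below), rep(tau_star + offset, n_above))
  walks <- purrr::imap(starts, function(tau0, i) {
    w <- adaptive_walk(params, tau0 = tau0, seed = seed + i,
                       tau_star = tau_star, constant_cohort = constant_cohort,
                       cohort = cohort, ...)
    list(
      summary = dplyr::mutate(glance(w), replicate = i, seed = seed + i,
                              start = if (tau0 < tau_star) "below" else "above",
                              .before = 1),
      events = dplyr::mutate(tidy(w), replicate = i, .before = 1)
    )
  })
  out <- purrr::map_dfr(walks, "summary")
  class(out) <- c("walk_ensemble", class(out))
  attr(out, "tau_star") <- tau_star
  attr(out, "constant_cohort") <- constant_cohort
  attr(out, "events") <- purrr::map_dfr(walks, "events")
  out
}

#' Per-event records of a walk ensemble
#'
#' @param x A `walk_ensemble` tibble.
#' @param ... Unused.
#' @return One row per mutant event across all replicates.
#' @export
tidy.walk_ensemble <- function(x, ...) attr(x, "events")

#' @export
glance.walk_ensemble <- function(x, ...) {
  # walks that never settle in the optimum band are right-censored at their
  # event cap; mean_events_to_optimum includes them at that cap
  eto <- ifelse(x$reached, x$events_to_optimum, x$n_events)
  tibble::tibble(
    n_replicates = nrow(x),
    n_reached = sum(x$reached),
    mean_events_to_optimum = mean(eto),
    min_events = min(eto),
    max_events = max(eto),
    mean_fraction_extinct = mean(1 - x$n_invaded / x$n_events),
    constant_cohort = attr(x, "constant_cohort")
  )
}
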