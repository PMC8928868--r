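---
title: "phenocycle: model, numerics and experimental protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenocycle: model, numerics and experimental protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the semi-discrete model, the numerical scheme and its tolerances, the
default protocol choices for each experiment, and the limits of what the
simulations can show.

## The model and its assumptions

We model a monocyclic, obligate-killer parasite of a seasonally active,
univoltine host. Within a season of length $T$, hosts emerge at a constant
per-capita rate over a window $[0, t_l]$ (a uniform emergence kernel
$g(t, t_l) = 1/t_l$; $t_l = 0$ is the synchronous limit in which the whole
cohort appears at $t = 0$). All parasites emerge at the start of the
season. Infection is mass-action with rate $\alpha$; an infected host is
killed $\tau$ time units after infection and releases $\beta$ progeny
provided it has not died of background mortality $\mu$ first — hence the
$e^{-\mu\tau}$ discount on the progeny source. Free parasites decay at
rate $\delta$. The monocyclic constraint means the progeny generation
$v_2$ does not reinfect within its season of release; progeny remaining at
$t = T$ found the next season's infecting generation, and infections still
incubating at $t = T$ are lost. Between seasons the uninfected survivors
$s(T)$ reproduce with Beverton–Holt density dependence
($\hat s(n+1) = \sigma s(T) / (1 + \rho s(T))$).

Key assumptions worth keeping in mind:

* **$\tau$ is inverse virulence** and is the only trait under selection in
  the evolution experiments; $\beta$ is constant regardless of $\tau$, so
  there is no transmission–virulence trade-off in the usual sense — the
  trait under selection is the timing of host death relative to the
  season.
* **Densities are absolute counts**, not proportions. The extinction rule
  — any parasite population below one individual at a season boundary is
  removed — only makes sense on a count scale, and it matters: it is what
  kills rare mutants during demographic bottlenecks.
* Parasite uptake by transmission is neglected in the $v_1$ balance
  (free-living parasite numbers are vastly larger than infection events),
  so $v_1(t) = \hat v\, e^{-\delta t}$ exactly.

## Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `alpha` | transmission rate | per (parasite · time) | 3.5e-7 |
| `beta`  | progeny per killed host | count | 200 |
| `delta` | environmental decay | per time | 2 |
| `mu`    | host background mortality | per time | 0.25 |
| `tau`   | infection-to-kill delay (1/virulence) | time | 2.8 |
| `sigma` | host fecundity | count | 500 |
| `rho`   | reproduction density dependence | per host | 1e-4 |
| `T`     | season length | time | 4 |
| `t_l`   | emergence window | time | 1 |

`T = 4, t_l = 1` is the headline short-season, synchronous-emergence
environment; `T` and `t_l` are the phenological axes, `tau` the
evolutionary one. The parasite-free host equilibrium for the defaults is
$\hat s^{\mathrm{pf}} \approx 4.98 \times 10^6$ hosts.

## Numerical scheme

**Semi-analytic season solver.** With
$K(t) = \mu t + \sum_i \alpha_i \hat v_i (1 - e^{-\delta_i t})/\delta_i$
(summing over co-circulating strains), the integrating factor gives
$s(t) = (\hat s / t_l)\, e^{-K(t)} \int_0^{\min(t, t_l)} e^{K(u)}\,du$,
and because each strain's progeny decay at the same rate as its infecting
generation the progeny integral collapses to
$v_{2,i}(T) = \alpha_i \beta_i e^{-\mu\tau_i} \hat v_i
e^{-\delta_i (T-\tau_i)} \int_0^{T-\tau_i} s(w)\,dw$.
Both integrals are evaluated by composite 7-point Gauss–Legendre
quadrature on a graded panel mesh: the emergence kink $t_l$ and every
delay horizon $T - \tau_i$ are forced panel boundaries, and panel lengths
are graded so $K$ changes by at most 0.5 per panel (capped at 0.5 time
units). Interior values of the cumulative $\int e^K$ use exact partial
integrals of the degree-6 interpolant on the panel nodes. This keeps the
solver at ~1e-10 relative error while costing a fraction of a millisecond
per season, which is what makes the million-season evolution experiments
feasible. Meshes are memoised on the phenology, the delay set and a
power-of-two bucket of the parasite pressure, so repeated seasons reuse
them. The synchronous limit `t_l = 0` is a distinct code path
($s(0^+) = \hat s$), not a shrunk uniform window. A survival exponent
above 690 aborts with an explicit overflow error naming the cause.

**Independent oracle.** `oracle_within_season()` integrates the delay
system directly with `deSolve::dede` (adaptive method of steps with
interpolated history) at tolerance 1e-10, sharing no code with the
semi-analytic path. The test suite holds the two to within 1e-5 relative
agreement in $s(T)$ and $v_2(T)$ on randomized log-uniform parameter
draws (1e-6 on the reference scenario). With synchronous emergence the
delayed kill term switches on discontinuously at $t = \tau$, which can
trip the strictest integrator error test; the oracle retries 100× looser
before giving up and always checks full time coverage.

**Fixed points and stability.** Because the within-season system is
linear in the host at fixed parasite pressure, a single unit-cohort
season solve yields both the survivor ratio $c(\hat v)$ and the
per-unit-cohort progeny $w(\hat v)$, each strictly decreasing in
$\hat v$; the host and parasite balance conditions then collapse to one
strictly decreasing scalar function of $\hat v$, and
`map_fixed_point()` finds its root by log-scale bisection. The
coexistence fixed point is therefore unique and is located reliably even
when it is an unstable focus inside the cycling window (a Newton scheme
tried first proved capable of sliding into the disease-free fixed point's
basin near the persistence boundary; the bisection formulation removes
that failure mode and its correctness is guarded by the neutrality
property: a mutant identical to the resident must have unit invasion
fitness in the fixed-point environment). `map_jacobian_stability()`
uses central differences with relative step 1e-5; quasiperiodic cycling
onsets where the complex eigenvalue pair crosses the unit circle
(Neimark–Sacker bifurcation of the map), and the test suite checks that
this crossing brackets the same window as the amplitude-based
classification.

## Classification of attractors

`classify_dynamics()` looks at the season-start parasite series over a
100-season window after an 800-season burn-in (matching the scan
convention used throughout). The label is `parasite_free` if the parasite
is extinct, `cycling` if the relative amplitude $(\max-\min)/\mathrm{mean}$
of $\hat v$ exceeds 1e-3, else `endemic_equilibrium`. The 1e-3 threshold
separates quadrature-level ringing (~1e-8 at the solver tolerances) from
genuine quasiperiodic orbits (amplitude ≥ 0.3 everywhere we have observed
cycling), so the classification is insensitive to the threshold over many
orders of magnitude. Burn-in invariance (800 vs 1600) is tested.

Cycle statistics are computed from discrete local maxima (plateaus take
the first index): the period is the mean host-peak spacing and the
host-to-parasite lag the mean offset from each host-cohort peak to the
next parasite peak, modulo the period. A caution on conventions: both
series are season-start quantities ($\hat s(n)$, $\hat v(n)$). On the
reference attractor (`tau = 2.8`) this measure gives a lag of ~1.1
seasons at a period of ~4.7 (harmonic regression and cross-correlation
agree). If the host is instead measured as end-of-season survivors
$s(T)$ — which peak exactly one season before the next cohort — the lag
reads ~2.1 seasons. Reported lags therefore depend entirely on which
population snapshot is paired with which, and cross-study comparisons
should state the convention.

**Initial conditions and establishment.** The default seed state is
$\hat s = 10^4$ hosts, $\hat v = 10^2$ parasites. Because counts below one
go extinct, establishment is a real threshold: a 3× smaller inoculum (or
host cohort) fails to establish in the reference environment, while
anything upward of the default reaches the same attractor. The
phenological phase diagram (`phase_boundary()`) therefore seeds each cell
with the host at its parasite-free equilibrium plus a 100-parasite
inoculum — the question asked there is whether the endemic state of an
adapted parasite is stable, not whether a small founding population can
colonise; with long seasons the colonisation transient would otherwise
read as parasite extinction.

## Invasion fitness and the ESS

`invasion_fitness()` evaluates the end-of-season progeny density
$v_{2m}(T)$ of a single mutant ($v_{1m}(0) = 1$) in a resident environment
at its seasonal fixed point, from the closed-form integrating-factor
solution by adaptive quadrature (`stats::integrate`, relative tolerance
1e-9 with the inner survival integral at 1e-10). The expression splits at
$\tau_m = T - t_l$: for smaller delays some kills release progeny while
hosts are still emerging (two-piece integral), for larger delays all
contributing infections occur within the emergence window. The two pieces
join continuously (tested to 1e-4). This code path is independent of the
panel-mesh season solver, and the two computations of $v_{2m}(T)$ agree to
better than 1e-3 relative across the whole $\tau_m$ range — a dual-route
check on both.

`ess_tau()` locates the optimum as the zero of the central-difference
selection gradient (step $\Delta\tau = 10^{-3}$, optional Richardson check
at $\Delta\tau/2$), recomputing the resident fixed point at every
candidate resident trait and bisecting to $|\Delta\tau^*| < 10^{-3}$.
Inside the cycling window the coexistence fixed point is unstable but
still exists and still defines the invasion-fitness maximand; the walk
simulations confirm that evolution is directed toward the same optimum.
For the reference environment $\tau^* \approx 2.98$, inside the cycling
window (2.78, 3.27) — the adapted parasite destabilises its own
demography. With fixed $T$, more synchronous emergence (smaller $t_l$)
shifts $\tau^*$ later: when all infections happen near-simultaneously the
optimal strategy kills close to the season's end to minimise environmental
decay of progeny.

## Evolution experiments

**Phase-dependent invasion.** The resident (`tau = 2.8`) is run 800
seasons onto its attractor; a mutant (`tau = 2.81`, density 1) is
introduced at the start of each of 12 consecutive seasons and the
two-strain system followed 250 seasons. "Invaded" is operationalised as
surviving at or above the extinction threshold for 50 consecutive seasons
*and* exceeding the introduction density; pruning below density one is
extinction. In the reference sweep exactly the introductions at low
resident parasite density with rising host density succeed, and a neutral
mutant never qualifies (its density rides the cycle and is culled at the
first bottleneck).

**Adaptive walks.** The protocol: 100 burn-in seasons; a mutant with
$\tau_m \sim \mathrm{Normal}(\tau_{\mathrm{dominant}}, 0.1)$ at density 1
at the start of the season; subsequent mutants every 1000 seasons, the
kernel centred on the currently highest-density strain; strains below
density one removed at season boundaries; draws outside $(0, T)$ redrawn.
Mutant introductions land at a fixed season offset, but the quasiperiodic
cycle period (~4.7, irrational) makes the introduction phases effectively
equidistributed. The walk stops when the dominant trait has been within
0.05 of $\tau^*$ (half a mutational standard deviation) for three
consecutive events; `events_to_optimum` is the first event of that
terminal run. Replicate ensembles found the walks at
$\tau^* \pm 0.5$ — the width of the virulence range over which the
bifurcation structure is interesting — six below and six above. The
constant-cohort control pins the emerging cohort at the parasite-free
equilibrium ($\approx 4.98 \times 10^6$; the natural interpretation of a
"host cohort held constant" at its demographic steady state) and uses the
optimum computed for that control demography (it differs from the
feedback optimum by < 0.01 here).

**What the paired comparison shows.** In the control, every mutant whose
invasion fitness exceeds one invades and the fate of each mutant follows
its fitness sign exactly (tested). With demographic feedback, only a
small minority of introduction phases admit an advantageous mutant — in
the tested reference sweep, introductions succeed at roughly one cycle
phase in ten — the eco-evolutionary brake.
Consequently the cycling system needs more mutant
events to reach the optimum, and the walk-duration distribution becomes
heavy-tailed: most walks finish in 9–36 events, but one or two replicates
per ensemble of twelve can stall for 50–150 events while the dominant
trait sits 0.1–0.2 away from the optimum waiting for a lucky
introduction phase. Ensemble means of a dozen heavy-tailed durations are
accordingly unstable across seeds (roughly 25–35 events with feedback
versus ~15 without, at the seeds we ran). Walks still unfinished at the
150-event cap are counted at the cap, which makes the reported mean a
lower bound. The qualitative contrast — cycling strictly slower, and only
there do advantageous mutants go extinct — is robust to all of these
choices; the precise cycling-system mean is not, and depends visibly on
the stopping rule and its band width.

## Problem sizes and determinism

The defaults used by the tests and the acceptance script: bifurcation
scans iterate 900 seasons per $\tau$ on a 0.01-step grid (101 values);
classifications use seasons 800–900; the invasion sweep follows 250
seasons per phase; each adaptive walk runs 1000 seasons per mutant event
with a 150-event cap, 12 replicates per condition. Everything except the
mutation draws is deterministic; walks take a single integer seed and are
bit-reproducible from it (the seed is stored in the result object).

## Known limitations

* Host evolution (resistance, phenology), polycyclic or non-obligate
  killer life cycles, and genetic drift are out of scope.
* The stability analysis is numerical (finite-difference Jacobians); no
  normal-form or Lyapunov-exponent computation is attempted.
* The absolute-count extinction rule makes establishment
  inoculum-dependent; results are reported for the documented seeds.
* Cycle period/lag statistics are estimated from discretely sampled
  quasiperiodic series; peak-based lags are convention-dependent as
  discussed above.
* The synthetic experiments emulate the model's own study conditions; they
  say nothing about measurement noise, spatial structure or environmental
  stochasticity in real systems.
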