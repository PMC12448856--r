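---
title: "Resolving a three-step base-flipping mechanism from stopped-flow and titration data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving a three-step base-flipping mechanism from stopped-flow and titration data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipkin)
```

## The scientific problem

The SRA domain of UHRF1 reads hemi-methylated CpG sites and flips the
5-methylcytosine base out of the DNA helix, the committed step that recruits
the maintenance methyltransferase DNMT1. Stopped-flow fluorescence traces of
duplexes carrying the emissive guanosine analogue thienoguanosine, recorded
against wild-type SRA, a flipping-incompetent mutant (G448D) and both
hemi-methylated (HM) and non-methylated (NM) duplexes, resolve this process
into a sequential scheme:

$$N + P \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} NP_{ns}
  \underset{k_{-2}}{\overset{k_2}{\rightleftharpoons}} NP_{fl}
  \underset{k_{-3}}{\overset{k_3}{\rightleftharpoons}} NP_{st}$$

where $N$ is free duplex, $P$ free protein, $NP_{ns}$ a non-specific
encounter complex formed within the instrument dead time, $NP_{fl}$ the
base-flipped intermediate (the terminal species for NM duplexes), and
$NP_{st}$ a conformationally rearranged final complex reached only with HM
duplexes. `flipkin` implements this scheme as a mass-action ODE system with
its thermodynamic closure relations, the instrument model of the stopped-flow
experiment, exponential and constrained global fitting, and synthetic-data
generators that reproduce the full experimental design with known ground
truth.

## The mechanism and its closure relations

Three mechanism variants restrict the active steps: `three_step`
(HM + wild type), `two_step` (NM + wild type, $k_3 = k_{-3} = 0$) and
`binding_only` (the G448D mutant, encounter step only). Because the first
step is shared by all three and is the *only* step for the mutant, the
measured association constants close the system:

* $K_{G448D} = K_1 = k_1/k_{-1}$,
* $K_{NM} = K_1 K_2$ with $K_2 = k_2/k_{-2}$,
* $K_{HM} = K_1 K_2 K_3$ with $K_3 = k_3/k_{-3}$.

These identities equate each measured constant with the stepwise product up
to the *final* species of the corresponding mechanism (the `final_state`
convention, the package default). An equilibrium titration, however,
physically reports *every* bound species, for which
$K_{NM}^{tot} = K_1(1+K_2)$ and $K_{HM}^{tot} = K_1(1+K_2+K_2K_3)$
(`total_bound`). Both conventions are implemented and every report
quantifies their ratio, $(1+K_2+K_2K_3)/(K_2K_3)$ for the HM duplex —
about 1.3 at the canonical rates, i.e. a 30% systematic gap that matters at
the precision the fits reach. The synthetic titration generator deliberately
uses `total_bound` (what the physics gives), exposing the gap rather than
hiding it.

```{r closures}
rc <- rate_constants(k1 = 3e9, k_m1 = 6000, k2 = 500, k_m2 = 100,
                     k3 = 15, k_m3 = 4)
equilibrium_constants_from_rates(rc, "final_state")
equilibrium_constants_from_rates(rc, "total_bound")
```

## Relaxation analysis and its validity domain

With the encounter step equilibrated within the dead time and step 2 much
faster than step 3, the two resolvable phases obey

$$k_{obs1} = k_2 + k_{-2}, \qquad
  k_{obs2} = \frac{k_3\,K_2}{1 + K_2} + k_{-3}.$$

`relaxation_rates_exact()` provides the independent check: the eigenvalues
of the mass-action Jacobian linearized at equilibrium. The comparison makes
the validity domain explicit, and one point deserves emphasis because it is
easy to miss: the stated timescale separations
($k_1 P \gg k_{obs1} \gg k_{obs2}$) are *not sufficient* for the $k_{obs1}$
expression. The exact slow eigenvalue is approximately
$k_2\,K_1P/(1+K_1P) + k_{-2}$, so the closed form additionally requires the
bimolecular pre-equilibrium to be saturated, $K_1 P \gg 1$. At the
experimental protein concentrations (1.5–9 uM, $K_1 P \approx 0.75$–4.4) the
closed form overestimates the exact relaxation rate of the fast resolvable
phase by 15–20%. The package's validity sweep therefore enforces
$K_1 P_{eq} \ge 10$ alongside the rate separations, under which both phases
agree with the exact eigenvalues to within 10% across randomized draws from
the reported rate ranges. Consequently, tests that compare fitted
exponential rates to the mechanism do so against the exact eigenvalues, not
the closed forms.

## From species to photons: the observable model

The observed fluorescence is linear in the species concentrations,
$F(t) = I_0[N] + I_{ns}[NP_{ns}] + I_{fl}[NP_{fl}] + I_{st}[NP_{st}]$.
Default response ratios anchor the steady-state fold changes: binding alone
raises emission ~1.25-fold ($I_{ns}/I_0$), flipping ~2.5-fold
($I_{fl}/I_0$), and the rearranged HM complex 5.5-fold ($I_{st}/I_0$, the
most sensitive label position). These are configurable because the
underlying steady-state data are fold changes read off bar plots, not
tabulated intensities.

The instrument model reproduces the acquisition design: a 2.7 ms dead time
(handled by discarding samples — mixing is treated as instantaneous),
either 10 000 points in the first 0.1 s plus 9 000 to 1 s (`dense_early`)
or 2 000 + 9 000 (`balanced`), block averaging by groups of 4, and
additive homoscedastic Gaussian detector noise with a default standard
deviation of 1% of the free-duplex signal (the source data do not
characterize the detector noise; 1% of full scale is typical of a
photomultiplier stopped-flow at good signal-to-noise). The two regimes are
verified to give observed rates agreeing within 2%.

Competition-chase dissociation mixes the pre-equilibrated complex 1:1 with
750 uM (nucleotides) unlabelled competitor DNA, modeled as a
pseudo-first-order sink on free protein with site size 12 nt and a trap
rate constant equal to $k_1$. The source protocol gives no competitor
kinetics; at this excess the fitted dissociation rate is insensitive to
both defaults (halving either moves it by well under 2%, which is itself a
test), and the decay rate equals the slowest eigenvalue of the bound-state
chain with rebinding blocked.

## Exponential fitting with dead-time extrapolation

Traces are fitted to
$y(t) = I_f - (I_f - I_i)\left[a e^{-k_{obs1}t} + (1-a)e^{-k_{obs2}t}\right]$
with model time running from the true mixing time, so $I_i$ extrapolates
through the dead time and captures the unresolvable burst. Rates are fitted
in log space, the amplitude fraction through a logistic transform. Starting
values matter more than usual here because the fast phase survives for only
a handful of samples after block averaging: the fitter first fits the
dominant phase mono-exponentially, estimates the fast rate from the
early-time residual, and multi-starts across a small ladder of candidate
rates, keeping the best sum of squares. Two phases within 10% of each other
are refitted as one and flagged "phases unresolved"; a rate above
$1/(2\,\Delta t)$ is flagged "beyond time resolution"; a trace whose total
change is within noise reports no rates at all.

## The constrained global fit

All traces (HM and NM, several protein concentrations) are fitted
simultaneously to the scheme with $k_1$ fixed at $3\times 10^9$
M$^{-1}$s$^{-1}$ — chosen between the instrument-derived lower bound
$k_{obs}^{max}/P_{min} = 5\times10^8$ and the diffusion ceiling $10^{10}$ —
and everything else floating. Titration constants enter as starting values
only (via the closure relations), not as hard constraints. Two
implementation choices keep the fit fast and stable:

* **Micromolar internally.** $k_1 P_t \approx 2\times10^4$ s$^{-1}$ against
  $k_{-3} \approx 4$ s$^{-1}$ spans four decades; rescaling concentrations
  to uM conditions the stiff system, integrated with `lsoda` (analytic
  Jacobian, rtol $10^{-9}$, atol $10^{-12}$ uM — budgeted so conservation
  holds to $10^{-6}$ relative on every trajectory).
* **Variable projection.** The responses enter $F(t)$ linearly, so for any
  trial rate set the optimal responses per duplex type are a weighted
  linear least-squares solve. The Levenberg–Marquardt search then covers
  only the five log rate constants. The free-duplex response is anchored
  from the buffer-control trace ($I_0 = $ mean control intensity $/N_t$);
  without a control the gain is unidentifiable and assembly fails loudly.

Per-trace weights default to the inverse variance of the final 5% of
points; non-convergence triggers up to five multiplicative ($\times/\div 3$)
restarts of the starting values. Two further numerical details matter: the
finite-difference steps for the LM Jacobian are set well above the
integrator's noise floor (`epsfcn = 1e-8`, about $10^{-4}$ relative steps
on the log rates) — with machine-epsilon steps the derivatives inherit ODE
solver noise and the search stalls partway along the soft
$k_{-1}$–$k_2$ ridge — and each converged run is polished by restarting
the LM from its own solution (which resets the damping parameter) until
the deviance stops improving.

Deciding whether the data support a third step at all is done by model
comparison, not by staring at a standard error: for every three-step
problem the nested two-step model is also fitted and an extra-sum-of-squares
F test is applied. This matters in practice — fitted to two-step data, the
three-step model tends to park $k_3$ at a small, spuriously well-determined
value that absorbs discretization structure; the F test correctly reports
that the extra step buys nothing (and on genuine three-step ensembles it is
significant beyond any doubt). Wald intervals on the natural scale and a
2-decade log-SE threshold provide the per-parameter unidentifiability
flags, and a residual-resampling bootstrap (seeded, reproducible) gives
distribution-free intervals; the reported standard errors are fit
covariances, and the bootstrap is offered without claiming the two
coincide.

## The synthetic-data generators define the study conditions

`make_ground_truth()` draws rates uniformly inside the reported ranges
($k_2 \in [400, 550]$, $k_{-2} \in [80, 110]$, $k_3 \in [14, 35]$,
$k_{-3} \in [3, 18]$ s$^{-1}$), with $k_1 = 3\times10^9$ M$^{-1}$s$^{-1}$
and $k_{-1} = k_1/K_{G448D}$, $K_{G448D} = 5\times10^5$ M$^{-1}$.
Association ensembles use 0.3 uM duplex and protein spanning 1.5–9 uM
(including the 7.5 uM point used for representative traces); paired HM/NM
ensembles share the encounter and flipping steps, as the mechanism demands.
Dissociation uses 0.6 uM duplex pre-incubated with 1.5 uM (HM) or 3.0 uM
(NM) protein, then half-diluted into 750 uM competitor. Titrations use 1 uM
duplex by default. All randomness flows from `(scenario, seed)`; every
artifact is bit-reproducible.

What the generators do *not* emulate — lamp drift, mixing artifacts,
photobleaching, inner-filter effects, gain drift across shots, heteroscedastic
shot noise — bounds what passing tests show about real data: they validate
the estimators against the stated noise model, not against instrument
pathologies. A single global gain per trace set is assumed.

### Problem sizes used in the validation studies

The recovery studies are sized to demonstrate the statistics, not to redo
the experiment at full instrument resolution: ensembles of 4 HM + 4 NM
traces at (1.5, 4.5, 7.5, 9) uM in the `balanced` regime, block-averaged by
16 (~690 points per trace), 50 replicate fits for parameter recovery and
for the two-vs-three-step discrimination study, 200 replicates for the
titration recovery, and a reduced 400-point instrument for bootstrap tests.
Noiseless ensembles are recovered to well under 1%; at 1% detector noise
the median relative errors of $k_2, k_{-2}, k_3, k_{-3}$ are a few percent.

## Design decisions on genuinely open points

* **Titration stoichiometry** is fixed at $n = 1$ by default (floating it
  returns values near 1), optionally free with a lower bound of 0.1.
* **Ka positivity** is enforced by fitting $\log_{10} K_a$ (the constants
  span $10^5$–$10^7$ M$^{-1}$).
* **The ±20% batch-validation gate** is boundary-inclusive: "within 20%"
  is read as $\le$.
* **Where the titration can and cannot measure $K_a$.** A Cramér–Rao
  analysis of the isotherm shows that at 1 uM duplex — the assay
  concentration, far above the dissociation constant of the high-affinity
  duplex — the curve is stoichiometric and $K_a$ is bounded rather than
  measured: with all four parameters floating, no 12-point design at
  0.003 anisotropy noise gets the relative standard error of $K_a$ below
  ~40%, because $R$ and $K_a$ are nearly collinear in the isotherm. The
  package's titration recovery study is therefore run in the identifiable
  regime: duplex near the dissociation constant (0.1 uM for
  $K_a = 8\times10^6$ M$^{-1}$), a 12-point grid spanning the transition,
  and $R$ fixed at its measured value — $R$ is the bound/free intensity
  ratio, which a titration records directly alongside the anisotropy.
  Under that design $K_a$ is recovered within 20% in ~97% of replicates.
  `fit_titration()` still floats $R$ by default; `fix_R` is the
  recommendation whenever intensities were recorded.
* **ϑ in the isotherm** is implemented as the fraction of *duplex* bound:
  it is normalized by the duplex concentration and saturates at 1 with
  excess protein, and it is the duplex's anisotropy being modeled. The
  quantity is sometimes described as the bound protein fraction; the
  behaviour, not the wording, is implemented.
* **Step-1 pre-equilibration** before $t = 0$ (the dead-time assumption)
  is available as a documented approximation mode
  (`initial = "step1_equilibrium"`), OFF by default: simulations integrate
  the full scheme from the unmixed state, as the global fit does.
* **Degenerate eigenvalues** in the exact relaxation spectrum are reported
  with a multiplicity attribute rather than silently collapsed.
* **Dissociation syringe concentrations** follow the written protocol
  (1.5 uM protein for HM complexes); a figure legend elsewhere in the
  source material quotes 1.8 uM for the same experiment — the difference
  is immaterial at these occupancies.

## A worked example

```{r example}
instr <- instrument_model(regimes = "balanced", noise_sd = 0.003)
truth <- make_ground_truth("HM", seed = 42, instrument = instr)
truth$rates

ens <- simulate_paired_ensemble(truth, Pt_series = c(1.5, 4.5, 7.5, 9))
traces <- lapply(ens$traces, reduce_by_group, group_size = 8)

# observed rates of the representative 7.5 uM HM trace
idx <- which(vapply(traces, function(x)
  identical(attr(x, "Pt"), 7.5) && attr(x, "duplex") == "HM", logical(1)))
fit_exponential(traces[[idx[1]]], n_phases = 2)

# dissociation gives the starting value for the reverse rearrangement rate
diss <- simulate_dissociation_dataset(truth)
k_m3_est <- fit_exponential(reduce_by_group(diss, 8), n_phases = 1)$kobs1

Ks <- equilibrium_constants_from_rates(truth$rates, "final_state")
problem <- build_global_problem(
  traces, list(K_G448D = Ks$K_G448D, K_NM = Ks$K_NM, K_HM = Ks$K_HM),
  k_m3_init = k_m3_est)
report <- run_global_fit(problem)
report
```

## Known limitations

* The mechanism is fixed to the three nested variants; there is no general
  reaction-scheme language, and no spatial (sliding/hopping) model of the
  target search that underlies the large effective $k_1$.
* Fit standard errors are conditional on the homoscedastic noise model;
  for real traces with correlated noise the bootstrap intervals are the
  safer quantity.
* The dead time is handled by sample discard, not by convolution with a
  mixing profile, so sub-dead-time amplitudes are extrapolated under the
  assumption of instantaneous mixing.
* `k1` is not estimable from these data (only bounded below); all
  first-order constants are conditional on its fixed value.
  `k1_sensitivity()` refits at the bound values ($5\times10^8$,
  $10^{10}$): raising `k1` to the diffusion ceiling moves the
  unimolecular constants by only a few percent, but lowering it to the
  instrument bound brings the encounter exchange rate within an order of
  magnitude of the flipping relaxation, and `k2`/`k_m2` compensate
  visibly — the insensitivity claim holds for fast `k1`, not uniformly
  across the admissible interval.
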