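# flipkin

Kinetic analysis of protein-induced DNA base flipping, built around the
system in which the SRA domain of UHRF1 reads hemi-methylated CpG sites:
stopped-flow fluorescence kinetics of thienoguanosine-labelled duplexes,
fluorescence-anisotropy binding titrations, and constrained global fitting
of a three-step reaction mechanism. It is written for biophysicists who
want to fit (or simulate, with known ground truth) this class of
experiment end to end.

## The model

The interaction of protein P with a labelled duplex N follows the
sequential scheme

    N + P  <=>[k1, k-1]  NPns  <=>[k2, k-2]  NPfl  <=>[k3, k-3]  NPst

- **NPns** — non-specific encounter complex, formed within the stopped-flow
  dead time (k1 fixed at 3×10⁹ M⁻¹s⁻¹, between the instrument bound
  kobs_max/P_min = 5×10⁸ and the diffusion ceiling 10¹⁰);
- **NPfl** — base-flipped intermediate, the final species for
  non-methylated (NM) duplexes;
- **NPst** — slowly rearranged final complex, reached only with
  hemi-methylated (HM) duplexes.

Measured association constants close the system
(K_G448D = K1, K_NM = K1·K2, K_HM = K1·K2·K3), the two resolvable
stopped-flow phases obey the pre-equilibrium relations
kobs1 = k2 + k−2 and kobs2 = k3·K2/(1+K2) + k−3, and the anisotropy
titrations follow the quadratic mass-balance isotherm with quantum-yield
correction. The package implements the ODE system (stiff solver, compiled
right-hand side), the relaxation-rate analysis with its exact eigenvalue
cross-check, Eq.-style exponential fitting with dead-time extrapolation,
a Dynafit-style Levenberg–Marquardt global fit with per-species
fluorescence responses profiled out by variable projection, a nested
two-vs-three-step F test, bootstrap intervals, and generators for the
full synthetic experimental design (acquisition regimes, 2.7 ms dead
time, block averaging, detector noise, competition-chase dissociation).

## A worked example

```r
library(flipkin)

instr <- instrument_model(regimes = "balanced", noise_sd = 0.003)  # 1% noise
truth <- make_ground_truth("HM", seed = 42, instrument = instr)
ens   <- simulate_paired_ensemble(truth, Pt_series = c(1.5, 4.5, 7.5, 9))
traces <- lapply(ens$traces, reduce_by_group, group_size = 8)

diss     <- simulate_dissociation_dataset(truth)
k_m3_est <- fit_exponential(reduce_by_group(diss, 8), n_phases = 1)$kobs1

Ks <- equilibrium_constants_from_rates(truth$rates, "final_state")
problem <- build_global_problem(
  traces, list(K_G448D = Ks$K_G448D, K_NM = Ks$K_NM, K_HM = Ks$K_HM),
  k_m3_init = k_m3_est)
run_global_fit(problem)
```

```
Global fit report (converged)
  k_m1  =       5971 +/- 48.1      s^-1  [5877, 6066]
  k2    =        533 +/- 4.83      s^-1  [523.7, 542.6]
  k_m2  =      107.9 +/- 0.518     s^-1  [106.9, 108.9]
  k3    =      20.05 +/- 0.0412    s^-1  [19.97, 20.13]
  k_m3  =      15.45 +/- 0.0135    s^-1  [15.42, 15.48]
  derived kobs1 = 641 s^-1, kobs2 = 32.12 s^-1
  weighted SSR = 0.0123785 over 10952 residuals
```

The ground truth behind this ensemble was k_m1 = 6000, k2 = 537.2,
k_m2 = 108.1, k3 = 20.01, k_m3 = 15.46 s⁻¹ — every floated constant is
recovered within 0.8% at 1% detector noise. `report$flags` is empty; on
data generated without a third step the same call flags k3 as
indistinguishable from zero via the built-in two-vs-three-step F test.

Other entry points: `fit_titration()` (anisotropy isotherms, ±20% batch
gate via `validate_binding_constant()`), `fit_exponential()` /
`summarize_kobs()` (per-trace rates and their concentration dependence),
`predict_dissociation_trace()` (competition chase),
`bootstrap_uncertainty()`, and `run_pipeline()` for a config-driven,
fully reproducible generate→fit→report run. The methods vignette
(`vignettes/base-flipping-kinetics.Rmd`) documents the model, the
conventions and every tunable default.

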