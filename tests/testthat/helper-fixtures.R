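# Shared fixtures: canonical rate sets and small, fast synthetic ensembles.

# Canonical three-step rate set used throughout (inside the reported ranges).
canonical_rates <- function() {
  rate_constants(k1 = 3e9, k_m1 = 6000, k2 = 500, k_m2 = 100,
                 k3 = 15, k_m3 = 4)
}

# Independent equilibrium oracle: root-solve the mass-balance equations for
# free duplex N (1-D in N after eliminating P), never reusing the package's
# closed form.
equilibrium_oracle <- function(rc, Nt, Pt) {
  K1 <- rc$k1 * 1e-6 / rc$k_m1
  K2 <- if (rc$k_m2 > 0) rc$k2 / rc$k_m2 else 0
  K3 <- if (rc$k_m3 > 0) rc$k3 / rc$k_m3 else 0
  S <- K1 * (1 + K2 + K2 * K3)
  # bound B = S * N * P, N = Nt - B, P = Pt - B; solve f(B) = 0 on [0, min]
  f <- function(B) S * (Nt - B) * (Pt - B) - B
  B <- if (S == 0 || Nt == 0 || Pt == 0) 0 else
    uniroot(f, c(0, min(Nt, Pt) * (1 - 1e-12)), tol = 1e-14)$root
  N <- Nt - B; P <- Pt - B
  ns <- K1 * N * P
  c(N = N, P = P, NPns = ns, NPfl = K2 * ns, NPst = K3 * K2 * ns)
}

# Small, fast instrument: few hundred points, same dead time.
small_instrument <- function(noise_sd = 0) {
  instrument_model(dead_time = 2.7e-3,
                   regimes = list(c(200, 0, 0.1), c(200, 0.1, 1)),
                   noise_sd = noise_sd)
}

# Fast experiment-design ensemble for global-fit tests: balanced regime,
# block-averaged by 16 (problem sizes sized for sub-second fits).
quick_ensemble <- function(seed, noise_sd = 0.003, Pt_series = c(1.5, 4.5,
                                                                 7.5, 9)) {
  instr <- instrument_model(regimes = "balanced", noise_sd = noise_sd)
  truth <- make_ground_truth("HM", seed = seed, instrument = instr)
  ens <- simulate_paired_ensemble(truth, Pt_series = Pt_series)
  ens$traces <- lapply(ens$traces, reduce_by_group, group_size = 16)
  ens
}

quick_problem <- function(ens, k_m3_init = NULL) {
  truth <- ens$truth_HM
  Ks <- equilibrium_constants_from_rates(truth$rates, "final_state")
  if (is.null(k_m3_init)) {
    diss <- simulate_dissociation_dataset(truth)
    k_m3_init <- fit_exponential(reduce_by_group(diss, 16),
                                 n_phases = 1)$kobs1
  }
  build_global_problem(ens$traces,
                       list(K_G448D = Ks$K_G448D, K_NM = Ks$K_NM,
                            K_HM = Ks$K_HM),
                       k_m3_init = k_m3_init)
}

true_rate_vector <- function(truth) {
  unlist(truth$rates[c("k_m1", "k2", "k_m2", "k3", "k_m3")])
}
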