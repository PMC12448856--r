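test_that("rate constant containers enforce nonnegativity and variant rules", {
  expect_error(rate_constants(-1, 6000), "nonnegative")
  expect_error(rate_constants(3e9, 6000, 500, 100, variant = "binding_only"),
               "binding_only")
  expect_error(rate_constants(3e9, 6000, 500, 100, 15, 4,
                              variant = "two_step"), "two_step")
  rc <- canonical_rates()
  expect_s3_class(rc, "rate_constants")
  expect_output(print(rc), "three_step")
})

test_that("equilibrium constants follow both closure conventions", {
  rc <- canonical_rates()
  fs <- equilibrium_constants_from_rates(rc, "final_state")
  expect_equal(fs$K_G448D, 5e5)
  expect_equal(fs$K_NM, 5e5 * 5)                 # K1 * K2
  expect_equal(fs$K_HM, 5e5 * 5 * 3.75)          # K1 * K2 * K3
  tb <- equilibrium_constants_from_rates(rc, "total_bound")
  expect_equal(tb$K_NM, 5e5 * (1 + 5))           # 3e6
  expect_equal(tb$K_HM, 5e5 * (1 + 5 + 5 * 3.75))
  # the convention discrepancy is quantified
  expect_equal(tb$convention_ratio_HM,
               (1 + 5 + 5 * 3.75) / (5 * 3.75))
  expect_equal(tb$K_HM / fs$K_HM, tb$convention_ratio_HM)
  # K2 from the worked example: 500/100 with final_state K_NM = 2.5e6
  rc2 <- rate_constants(3e9, 6000, 500, 100, variant = "two_step")
  expect_equal(equilibrium_constants_from_rates(rc2)$K_NM, 2.5e6)
  expect_error(equilibrium_constants_from_rates(
    rate_constants(3e9, 0)), "undefined")
})

test_that("initial rate estimates invert the closure and relaxation relations", {
  # k_m1 = k1 / K_G448D
  rc <- initial_rates_from_constants(K_G448D = 5e5, K_NM = 2.5e6,
                                     k1_fixed = 3e9, kobs1 = 540)
  expect_equal(rc$k_m1, 6000)
  # K_NM/K_G448D = 5, kobs1 = 540 -> k2 = 450, k_m2 = 90
  expect_equal(rc$k2, 450)
  expect_equal(rc$k_m2, 90)
  # k2/k_m2 = 5, k_m3 = 4, kobs2 = 16.5 -> k3 = (16.5 - 4) * 6/5 = 15
  rc3 <- initial_rates_from_constants(5e5, 2.5e6, K_HM = 2.5e6 * 3.75,
                                      k1_fixed = 3e9, kobs1 = 540,
                                      kobs2 = 16.5,
                                      k_m3_from_dissociation = 4)
  expect_equal(rc3$k3, (16.5 - 4) * 6 / 5)
  expect_equal(rc3$k3, 15)
  # returned rates reproduce the K's and the relaxation relations
  Ks <- equilibrium_constants_from_rates(rc3, "final_state")
  expect_equal(Ks$K_G448D, 5e5)
  expect_equal(Ks$K_NM, 2.5e6)
  expect_equal(unname(relaxation_rates_approx(rc3)), c(540, 16.5))
  # inconsistent inputs are rejected, naming the violated relation
  expect_error(initial_rates_from_constants(5e5, 2e5, k1_fixed = 3e9,
                                            kobs1 = 540), "K_NM")
  expect_error(initial_rates_from_constants(5e5, 2.5e6, K_HM = 1e7,
                                            k1_fixed = 3e9, kobs1 = 540,
                                            kobs2 = 3,
                                            k_m3_from_dissociation = 4),
               "negative k3")
  expect_error(initial_rates_from_constants(5e5, 2.5e6, K_HM = 1e7,
                                            k1_fixed = 3e9, kobs1 = 10,
                                            kobs2 = 16.5,
                                            k_m3_from_dissociation = 4),
               "kobs1 must exceed kobs2")
})

test_that("pre-equilibrium relaxation rates match the worked arithmetic", {
  expect_equal(
    relaxation_rates_approx(rate_constants(3e9, 6000, 450, 90,
                                           variant = "two_step"))[["kobs1"]],
    540)
  expect_equal(
    relaxation_rates_approx(rate_constants(3e9, 6000, 450, 90,
                                           variant = "two_step"))[["kobs2"]],
    0)
  rc <- canonical_rates()
  expect_equal(relaxation_rates_approx(rc)[["kobs2"]], 15 * (5 / 6) + 4)
  # k_m2 = 0 limit: step-2 pre-equilibrium fully forward
  rc0 <- rate_constants(3e9, 6000, 500, 0, 15, 4)
  expect_equal(relaxation_rates_approx(rc0)[["kobs2"]], 19)
})

test_that("k3 from the thermodynamic cycle matches the closure", {
  rc <- rate_constants(3e9, 6000, 500, 100, k3 = 0, k_m3 = 4)
  expect_equal(derive_k3_from_equilibrium(4e6, rc),
               4e6 * 6000 * 100 * 4 / (3e9 * 500))
  expect_equal(derive_k3_from_equilibrium(4e6, rc), 6.4)
  expect_equal(derive_k3_from_equilibrium(8e6, rc),
               2 * derive_k3_from_equilibrium(4e6, rc))
  # consistency with K_HM = K1 K2 K3 inverted for k3
  k3 <- derive_k3_from_equilibrium(4e6, rc)
  K_HM <- (rc$k1 / rc$k_m1) * (rc$k2 / rc$k_m2) * (k3 / rc$k_m3)
  expect_equal(K_HM, 4e6)
  expect_error(derive_k3_from_equilibrium(4e6,
    rate_constants(0, 6000, 500, 100, 0, 4)), "denominator")
})

test_that("the bimolecular lower bound is kobs_max / P_min", {
  expect_equal(k1_lower_bound(1000, 2e-6), 5e8)
  expect_equal(k1_lower_bound(1000, 1, units = "uM"), 1e9)
  expect_warning(b0 <- k1_lower_bound(0, 2e-6), "degenerate")
  expect_equal(b0, 0)
  expect_error(k1_lower_bound(1000, 0), "positive")
})

test_that("equilibrium state matches an independent root-solve oracle", {
  # binding-only worked example: K1 = 5e5 M^-1, 10 + 20 uM -> ~85% bound
  rc1 <- rate_constants(3e9, 6000, variant = "binding_only")
  eq <- equilibrium_state(rc1, Nt = 10, Pt = 20)
  frac <- eq[["NPns"]] / 10
  expect_gt(frac, 0.80)
  oracle <- equilibrium_oracle(rc1, 10, 20)
  expect_equal(frac, oracle[["NPns"]] / 10, tolerance = 1e-9)
  # blocked step 2 leaves downstream species empty
  rc_blocked <- rate_constants(3e9, 6000, 0, 100, 0, 4)
  eqb <- equilibrium_state(rc_blocked, 0.3, 7.5)
  expect_equal(unname(eqb[c("NPfl", "NPst")]), c(0, 0))
  # detailed balance of the unimolecular steps: population ratios equal K2, K3
  rc <- rate_constants(3e9, 6000, 500, 100, 500 * 3.75 / 5, 100,
                       variant = "three_step")  # K2 = 5, K3 = 3.75
  for (conc in list(c(0.3, 7.5), c(5, 2))) {
    eq3 <- equilibrium_state(rc, conc[1], conc[2])
    expect_equal(eq3[["NPfl"]] / eq3[["NPns"]], 5, tolerance = 1e-10)
    expect_equal(eq3[["NPst"]] / eq3[["NPfl"]], 3.75, tolerance = 1e-10)
  }
  # molar units round-trip
  eqM <- equilibrium_state(rc1, 10e-6, 20e-6, units = "M")
  expect_equal(unname(eqM), unname(eq) * 1e-6, tolerance = 1e-12)
})

test_that("time courses conserve mass, stay nonnegative and reach equilibrium", {
  rc <- canonical_rates()
  tg <- 10^seq(-5, 0, length.out = 120)
  tc <- simulate_timecourse(rc, Nt = 0.3, Pt = 7.5, t_grid = tg)
  dup_tot <- tc$N + tc$NPns + tc$NPfl + tc$NPst
  pro_tot <- tc$P + tc$NPns + tc$NPfl + tc$NPst
  expect_lt(max(abs(dup_tot - 0.3)) / 0.3, 1e-6)
  expect_lt(max(abs(pro_tot - 7.5)) / 7.5, 1e-6)
  expect_true(all(as.matrix(tc[-1]) >= 0))
  # long-time state agrees with the closed-form equilibrium and with the
  # independent oracle to < 0.1% relative
  eq <- equilibrium_state(rc, 0.3, 7.5)
  oracle <- equilibrium_oracle(rc, 0.3, 7.5)
  final <- unlist(tc[nrow(tc), c("N", "P", "NPns", "NPfl", "NPst")])
  expect_lt(max(abs(final - eq) / pmax(eq, 1e-12)), 1e-3)
  expect_lt(max(abs(final - oracle) / pmax(oracle, 1e-12)), 1e-3)
})

test_that("degenerate time courses behave as closed forms dictate", {
  rc <- canonical_rates()
  tg <- seq(0.001, 1, length.out = 50)
  # no protein, no binding
  tc0 <- simulate_timecourse(rc, Nt = 0.3, Pt = 0, t_grid = tg)
  expect_equal(tc0$N, rep(0.3, 50), tolerance = 1e-9)
  expect_equal(max(tc0$NPns, tc0$NPfl, tc0$NPst), 0, tolerance = 1e-12)
  # frozen dynamics: all six rates zero
  frozen <- rate_constants(0, 0, 0, 0, 0, 0)
  y0 <- c(N = 0.1, P = 0.2, NPns = 0.05, NPfl = 0.02, NPst = 0.01)
  tcf <- simulate_timecourse(frozen, Nt = 0.18, Pt = 0.28, t_grid = tg,
                             initial = y0)
  for (sp in names(y0)) {
    expect_equal(tcf[[sp]], rep(unname(y0[[sp]]), 50), tolerance = 1e-10)
  }
  expect_error(simulate_timecourse(rc, 0.3, 7.5, t_grid = c(1, 1)),
               "strictly increasing")
  expect_error(simulate_timecourse(rc, -0.3, 7.5, t_grid = tg),
               "nonnegative")
})

test_that("analytic step-1 pre-equilibration starts from the encounter equilibrium", {
  rc <- canonical_rates()
  tg <- c(1e-6, 1e-5)
  tc <- simulate_timecourse(rc, 0.3, 7.5, t_grid = tg,
                            initial = "step1_equilibrium")
  rc1 <- rate_constants(rc$k1, rc$k_m1, variant = "binding_only")
  eq1 <- equilibrium_state(rc1, 0.3, 7.5)
  # at t ~ 1 us the encounter pool is at its pre-equilibrated level and
  # only ~ k2 * NPns * t has leaked into the flipped state
  expect_equal(tc$NPns[1], eq1[["NPns"]], tolerance = 1e-3)
  expect_lt(tc$NPfl[1], rc$k2 * eq1[["NPns"]] * 2e-6)
})

test_that("exact relaxation rates reduce to textbook forms", {
  # one-step relaxation: single rate k1 (N_eq + P_eq) + k_m1
  rc1 <- rate_constants(3e9, 6000, variant = "binding_only")
  eq <- equilibrium_state(rc1, 0.3, 7.5)
  lam <- relaxation_rates_exact(rc1, 0.3, 7.5)
  expect_length(lam, 1)
  expect_equal(lam[1],
               rc1$k1 * 1e-6 * (eq[["N"]] + eq[["P"]]) + rc1$k_m1,
               tolerance = 1e-8)
  # two-step: slowest exact rate approaches k2 + k_m2 as k1 Pt grows
  rc2 <- rate_constants(3e9, 6000, 450, 90, variant = "two_step")
  lam_lo <- relaxation_rates_exact(rc2, 0.3, 50)
  lam_hi <- relaxation_rates_exact(rc2, 0.3, 5000)
  k21 <- relaxation_rates_approx(rc2)[["kobs1"]]
  expect_lt(abs(lam_hi[2] - k21) / k21,
            abs(lam_lo[2] - k21) / k21)
  expect_equal(lam_hi[2], k21, tolerance = 2e-3)
  # multiplicity attribute present and summing to the count
  expect_equal(sum(attr(lam_hi, "multiplicity")), length(lam_hi))
})

test_that("pre-equilibrium rates match exact eigenvalues under timescale separation", {
  # randomized sweep inside the reported ranges, with saturating protein so
  # that the bimolecular pre-equilibrium lies far to the bound side
  # (K1 * P_eq >= 10), plus the stated rate separations
  set.seed(101)
  n_ok <- 0
  worst <- 0
  for (i in 1:120) {
    rc <- rate_constants(3e9, 6000, runif(1, 400, 550), runif(1, 80, 110),
                         runif(1, 14, 35), runif(1, 3, 18))
    Pt <- runif(1, 25, 120)
    approx_k <- relaxation_rates_approx(rc)
    eq <- equilibrium_state(rc, 0.3, Pt)
    K1P <- rc$k1 * 1e-6 / rc$k_m1 * eq[["P"]]
    sep1 <- rc$k1 * 1e-6 * eq[["P"]] >= 10 * approx_k[["kobs1"]]
    sep2 <- approx_k[["kobs1"]] >= 10 * approx_k[["kobs2"]]
    if (!(sep1 && sep2 && K1P >= 10)) next
    n_ok <- n_ok + 1
    lam <- relaxation_rates_exact(rc, 0.3, Pt)
    err1 <- abs(lam[2] - approx_k[["kobs1"]]) / approx_k[["kobs1"]]
    err2 <- abs(lam[3] - approx_k[["kobs2"]]) / approx_k[["kobs2"]]
    worst <- max(worst, err1, err2)
  }
  expect_gte(n_ok, 100)
  expect_lt(worst, 0.10)
})

test_that("rate-constant configs round-trip through YAML", {
  rc <- canonical_rates()
  path <- tempfile(fileext = ".yaml")
  write_rate_constants(rc, path, convention = "final_state")
  rc2 <- read_rate_constants(path)
  expect_equal(unclass(rc2)[1:7], unclass(rc)[1:7])
  expect_equal(attr(rc2, "convention"), "final_state")
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(k1 = 3e9), bad)
  expect_error(read_rate_constants(bad), "missing keys")
})
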