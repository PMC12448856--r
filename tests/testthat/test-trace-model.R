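test_that("fluorescence is the response-weighted sum of duplex species", {
  rc <- canonical_rates()
  tg <- 10^seq(-4, 0, length.out = 80)
  tc <- simulate_timecourse(rc, 0.3, 7.5, t_grid = tg)
  # equal responses + conservation -> constant trace
  f_eq <- predict_fluorescence_trace(tc, species_responses(2, 2, 2, 2))
  expect_equal(f_eq, rep(2 * 0.3, length(tg)), tolerance = 1e-6)
  # all duplex free -> I0 * Nt
  tc0 <- simulate_timecourse(rc, 0.3, 0, t_grid = tg)
  f0 <- predict_fluorescence_trace(tc0, species_responses(1))
  expect_equal(f0, rep(0.3, length(tg)), tolerance = 1e-8)
  # full conversion to the stabilized complex rises 5.5-fold over free
  resp <- species_responses(I0 = 1, Ins = 1.25, Ifl = 2.5, Ist = 5.5)
  fake <- structure(data.frame(time = c(0, 1), N = c(0.3, 0), P = c(5, 4.7),
                               NPns = 0, NPfl = 0, NPst = c(0, 0.3)),
                    class = c("timecourse", "data.frame"))
  f <- predict_fluorescence_trace(fake, resp)
  expect_equal(f[2] / f[1], 5.5)
})

test_that("fluorescence is invariant under response rescaling with inverse gain", {
  rc <- canonical_rates()
  tc <- simulate_timecourse(rc, 0.3, 7.5,
                            t_grid = 10^seq(-4, 0, length.out = 40))
  resp <- species_responses(1, 1.25, 2.5, 5.5)
  gain <- 3.7
  resp_scaled <- species_responses(gain * 1, gain * 1.25, gain * 2.5,
                                   gain * 5.5)
  expect_equal(predict_fluorescence_trace(tc, resp_scaled) / gain,
               predict_fluorescence_trace(tc, resp))
})

test_that("the instrument model samples, discards the dead time, and seeds noise", {
  instr <- instrument_model(dead_time = 2.7e-3, regimes = "dense_early",
                            noise_sd = 0)
  ideal <- function(t) 1 - exp(-50 * t)
  tr <- apply_instrument(ideal, instr)
  expect_gte(tr$time[1], 2.7e-3)
  expect_lte(nrow(tr), 19000)
  expect_equal(tr$intensity, ideal(tr$time))  # noiseless sampling is exact
  # both acquisition regimes represented
  expect_gt(sum(tr$time <= 0.1), 5000)
  expect_gt(sum(tr$time > 0.1), 8000)
  # fixed seed reproduces the identical noise realization
  instr_n <- instrument_model(regimes = "balanced", noise_sd = 0.01)
  t1 <- apply_instrument(ideal, instr_n, seed = 42)
  t2 <- apply_instrument(ideal, instr_n, seed = 42)
  t3 <- apply_instrument(ideal, instr_n, seed = 43)
  expect_identical(t1$intensity, t2$intensity)
  expect_false(identical(t1$intensity, t3$intensity))
  # trace input not covering the span is rejected
  expect_error(apply_instrument(data.frame(time = c(0, 0.5),
                                           intensity = c(0, 1)), instr),
               "span")
  expect_error(instrument_model(dead_time = 0), "positive")
  expect_error(instrument_model(regimes = list(c(100, 0, 0.2),
                                               c(100, 0.1, 1))),
               "non-overlapping")
})

test_that("block averaging reduces by group with a short trailing block", {
  tr <- kinetic_trace(1:8, c(1, 3, 5, 7, 2, 4, 6, 8))
  r <- reduce_by_group(tr, 4)
  expect_equal(nrow(r), 2)
  expect_equal(r$time, c(2.5, 6.5))
  expect_equal(r$intensity, c(4, 5))
  expect_identical(reduce_by_group(tr, 1), tr)
  # constant trace stays constant at any group size
  trc <- kinetic_trace(1:10, rep(2.5, 10))
  expect_true(all(reduce_by_group(trc, 3)$intensity == 2.5))
  # trailing remainder: 10 points by 4 -> blocks of 4, 4, 2
  expect_equal(nrow(reduce_by_group(trc, 4)), 3)
  expect_error(reduce_by_group(tr, 0), "positive integer")
})

test_that("competition-chase traces decay at the bound-chain escape rate", {
  rc <- canonical_rates()
  resp <- species_responses(1, 1.25, 2.5, 5.5)
  # no trap -> no net dissociation: flat trace
  flat <- predict_dissociation_trace(rc, resp, Nt_pre = 0.6, Pt_pre = 1.5,
                                     competitor_uM = 0)
  expect_lt(diff(range(flat$intensity)) / flat$intensity[1], 1e-6)
  # effective trap: decay is mono-exponential at the slowest eigenvalue of
  # the bound-state chain with rebinding blocked (independent oracle)
  tr <- predict_dissociation_trace(rc, resp, Nt_pre = 0.6, Pt_pre = 1.5,
                                   competitor_uM = 750)
  fit <- fit_exponential(tr, n_phases = 1)
  chain <- matrix(c(-(rc$k_m1 + rc$k2), rc$k_m2, 0,
                    rc$k2, -(rc$k_m2 + rc$k3), rc$k_m3,
                    0, rc$k3, -rc$k_m3), 3, 3, byrow = TRUE)
  lam_slow <- min(abs(Re(eigen(chain, only.values = TRUE)$values)))
  expect_lt(abs(fit$kobs1 - lam_slow) / lam_slow, 0.15)
  # traces are monotonically nonincreasing when the trap is effective
  set.seed(5)
  for (i in 1:5) {
    rci <- rate_constants(3e9, 6000, runif(1, 400, 550), runif(1, 80, 110),
                          runif(1, 14, 35), runif(1, 3, 18))
    tri <- predict_dissociation_trace(rci, resp, 0.6, 1.5,
                                      competitor_uM = 750)
    expect_true(all(diff(tri$intensity) <= 1e-9))
  }
  # ineffective competition warns
  expect_warning(predict_dissociation_trace(rc, resp, 0.6, 1.5,
                                            competitor_uM = 750,
                                            trap_rate = 1e4),
                 "not effective")
})

test_that("two-step complexes dissociate roughly an order of magnitude faster", {
  resp <- species_responses(1, 1.25, 2.5, 5.5)
  rc_hm <- canonical_rates()
  rc_nm <- rate_constants(3e9, 6000, 500, 100, variant = "two_step")
  k_hm <- fit_exponential(predict_dissociation_trace(rc_hm, resp, 0.6, 1.5),
                          n_phases = 1)$kobs1
  k_nm <- fit_exponential(predict_dissociation_trace(rc_nm, resp, 0.6, 3.0),
                          n_phases = 1)$kobs1
  expect_gt(k_nm / k_hm, 5)
  # insensitivity to the competitor defaults at large excess: halving the
  # assumed site size or trap constant barely moves the fitted rate
  k_hm2 <- fit_exponential(
    predict_dissociation_trace(rc_hm, resp, 0.6, 1.5, site_size = 24,
                               trap_rate = 1.5e9), n_phases = 1)$kobs1
  expect_lt(abs(k_hm2 - k_hm) / k_hm, 0.02)
})

test_that("kinetic trace files round-trip with their metadata", {
  tr <- kinetic_trace(seq(0.003, 1, length.out = 30),
                      rnorm(30, 1), duplex = "HM", position = "7",
                      protein = "SRA", Nt = 0.3, Pt = 7.5,
                      kind = "association")
  path <- tempfile(fileext = ".csv")
  write_trace(tr, path)
  tr2 <- read_trace(path)
  expect_equal(tr2$time, tr$time, tolerance = 1e-9)
  expect_equal(tr2$intensity, tr$intensity, tolerance = 1e-9)
  m <- attributes(tr2)
  expect_equal(m$duplex, "HM")
  expect_equal(m$position, "7")
  expect_equal(m$Pt, 7.5)
  expect_equal(m$kind, "association")
  expect_error(kinetic_trace(c(1, 1), c(0, 0)), "increasing")
})
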