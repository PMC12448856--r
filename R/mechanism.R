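#' Elementary rate constants of the base-flipping scheme
#'
#' Container for the six elementary rate constants of the sequential
#' mechanism
#' \deqn{N + P \rightleftharpoons NP_{ns} \rightleftharpoons NP_{fl}
#'       \rightleftharpoons NP_{st}}
#' where `N` is the free (labelled) DNA duplex, `P` the free protein,
#' `NPns` the initial non-specific encounter complex, `NPfl` the
#' base-flipped intermediate and `NPst` the final stabilized complex.
#'
#' The bimolecular association constant `k1` is given in M^-1 s^-1 (the
#' unit in which such constants are reported); all other constants are
#' first-order, in s^-1.  The mechanism variant restricts which steps are
#' active: `"three_step"` (hemi-methylated duplex + wild-type protein),
#' `"two_step"` (non-methylated duplex; forces `k3 = k_m3 = 0`) and
#' `"binding_only"` (flipping-incompetent mutant, e.g. SRA G448D; forces
#' `k2 = k_m2 = k3 = k_m3 = 0`).
#'
#' @param k1 bimolecular association rate constant, M^-1 s^-1.
#' @param k_m1 dissociation of the encounter complex, s^-1.
#' @param k2,k_m2 forward/backward base flipping, s^-1.
#' @param k3,k_m3 forward/backward conformational rearrangement, s^-1.
#' @param variant mechanism variant, one of `"three_step"`, `"two_step"`,
#'   `"binding_only"`.
#' @return An object of class `rate_constants`.
#' @examples
#' rc <- rate_constants(k1 = 3e9, k_m1 = 6000, k2 = 500, k_m2 = 100,
#'                      k3 = 15, k_m3 = 4)
#' equilibrium_constants_from_rates(rc)
#' @export
rate_constants <- function(k1, k_m1, k2 = 0, k_m2 = 0, k3 = 0, k_m3 = 0,
                           variant = c("three_step", "two_step",
                                       "binding_only")) {
  variant <- match.arg(variant)
  vals <- c(k1 = k1, k_m1 = k_m1, k2 = k2, k_m2 = k_m2, k3 = k3, k_m3 = k_m3)
  if (any(!is.finite(vals))) {
    stop("all rate constants must be finite numbers", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("rate constants must be nonnegative; offending: ",
         paste(names(vals)[vals < 0], collapse = ", "), call. = FALSE)
  }
  if (variant == "two_step" && (k3 != 0 || k_m3 != 0)) {
    stop("two_step variant forces k3 = k_m3 = 0", call. = FALSE)
  }
  if (variant == "binding_only" &&
      (k2 != 0 || k_m2 != 0 || k3 != 0 || k_m3 != 0)) {
    stop("binding_only variant forces k2 = k_m2 = k3 = k_m3 = 0",
         call. = FALSE)
  }
  structure(list(k1 = k1, k_m1 = k_m1, k2 = k2, k_m2 = k_m2,
                 k3 = k3, k_m3 = k_m3, variant = variant),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constants (", x$variant, " mechanism)\n", sep = "")
  cat(sprintf("  k1   = %.4g M^-1 s^-1   k_m1 = %.4g s^-1\n", x$k1, x$k_m1))
  if (x$variant != "binding_only") {
    cat(sprintf("  k2   = %.4g s^-1        k_m2 = %.4g s^-1\n", x$k2, x$k_m2))
  }
  if (x$variant == "three_step") {
    cat(sprintf("  k3   = %.4g s^-1        k_m3 = %.4g s^-1\n", x$k3, x$k_m3))
  }
  invisible(x)
}

# Which steps are active under a variant (step 1 always is).
active_steps <- function(variant) {
  switch(variant,
         three_step   = c(TRUE, TRUE, TRUE),
         two_step     = c(TRUE, TRUE, FALSE),
         binding_only = c(TRUE, FALSE, FALSE))
}

# Stepwise association constants in uM^-1 (K1) and dimensionless (K2, K3).
# Inactive steps contribute K = 0; an active step with zero backward rate
# has no finite equilibrium constant and is rejected.
stepwise_K <- function(rc, require_finite = TRUE) {
  act <- active_steps(rc$variant)
  back <- c(rc$k_m1, rc$k_m2, rc$k_m3)
  fwd <- c(rc$k1 * 1e-6, rc$k2, rc$k3)  # k1 rescaled to uM^-1 s^-1
  K <- numeric(3)
  for (i in 1:3) {
    if (!act[i]) next
    if (back[i] <= 0) {
      if (fwd[i] == 0 && i > 1) next  # step formally active but frozen
      if (require_finite) {
        stop("equilibrium constant of step ", i,
             " undefined: backward rate is zero", call. = FALSE)
      }
      K[i] <- Inf
    } else {
      K[i] <- fwd[i] / back[i]
    }
  }
  K
}

#' Equilibrium association constants implied by the rate constants
#'
#' Two closure conventions relate the stepwise constants
#' `K1 = k1/k_m1`, `K2 = k2/k_m2`, `K3 = k3/k_m3` to the measurable
#' association constants of the binding-only mutant (`K_G448D`), the
#' non-methylated duplex (`K_NM`) and the hemi-methylated duplex (`K_HM`):
#'
#' * `"final_state"` equates each measured constant with the product of
#'   stepwise constants up to the final species of that mechanism:
#'   `K_G448D = K1`, `K_NM = K1 K2`, `K_HM = K1 K2 K3`.
#' * `"total_bound"` counts every bound species, which is what an
#'   equilibrium titration physically reports:
#'   `K_NM = K1 (1 + K2)`, `K_HM = K1 (1 + K2 + K2 K3)`.
#'
#' The ratio of the two conventions for the hemi-methylated duplex,
#' `(1 + K2 + K2 K3)/(K2 K3)`, is returned alongside so the discrepancy is
#' always quantified.
#'
#' @param rc a [rate_constants] object (all backward rates of active steps
#'   must be positive).
#' @param convention `"final_state"` (default) or `"total_bound"`.
#' @return A list of class `equilibrium_constants` with elements
#'   `K_G448D`, `K_NM`, `K_HM` (M^-1), the `convention`, the stepwise
#'   constants `K1` (M^-1), `K2`, `K3`, and `convention_ratio_HM`.
#' @export
equilibrium_constants_from_rates <- function(rc,
                                             convention = c("final_state",
                                                            "total_bound")) {
  convention <- match.arg(convention)
  stopifnot(inherits(rc, "rate_constants"))
  K <- stepwise_K(rc)                  # K1 in uM^-1
  K1_M <- K[1] * 1e6                   # back to M^-1 for reporting
  K2 <- K[2]; K3 <- K[3]
  if (convention == "final_state") {
    out <- list(K_G448D = K1_M, K_NM = K1_M * K2, K_HM = K1_M * K2 * K3)
  } else {
    out <- list(K_G448D = K1_M,
                K_NM = K1_M * (1 + K2),
                K_HM = K1_M * (1 + K2 + K2 * K3))
  }
  ratio <- if (K2 > 0 && K3 > 0) (1 + K2 + K2 * K3) / (K2 * K3) else NA_real_
  structure(c(out, list(convention = convention, K1 = K1_M, K2 = K2, K3 = K3,
                        convention_ratio_HM = ratio)),
            class = "equilibrium_constants")
}

#' @export
print.equilibrium_constants <- function(x, ...) {
  cat("Equilibrium association constants (", x$convention, " convention)\n",
      sep = "")
  cat(sprintf("  K_G448D = %.4g M^-1\n  K_NM    = %.4g M^-1\n  K_HM    = %.4g M^-1\n",
              x$K_G448D, x$K_NM, x$K_HM))
  if (is.finite(x$convention_ratio_HM)) {
    cat(sprintf("  total-bound/final-state ratio for K_HM: %.4g\n",
                x$convention_ratio_HM))
  }
  invisible(x)
}

#' Initial rate-constant estimates from measured equilibrium and observed rates
#'
#' Inverts the closure relations and the relaxation-rate expressions to turn
#' titration-derived association constants and exponential-fit observed rates
#' into a full starting set of elementary rate constants for the global fit
#' (final-state convention):
#' `k_m1 = k1/K_G448D`; `k2 + k_m2 = kobs1` with `k2/k_m2 = K_NM/K_G448D`;
#' `k_m3` taken from the competition-chase dissociation rate; and
#' `k3 = (kobs2 - k_m3)(1 + K2)/K2`.
#'
#' @param K_G448D,K_NM,K_HM measured association constants, M^-1.  `K_HM`
#'   may be `NA` for a two-step (non-methylated) problem.
#' @param k1_fixed the fixed bimolecular rate constant, M^-1 s^-1.
#' @param kobs1,kobs2 observed rate constants of the fast and slow resolvable
#'   phases, s^-1 (`kobs2` may be `NA` for a two-step problem).
#' @param k_m3_from_dissociation dissociation rate constant measured in the
#'   competition-chase experiment, s^-1 (ignored for two-step problems).
#' @return A [rate_constants] object (variant `"three_step"` when `kobs2`
#'   and `k_m3_from_dissociation` are supplied, else `"two_step"`).
#' @export
initial_rates_from_constants <- function(K_G448D, K_NM, K_HM = NA,
                                         k1_fixed = 3e9,
                                         kobs1, kobs2 = NA,
                                         k_m3_from_dissociation = NA) {
  if (any(c(K_G448D, K_NM, k1_fixed, kobs1) <= 0, na.rm = TRUE)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  k_m1 <- k1_fixed / K_G448D
  K2 <- K_NM / K_G448D
  if (K2 <= 0) stop("K_NM must exceed zero", call. = FALSE)
  if (K2 < 1) {
    stop("inconsistent inputs: K_NM < K_G448D implies k2 < k_m2 with ",
         "K2 = K_NM/K_G448D < 1; check the titration constants",
         call. = FALSE)
  }
  # solve k2 + k_m2 = kobs1, k2/k_m2 = K2
  k_m2 <- kobs1 / (1 + K2)
  k2 <- kobs1 - k_m2
  three <- is.finite(kobs2) && is.finite(k_m3_from_dissociation)
  if (three) {
    if (kobs2 <= 0 || k_m3_from_dissociation <= 0) {
      stop("kobs2 and k_m3 must be positive", call. = FALSE)
    }
    if (kobs1 <= kobs2) {
      stop("inconsistent inputs: kobs1 must exceed kobs2 ",
         "(fast phase slower than slow phase)", call. = FALSE)
    }
    k_m3 <- k_m3_from_dissociation
    if (kobs2 <= k_m3) {
      stop("inconsistent inputs: kobs2 <= k_m3 implies a negative k3 in ",
           "kobs2 = k3*K2/(1+K2) + k_m3", call. = FALSE)
    }
    k3 <- (kobs2 - k_m3) * (1 + K2) / K2
    rate_constants(k1_fixed, k_m1, k2, k_m2, k3, k_m3, variant = "three_step")
  } else {
    rate_constants(k1_fixed, k_m1, k2, k_m2, variant = "two_step")
  }
}

#' Approximate observed relaxation rates (pre-equilibrium analysis)
#'
#' The fast and slow resolvable relaxation rates of the scheme, under the
#' assumptions that the bimolecular step equilibrates within the instrument
#' dead time and that step 2 is much faster than step 3:
#' \deqn{k_{obs1} = k_2 + k_{-2}, \qquad
#'       k_{obs2} = \frac{k_3\,k_2/k_{-2}}{1 + k_2/k_{-2}} + k_{-3}.}
#' When `k_m2 = 0` with `k3 > 0` the pre-equilibrium of step 2 lies fully
#' forward and the limit `kobs2 = k3 + k_m3` is returned.
#'
#' @param rc a [rate_constants] object.
#' @return Named numeric vector `c(kobs1, kobs2)` in s^-1.
#' @seealso [relaxation_rates_exact()] for the eigenvalue-based check of
#'   this approximation.
#' @export
relaxation_rates_approx <- function(rc) {
  stopifnot(inherits(rc, "rate_constants"))
  kobs1 <- rc$k2 + rc$k_m2
  kobs2 <- if (rc$k3 == 0 && rc$k_m3 == 0) {
    0
  } else if (rc$k_m2 == 0) {
    rc$k3 + rc$k_m3  # step-2 pre-equilibrium fully forward
  } else {
    K2 <- rc$k2 / rc$k_m2
    rc$k3 * K2 / (1 + K2) + rc$k_m3
  }
  c(kobs1 = kobs1, kobs2 = kobs2)
}

#' Forward rearrangement rate from the overall equilibrium constant
#'
#' When the slow kinetic phase is spectroscopically silent (as for a label
#' position insensitive to the rearrangement), `k3` cannot be fitted
#' directly but follows from the thermodynamic cycle:
#' \deqn{k_3 = K_a\,k_{-1}\,k_{-2}\,k_{-3}/(k_1\,k_2)}
#' i.e. the overall association constant `Ka` (final-state convention,
#' `Ka = K1 K2 K3`) inverted for `k3`.
#'
#' @param Ka_HM overall association constant of the hemi-methylated duplex,
#'   M^-1.
#' @param rates a [rate_constants] object supplying `k1`, `k_m1`, `k2`,
#'   `k_m2` and `k_m3` (its `k3` entry is ignored).
#' @return `k3` in s^-1.
#' @export
derive_k3_from_equilibrium <- function(Ka_HM, rates) {
  stopifnot(inherits(rates, "rate_constants"))
  if (Ka_HM <= 0) stop("Ka_HM must be positive", call. = FALSE)
  den <- rates$k1 * rates$k2
  if (den <= 0) stop("k1*k2 must be positive (zero denominator)",
                     call. = FALSE)
  num <- rates$k_m1 * rates$k_m2 * rates$k_m3
  if (num <= 0) stop("all backward rates must be positive", call. = FALSE)
  Ka_HM * num / den
}

#' Lower bound on the bimolecular association rate constant
#'
#' The largest observed rate measurable on the instrument at the lowest
#' protein concentration used bounds the bimolecular rate constant from
#' below: `k1 >= kobs_max / P_min`.
#'
#' @param kobs_max largest measurable observed rate, s^-1.
#' @param P_min lowest protein concentration used, in molar by default.
#' @param units concentration unit of `P_min`: `"M"` or `"uM"`.
#' @return Lower bound on `k1` in M^-1 s^-1.
#' @examples
#' k1_lower_bound(1000, 2e-6)          # 5e8 M^-1 s^-1
#' k1_lower_bound(1000, 2, units = "uM")
#' @export
k1_lower_bound <- function(kobs_max, P_min, units = c("M", "uM")) {
  units <- match.arg(units)
  if (P_min <= 0) stop("P_min must be positive", call. = FALSE)
  if (kobs_max < 0) stop("kobs_max must be nonnegative", call. = FALSE)
  P_M <- if (units == "uM") P_min * 1e-6 else P_min
  bound <- kobs_max / P_M
  if (kobs_max == 0) {
    warning("kobs_max = 0: degenerate bound of zero", call. = FALSE)
  }
  bound
}
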