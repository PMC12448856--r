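# Concentration unit handling: the solver works in micromolar so that the
# bimolecular step (k1*Pt ~ 2e4 s^-1) and the slow rearrangement (~4 s^-1)
# are decently conditioned; user-facing concentrations default to uM and
# may be given in M.
to_uM <- function(x, units = c("uM", "M")) {
  units <- match.arg(units)
  if (units == "M") x * 1e6 else x
}

species_names <- c("N", "P", "NPns", "NPfl", "NPst")

# parms vector for the compiled RHS; k_trap is the pseudo-first-order sink
# on free protein used in competition-chase experiments.
ode_parms <- function(rc, k_trap = 0) {
  c(rc$k1 * 1e-6, rc$k_m1, rc$k2, rc$k_m2, rc$k3, rc$k_m3, k_trap)
}

#' Equilibrium state of the base-flipping scheme
#'
#' Closed-form equilibrium of the sequential mechanism.  With stepwise
#' constants `K1` (per uM), `K2`, `K3`, every bound species is proportional
#' to the free-species product `N*P`, so total bound
#' `B = S*N*P` with `S = K1 (1 + K2 + K2 K3)` (terms dropped for inactive
#' steps), and `B` is the smaller root of
#' `S B^2 - (S (Nt + Pt) + 1) B + S Nt Pt = 0`.
#'
#' @param rc a [rate_constants] object.  Backward rates of all active steps
#'   with nonzero forward rates must be positive.
#' @param Nt,Pt total duplex and protein concentrations.
#' @param units concentration unit of `Nt`/`Pt` (`"uM"` default or `"M"`).
#' @return Named numeric vector over species `N, P, NPns, NPfl, NPst`
#'   (same unit as the input, i.e. uM unless `units = "M"`, in which case
#'   molar is returned).
#' @export
equilibrium_state <- function(rc, Nt, Pt, units = c("uM", "M")) {
  units <- match.arg(units)
  stopifnot(inherits(rc, "rate_constants"))
  if (Nt < 0 || Pt < 0) stop("Nt and Pt must be nonnegative", call. = FALSE)
  Nt_u <- to_uM(Nt, units); Pt_u <- to_uM(Pt, units)
  K <- stepwise_K(rc)  # errors if an active step has zero backward rate
  K1 <- K[1]; K2 <- K[2]; K3 <- K[3]
  S <- K1 * (1 + K2 + K2 * K3)
  if (S == 0 || Nt_u == 0 || Pt_u == 0) {
    B <- 0
  } else {
    b <- S * (Nt_u + Pt_u) + 1
    disc <- b^2 - 4 * S^2 * Nt_u * Pt_u
    B <- (b - sqrt(max(disc, 0))) / (2 * S)
    B <- min(B, Nt_u, Pt_u)  # guard float excursions
  }
  N <- Nt_u - B; P <- Pt_u - B
  NPns <- K1 * N * P
  NPfl <- K2 * NPns
  NPst <- K3 * NPfl
  out <- c(N = N, P = P, NPns = NPns, NPfl = NPfl, NPst = NPst)
  if (units == "M") out * 1e-6 else out
}

# Equilibrium of step 1 alone (used for optional analytic pre-equilibration
# of the encounter step before t = 0).
step1_equilibrium <- function(rc, Nt_u, Pt_u) {
  rc1 <- rate_constants(rc$k1, rc$k_m1, variant = "binding_only")
  eq <- equilibrium_state(rc1, Nt_u, Pt_u)
  c(N = unname(eq["N"]), P = unname(eq["P"]), NPns = unname(eq["NPns"]),
    NPfl = 0, NPst = 0)
}

#' Simulate a concentration time course of the base-flipping scheme
#'
#' Integrates the mass-action ODE system with a stiff implicit solver
#' ([deSolve::lsoda] with analytic Jacobian, rtol 1e-9, atol 1e-12 uM).
#'
#' @param rc a [rate_constants] object.
#' @param Nt,Pt total duplex and protein concentrations (uM by default).
#' @param t_grid strictly increasing time grid, seconds, at least 2 points.
#'   A leading `t = 0` is added internally if absent.
#' @param initial initial condition: `"unmixed"` (all duplex free, all
#'   protein free — the stopped-flow association start), `"step1_equilibrium"`
#'   (the encounter step analytically pre-equilibrated before t = 0,
#'   mimicking a bimolecular step fully equilibrated within the instrument
#'   dead time), or a named numeric vector over
#'   `N, P, NPns, NPfl, NPst` (uM).
#' @param units concentration unit of `Nt`, `Pt` and a numeric `initial`.
#' @param k_trap pseudo-first-order sink rate on free protein, s^-1
#'   (competition-chase; 0 for association).
#' @return A data.frame with column `time` and one column per species, in
#'   uM, of class `c("timecourse", "data.frame")`, with attributes `Nt`,
#'   `Pt` (uM) and `rates`.
#' @export
simulate_timecourse <- function(rc, Nt, Pt, t_grid,
                                initial = c("unmixed", "step1_equilibrium"),
                                units = c("uM", "M"), k_trap = 0) {
  units <- match.arg(units)
  stopifnot(inherits(rc, "rate_constants"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing with at least 2 points",
         call. = FALSE)
  }
  if (Nt < 0 || Pt < 0) stop("Nt and Pt must be nonnegative", call. = FALSE)
  Nt_u <- to_uM(Nt, units); Pt_u <- to_uM(Pt, units)

  if (is.character(initial)) {
    initial <- match.arg(initial)
    y0 <- if (initial == "unmixed") {
      c(N = Nt_u, P = Pt_u, NPns = 0, NPfl = 0, NPst = 0)
    } else {
      step1_equilibrium(rc, Nt_u, Pt_u)
    }
  } else {
    if (length(initial) != 5) {
      stop("numeric initial state must have 5 species", call. = FALSE)
    }
    y0 <- to_uM(as.numeric(initial), units)
    names(y0) <- species_names
    if (any(y0 < 0)) stop("initial concentrations must be nonnegative",
                          call. = FALSE)
  }

  times <- t_grid
  prepend <- times[1] > 0
  if (prepend) times <- c(0, times)
  sol <- deSolve::lsoda(y = y0, times = times, parms = ode_parms(rc, k_trap),
                        func = "flipkin_derivs", jacfunc = "flipkin_jac",
                        initfunc = "flipkin_initmod", dllname = "flipkin",
                        jactype = "fullusr", rtol = 1e-9, atol = 1e-12)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop(sprintf(paste0("stiff ODE integration failed (lsoda istate %d) ",
                        "near t = %.3g s; consider refining t_grid there"),
                 diagn[1], sol[nrow(sol), 1]), call. = FALSE)
  }
  out <- as.data.frame(sol)
  if (prepend) out <- out[-1, , drop = FALSE]
  rownames(out) <- NULL
  # clip tiny negative excursions within solver tolerance
  sp <- out[species_names]
  sp[sp < 0 & sp > -1e-9] <- 0
  out[species_names] <- sp
  structure(out, Nt = Nt_u, Pt = Pt_u, rates = rc, k_trap = k_trap,
            class = c("timecourse", "data.frame"))
}

#' Exact relaxation rates from the linearized mass-action system
#'
#' Linearizes the full mass-action system at its equilibrium point and
#' returns the magnitudes of the nonzero eigenvalues of the Jacobian,
#' sorted decreasing.  These are the exact relaxation rates against which
#' the pre-equilibrium approximation [relaxation_rates_approx()] can be
#' validated.  Conservation of total duplex and total protein contributes
#' null directions, which are removed by a relative magnitude threshold;
#' degenerate (repeated) nonzero eigenvalues are reported with their
#' multiplicity in the `"multiplicity"` attribute rather than collapsed.
#'
#' @inheritParams equilibrium_state
#' @return Numeric vector of relaxation rates in s^-1 (length 3, 2 or 1 for
#'   the three-, two- and one-step variants), sorted decreasing, with
#'   attribute `multiplicity`.
#' @export
relaxation_rates_exact <- function(rc, Nt, Pt, units = c("uM", "M")) {
  units <- match.arg(units)
  eq <- equilibrium_state(rc, Nt, Pt, units = units)
  eq_u <- to_uM(eq, units)
  k1u <- rc$k1 * 1e-6
  N <- eq_u["N"]; P <- eq_u["P"]
  J <- matrix(0, 5, 5, dimnames = list(species_names, species_names))
  J["N", ]    <- c(-k1u * P, -k1u * N,  rc$k_m1, 0, 0)
  J["P", ]    <- c(-k1u * P, -k1u * N,  rc$k_m1, 0, 0)
  J["NPns", ] <- c(k1u * P, k1u * N, -(rc$k_m1 + rc$k2), rc$k_m2, 0)
  J["NPfl", ] <- c(0, 0, rc$k2, -(rc$k_m2 + rc$k3), rc$k_m3)
  J["NPst", ] <- c(0, 0, 0, rc$k3, -rc$k_m3)
  ev <- eigen(J, only.values = TRUE)$values
  mag <- abs(Re(ev))
  keep <- mag > max(mag) * 1e-9
  rates <- sort(mag[keep], decreasing = TRUE)
  # group near-degenerate eigenvalues (relative spacing < 1e-7)
  mult <- integer(0); uniq <- numeric(0)
  for (r in rates) {
    if (length(uniq) && abs(r - uniq[length(uniq)]) <=
        1e-7 * max(r, uniq[length(uniq)])) {
      mult[length(mult)] <- mult[length(mult)] + 1L
    } else {
      uniq <- c(uniq, r); mult <- c(mult, 1L)
    }
  }
  structure(rates, multiplicity = mult)
}

#' Read or write rate constants as a structured config file
#'
#' Serializes a [rate_constants] object (plus the equilibrium-constant
#' convention in use) to a YAML mapping with keys `k1, k_m1, k2, k_m2, k3,
#' k_m3, variant, convention, units`, and back.  `units` records the
#' concentration unit in which `k1` is expressed (`"M"`, the default
#' reporting unit, or `"uM"`).
#'
#' @param rc a [rate_constants] object.
#' @param path file path.
#' @param convention equilibrium-constant convention to record.
#' @return `write_rate_constants` returns `path` invisibly;
#'   `read_rate_constants` returns a [rate_constants] object with attribute
#'   `convention`.
#' @export
write_rate_constants <- function(rc, path,
                                 convention = c("final_state",
                                                "total_bound")) {
  convention <- match.arg(convention)
  stopifnot(inherits(rc, "rate_constants"))
  yaml::write_yaml(list(k1 = rc$k1, k_m1 = rc$k_m1, k2 = rc$k2,
                        k_m2 = rc$k_m2, k3 = rc$k3, k_m3 = rc$k_m3,
                        variant = rc$variant, convention = convention,
                        units = "M"), path)
  invisible(path)
}

#' @rdname write_rate_constants
#' @export
read_rate_constants <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("k1", "k_m1", "variant")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("rate-constant config missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  units <- if (is.null(cfg$units)) "M" else cfg$units
  scale <- switch(units, M = 1, uM = 1e6,
                  stop("unknown units in config: ", units, call. = FALSE))
  num0 <- function(x) if (is.null(x)) 0 else x
  rc <- rate_constants(cfg$k1 * scale, cfg$k_m1, num0(cfg$k2), num0(cfg$k_m2),
                       num0(cfg$k3), num0(cfg$k_m3), variant = cfg$variant)
  attr(rc, "convention") <- if (is.null(cfg$convention)) "final_state" else
    cfg$convention
  rc
}
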