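#' Assemble a constrained global-fit problem from an ensemble of traces
#'
#' Prepares the simultaneous fit of the reaction scheme to association
#' traces of hemi-methylated (three-step) and non-methylated (two-step)
#' duplexes at several protein concentrations.  Following the experimental
#' protocol:
#'
#' * the free-duplex response is anchored as
#'   `I0 = mean(buffer-control intensity) / Nt` (a buffer-control trace is
#'   required — without it the gain is unidentifiable);
#' * bound-species responses are initialized from the steady-state
#'   fold changes;
#' * rate-constant starting values come from
#'   [initial_rates_from_constants()], i.e. from the titration association
#'   constants and the observed rates of a representative trace (fitted
#'   here with [fit_exponential()]), with `k1` fixed;
#' * the titration constants act as initial estimates only, not hard
#'   constraints: all rate constants except `k1` float in the fit.
#'
#' @param traces list of association [kinetic_trace] objects (each with
#'   `duplex` `"HM"` or `"NM"`, `Nt` and `Pt` metadata) plus at least one
#'   `kind = "buffer"` control trace.
#' @param titration_constants named list/vector with `K_G448D`, `K_NM` and
#'   (for three-step problems) `K_HM`, in M^-1.
#' @param steady_state_ratios named list/vector of response fold changes
#'   `Ins_over_I0`, `Ifl_over_I0`, `Ist_over_I0` used to initialize the
#'   bound-species responses.
#' @param k1_fixed fixed bimolecular rate constant, M^-1 s^-1.
#' @param k_m3_init optional starting value for `k_m3` from a
#'   competition-chase dissociation experiment, s^-1; when `NULL` it is
#'   derived from `kobs2` and the closure `K3 = K_HM/K_NM`.
#' @param variant_override force every trace to be modeled with this
#'   mechanism variant regardless of its duplex metadata (used e.g. to ask
#'   whether two-step data support a third step).
#' @return Object of class `global_fit_problem`.
#' @export
build_global_problem <- function(traces, titration_constants,
                                 steady_state_ratios =
                                   c(Ins_over_I0 = 1.25,
                                     Ifl_over_I0 = 2.5,
                                     Ist_over_I0 = 5.5),
                                 k1_fixed = 3e9,
                                 k_m3_init = NULL,
                                 variant_override = NULL) {
  stopifnot(is.list(traces), length(traces) > 0)
  kinds <- vapply(traces, function(x) attr(x, "kind"), character(1))
  buffers <- traces[kinds == "buffer"]
  assoc <- traces[kinds == "association"]
  if (!length(buffers)) {
    stop("missing buffer-control trace: the free-duplex response I0 ",
         "cannot be anchored", call. = FALSE)
  }
  if (!length(assoc)) stop("no association traces supplied", call. = FALSE)
  duplex <- vapply(assoc, function(x) attr(x, "duplex"), character(1))
  Pt <- vapply(assoc, function(x) attr(x, "Pt"), numeric(1))
  Nt <- vapply(assoc, function(x) attr(x, "Nt"), numeric(1))
  if (any(is.na(duplex)) || any(!duplex %in% c("HM", "NM"))) {
    stop("every association trace needs duplex metadata 'HM' or 'NM'",
         call. = FALSE)
  }
  if (max(table(duplex)) < 2) {
    stop("need at least 2 protein concentrations for one duplex type",
         call. = FALSE)
  }

  variant_of <- function(dup) {
    if (!is.null(variant_override)) variant_override
    else if (dup == "HM") "three_step" else "two_step"
  }
  variants <- vapply(duplex, variant_of, character(1))
  three <- any(variants == "three_step")

  # anchor I0 per duplex type from its buffer control (shared if only one)
  buf_dup <- vapply(buffers, function(x) attr(x, "duplex"), character(1))
  I0_of <- function(dup) {
    b <- buffers[buf_dup == dup]
    if (!length(b)) b <- buffers[1]
    mean(b[[1]]$intensity) / attr(b[[1]], "Nt")
  }
  I0 <- vapply(unique(duplex), I0_of, numeric(1))
  names(I0) <- unique(duplex)

  tc <- as.list(titration_constants)
  if (is.null(tc$K_G448D) || is.null(tc$K_NM)) {
    stop("titration_constants must supply K_G448D and K_NM", call. = FALSE)
  }
  if (three && is.null(tc$K_HM)) {
    stop("three-step problem needs K_HM in titration_constants",
         call. = FALSE)
  }

  # observed rates from a representative trace: the highest-concentration
  # trace of the most informative duplex present
  cand_idx <- if (three && any(duplex == "HM")) {
    which(duplex == "HM")[order(Pt[duplex == "HM"], decreasing = TRUE)]
  } else {
    order(Pt, decreasing = TRUE)
  }
  rep_fit <- NULL
  for (idx in cand_idx) {  # skip traces whose fast phase is unresolvable
    f <- fit_exponential(assoc[[idx]], n_phases = if (three) 2 else 1)
    if (is.null(rep_fit)) rep_fit <- f
    if (!"beyond time resolution" %in% f$flags) {
      rep_fit <- f
      break
    }
  }
  kobs1 <- rep_fit$kobs1
  if ("beyond time resolution" %in% rep_fit$flags) {
    # every candidate hit the resolution limit; clamp the start there
    kobs1 <- 1 / (2 * median(diff(assoc[[cand_idx[1]]]$time)))
  }
  kobs2 <- if (three) rep_fit$kobs2 else NA
  if (is.finite(kobs2) && kobs2 >= 0.9 * kobs1) kobs2 <- NA  # not resolved

  if (three) {
    K2 <- tc$K_NM / tc$K_G448D
    K3 <- tc$K_HM / tc$K_NM
    if (is.null(k_m3_init)) {
      if (!is.finite(kobs2)) {
        stop("slow phase not resolved in the representative trace; ",
             "supply k_m3_init", call. = FALSE)
      }
      k_m3_init <- kobs2 / (1 + K3 * K2 / (1 + K2))
    }
    if (!is.finite(kobs2) || kobs2 <= k_m3_init) {
      # slow phase unresolved or inconsistent with the dissociation rate
      # (e.g. probing whether a third step exists at all): start it from
      # the dissociation rate and the closure
      kobs2 <- k_m3_init * (1 + K3 * K2 / (1 + K2))
      if (kobs2 >= kobs1) kobs2 <- kobs1 / 20
    }
    start <- initial_rates_from_constants(tc$K_G448D, tc$K_NM, tc$K_HM,
                                          k1_fixed, kobs1, kobs2, k_m3_init)
  } else {
    start <- initial_rates_from_constants(tc$K_G448D, tc$K_NM,
                                          k1_fixed = k1_fixed, kobs1 = kobs1)
  }

  # per-trace weights: inverse variance of the final 5% of points
  weights <- vapply(assoc, function(tr) {
    tail_y <- tr$intensity[tr$time >= quantile(tr$time, 0.95)]
    v <- var(tail_y)
    if (!is.finite(v) || v <= 0) NA_real_ else 1 / v
  }, numeric(1))
  if (all(is.na(weights))) weights[] <- 1
  weights[is.na(weights)] <- max(weights, na.rm = TRUE)
  weights <- weights / mean(weights)

  responses0 <- lapply(I0, function(i0) {
    ssr <- as.list(steady_state_ratios)
    species_responses(I0 = i0,
                      Ins = ssr$Ins_over_I0 * i0,
                      Ifl = ssr$Ifl_over_I0 * i0,
                      Ist = ssr$Ist_over_I0 * i0)
  })

  structure(list(traces = assoc, duplex = duplex, variants = variants,
                 Pt = Pt, Nt = Nt, weights = weights,
                 I0 = I0, responses0 = responses0,
                 start = start, k1_fixed = k1_fixed,
                 three_step = three,
                 titration_constants = tc,
                 rep_fit = rep_fit),
            class = "global_fit_problem")
}

#' @export
print.global_fit_problem <- function(x, ...) {
  cat(sprintf("Global fit problem: %d traces (%d HM, %d NM), %s\n",
              length(x$traces), sum(x$duplex == "HM"),
              sum(x$duplex == "NM"),
              if (x$three_step) "three-step scheme" else "two-step scheme"))
  cat("  starting rates:\n")
  print(x$start)
  invisible(x)
}

# Free parameter names for a problem
free_par_names <- function(problem) {
  c("k_m1", "k2", "k_m2", if (problem$three_step) c("k3", "k_m3"))
}

rates_from_logpar <- function(problem, logp) {
  k <- exp(logp)
  rate_constants(problem$k1_fixed, k[["k_m1"]], k[["k2"]], k[["k_m2"]],
                 if (problem$three_step) k[["k3"]] else 0,
                 if (problem$three_step) k[["k_m3"]] else 0,
                 variant = if (problem$three_step) "three_step" else
                   "two_step")
}

# Weighted residuals with species responses profiled out per duplex type
# (they enter linearly, so for trial rates the optimal responses are a
# weighted linear least-squares solve; the LM search then only covers the
# log rate constants).  Returns residual vector with attributes
# "responses" (per duplex) and "pertrace" (residual norms).
global_residuals <- function(problem, logp) {
  n_tr <- length(problem$traces)
  n_tot <- sum(vapply(problem$traces, nrow, integer(1)))
  rc_full <- tryCatch(rates_from_logpar(problem, logp),
                      error = function(e) NULL)
  if (is.null(rc_full)) return(rep(1e6, n_tot))  # overflowed trial step
  Xb_list <- vector("list", n_tr)   # bound-species concentration columns
  y0_list <- vector("list", n_tr)   # data minus fixed free-duplex term
  for (i in seq_len(n_tr)) {
    tr <- problem$traces[[i]]
    variant <- problem$variants[i]
    rc_i <- if (variant == rc_full$variant) rc_full else
      rate_constants(rc_full$k1, rc_full$k_m1, rc_full$k2, rc_full$k_m2,
                     variant = variant)
    tc <- tryCatch(
      simulate_timecourse(rc_i, problem$Nt[i], problem$Pt[i],
                          t_grid = tr$time),
      error = function(e) NULL)
    if (is.null(tc)) return(rep(1e6, n_tot))  # stiff failure at trial step
    sw <- sqrt(problem$weights[i])
    I0 <- problem$I0[[attr(tr, "duplex")]]
    y0_list[[i]] <- sw * (tr$intensity - I0 * tc$N)
    Xb_list[[i]] <- sw * as.matrix(tc[, c("NPns", "NPfl", "NPst")])
  }
  res <- numeric(0)
  responses <- list()
  pertrace <- numeric(n_tr)
  for (dup in unique(problem$duplex)) {
    idx <- which(problem$duplex == dup)
    X <- do.call(rbind, Xb_list[idx])
    yv <- unlist(y0_list[idx])
    qr_X <- qr(X)
    beta <- qr.coef(qr_X, yv)
    beta[is.na(beta)] <- 0           # rank-deficient column (e.g. NPst ~ 0)
    r <- yv - X %*% beta
    n_per <- vapply(Xb_list[idx], nrow, integer(1))
    split_idx <- rep(seq_along(idx), n_per)
    pertrace[idx] <- vapply(seq_along(idx),
                            function(j) sqrt(sum(r[split_idx == j]^2)),
                            numeric(1))
    responses[[dup]] <- c(I0 = unname(problem$I0[[dup]]),
                          Ins = beta[[1]], Ifl = beta[[2]], Ist = beta[[3]])
    res <- c(res, r)
  }
  attr(res, "responses") <- responses
  attr(res, "pertrace") <- pertrace
  res
}

#' Run the constrained global fit
#'
#' Levenberg-Marquardt minimization of the weighted sum of squared
#' residuals between predicted and observed fluorescence over all traces
#' simultaneously.  Rates are searched in log space (`k1` stays fixed);
#' per-species responses are profiled out by linear least squares at each
#' step.  On non-convergence the start is perturbed multiplicatively
#' (factors of 3, alternating direction) up to 5 times.
#'
#' @param problem a `global_fit_problem` from [build_global_problem()].
#' @param maxiter maximum LM iterations per attempt.
#' @param restarts maximum restart attempts on non-convergence.
#' @return Object of class `global_fit_report`: fitted [rate_constants],
#'   standard errors (`se`, delta-method on the natural scale, from the
#'   residual covariance), 95 percent Wald intervals `ci`, profiled
#'   `responses` per duplex, per-trace residual norms, derived observed
#'   rates (`kobs`, via the pre-equilibrium relations) and equilibrium
#'   constants in both conventions, convergence diagnostics, and
#'   identifiability `flags` (a rate whose log-scale standard error
#'   exceeds 2 decades, or whose Wald interval reaches 0, is flagged).
#'   For three-step problems the nested two-step model is also fitted and
#'   compared by an extra-sum-of-squares F test (`nested`); when the third
#'   step does not significantly improve the fit, `k3` is flagged as
#'   indistinguishable from zero.
#' @export
run_global_fit <- function(problem, maxiter = 200, restarts = 5) {
  stopifnot(inherits(problem, "global_fit_problem"))
  pn <- free_par_names(problem)
  start_vec <- log(unlist(problem$start[pn]))
  names(start_vec) <- pn

  # LM with polish rounds: restarting from the converged point resets the
  # damping parameter and walks off shallow ridges where a single run can
  # stall with a small step size but a nonzero gradient
  lm_polished <- function(par0, prob) {
    f <- NULL
    for (round in 1:4) {
      f_new <- minpack.lm::nls.lm(
        par = if (is.null(f)) par0 else f$par,
        fn = function(p) as.numeric(global_residuals(prob, p)),
        lower = rep(log(1e-6), length(par0)),
        upper = rep(log(1e7), length(par0)),
        control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                             ftol = 1e-12, ptol = 1e-12,
                                             epsfcn = 1e-8))
      if (!is.null(f) &&
          (f$deviance - f_new$deviance) < 1e-8 * f$deviance) {
        if (f_new$deviance < f$deviance) f <- f_new
        break
      }
      f <- f_new
    }
    f
  }
  attempt <- 0
  repeat {
    fit <- lm_polished(start_vec, problem)
    converged <- fit$info %in% 1:3
    if (converged || attempt >= restarts) break
    attempt <- attempt + 1
    # alternate multiplicative perturbation of the starting values
    start_vec <- log(unlist(problem$start[pn])) +
      log(3) * (-1)^(attempt + seq_along(pn))
  }

  p <- fit$par
  final <- global_residuals(problem, p)
  rc_hat <- rates_from_logpar(problem, p)
  n_res <- length(final)
  dof <- max(n_res - length(p) - 3 * length(unique(problem$duplex)), 1)
  covm <- tryCatch(fit$deviance / dof * chol2inv(chol(fit$hessian)),
                   error = function(e)
                     matrix(Inf, length(p), length(p)))
  se_log <- sqrt(pmax(diag(covm), 0))
  names(se_log) <- pn
  k_hat <- exp(p)
  se_nat <- k_hat * se_log
  z <- qnorm(0.975)
  ci <- cbind(lower = k_hat * exp(-z * se_log),
              upper = k_hat * exp(z * se_log))
  # Wald interval on the natural scale for the zero test
  ci_nat <- cbind(lower = k_hat - z * se_nat, upper = k_hat + z * se_nat)
  rownames(ci) <- rownames(ci_nat) <- pn

  flags <- character(0)
  for (nm in pn) {
    if (!is.finite(se_log[[nm]]) || se_log[[nm]] > log(10) * 2) {
      flags <- c(flags, paste0(nm, " unidentifiable"))
    } else if (ci_nat[nm, "lower"] <= 0) {
      flags <- c(flags, paste0(nm, " indistinguishable from zero"))
    }
  }

  # Two-vs-three-step discrimination: for a three-step problem, fit the
  # nested two-step model (k3 = k_m3 = 0 boundary) and test whether the
  # third step improves the fit (extra-sum-of-squares F test).  If not,
  # the rearrangement step is unsupported and k3 is flagged.
  nested <- NULL
  if (problem$three_step) {
    prob2 <- problem
    prob2$three_step <- FALSE
    prob2$variants[] <- "two_step"
    pn2 <- free_par_names(prob2)
    fit2 <- lm_polished(fit$par[pn2], prob2)
    ssr3 <- fit$deviance; ssr2 <- fit2$deviance
    Fstat <- ((ssr2 - ssr3) / 2) / (ssr3 / dof)
    p_F <- if (is.finite(Fstat) && Fstat > 0) {
      stats::pf(Fstat, 2, dof, lower.tail = FALSE)
    } else {
      1
    }
    nested <- list(two_step_estimates = setNames(exp(fit2$par), pn2),
                   two_step_deviance = ssr2, F_statistic = Fstat,
                   p_value = p_F)
    if (p_F > 0.05) {
      flags <- c(flags,
                 "k3 indistinguishable from zero (third step not supported over two-step model)")
    }
  }

  Ks <- tryCatch(list(
    final_state = equilibrium_constants_from_rates(rc_hat, "final_state"),
    total_bound = equilibrium_constants_from_rates(rc_hat, "total_bound")),
    error = function(e) NULL)

  out <- list(rates = rc_hat,
              estimates = setNames(as.numeric(k_hat), pn),
              se = setNames(as.numeric(se_nat), pn),
              se_log = se_log, ci = ci, ci_natural = ci_nat,
              responses = attr(final, "responses"),
              pertrace_norms = attr(final, "pertrace"),
              kobs = relaxation_rates_approx(rc_hat),
              equilibrium_constants = Ks,
              nested = nested,
              deviance = fit$deviance, n_residuals = n_res,
              convergence = list(info = fit$info, message = fit$message,
                                 niter = fit$niter, restarts = attempt,
                                 converged = fit$info %in% 1:3),
              flags = flags, problem = problem)
  class(out) <- "global_fit_report"
  if (!out$convergence$converged) {
    warning("global fit did not converge after restart schedule: ",
            fit$message, call. = FALSE)
  }
  out
}

#' @export
print.global_fit_report <- function(x, ...) {
  cat("Global fit report",
      if (x$convergence$converged) "(converged)" else "(NOT CONVERGED)",
      "\n")
  est <- x$estimates
  for (nm in names(est)) {
    cat(sprintf("  %-5s = %10.4g +/- %-9.3g s^-1  [%.4g, %.4g]\n",
                nm, est[[nm]], x$se[[nm]], x$ci[nm, 1], x$ci[nm, 2]))
  }
  cat(sprintf("  derived kobs1 = %.4g s^-1, kobs2 = %.4g s^-1\n",
              x$kobs[["kobs1"]], x$kobs[["kobs2"]]))
  cat(sprintf("  weighted SSR = %.6g over %d residuals\n",
              x$deviance, x$n_residuals))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Residual-resampling bootstrap intervals for the global fit
#'
#' Resamples (with replacement, within each trace) the residuals of the
#' converged fit, adds them back to the fitted curves, refits, and returns
#' percentile intervals per rate constant.  Fully reproducible under a
#' fixed seed.
#'
#' @param problem the fitted `global_fit_problem`.
#' @param report the converged `global_fit_report`.
#' @param n_boot number of bootstrap replicates (>= 20).
#' @param seed integer seed.
#' @param level interval level (default 0.95).
#' @return Object of class `bootstrap_intervals`: matrix of percentile
#'   intervals, the replicate estimates, `n_boot` and `seed`.
#' @export
bootstrap_uncertainty <- function(problem, report, n_boot = 200, seed = 1,
                                  level = 0.95) {
  stopifnot(inherits(problem, "global_fit_problem"),
            inherits(report, "global_fit_report"))
  if (n_boot < 20) stop("n_boot must be at least 20", call. = FALSE)
  if (!report$convergence$converged) {
    stop("bootstrap requires a converged report", call. = FALSE)
  }
  pn <- free_par_names(problem)
  logp_hat <- log(report$estimates[pn])

  # fitted curves per trace at the estimate
  fitted_tr <- vector("list", length(problem$traces))
  resid_tr <- vector("list", length(problem$traces))
  rc_full <- report$rates
  for (i in seq_along(problem$traces)) {
    tr <- problem$traces[[i]]
    variant <- problem$variants[i]
    rc_i <- if (variant == rc_full$variant) rc_full else
      rate_constants(rc_full$k1, rc_full$k_m1, rc_full$k2, rc_full$k_m2,
                     variant = variant)
    tc <- simulate_timecourse(rc_i, problem$Nt[i], problem$Pt[i],
                              t_grid = tr$time)
    resp <- report$responses[[attr(tr, "duplex")]]
    fitted_tr[[i]] <- as.numeric(
      as.matrix(tc[, c("N", "NPns", "NPfl", "NPst")]) %*% resp)
    resid_tr[[i]] <- tr$intensity - fitted_tr[[i]]
  }

  set.seed(seed)
  est <- matrix(NA_real_, n_boot, length(pn), dimnames = list(NULL, pn))
  for (b in seq_len(n_boot)) {
    prob_b <- problem
    for (i in seq_along(problem$traces)) {
      y_b <- fitted_tr[[i]] + sample(resid_tr[[i]], replace = TRUE)
      prob_b$traces[[i]]$intensity <- y_b
    }
    fit_b <- minpack.lm::nls.lm(
      par = logp_hat,
      fn = function(p) as.numeric(global_residuals(prob_b, p)),
      control = minpack.lm::nls.lm.control(maxiter = 50,
                                           ftol = 1e-10, ptol = 1e-10))
    est[b, ] <- exp(fit_b$par)
  }
  alpha <- (1 - level) / 2
  ints <- t(apply(est, 2, quantile, probs = c(alpha, 1 - alpha),
                  na.rm = TRUE))
  colnames(ints) <- c("lower", "upper")
  structure(list(intervals = ints, estimates = est, n_boot = n_boot,
                 seed = seed, level = level),
            class = "bootstrap_intervals")
}

#' @export
print.bootstrap_intervals <- function(x, ...) {
  cat(sprintf("Bootstrap percentile intervals (%d replicates, %.0f%%)\n",
              x$n_boot, 100 * x$level))
  print(round(x$intervals, 4))
  invisible(x)
}

#' Sensitivity of the fitted constants to the fixed bimolecular rate
#'
#' The bimolecular rate constant cannot be estimated from these data (it
#' is only bounded below by the instrument and above by diffusion), so the
#' scheme is fitted with `k1` fixed.  This refits the problem at
#' alternative `k1` values — by default the two bounds — to demonstrate
#' how insensitive the unimolecular constants are to the choice.
#'
#' @param problem a `global_fit_problem`.
#' @param report the converged `global_fit_report` at the problem's `k1`.
#' @param k1_values alternative fixed values, M^-1 s^-1 (default the
#'   instrument-derived lower bound 5e8 and the diffusion limit 1e10).
#' @return Data frame with one row per `k1` value (the reference first):
#'   fitted rates and the maximum relative shift of the unimolecular
#'   constants (`k2`, `k_m2`, `k3`, `k_m3`) from the reference fit.
#' @export
k1_sensitivity <- function(problem, report, k1_values = c(5e8, 1e10)) {
  stopifnot(inherits(problem, "global_fit_problem"),
            inherits(report, "global_fit_report"))
  pn <- free_par_names(problem)
  uni <- intersect(c("k2", "k_m2", "k3", "k_m3"), pn)
  ref <- report$estimates
  rows <- data.frame(k1 = problem$k1_fixed, t(ref),
                     max_uni_shift = 0, converged = TRUE)
  for (k1v in k1_values) {
    prob_v <- problem
    prob_v$k1_fixed <- k1v
    # rescale the encounter dissociation start to keep K1 at its measured
    # value; the unimolecular starts carry over
    prob_v$start <- rate_constants(
      k1v, k1v / problem$titration_constants$K_G448D,
      report$estimates[["k2"]], report$estimates[["k_m2"]],
      if (problem$three_step) report$estimates[["k3"]] else 0,
      if (problem$three_step) report$estimates[["k_m3"]] else 0,
      variant = report$rates$variant)
    rep_v <- run_global_fit(prob_v)
    shift <- max(abs(rep_v$estimates[uni] - ref[uni]) / ref[uni])
    rows <- rbind(rows, data.frame(k1 = k1v, t(rep_v$estimates),
                                   max_uni_shift = shift,
                                   converged = rep_v$convergence$converged))
  }
  rownames(rows) <- NULL
  rows
}
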