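#' Anisotropy titration curve
#'
#' A fluorescence-anisotropy titration of a labelled duplex at fixed total
#' duplex concentration `Nt` with increasing total protein `Pt`.
#'
#' @param Pt total protein concentrations (strictly increasing,
#'   nonnegative), uM by default.
#' @param r measured anisotropies (must lie in the physical one-photon
#'   range (-0.2, 0.4)).
#' @param sd optional per-point anisotropy standard deviations.
#' @param Nt total duplex concentration (same unit as `Pt`).
#' @param units concentration unit of `Pt` and `Nt`.
#' @param label free-text duplex/protein identifier.
#' @return Object of class `titration_curve`: a data.frame with columns
#'   `Pt` (uM), `r`, `sd`, and attributes `Nt` (uM), `label`.
#' @export
titration_curve <- function(Pt, r, sd = NULL, Nt, units = c("uM", "M"),
                            label = "") {
  units <- match.arg(units)
  if (length(Pt) != length(r)) stop("Pt and r lengths differ", call. = FALSE)
  if (any(Pt < 0) || any(diff(Pt) <= 0)) {
    stop("Pt must be nonnegative and strictly increasing", call. = FALSE)
  }
  if (any(r <= -0.2 | r >= 0.4)) {
    stop("anisotropy outside the physical range (-0.2, 0.4)", call. = FALSE)
  }
  if (is.null(sd)) sd <- rep(NA_real_, length(r))
  if (length(sd) != length(r)) stop("sd length mismatch", call. = FALSE)
  Nt_u <- to_uM(Nt, units)
  if (Nt_u <= 0) stop("Nt must be positive", call. = FALSE)
  structure(data.frame(Pt = to_uM(Pt, units), r = r, sd = sd),
            Nt = Nt_u, label = label,
            class = c("titration_curve", "data.frame"))
}

#' Fraction of duplex bound at equilibrium (quadratic mass balance)
#'
#' Closed-form solution of the 1:n binding mass balance,
#' \deqn{\vartheta = \frac{(K_a^{-1} + n N_t + P_t) -
#'   \sqrt{(K_a^{-1} + n N_t + P_t)^2 - 4 n P_t N_t}}{2 N_t},}
#' the fraction of duplex bound (which is also how the quantity enters the
#' anisotropy model, even though with `n = 1` and excess protein it is
#' often loosely called the bound protein fraction).
#'
#' @param Ka association constant, M^-1.
#' @param Pt,Nt total protein and duplex concentrations (uM by default;
#'   `Pt` may be a vector).
#' @param n binding stoichiometry (proteins per duplex), default 1.
#' @param units concentration unit of `Pt`/`Nt`.
#' @return Fraction bound in `[0, 1]` (floating-point excursions below
#'   1e-12 outside the interval are clipped).
#' @export
fraction_bound <- function(Ka, Pt, Nt, n = 1, units = c("uM", "M")) {
  units <- match.arg(units)
  if (Ka <= 0) stop("Ka must be positive", call. = FALSE)
  if (Nt <= 0) stop("Nt must be positive (division by zero)", call. = FALSE)
  if (any(Pt < 0)) stop("Pt must be nonnegative", call. = FALSE)
  Pt_M <- to_uM(Pt, units) * 1e-6
  Nt_M <- to_uM(Nt, units) * 1e-6
  A <- 1 / Ka + n * Nt_M + Pt_M
  disc <- A^2 - 4 * n * Pt_M * Nt_M
  th <- (A - sqrt(pmax(disc, 0))) / (2 * Nt_M)
  if (any(th < -1e-12 | th > 1 + 1e-12)) {
    stop("fraction bound escaped [0,1] beyond floating-point tolerance",
         call. = FALSE)
  }
  pmin(pmax(th, 0), 1)
}

#' Anisotropy of a partially bound duplex with quantum-yield correction
#'
#' \deqn{r = \frac{\vartheta R r_t - r_d(\vartheta - 1)}
#'                {1 + R\vartheta - \vartheta}}
#' where `R` is the ratio of the quantum yield of the bound to the free
#' duplex; the intensity weighting makes the apparent anisotropy a
#' brightness-weighted mixture of the free (`r_d`) and saturated (`r_t`)
#' values.
#'
#' @param theta fraction bound, in `[0, 1]` (vectorized).
#' @param r_d anisotropy of the free duplex.
#' @param r_t anisotropy at saturation.
#' @param R bound/free quantum-yield ratio (> 0).
#' @return Anisotropy values.
#' @export
anisotropy_model <- function(theta, r_d, r_t, R) {
  if (any(theta < 0 | theta > 1)) {
    stop("theta must lie in [0, 1]", call. = FALSE)
  }
  den <- 1 + R * theta - theta
  if (any(den <= 0)) {
    stop("unphysical quantum-yield ratio: denominator 1 + (R-1)*theta <= 0",
         call. = FALSE)
  }
  (theta * R * r_t - r_d * (theta - 1)) / den
}

#' Fit the anisotropy binding isotherm to a titration curve
#'
#' Nonlinear least squares of the quantum-yield-corrected anisotropy model
#' composed with the quadratic mass-balance bound fraction.  `Ka` is fitted
#' as `log10(Ka)` to enforce positivity across the 1e5-1e7 M^-1 range;
#' the stoichiometry `n` is fixed at 1 by default (it can be freed, with a
#' lower bound of 0.1).  Points are weighted by inverse variance when
#' standard deviations are supplied, else unweighted.
#'
#' A curve whose total anisotropy change is smaller than three times the
#' median point standard deviation (or, lacking sds, three times the
#' robust noise estimated from second differences) is declared
#' "no binding detected" and no `Ka` is reported.
#'
#' Because the quantum-yield ratio `R` is directly measurable from the
#' total-intensity fold change recorded alongside the anisotropy, it can be
#' fixed (`fix_R = TRUE`, with the value supplied via `start$R`); fitting
#' it is the default, but `R` and `Ka` are strongly correlated, so fixing a
#' measured `R` substantially sharpens `Ka` when the titration is run near
#' the dissociation constant.
#'
#' @param curve a [titration_curve] (at least 5 points spanning sub- to
#'   super-saturating protein).
#' @param fix_n if `TRUE` (default) the stoichiometry is fixed at 1.
#' @param fix_R if `TRUE`, fix the quantum-yield ratio at `start$R`
#'   instead of fitting it.
#' @param start optional named list overriding starting values
#'   (`log10_Ka`, `r_d`, `r_t`, `R`, `n`).
#' @return Object of class `titration_fit`: list with `Ka` (M^-1), `r_d`,
#'   `r_t`, `R`, `n`, standard errors (`se`, delta-method for `Ka`),
#'   `binding_detected`, the fitted curve and residuals.
#' @export
fit_titration <- function(curve, fix_n = TRUE, fix_R = FALSE, start = NULL) {
  stopifnot(inherits(curve, "titration_curve"))
  if (nrow(curve) < 5) stop("need at least 5 titration points", call. = FALSE)
  Nt <- attr(curve, "Nt")
  Pt <- curve$Pt; r <- curve$r
  have_sd <- all(is.finite(curve$sd)) && any(curve$sd > 0)
  noise <- if (have_sd) median(curve$sd) else
    sd(diff(diff(r))) / sqrt(6)  # second-difference noise estimate
  if (!is.finite(noise)) noise <- 0
  if (diff(range(r)) < 3 * noise || diff(range(r)) == 0) {
    out <- list(binding_detected = FALSE, Ka = NA_real_,
                message = "no binding detected: anisotropy change within noise")
    class(out) <- "titration_fit"
    return(out)
  }
  w <- if (have_sd) 1 / curve$sd^2 else rep(1, length(r))

  # starting values: r_d from the lowest-Pt point, r_t from the highest,
  # Ka^-1 from the protein concentration at half signal change
  r_half <- (min(r) + max(r)) / 2
  P_half <- Pt[which.min(abs(r - r_half))]
  Ka0 <- 1 / max((P_half - Nt / 2) * 1e-6, 1e-8)
  s <- list(log10_Ka = log10(Ka0), r_d = r[1], r_t = r[length(r)],
            R = 2, n = 1)
  if (!is.null(start)) s <- modifyList(s, start)

  R_fixed <- s$R
  model_r <- function(p) {
    n <- if (fix_n) 1 else max(p[["n"]], 0.1)
    R <- if (fix_R) R_fixed else max(p[["R"]], 1e-6)
    th <- fraction_bound(10^p[["log10_Ka"]], Pt, Nt, n = n)
    anisotropy_model(th, p[["r_d"]], p[["r_t"]], R)
  }
  par0 <- unlist(s[c("log10_Ka", "r_d", "r_t", if (!fix_R) "R",
                     if (!fix_n) "n")])
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(p) sqrt(w) * (r - model_r(p)),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  p <- fit$par
  dof <- length(r) - length(p)
  covm <- tryCatch(fit$deviance / max(dof, 1) * chol2inv(chol(fit$hessian)),
                   error = function(e) matrix(NA_real_, length(p), length(p)))
  se <- sqrt(pmax(diag(covm), 0))
  names(se) <- names(p)
  Ka <- 10^p[["log10_Ka"]]
  se_Ka <- Ka * log(10) * se[["log10_Ka"]]
  out <- list(binding_detected = TRUE,
              Ka = Ka, r_d = p[["r_d"]], r_t = p[["r_t"]],
              R = if (fix_R) R_fixed else p[["R"]],
              n = if (fix_n) 1 else max(p[["n"]], 0.1),
              se = c(Ka = se_Ka, se),
              fitted = model_r(p), residuals = r - model_r(p),
              deviance = fit$deviance, convergence = fit$info,
              curve = curve)
  class(out) <- "titration_fit"
  out
}

#' @export
print.titration_fit <- function(x, ...) {
  if (!x$binding_detected) {
    cat("Titration fit:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("Titration fit: Ka = %.4g +/- %.2g M^-1 (n = %.3g)\n",
              x$Ka, x$se[["Ka"]], x$n))
  cat(sprintf("  r_d = %.4f  r_t = %.4f  R = %.3g\n", x$r_d, x$r_t, x$R))
  invisible(x)
}

#' Batch-validation rule for a measured binding constant
#'
#' A protein preparation is accepted when its measured association constant
#' lies within 20 percent of the target value (boundary inclusive).
#'
#' @param Ka_est,Ka_target estimated and target association constants
#'   (same units, both positive).
#' @return `TRUE` (pass) or `FALSE`, with attribute `relative_deviation`.
#' @export
validate_binding_constant <- function(Ka_est, Ka_target) {
  if (Ka_est <= 0 || Ka_target <= 0) {
    stop("association constants must be positive", call. = FALSE)
  }
  dev <- abs(Ka_est - Ka_target) / Ka_target
  structure(dev <= 0.20, relative_deviation = dev)
}

#' Free-energy difference corresponding to an affinity ratio
#'
#' `dG = R T ln(ratio)` with the gas constant in calories,
#' `R = 1.987 cal mol^-1 K^-1`.
#'
#' @param affinity_ratio ratio of association constants (> 0).
#' @param T_K temperature in kelvin (default 293.15, i.e. 20 C).
#' @return Free-energy difference in cal/mol.
#' @export
free_energy_difference <- function(affinity_ratio, T_K = 293.15) {
  if (affinity_ratio <= 0 || T_K <= 0) {
    stop("affinity_ratio and T_K must be positive", call. = FALSE)
  }
  1.987 * T_K * log(affinity_ratio)
}

#' Read and write titration curves as delimited text
#'
#' CSV with a commented header block (`# key: value`: `Nt_molar`, `label`)
#' followed by columns `Pt_molar, anisotropy` and optional `sd`.
#'
#' @param curve a [titration_curve].
#' @param path file path.
#' @return `write_titration` returns `path` invisibly; `read_titration`
#'   returns a [titration_curve].
#' @export
write_titration <- function(curve, path) {
  stopifnot(inherits(curve, "titration_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# Nt_molar: %.10g", attr(curve, "Nt") * 1e-6),
               sprintf("# label: %s", attr(curve, "label"))), con)
  df <- data.frame(Pt_molar = curve$Pt * 1e-6, anisotropy = curve$r,
                   sd = curve$sd)
  if (all(is.na(df$sd))) df$sd <- NULL
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- parse_header_block(hdr)
  if (is.null(meta$Nt_molar)) {
    stop("titration file lacks '# Nt_molar:' header", call. = FALSE)
  }
  df <- read.csv(text = lines[!grepl("^#", lines)])
  titration_curve(Pt = df$Pt_molar, r = df$anisotropy,
                  sd = if ("sd" %in% names(df)) df$sd else NULL,
                  Nt = as.numeric(meta$Nt_molar), units = "M",
                  label = if (is.null(meta$label)) "" else meta$label)
}

# "# key: value" header lines -> named list (numeric where possible)
parse_header_block <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) == 3) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      out[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  out
}
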