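#' Per-species fluorescence responses
#'
#' Fluorescence emitted per unit concentration of each duplex species:
#' free duplex (`I0`), encounter complex (`Ins`), flipped intermediate
#' (`Ifl`) and stabilized complex (`Ist`).  Defaults anchor the ratios to
#' the steady-state fold changes observed on complex formation: the
#' binding-only mutant raises emission ~1.25-fold (giving `Ins/I0`), the
#' non-methylated duplex ~2.5-fold (`Ifl/I0`), and the hemi-methylated
#' duplex 5- to 6-fold at the most sensitive label position (`Ist/I0`).
#' All values are configurable since the underlying steady-state data are
#' reported as fold changes, not absolute intensities.
#'
#' @param I0 response of the free duplex, intensity per uM (sets the gain).
#' @param Ins,Ifl,Ist responses of the bound species, same unit.
#' @return Object of class `species_responses` (named numeric vector).
#' @export
species_responses <- function(I0 = 1, Ins = 1.25 * I0, Ifl = 2.5 * I0,
                              Ist = 5.5 * I0) {
  v <- c(I0 = I0, Ins = Ins, Ifl = Ifl, Ist = Ist)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("responses must be finite and nonnegative", call. = FALSE)
  }
  if (I0 <= 0) stop("I0 must be positive (it anchors the ratios)",
                    call. = FALSE)
  structure(v, class = "species_responses")
}

#' Stopped-flow instrument model
#'
#' Dead time, point-acquisition regimes and additive detector noise.
#' The two acquisition regimes of the experimental design are provided as
#' presets: `"dense_early"` collects the instrument maximum of 10000
#' points within the first 0.1 s plus 9000 points out to 1 s;
#' `"balanced"` collects 2000 points in 0.1 s plus 9000 points to 1 s.
#'
#' @param dead_time instrument dead time, seconds (> 0; default 2.7 ms).
#' @param regimes either a preset name or a list of
#'   `c(n_points, t_start, t_end)` triplets, non-overlapping and ordered.
#' @param noise_sd additive Gaussian noise standard deviation, intensity
#'   units.
#' @return Object of class `instrument_model`.
#' @export
instrument_model <- function(dead_time = 2.7e-3,
                             regimes = "dense_early",
                             noise_sd = 0) {
  if (dead_time <= 0) stop("dead_time must be positive", call. = FALSE)
  if (is.character(regimes)) {
    regimes <- switch(match.arg(regimes, c("dense_early", "balanced")),
                      dense_early = list(c(10000, 0, 0.1), c(9000, 0.1, 1)),
                      balanced    = list(c(2000, 0, 0.1), c(9000, 0.1, 1)))
  }
  for (rg in regimes) {
    if (length(rg) != 3 || rg[1] < 1 || rg[3] <= rg[2]) {
      stop("each regime must be c(n_points, t_start, t_end) with t_end > t_start",
           call. = FALSE)
    }
  }
  ends <- vapply(regimes, `[`, numeric(1), 3)
  starts <- vapply(regimes, `[`, numeric(1), 2)
  if (length(regimes) > 1 &&
      any(starts[-1] < ends[-length(ends)] - 1e-12)) {
    stop("regimes must be non-overlapping and ordered", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(dead_time = dead_time, regimes = regimes,
                 noise_sd = noise_sd), class = "instrument_model")
}

# Sampling grid of an instrument model: n uniform points per regime,
# placed at the regime's right-open grid (t_start excluded, t_end included).
instrument_times <- function(instrument) {
  unlist(lapply(instrument$regimes, function(rg) {
    seq(rg[2], rg[3], length.out = rg[1] + 1)[-1]
  }))
}

#' Kinetic fluorescence trace
#'
#' A sampled stopped-flow fluorescence time series with experiment
#' metadata.  Times are seconds since the true mixing time; for recorded
#' (instrument-applied) traces the first point is at or after the dead
#' time.
#'
#' @param time strictly increasing times, seconds.
#' @param intensity fluorescence intensities, arbitrary units.
#' @param duplex `"HM"`, `"NM"` or `NA`.
#' @param position label position identifier (e.g. `"7"`, `"5"`, `"6p"`,
#'   `"8p"`), free text.
#' @param protein protein variant (e.g. `"SRA"`, `"SRA_G448D"`).
#' @param Nt,Pt total duplex and protein concentrations after mixing, uM.
#' @param kind `"association"`, `"dissociation"` or `"buffer"` (control).
#' @return Object of class `kinetic_trace`: data.frame with columns `time`
#'   and `intensity` plus metadata attributes.
#' @export
kinetic_trace <- function(time, intensity, duplex = NA_character_,
                          position = NA_character_, protein = NA_character_,
                          Nt = NA_real_, Pt = NA_real_,
                          kind = c("association", "dissociation", "buffer")) {
  kind <- match.arg(kind)
  if (length(time) != length(intensity)) {
    stop("time and intensity lengths differ", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(time = time, intensity = intensity),
            duplex = duplex, position = position, protein = protein,
            Nt = Nt, Pt = Pt, kind = kind,
            class = c("kinetic_trace", "data.frame"))
}

trace_meta <- function(trace) {
  list(duplex = attr(trace, "duplex"), position = attr(trace, "position"),
       protein = attr(trace, "protein"), Nt = attr(trace, "Nt"),
       Pt = attr(trace, "Pt"), kind = attr(trace, "kind"))
}

#' @export
print.kinetic_trace <- function(x, ...) {
  m <- trace_meta(x)
  cat(sprintf("Kinetic trace (%s): %d points, t in [%.4g, %.4g] s\n",
              m$kind, nrow(x), x$time[1], x$time[nrow(x)]))
  cat(sprintf("  duplex %s, position %s, protein %s, Nt = %.3g uM, Pt = %.3g uM\n",
              m$duplex, m$position, m$protein, m$Nt, m$Pt))
  invisible(x)
}

#' @export
plot.kinetic_trace <- function(x, log_time = TRUE, ...) {
  graphics::plot(x$time, x$intensity,
                 log = if (log_time && x$time[1] > 0) "x" else "",
                 xlab = "time (s)", ylab = "fluorescence (a.u.)",
                 type = "l", ...)
  invisible(x)
}

#' Ideal fluorescence trace from a species trajectory
#'
#' Linear response model: the observed fluorescence is the response-weighted
#' sum of the labelled-duplex species,
#' `F(t) = I0 [N] + Ins [NPns] + Ifl [NPfl] + Ist [NPst]`
#' (free protein and trapped protein do not fluoresce at the detection
#' wavelength).
#'
#' @param trajectory a `timecourse` from [simulate_timecourse()].
#' @param responses a [species_responses] object.
#' @return Numeric vector of intensities, one per trajectory time point.
#' @export
predict_fluorescence_trace <- function(trajectory, responses) {
  stopifnot(inherits(responses, "species_responses"))
  as.numeric(as.matrix(trajectory[, c("N", "NPns", "NPfl", "NPst")]) %*%
               responses[c("I0", "Ins", "Ifl", "Ist")])
}

#' Apply the stopped-flow instrument model to an ideal trace
#'
#' Samples the ideal trace on the instrument's acquisition grids, discards
#' points before the dead time (the dead time is handled by discarding, not
#' by convolution: mixing is treated as instantaneous at t = 0) and adds
#' seeded Gaussian detector noise.
#'
#' @param ideal either a function of time returning intensity, or a
#'   two-column object with `time` and `intensity` covering the full regime
#'   span (interpolated linearly).
#' @param instrument an [instrument_model].
#' @param seed integer seed for the noise realization (ignored when
#'   `noise_sd = 0`).
#' @param ... metadata passed to [kinetic_trace()].
#' @return A [kinetic_trace] starting at or after the dead time.
#' @export
apply_instrument <- function(ideal, instrument, seed = NULL, ...) {
  stopifnot(inherits(instrument, "instrument_model"))
  tt <- instrument_times(instrument)
  tt <- tt[tt >= instrument$dead_time]
  if (is.function(ideal)) {
    y <- ideal(tt)
  } else {
    span <- range(ideal$time)
    tmax <- max(vapply(instrument$regimes, `[`, numeric(1), 3))
    if (span[1] > instrument$dead_time + 1e-12 || span[2] < tmax - 1e-12) {
      stop("ideal trace does not cover the acquisition span", call. = FALSE)
    }
    y <- approx(ideal$time, ideal$intensity, xout = tt)$y
  }
  if (instrument$noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(length(y), sd = instrument$noise_sd)
  }
  kinetic_trace(tt, y, ...)
}

#' Block-average a trace by groups of consecutive points
#'
#' Consecutive non-overlapping blocks of `group_size` points are averaged
#' in both time and intensity (a trailing short block is averaged as is),
#' reproducing the standard stopped-flow data reduction.
#'
#' @param trace a [kinetic_trace].
#' @param group_size block length (default 4).
#' @return The reduced [kinetic_trace] (metadata preserved).
#' @export
reduce_by_group <- function(trace, group_size = 4) {
  stopifnot(inherits(trace, "kinetic_trace"))
  if (group_size < 1 || group_size != round(group_size)) {
    stop("group_size must be a positive integer", call. = FALSE)
  }
  if (group_size == 1) return(trace)
  g <- (seq_len(nrow(trace)) - 1) %/% group_size
  tm <- as.numeric(tapply(trace$time, g, mean))
  im <- as.numeric(tapply(trace$intensity, g, mean))
  meta <- trace_meta(trace)
  kinetic_trace(tm, im, duplex = meta$duplex, position = meta$position,
                protein = meta$protein, Nt = meta$Nt, Pt = meta$Pt,
                kind = meta$kind)
}

#' Predict a competition-chase dissociation trace
#'
#' The pre-formed protein-duplex complex is equilibrated at the syringe
#' concentrations, diluted on mixing, and challenged with a large excess of
#' unlabelled competitor DNA.  The competitor is modeled as a
#' pseudo-first-order sink on free protein with rate
#' `trap_rate * (competitor nucleotides / site_size)`, so that released
#' protein cannot rebind the labelled duplex.  Fluorescence comes from the
#' labelled-duplex species only.
#'
#' @param rc a [rate_constants] object.
#' @param responses a [species_responses].
#' @param Nt_pre,Pt_pre duplex and protein concentrations in the complex
#'   syringe before mixing, uM.
#' @param competitor_uM competitor concentration after mixing, uM
#'   nucleotides (default 750).
#' @param trap_rate bimolecular trap rate constant, M^-1 s^-1 (default
#'   3e9, matching the encounter step).
#' @param site_size nucleotides per protein binding site (default 12).
#' @param t_grid output times, seconds.
#' @param dilution fold dilution on mixing (default 2: equal volumes).
#' @param instrument optional [instrument_model]; when supplied the ideal
#'   trace is sampled/noised through it (`t_grid` then only sets the
#'   integration span).
#' @param seed noise seed forwarded to [apply_instrument()].
#' @param ... metadata passed to [kinetic_trace()].
#' @return A [kinetic_trace] of kind `"dissociation"`.
#' @export
predict_dissociation_trace <- function(rc, responses, Nt_pre, Pt_pre,
                                       competitor_uM = 750,
                                       trap_rate = 3e9, site_size = 12,
                                       t_grid = NULL, dilution = 2,
                                       instrument = NULL, seed = NULL, ...) {
  stopifnot(inherits(rc, "rate_constants"),
            inherits(responses, "species_responses"))
  # equilibrate at the post-mixing concentrations: the encounter step
  # re-equilibrates within the dead time after dilution, so starting from
  # the diluted equilibrium avoids a spurious dilution-relaxation phase
  eq <- equilibrium_state(rc, Nt_pre / dilution, Pt_pre / dilution)
  k_trap <- trap_rate * 1e-6 * competitor_uM / site_size  # s^-1
  rebind <- rc$k1 * 1e-6 * (eq[["N"]] + eq[["NPns"]] + eq[["NPfl"]] +
                              eq[["NPst"]])
  if (k_trap > 0 && k_trap < 10 * rebind) {
    warning("competition not effective: trap rate < 10x rebinding rate",
            call. = FALSE)
  }
  if (is.null(t_grid)) {
    t_grid <- if (is.null(instrument)) {
      10^seq(-4, 0, length.out = 400)
    } else {
      tt <- instrument_times(instrument)
      sort(unique(c(tt[tt > 0], max(tt))))
    }
  }
  tc <- simulate_timecourse(rc, Nt = sum(eq[c("N", "NPns", "NPfl", "NPst")]),
                            Pt = sum(eq[c("P", "NPns", "NPfl", "NPst")]),
                            t_grid = t_grid, initial = eq, k_trap = k_trap)
  f <- predict_fluorescence_trace(tc, responses)
  if (is.null(instrument)) {
    kinetic_trace(tc$time, f, Nt = attr(tc, "Nt"), Pt = attr(tc, "Pt"),
                  kind = "dissociation", ...)
  } else {
    apply_instrument(data.frame(time = c(0, tc$time),
                                intensity = c(sum(eq[c("N", "NPns", "NPfl",
                                                       "NPst")] *
                                                  responses[c("I0", "Ins",
                                                              "Ifl", "Ist")]),
                                              f)),
                     instrument, seed = seed,
                     Nt = attr(tc, "Nt"), Pt = attr(tc, "Pt"),
                     kind = "dissociation", ...)
  }
}

#' Read and write kinetic traces as delimited text
#'
#' CSV with a commented metadata header (`# key: value` lines for `duplex`,
#' `position`, `protein`, `Nt_uM`, `Pt_uM`, `kind`) followed by columns
#' `time_s, intensity`.
#'
#' @param trace a [kinetic_trace].
#' @param path file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   [kinetic_trace].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "kinetic_trace"))
  m <- trace_meta(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# duplex: %s", m$duplex),
               sprintf("# position: %s", m$position),
               sprintf("# protein: %s", m$protein),
               sprintf("# Nt_uM: %.10g", m$Nt),
               sprintf("# Pt_uM: %.10g", m$Pt),
               sprintf("# kind: %s", m$kind)), con)
  write.csv(data.frame(time_s = trace$time, intensity = trace$intensity),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  meta <- parse_header_block(grep("^#", lines, value = TRUE))
  df <- read.csv(text = lines[!grepl("^#", lines)])
  chr_or_na <- function(x) {
    if (is.null(x) || identical(x, "NA")) NA_character_ else as.character(x)
  }
  kinetic_trace(df$time_s, df$intensity,
                duplex = chr_or_na(meta$duplex),
                position = chr_or_na(meta$position),
                protein = chr_or_na(meta$protein),
                Nt = if (is.null(meta$Nt_uM)) NA_real_ else
                  as.numeric(meta$Nt_uM),
                Pt = if (is.null(meta$Pt_uM)) NA_real_ else
                  as.numeric(meta$Pt_uM),
                kind = if (is.null(meta$kind)) "association" else meta$kind)
}
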