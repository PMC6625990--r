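#' Subtract a reference trace from sample traces
#'
#' Removes baseline drift and non-specific signal recorded on a reference
#' sensor. The reference is linearly interpolated onto the sample time grid
#' when the grids differ; time ranges must overlap fully.
#'
#' @param sample `trace_table` of sample signals
#' @param reference `trace_table` with one signal column (or a numeric
#'   vector on the sample grid)
#' @return corrected `trace_table` (metadata preserved)
#' @export
reference_subtract <- function(sample, reference) {
  if (is.numeric(reference)) {
    ref <- reference
    if (length(ref) != nrow(sample)) stop("reference length mismatch")
  } else {
    rt <- reference$t
    if (min(sample$t) < min(rt) - 1e-9 || max(sample$t) > max(rt) + 1e-9)
      stop("reference does not cover the sample time range")
    rv <- reference[[setdiff(names(reference), "t")[1]]]
    ref <- stats::approx(rt, rv, xout = sample$t)$y
  }
  out <- sample
  for (nm in setdiff(names(out), "t")) out[[nm]] <- out[[nm]] - ref
  out
}

.trace_col <- function(trace, column) {
  if (is.numeric(trace)) return(list(t = seq_along(trace) - 1, y = trace))
  nm <- if (is.null(column)) setdiff(names(trace), "t")[1] else column
  list(t = trace$t, y = trace[[nm]])
}

#' Fit the dissociation phase of a binding trace
#'
#' Least-squares fit of `R(t) = R0 exp(-k_d t) + plateau` (free plateau).
#' Time is re-zeroed to the start of the supplied trace.
#'
#' @param trace `trace_table` (dissociation phase only) or numeric vector
#' @param column signal column to fit (default: first)
#' @param offset fit a free plateau (default TRUE)
#' @return list of class `dissoc_fit`: `k_d` (1/s), `R0`, `plateau`,
#'   `residual_norm`
#' @export
fit_dissociation <- function(trace, column = NULL, offset = TRUE) {
  tc <- .trace_col(trace, column)
  t <- tc$t - tc$t[1]; y <- tc$y
  if (length(t) < 10L) stop("at least 10 points required")
  drop_total <- y[1] - y[length(y)]
  if (!is.finite(drop_total) || drop_total <= 0 ||
      drop_total < 0.02 * max(abs(y), 1e-12))
    stop("trace is not decaying: cannot fit a dissociation phase")
  # log-linear start values
  ylo <- min(y); amp0 <- y[1] - ylo
  pos <- y - ylo + 0.05 * amp0 > 0
  k0 <- tryCatch({
    cf <- stats::coef(stats::lm(log(y[pos] - ylo + 0.05 * amp0) ~ t[pos]))
    max(-cf[2], 1e-6)
  }, error = function(e) 1 / max(t[length(t)], 1))
  fml <- if (offset) y ~ R0 * exp(-kd * t) + C else y ~ R0 * exp(-kd * t)
  st <- if (offset) list(R0 = amp0, kd = k0, C = ylo)
        else list(R0 = y[1], kd = k0)
  fit <- minpack.lm::nlsLM(fml, data = data.frame(t = t, y = y), start = st,
                           lower = c(0, 1e-9, if (offset) -Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(k_d = unname(cf["kd"]), R0 = unname(cf["R0"]),
                 plateau = if (offset) unname(cf["C"]) else 0,
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "dissoc_fit")
}

#' Fit the association phase and derive the association rate constant
#'
#' Fits `R(t) = R_eq (1 - exp(-k_obs t)) + baseline` and converts the
#' observed rate to `k_a = (k_obs - k_d) / concentration` for the 1:1
#' binding model.
#'
#' @param trace `trace_table` (association phase) or numeric vector
#' @param concentration analyte concentration, M
#' @param k_d dissociation rate constant from [fit_dissociation()], 1/s
#' @param column signal column (default: first)
#' @return list of class `assoc_fit`: `k_obs` (1/s), `k_a` (1/M/s),
#'   `R_eq`, `baseline`, `residual_norm`
#' @export
fit_association <- function(trace, concentration, k_d, column = NULL) {
  if (concentration <= 0) stop("concentration must be positive")
  tc <- .trace_col(trace, column)
  t <- tc$t - tc$t[1]; y <- tc$y
  if (length(t) < 10L) stop("at least 10 points required")
  amp0 <- max(y) - y[1]
  if (amp0 <= 0) stop("trace is not rising: cannot fit an association phase")
  thalf <- t[which(y - y[1] >= amp0 / 2)[1]]
  k0 <- log(2) / max(thalf, t[2])
  fit <- minpack.lm::nlsLM(
    y ~ Req * (1 - exp(-kobs * t)) + B,
    data = data.frame(t = t, y = y),
    start = list(Req = amp0, kobs = k0, B = y[1]),
    lower = c(0, 1e-9, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  k_obs <- unname(cf["kobs"])
  if (k_obs <= k_d)
    stop(sprintf(
      "fitted k_obs (%.4g/s) <= k_d (%.4g/s): non-physical for a 1:1 model; check concentration/phase labeling",
      k_obs, k_d))
  structure(list(k_obs = k_obs,
                 k_a = (k_obs - k_d) / concentration,
                 R_eq = unname(cf["Req"]), baseline = unname(cf["B"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "assoc_fit")
}

#' Combine replicate rate constants into an equilibrium constant
#'
#' Replicates are aggregated as the mean of individual `k_a` and `k_d`
#' values, and the equilibrium dissociation constant is taken as
#' `K_D = mean(k_d) / mean(k_a)` (not the mean of per-trace ratios).
#'
#' @param k_a association rate constants, 1/M/s
#' @param k_d dissociation rate constants, 1/s
#' @return list of class `rate_constants`: `k_a`, `k_d`, `K_D` (M), with
#'   `k_a_sd`/`k_d_sd` when n >= 2
#' @export
combine_kinetics <- function(k_a, k_d) {
  if (length(k_a) == 0L || length(k_d) == 0L) stop("empty rate list")
  if (any(k_a <= 0) || any(k_d <= 0)) stop("rates must be positive")
  ka <- mean(k_a); kd <- mean(k_d)
  structure(list(k_a = ka, k_d = kd, K_D = kd / ka,
                 k_a_sd = if (length(k_a) >= 2) stats::sd(k_a) else NA_real_,
                 k_d_sd = if (length(k_d) >= 2) stats::sd(k_d) else NA_real_,
                 n = c(k_a = length(k_a), k_d = length(k_d))),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat(sprintf("k_a = %.3g /M/s, k_d = %.3g /s, K_D = %.3g M (%.2f uM)\n",
              x$k_a, x$k_d, x$K_D, x$K_D * 1e6))
  invisible(x)
}

#' Steady-state one-site binding fit
#'
#' Fits `R = Bmax C / (K_D + C)` to equilibrium responses.
#'
#' @param concentrations analyte concentrations, M (>= 4 values)
#' @param equilibrium_responses equilibrium responses at each concentration
#' @return list of class `steady_state_fit`: `K_D` (M), `Bmax`,
#'   `residual_norm`, `low_curvature` flag
#' @export
fit_steady_state <- function(concentrations, equilibrium_responses) {
  C <- as.numeric(concentrations); R <- as.numeric(equilibrium_responses)
  if (length(C) < 4L) stop("need >= 4 concentrations")
  low_curvature <- FALSE
  lin <- stats::lm(R ~ C)
  if (suppressWarnings(summary(lin)$r.squared) > 0.995) {
    warning("responses nearly linear in concentration: K_D poorly bounded")
    low_curvature <- TRUE
  }
  fit <- tryCatch(minpack.lm::nlsLM(
    R ~ Bmax * C / (KD + C), data = data.frame(C = C, R = R),
    start = list(Bmax = max(R) * 1.2, KD = stats::median(C)),
    lower = c(1e-12, 1e-15),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    if (!low_curvature) stop("one-site binding fit failed")
    # no measurable curvature: K_D is only bounded below by the range probed
    return(structure(list(K_D = Inf, Bmax = NA_real_,
                          residual_norm = NA_real_, low_curvature = TRUE),
                     class = "steady_state_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(K_D = unname(cf["KD"]), Bmax = unname(cf["Bmax"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 low_curvature = low_curvature),
            class = "steady_state_fit")
}

#' One-phase association fit
#'
#' Fits `y = y0 + A (1 - exp(-k t))`, the standard model for e.g.
#' nucleotide-binding fluorescence time courses.
#'
#' @param trace `trace_table` or numeric vector
#' @param column signal column (default: first)
#' @return list of class `one_phase_fit`: `k` (1/s), `A`, `y0`,
#'   `residual_norm`
#' @export
fit_one_phase <- function(trace, column = NULL) {
  tc <- .trace_col(trace, column)
  t <- tc$t - tc$t[1]; y <- tc$y
  if (length(t) < 10L) stop("at least 10 points required")
  A0 <- max(y) - y[1]
  if (A0 <= 0 || A0 < 1e-6 * max(abs(y), 1e-12))
    stop("degenerate trace: no rising amplitude to fit")
  tail_n <- max(3L, length(y) %/% 5L)
  late_slope <- stats::coef(stats::lm(utils::tail(y, tail_n) ~
                                        utils::tail(t, tail_n)))[2]
  if (late_slope > 0.25 * A0 / (t[length(t)] - t[1]))
    warning("signal not saturating over the observed window")
  thalf <- t[which(y - y[1] >= A0 / 2)[1]]
  fit <- minpack.lm::nlsLM(
    y ~ y0 + A * (1 - exp(-k * t)), data = data.frame(t = t, y = y),
    start = list(y0 = y[1], A = A0, k = log(2) / max(thalf, t[2])),
    lower = c(-Inf, 0, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(k = unname(cf["k"]), A = unname(cf["A"]),
                 y0 = unname(cf["y0"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2))),
            class = "one_phase_fit")
}

#' Melting temperature from a thermal-melt curve
#'
#' Two estimators: `derivative` takes the argmax of the Savitzky-Golay
#' smoothed first derivative dF/dT (window 5, quadratic); `sigmoid` fits a
#' Boltzmann sigmoid `F = F_low + (F_high - F_low)/(1 + exp((Tm - T)/slope))`
#' and reports its midpoint. The default computes both and headlines the
#' sigmoid value (more noise-robust).
#'
#' @param curve `trace_table` with temperature in `t` (degrees C) and one
#'   fluorescence column
#' @param method `"sigmoid"`, `"derivative"`, or `"both"` (default)
#' @param column signal column (default: first)
#' @return list of class `melt_fit`: `Tm` (headline, degrees C), `method`,
#'   `Tm_sigmoid`, `Tm_derivative`, fit diagnostics
#' @export
melt_tm <- function(curve, method = c("both", "sigmoid", "derivative"),
                    column = NULL) {
  method <- match.arg(method)
  tc <- .trace_col(curve, column)
  T <- tc$t; F <- tc$y
  if (length(T) < 7L) stop("melt curve too short")
  tm_der <- NA_real_; tm_sig <- NA_real_; resid_norm <- NA_real_
  if (method %in% c("both", "derivative")) {
    Fs <- signal::sgolayfilt(F, p = 2, n = 5)
    dmid <- diff(Fs) / diff(T)
    tmid <- (T[-1] + T[-length(T)]) / 2
    i <- which.max(dmid)
    if (!is.finite(dmid[i]) || dmid[i] <= 1e-8 * max(abs(diff(range(F))), 1))
      stop("no rising inflection found in the melt region")
    tm_der <- tmid[i]
    if (i > 1 && i < length(dmid)) {
      # parabolic interpolation of the derivative peak for sub-grid Tm
      y <- dmid[(i - 1):(i + 1)]
      denom <- y[1] - 2 * y[2] + y[3]
      if (abs(denom) > 1e-12) {
        off <- 0.5 * (y[1] - y[3]) / denom
        tm_der <- tmid[i] + off * (tmid[i + 1] - tmid[i])
      }
    }
  }
  if (method %in% c("both", "sigmoid")) {
    rng <- range(F)
    i0 <- which.min(abs(F - mean(rng)))
    fit <- tryCatch(minpack.lm::nlsLM(
      F ~ Flow + (Fhigh - Flow) / (1 + exp((Tm - T) / s)),
      data = data.frame(T = T, F = F),
      start = list(Flow = rng[1], Fhigh = rng[2], Tm = T[i0], s = 2),
      lower = c(-Inf, -Inf, min(T), 1e-3),
      upper = c(Inf, Inf, max(T), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop("no rising transition found in the melt region"))
    cf <- stats::coef(fit)
    if (cf["Fhigh"] <= cf["Flow"])
      stop("no rising transition found in the melt region")
    tm_sig <- unname(cf["Tm"])
    resid_norm <- sqrt(sum(stats::resid(fit)^2))
  }
  headline <- if (method == "derivative") tm_der else tm_sig
  structure(list(Tm = headline,
                 method = if (method == "both") "sigmoid" else method,
                 Tm_sigmoid = tm_sig, Tm_derivative = tm_der,
                 residual_norm = resid_norm),
            class = "melt_fit")
}

#' Fold change between two equilibrium dissociation constants
#' @param K_D_mut mutant (or condition B) K_D
#' @param K_D_wt wild-type (or condition A) K_D
#' @return ratio `K_D_mut / K_D_wt`
#' @export
fold_change <- function(K_D_mut, K_D_wt) {
  if (K_D_mut <= 0 || K_D_wt <= 0) stop("K_D values must be positive")
  K_D_mut / K_D_wt
}
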