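#' Per-site scattering weights for profile computation
#'
#' In Ca (residue-level) mode every site carries a constant effective
#' electron count (default 60, roughly one average residue); on all-atom
#' input, per-element electron counts are used. No hydration shell or
#' excluded-volume term is modeled.
#'
#' @param structure structure3d
#' @param ca_weight effective electrons per residue site in Ca mode
#' @return numeric vector of weights, one per site used by [debye_profile()]
#' @export
form_factors <- function(structure, ca_weight = 60) {
  a <- structure$atoms
  if (all(a$name == "CA")) return(rep(ca_weight, nrow(a)))
  electrons <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15)
  z <- electrons[toupper(a$element)]
  z[is.na(z)] <- 6
  as.numeric(z)
}

#' Theoretical scattering profile by the Debye equation
#'
#' `I(q) = sum_i sum_j f_i f_j sin(q d_ij)/(q d_ij)`, with the q -> 0 and
#' d -> 0 limits taken as 1, so that `I(0) = (sum f)^2`.
#'
#' @param structure structure3d (sites taken in atom order; use Ca-only
#'   structures for residue-level profiles)
#' @param q_grid ascending q values, 1/Angstrom, q >= 0
#' @param form per-site weights (default [form_factors()])
#' @return numeric intensity vector on `q_grid`
#' @export
debye_profile <- function(structure, q_grid, form = form_factors(structure)) {
  if (n_atoms(structure) == 0L) stop("empty structure")
  if (any(diff(q_grid) <= 0) || any(q_grid < 0))
    stop("q_grid must be ascending and non-negative")
  xyz <- as.matrix(structure$atoms[c("x", "y", "z")])
  n <- nrow(xyz)
  f <- rep_len(form, n)
  .debye_cpp(xyz, as.numeric(q_grid), as.numeric(f))
}

#' Radius of gyration from coordinates
#'
#' Weight-averaged second moment about the centroid; the direct-space
#' oracle for Guinier estimates on noiseless Debye profiles.
#'
#' @param structure structure3d
#' @param form per-site weights
#' @return Rg in Angstrom
#' @export
coord_rg <- function(structure, form = form_factors(structure)) {
  xyz <- as.matrix(structure$atoms[c("x", "y", "z")])
  w <- rep_len(form, nrow(xyz)) ; w <- w / sum(w)
  ctr <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Guinier analysis of a scattering curve
#'
#' Iteratively fits `ln I` versus `q^2` by least squares, estimating
#' `Rg = sqrt(-3 slope)`, then shrinks the fit window to `q Rg < 1.3` and
#' repeats until the estimate changes by < 0.1 % (or 20 iterations, with a
#' warning).
#'
#' @param curve `saxs_curve`
#' @param q_rg_max Guinier validity limit (default 1.3)
#' @return list of class `guinier_fit`: `Rg`, `I0`, `q_range`, `r_squared`,
#'   `n_points`, `converged`
#' @export
guinier <- function(curve, q_rg_max = 1.3) {
  q <- curve$q; I <- curve$I
  usable <- I > 0
  q <- q[usable]; I <- I[usable]
  if (length(q) < 5L) stop("need >= 5 positive-intensity points")
  window <- seq_len(length(q))
  rg_old <- NA_real_
  converged <- FALSE
  fit <- NULL
  for (iter in 1:20) {
    if (length(window) < 5L)
      window <- seq_len(5L)
    fit <- stats::lm.fit(cbind(1, q[window]^2), log(I[window]))
    slope <- unname(fit$coefficients[2])
    if (slope >= 0)
      stop("positive Guinier slope: no Guinier region at low q")
    rg <- sqrt(-3 * slope)
    window <- which(q * rg < q_rg_max)
    if (!is.na(rg_old) && abs(rg - rg_old) / rg_old < 1e-3) {
      converged <- TRUE
      rg_old <- rg
      break
    }
    rg_old <- rg
  }
  if (!converged) warning("Guinier iteration did not converge; last estimate returned")
  r2 <- 1 - sum(fit$residuals^2) /
    sum((log(I[window]) - mean(log(I[window])))^2)
  structure(list(Rg = rg_old,
                 I0 = exp(unname(fit$coefficients[1])),
                 q_range = range(q[window]),
                 r_squared = r2,
                 n_points = length(window),
                 converged = converged),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.2f A, I0 = %.4g (q %.4f-%.4f, %d pts, R2 = %.4f)\n",
              x$Rg, x$I0, x$q_range[1], x$q_range[2], x$n_points, x$r_squared))
  invisible(x)
}

#' Chi-square fit of a model profile against an experimental curve
#'
#' The scale is the analytic least-squares minimizer
#' `c = sum(Ie Im / s^2) / sum(Im^2 / s^2)`, and
#' `chi2 = 1/(N-1) sum(((Ie - c Im)/s)^2)` (Crysol-style normalization).
#'
#' @param model_I model intensity evaluated on the experimental q grid
#' @param exp_curve `saxs_curve`
#' @return list of class `chi_fit`: `scale`, `chi2`
#' @export
chi_square <- function(model_I, exp_curve) {
  if (length(model_I) != nrow(exp_curve))
    stop("model profile and experimental curve length mismatch")
  Ie <- exp_curve$I; s <- exp_curve$sigma
  cc <- sum(Ie * model_I / s^2) / sum(model_I^2 / s^2)
  chi2 <- sum(((Ie - cc * model_I) / s)^2) / (length(Ie) - 1)
  structure(list(scale = cc, chi2 = chi2), class = "chi_fit")
}

#' Reduce SEC-SAXS frames: peak averaging and buffer subtraction
#'
#' `curve = mean(peak frames) - mean(buffer frames)`, with the uncertainty
#' propagated in quadrature of the standard errors of the two means (each
#' from the per-frame sigmas: `sqrt(sum(sigma_i^2))/n`).
#'
#' @param frames list of `saxs_curve` objects on one shared q grid
#' @param peak_ids indices of protein-peak frames
#' @param buffer_ids indices of buffer frames (disjoint from `peak_ids`)
#' @return `saxs_curve`
#' @export
reduce_sec_saxs <- function(frames, peak_ids, buffer_ids) {
  if (length(peak_ids) == 0L || length(buffer_ids) == 0L)
    stop("peak and buffer id sets must both be non-empty")
  if (length(intersect(peak_ids, buffer_ids)))
    stop("peak and buffer id sets overlap")
  q0 <- frames[[peak_ids[1]]]$q
  for (i in c(peak_ids, buffer_ids))
    if (!isTRUE(all.equal(frames[[i]]$q, q0)))
      stop("all frames must share one q grid")
  stack <- function(ids) {
    m <- vapply(ids, function(i) frames[[i]]$I, numeric(length(q0)))
    m <- matrix(m, nrow = length(q0))
    s2 <- vapply(ids, function(i) frames[[i]]$sigma^2, numeric(length(q0)))
    s2 <- matrix(s2, nrow = length(q0))
    list(mu = rowMeans(m), se = sqrt(rowSums(s2)) / length(ids))
  }
  pk <- stack(peak_ids); bf <- stack(buffer_ids)
  sig <- sqrt(pk$se^2 + bf$se^2)
  sig[sig <= 0] <- max(min(sig[sig > 0], na.rm = TRUE), 1e-12)
  saxs_curve(q0, pk$mu - bf$mu, sig)
}

#' Minimal multi-state fitting of candidate profiles
#'
#' Exhaustively enumerates candidate subsets of size 1..`max_states`; for
#' each subset solves the non-negative least-squares weight problem (the
#' overall scale is folded into the weight vector and factored out), and
#' returns the subset with the global minimum chi-square.
#'
#' @param candidate_profiles list (or matrix columns) of model intensities
#'   on the experimental q grid
#' @param exp_curve `saxs_curve`
#' @param max_states maximum subset size (1-3)
#' @return list of class `multistate_fit`: `members` (indices), `weights`
#'   (sum to 1), `scale`, `chi2`
#' @export
multistate_fit <- function(candidate_profiles, exp_curve, max_states = 3) {
  if (length(candidate_profiles) == 0L) stop("empty candidate pool")
  if (is.list(candidate_profiles))
    M <- do.call(cbind, candidate_profiles)
  else M <- as.matrix(candidate_profiles)
  npool <- ncol(M)
  if (npool > 50L) stop("candidate pool limited to 50 (enumeration bound)")
  if (max_states < 1 || max_states > 3) stop("max_states must be 1..3")
  if (nrow(M) != nrow(exp_curve)) stop("profile/experiment length mismatch")
  b <- exp_curve$I / exp_curve$sigma
  A <- M / exp_curve$sigma
  nobs <- nrow(M)
  best <- list(chi2 = Inf)
  for (k in seq_len(min(max_states, npool))) {
    subsets <- utils::combn(npool, k)
    for (j in seq_len(ncol(subsets))) {
      idx <- subsets[, j]
      w <- if (k == 1L) {
        max(sum(A[, idx] * b) / sum(A[, idx]^2), 0)
      } else {
        pracma::lsqnonneg(A[, idx, drop = FALSE], b)$x
      }
      resid <- b - A[, idx, drop = FALSE] %*% matrix(w, ncol = 1)
      chi2 <- sum(resid^2) / (nobs - 1)
      if (chi2 < best$chi2 - 1e-12) {
        total <- sum(w)
        best <- list(members = idx[w > 0],
                     weights = if (total > 0) (w / total)[w > 0] else w[w > 0],
                     scale = total, chi2 = chi2)
      }
    }
  }
  structure(best, class = "multistate_fit")
}

#' @export
print.multistate_fit <- function(x, ...) {
  cat(sprintf("multi-state fit: members {%s}, weights {%s}, chi2 = %.4g\n",
              paste(x$members, collapse = ","),
              paste(sprintf("%.3f", x$weights), collapse = ","),
              x$chi2))
  invisible(x)
}
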