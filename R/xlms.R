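#' Flat-harmonic crosslink restraint parameters
#'
#' The restraint on a crosslinked residue pair is zero while the Ca-Ca
#' distance stays inside the flat window and grows quadratically outside:
#' with target `x0`, half-width `tolerance` and softness `sigma`, the
#' penalty is `((d - x0 - tolerance)/sigma)^2` for `d > x0 + tolerance` and
#' 0 otherwise. The defaults (x0 = 15 A, tolerance = 15 A, sigma = 1)
#' effectively cap Ca-Ca distances at 30 A, the DSS crosslink threshold
#' once linker flexibility is allowed for.
#'
#' @param x0 target distance, Angstrom (default 15)
#' @param tolerance flat half-width, Angstrom (default 15)
#' @param sigma softness, dimensionless (default 1)
#' @return list of class `flat_harmonic_params`
#' @export
flat_harmonic_params <- function(x0 = 15, tolerance = 15, sigma = 1) {
  if (x0 < 0 || tolerance < 0) stop("x0 and tolerance must be >= 0")
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(x0 = x0, tolerance = tolerance, sigma = sigma),
            class = "flat_harmonic_params")
}

#' Flat-harmonic restraint penalty
#'
#' @param dist Ca-Ca distance(s), Angstrom, >= 0
#' @param params [flat_harmonic_params()]
#' @return penalty (vectorized over `dist`)
#' @export
flat_harmonic <- function(dist, params = flat_harmonic_params()) {
  if (any(dist < 0)) stop("dist must be >= 0")
  edge <- params$x0 + params$tolerance
  ifelse(dist <= edge, 0, ((dist - edge) / params$sigma)^2)
}

#' DSS linker distance geometry
#'
#' Spacer length of the crosslinker plus two lysine side chains gives the
#' maximal geometric Ca-Ca span; adding a dynamics allowance gives the
#' satisfaction threshold used in model assessment.
#'
#' @param spacer_length crosslinker spacer, Angstrom (DSS: 11.4)
#' @param sidechain_length lysine side chain, Angstrom (6.4)
#' @param dynamics_allowance extra span for protein flexibility (6)
#' @param threshold satisfaction threshold, Angstrom (30)
#' @return list of class `linker_geometry`
#' @export
linker_geometry <- function(spacer_length = 11.4, sidechain_length = 6.4,
                            dynamics_allowance = 6, threshold = 30) {
  if (threshold < spacer_length + 2 * sidechain_length)
    stop("threshold must be >= spacer + 2 x sidechain length")
  structure(list(spacer_length = spacer_length,
                 sidechain_length = sidechain_length,
                 dynamics_allowance = dynamics_allowance,
                 threshold = threshold),
            class = "linker_geometry")
}

#' Maximal geometric Ca-Ca distance bridged by a crosslinker
#' @param geometry [linker_geometry()]
#' @return distance in Angstrom (DSS/Lys defaults: 24.2)
#' @export
max_linker_distance <- function(geometry = linker_geometry()) {
  geometry$spacer_length + 2 * geometry$sidechain_length
}

#' Crosslink satisfaction report for a model
#'
#' Computes the Euclidean Ca-Ca distance for every crosslinked pair and
#' flags pairs under the threshold as satisfied.
#'
#' @param structure structure3d
#' @param crosslinks `crosslinks` table
#' @param threshold satisfaction threshold, Angstrom (default 30)
#' @return list of class `satisfaction_report` with elements `links`
#'   (data.frame: addresses, distance, satisfied) and `fraction_satisfied`
#' @export
satisfaction <- function(structure, crosslinks, threshold = 30) {
  ca <- ca_coords(structure)
  k1 <- paste0(crosslinks$chain1, ":", crosslinks$res1)
  k2 <- paste0(crosslinks$chain2, ":", crosslinks$res2)
  missing <- setdiff(unique(c(k1, k2)), rownames(ca))
  if (length(missing))
    stop("crosslink address(es) not resolvable to a CA: ",
         paste(missing, collapse = ", "))
  d <- sqrt(rowSums((ca[k1, , drop = FALSE] - ca[k2, , drop = FALSE])^2))
  links <- data.frame(chain1 = crosslinks$chain1, res1 = crosslinks$res1,
                      chain2 = crosslinks$chain2, res2 = crosslinks$res2,
                      distance = as.numeric(d),
                      satisfied = as.numeric(d) < threshold)
  structure(list(links = links,
                 fraction_satisfied = mean(links$satisfied),
                 threshold = threshold),
            class = "satisfaction_report")
}

#' @export
print.satisfaction_report <- function(x, ...) {
  cat(sprintf("crosslink satisfaction: %d/%d links < %g A (fraction %.3f)\n",
              sum(x$links$satisfied), nrow(x$links), x$threshold,
              x$fraction_satisfied))
  invisible(x)
}

#' Decoy-based FDR filtering of crosslink matches
#'
#' Target/decoy competition with the simple counting estimator: at score
#' cutoff s, `FDR(s) = (#decoys >= s / n_decoy_copies) / max(#targets >= s, 1)`.
#' The decoy database is assumed to be the target sequences randomized
#' `n_decoy_copies` times and appended, so the decoy count is scaled down
#' accordingly. Returns the targets surviving at the loosest (lowest) score
#' cutoff whose FDR is at or below `fdr_threshold`.
#'
#' @param matches `crosslinks` table (or data.frame) with `score` and
#'   `is_decoy` columns
#' @param n_decoy_copies number of appended decoy database copies (>= 1)
#' @param fdr_threshold FDR level (default 0.05)
#' @return list: `fdr_at_threshold`, `score_cutoff`, `kept` (target rows)
#' @export
decoy_fdr <- function(matches, n_decoy_copies = 10, fdr_threshold = 0.05) {
  if (n_decoy_copies < 1) stop("n_decoy_copies must be >= 1")
  targets <- matches[!matches$is_decoy, , drop = FALSE]
  decoys <- matches[matches$is_decoy, , drop = FALSE]
  if (nrow(targets) == 0L) stop("no target matches")
  cutoffs <- sort(unique(targets$score), decreasing = TRUE)
  fdr_at <- vapply(cutoffs, function(s) {
    nt <- sum(targets$score >= s)
    nd <- sum(decoys$score >= s) / n_decoy_copies
    nd / max(nt, 1)
  }, numeric(1))
  ok <- fdr_at <= fdr_threshold
  if (!any(ok)) {
    # nothing passes: keep nothing, report FDR at the strictest cutoff
    return(list(fdr_at_threshold = min(fdr_at), score_cutoff = Inf,
                kept = targets[0, , drop = FALSE]))
  }
  cut <- min(cutoffs[ok])  # loosest cutoff with FDR <= threshold
  list(fdr_at_threshold = fdr_at[which(cutoffs == cut)],
       score_cutoff = cut,
       kept = targets[targets$score >= cut, , drop = FALSE])
}
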