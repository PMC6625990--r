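#' One scored model in an ensemble
#'
#' The unit of the selection cascade: a structure together with its sortable
#' energy score, SAXS chi-square, and per-crosslink Ca distances.
#'
#' @param model_id integer id
#' @param structure structure3d
#' @param energy final total energy (sortable score)
#' @param chi2 SAXS chi-square against the experimental curve (optional
#'   until the chi-square cascade stage is used)
#' @param link_distances named numeric vector of Ca distances, one per
#'   crosslink, named `"chain:res1-chain:res2"`
#' @return list of class `ensemble_entry`
#' @export
ensemble_entry <- function(model_id, structure, energy, chi2 = NA_real_,
                           link_distances = NULL) {
  structure(list(model_id = as.integer(model_id), structure = structure,
                 energy = as.numeric(energy), chi2 = as.numeric(chi2),
                 link_distances = link_distances),
            class = "ensemble_entry")
}

#' Selection-cascade configuration
#'
#' Defaults mirror a production-scale run (top 500 by energy, chi2 < 2.0,
#' held-out crosslinks under 30 A, leader clustering at 2.5 A, minor
#' clusters of fewer than 14 models rejected unless they contain one of the
#' top 10 energy models).
#'
#' @param top_n_energy models kept at the energy stage
#' @param chi_cutoff chi-square cutoff
#' @param heldout_links `crosslinks` table of held-out validation links
#' @param link_threshold Ca distance threshold for held-out links, Angstrom
#' @param rmsd_cutoff leader-clustering RMSD cutoff, Angstrom
#' @param min_cluster_size clusters smaller than this are candidate minors
#' @param top_k_energy minors containing one of the best `top_k_energy`
#'   models are retained regardless of size
#' @return list of class `cascade_config`
#' @export
cascade_config <- function(top_n_energy = 500, chi_cutoff = 2.0,
                           heldout_links = NULL, link_threshold = 30,
                           rmsd_cutoff = 2.5, min_cluster_size = 14,
                           top_k_energy = 10) {
  stopifnot(top_n_energy > 0, chi_cutoff > 0, link_threshold > 0,
            rmsd_cutoff > 0, min_cluster_size > 0, top_k_energy > 0)
  structure(list(top_n_energy = top_n_energy, chi_cutoff = chi_cutoff,
                 heldout_links = heldout_links,
                 link_threshold = link_threshold, rmsd_cutoff = rmsd_cutoff,
                 min_cluster_size = min_cluster_size,
                 top_k_energy = top_k_energy),
            class = "cascade_config")
}

.entry_order <- function(entries) {
  e <- vapply(entries, `[[`, numeric(1), "energy")
  id <- vapply(entries, `[[`, integer(1), "model_id")
  order(e, id)
}

#' Energy / chi-square / held-out-crosslink selection cascade
#'
#' Stage A keeps the `top_n_energy` models by ascending energy (ties broken
#' by model id); stage B keeps models with `chi2 < chi_cutoff`; stage C
#' keeps models whose every held-out crosslink distance is under
#' `link_threshold`. Held-out link distances are taken from
#' `link_distances` when present, otherwise computed from the structure.
#'
#' @param entries list of [ensemble_entry()]
#' @param cfg [cascade_config()]
#' @return list of class `cascade_result`: `survivors` (entry list),
#'   `stage_ids` (model ids surviving each stage), `stage_counts`
#' @export
filter_cascade <- function(entries, cfg = cascade_config()) {
  if (length(entries) == 0L) stop("empty ensemble")
  ord <- .entry_order(entries)
  ids <- vapply(entries, `[[`, integer(1), "model_id")
  # stage A: energy rank
  keepA <- ord[seq_len(min(cfg$top_n_energy, length(ord)))]
  if (length(keepA) == 0L) stop("empty survivor set after energy stage")
  # stage B: chi-square
  chi <- vapply(entries[keepA], `[[`, numeric(1), "chi2")
  if (anyNA(chi) && cfg$chi_cutoff < Inf)
    stop("chi2 not populated for all entries at the chi-square stage")
  keepB <- keepA[is.na(chi) | chi < cfg$chi_cutoff]
  if (length(keepB) == 0L) stop("empty survivor set after chi-square stage")
  # stage C: held-out crosslinks
  if (!is.null(cfg$heldout_links) && nrow(cfg$heldout_links) > 0L) {
    okC <- vapply(entries[keepB], function(e) {
      lk <- .heldout_key(cfg$heldout_links)
      d <- if (!is.null(e$link_distances) && all(lk %in% names(e$link_distances)))
        e$link_distances[lk]
      else satisfaction(e$structure, cfg$heldout_links,
                        cfg$link_threshold)$links$distance
      all(d < cfg$link_threshold)
    }, logical(1))
    keepC <- keepB[okC]
  } else keepC <- keepB
  if (length(keepC) == 0L) stop("empty survivor set after crosslink stage")
  structure(list(survivors = entries[keepC],
                 stage_ids = list(energy = ids[keepA], chi2 = ids[keepB],
                                  crosslink = ids[keepC]),
                 stage_counts = c(input = length(entries),
                                  energy = length(keepA),
                                  chi2 = length(keepB),
                                  crosslink = length(keepC))),
            class = "cascade_result")
}

.heldout_key <- function(links) {
  paste0(links$chain1, ":", links$res1, "-", links$chain2, ":", links$res2)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation (det = +1) and translation minimizing the RMSD
#' between paired point sets.
#'
#' @param mobile n x 3 matrix (or structure3d) to transform
#' @param reference n x 3 matrix (or structure3d) held fixed
#' @param atom_subset optional rownames (as in [ca_coords()]) selecting
#'   matched points from both inputs
#' @return list: `rotation` (3x3), `translation` (length 3, applied as
#'   `x %*% t(R) + t`), `rmsd`
#' @export
superpose <- function(mobile, reference, atom_subset = NULL) {
  X <- .as_points(mobile, atom_subset)
  Y <- .as_points(reference, atom_subset)
  if (nrow(X) != nrow(Y)) stop("point sets must map 1:1")
  if (nrow(X) < 3L) stop("need >= 3 points for superposition")
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  s <- svd(crossprod(X0, Y0))
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2)
    stop("degenerate (collinear) point set")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  tr <- cy - as.numeric(R %*% cx)
  Xf <- X %*% t(R) + matrix(tr, nrow(X), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Xf - Y)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

.as_points <- function(x, atom_subset = NULL) {
  m <- if (inherits(x, "structure3d")) ca_coords(x) else as.matrix(x)
  if (!is.null(atom_subset)) {
    missing <- setdiff(atom_subset, rownames(m))
    if (length(missing))
      stop("subset addresses missing: ", paste(missing, collapse = ", "))
    m <- m[atom_subset, , drop = FALSE]
  }
  m
}

#' Apply a superposition transform to coordinates
#' @param xyz n x 3 matrix
#' @param fit result of [superpose()]
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(xyz, fit) {
  xyz %*% t(fit$rotation) +
    matrix(fit$translation, nrow(xyz), 3, byrow = TRUE)
}

#' RMSD between two conformations after optional superposition
#' @param a,b structures or coordinate matrices
#' @param align_subset addresses used for superposition (default: all
#'   shared points)
#' @param measure_subset addresses over which RMSD is measured (default:
#'   the alignment subset)
#' @return RMSD in Angstrom
#' @export
pair_rmsd <- function(a, b, align_subset = NULL, measure_subset = NULL) {
  A <- .as_points(a); B <- .as_points(b)
  al <- if (is.null(align_subset)) intersect(rownames(A), rownames(B))
        else align_subset
  fit <- superpose(A[al, , drop = FALSE], B[al, , drop = FALSE])
  ms <- if (is.null(measure_subset)) al else measure_subset
  Am <- apply_transform(A[ms, , drop = FALSE], fit)
  sqrt(mean(rowSums((Am - B[ms, , drop = FALSE])^2)))
}

#' Leader clustering of an ensemble by pairwise RMSD
#'
#' Entries are visited in ascending-energy order (ties by model id); an
#' entry joins the first existing cluster whose leader lies within
#' `rmsd_cutoff` (RMSD measured on `cluster_subset` after superposition on
#' `align_subset`), otherwise it founds a new cluster. Clusters are
#' returned sorted by decreasing size (size ties broken by leader energy
#' order).
#'
#' @param entries list of [ensemble_entry()]
#' @param cfg [cascade_config()] (uses `rmsd_cutoff`)
#' @param align_subset addresses superposed before measuring (default: all)
#' @param cluster_subset addresses over which RMSD is measured (default:
#'   the alignment subset)
#' @return list of class `cluster_result`: `clusters` (list of model-id
#'   vectors), `representatives` (lowest-energy member per cluster),
#'   `leaders`
#' @export
rmsd_cluster <- function(entries, cfg = cascade_config(),
                         align_subset = NULL, cluster_subset = NULL) {
  if (length(entries) == 0L) stop("empty ensemble")
  ord <- .entry_order(entries)
  coords <- lapply(entries, function(e) ca_coords(e$structure))
  ids <- vapply(entries, `[[`, integer(1), "model_id")
  energies <- vapply(entries, `[[`, numeric(1), "energy")
  leaders <- integer(0)          # positions in `entries`
  membership <- integer(length(entries))
  for (i in ord) {
    placed <- FALSE
    for (li in seq_along(leaders)) {
      l <- leaders[li]
      r <- pair_rmsd(coords[[i]], coords[[l]], align_subset, cluster_subset)
      if (r <= cfg$rmsd_cutoff) {
        membership[i] <- li
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, i)
      membership[i] <- length(leaders)
    }
  }
  sizes <- tabulate(membership, nbins = length(leaders))
  cl_order <- order(-sizes, seq_along(leaders))
  clusters <- lapply(cl_order, function(li) {
    mem <- which(membership == li)
    mem[order(energies[mem], ids[mem])]
  })
  reps <- vapply(clusters, function(mem) ids[mem[1]], integer(1))
  structure(list(clusters = lapply(clusters, function(m) ids[m]),
                 representatives = reps,
                 leaders = ids[leaders[cl_order]],
                 membership = stats::setNames(membership, ids)),
            class = "cluster_result")
}

#' Retain main clusters and pick representatives
#'
#' Clusters smaller than `min_cluster_size` that contain none of the best
#' `top_k_energy` models are rejected as minor; the representative of each
#' retained cluster is its lowest-energy member.
#'
#' @param cluster_result result of [rmsd_cluster()]
#' @param entries the clustered entry list
#' @param cfg [cascade_config()]
#' @return list of class `representative_set`: `retained` (cluster id
#'   lists), `representatives` (model ids), `rejected_minor` (model ids)
#' @export
select_representatives <- function(cluster_result, entries,
                                   cfg = cascade_config()) {
  ids <- vapply(entries, `[[`, integer(1), "model_id")
  ord <- .entry_order(entries)
  top_ids <- ids[ord[seq_len(min(cfg$top_k_energy, length(ord)))]]
  energies <- stats::setNames(vapply(entries, `[[`, numeric(1), "energy"), ids)
  keep <- vapply(cluster_result$clusters, function(mem) {
    length(mem) >= cfg$min_cluster_size || any(mem %in% top_ids)
  }, logical(1))
  if (!any(keep)) stop("all clusters rejected as minor")
  retained <- cluster_result$clusters[keep]
  reps <- vapply(retained, function(mem) {
    mem[order(energies[as.character(mem)], mem)][1]
  }, numeric(1))
  structure(list(retained = retained,
                 representatives = as.integer(reps),
                 rejected_minor = unlist(cluster_result$clusters[!keep],
                                         use.names = FALSE)),
            class = "representative_set")
}
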