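# lightweight entries with planted scores; structures only where clustering
# or crosslink distances require them
fake_entry <- function(id, energy, chi2 = NA_real_, link_d = NULL,
                       structure = NULL) {
  ensemble_entry(id, structure, energy, chi2, link_d)
}

test_that("the cascade matches an independent set-filter oracle", {
  set.seed(77)
  n <- 1000
  energy <- rnorm(n)
  chi2 <- rexp(n, 1)
  d1 <- runif(n, 10, 50)
  d2 <- runif(n, 10, 50)
  entries <- lapply(seq_len(n), function(i)
    fake_entry(i, energy[i], chi2[i],
               c("A:10-A:200" = d1[i], "A:20-A:210" = d2[i])))
  held <- crosslinks(c("A", "A"), c(10, 20), c("A", "A"), c(200, 210))
  cfg <- cascade_config(top_n_energy = 500, chi_cutoff = 2.0,
                        heldout_links = held, link_threshold = 30)
  res <- filter_cascade(entries, cfg)

  # oracle: plain vector filtering
  oA <- order(energy, seq_len(n))[1:500]
  oB <- oA[chi2[oA] < 2.0]
  oC <- oB[d1[oB] < 30 & d2[oB] < 30]
  expect_equal(sort(res$stage_ids$energy), sort(oA))
  expect_equal(sort(res$stage_ids$chi2), sort(oB))
  expect_equal(sort(res$stage_ids$crosslink), sort(oC))
  expect_equal(unname(res$stage_counts),
               c(n, length(oA), length(oB), length(oC)))
  # counts are non-increasing along the cascade
  expect_true(all(diff(res$stage_counts) <= 0))

  # permutation invariance (deterministic tie-break makes results set-equal)
  perm <- sample(n)
  res2 <- filter_cascade(entries[perm], cfg)
  expect_setequal(res2$stage_ids$crosslink, res$stage_ids$crosslink)

  # infinite cutoffs keep everything
  all_cfg <- cascade_config(top_n_energy = n, chi_cutoff = Inf,
                            heldout_links = NULL)
  expect_equal(unname(filter_cascade(entries, all_cfg)$stage_counts),
               rep(n, 4))

  # an impossible chi-square cutoff names the failing stage
  expect_error(filter_cascade(entries,
                              cascade_config(chi_cutoff = 1e-12)),
               "chi-square stage")
})

test_that("Kabsch superposition recovers planted rigid transforms", {
  X <- ca_coords(random_chain(20, seed = 2))
  self <- superpose(X, X)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-10)

  R <- rotation_matrix(c(0.3, -1, 2), 1.1)
  tr <- c(7, -4, 2)
  Y <- X %*% t(R) + matrix(tr, nrow(X), 3, byrow = TRUE)
  fit <- superpose(X, Y)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(fit$translation, tr, tolerance = 1e-8)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # mirror image: proper rotation enforced, residual RMSD stays positive
  M <- X; M[, 1] <- -M[, 1]
  mf <- superpose(M, X)
  expect_equal(det(mf$rotation), 1, tolerance = 1e-10)
  expect_gt(mf$rmsd, 0.1)

  # rigid pre-transforms leave the minimized RMSD unchanged
  Xj <- X + matrix(rnorm(length(X), sd = 0.5), nrow(X))
  base <- superpose(Xj, X)$rmsd
  R2 <- rotation_matrix(c(1, 1, 0), 0.7)
  expect_equal(superpose(Xj %*% t(R2), X)$rmsd, base, tolerance = 1e-8)
  expect_equal(superpose(Xj, X %*% t(R2))$rmsd, base, tolerance = 1e-8)

  expect_error(superpose(X[1:2, ], X[1:2, ]), ">= 3")
  line <- cbind(1:5 * 1.0, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("leader clustering separates planted conformational bundles", {
  set.seed(33)
  shapeA <- ca_coords(random_chain(12, seed = 101))
  shapeB <- ca_coords(random_chain(12, seed = 202))
  jitter <- function(X, sd = 0.25) X + matrix(rnorm(length(X), sd = sd),
                                              nrow(X))
  mk <- function(id, X) fake_entry(id, energy = rnorm(1),
                                   structure = point_structure(X))
  entries <- c(lapply(1:7, function(i) mk(i, jitter(shapeA))),
               lapply(8:12, function(i) mk(i, jitter(shapeB))))
  cfg <- cascade_config(rmsd_cutoff = 2.5)
  cl <- rmsd_cluster(entries, cfg)
  expect_length(cl$clusters, 2L)
  expect_setequal(cl$clusters[[1]], 1:7)     # largest first
  expect_setequal(cl$clusters[[2]], 8:12)

  # every entry lands in exactly one cluster
  all_ids <- sort(unlist(cl$clusters))
  expect_equal(all_ids, 1:12)

  # infinite cutoff: one cluster; raising the cutoff never adds clusters
  expect_length(rmsd_cluster(entries,
                             cascade_config(rmsd_cutoff = Inf))$clusters, 1L)
  n_at <- function(cut) length(rmsd_cluster(entries,
    cascade_config(rmsd_cutoff = cut))$clusters)
  cuts <- c(0.5, 1, 2.5, 5, 20, Inf)
  expect_true(all(diff(vapply(cuts, n_at, integer(1))) <= 0))
})

test_that("minor clusters are rejected unless they hold a top-energy model", {
  # sizes mirroring a production run: main clusters of 50 and 20 models,
  # minors of 13 and 8
  ids <- seq_len(91)
  energy <- as.numeric(ids)           # id order = energy order
  clusters <- list(1:50, 51:70, 71:83, 84:91)
  cl <- structure(list(clusters = clusters,
                       representatives = vapply(clusters, min, numeric(1)),
                       leaders = vapply(clusters, min, numeric(1))),
                  class = "cluster_result")
  entries <- lapply(ids, function(i) fake_entry(i, energy[i]))
  cfg <- cascade_config(min_cluster_size = 14, top_k_energy = 10)
  sel <- select_representatives(cl, entries, cfg)
  expect_length(sel$retained, 2L)
  expect_equal(sel$representatives, c(1L, 51L))   # lowest energy members
  expect_setequal(sel$rejected_minor, 71:91)

  # a 5-member minor containing the global best-energy model is retained
  cl2 <- structure(list(clusters = list(6:60, 1:5)),
                   class = "cluster_result")
  sel2 <- select_representatives(cl2, entries, cfg)
  expect_length(sel2$retained, 2L)
  expect_true(1 %in% sel2$retained[[2]])

  # min_cluster_size = 1 rejects nothing
  sel3 <- select_representatives(cl, entries,
                                 cascade_config(min_cluster_size = 1))
  expect_length(sel3$retained, 4L)
  expect_length(sel3$rejected_minor, 0L)
})
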