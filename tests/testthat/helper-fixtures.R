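# shared fixtures, built once per test run

.cache <- new.env(parent = emptyenv())

bench_sys <- function() {
  if (is.null(.cache$sys)) .cache$sys <- benchmark_system()
  .cache$sys
}

# small random Ca-only chain for geometry tests (freely-jointed, 3.8 A steps)
random_chain <- function(n, seed = 1, bond = 3.8) {
  set.seed(seed)
  dirs <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2)) * bond
  pts <- rbind(0, apply(dirs, 2, cumsum))
  structure3d(data.frame(serial = seq_len(n), name = "CA", element = "C",
                         res_name = "ALA", chain_id = "A",
                         res_num = seq_len(n),
                         x = pts[, 1], y = pts[, 2], z = pts[, 3]))
}

# arbitrary small all-atom-like structure from explicit coordinates
point_structure <- function(xyz, element = "C", name = "CA",
                            chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  structure3d(data.frame(serial = seq_len(n),
                         name = rep_len(name, n),
                         element = rep_len(element, n),
                         res_name = "ALA",
                         chain_id = rep_len(chain, n),
                         res_num = seq_len(n),
                         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

rotation_matrix <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

min_nonadjacent_dist <- function(xyz) {
  D <- as.matrix(dist(xyz))
  n <- nrow(D)
  diag(D) <- Inf
  D[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- Inf
  D[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- Inf
  min(D)
}
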