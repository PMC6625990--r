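# small system used throughout: 2-repeat core (64 residues) + 12-residue tail
small_sys <- function() {
  if (is.null(.cache$small)) {
    core <- build_core(2)
    .cache$small <- attach_truth_tail(core,
                                      tail_sequence = "SGEDEDESGKGL",
                                      seed = 5)
  }
  .cache$small
}

test_that("energy terms reproduce hand-computed boundary cases", {
  # three collinear residues spaced 4.0 A: clash term exactly zero
  s <- point_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)))
  e <- tail_energy(s)
  expect_equal(e$clash, 0)
  expect_equal(e$elec, 0)
  expect_equal(e$total, 0)

  # nonadjacent pair at 3 A: (4 - 3)^2
  s2 <- point_structure(rbind(c(0, 0, 0), c(2.6, 2.2, 0), c(3, 0, 0)))
  expect_equal(tail_energy(s2)$clash, 1, tolerance = 1e-9)

  # flat-harmonic boundary through the full energy: d = 30 -> 0, d = 32 -> 4
  s3 <- point_structure(rbind(c(0, 0, 0), c(15, 10, 0), c(30, 0, 0)))
  lk <- crosslinks("A", 1, "A", 3)
  expect_equal(tail_energy(s3, lk)$xl, 0)
  s4 <- point_structure(rbind(c(0, 0, 0), c(16, 10, 0), c(32, 0, 0)))
  expect_equal(tail_energy(s4, lk)$xl, 4, tolerance = 1e-9)

  # screened electrostatics: one +/- pair at distance d
  sq <- point_structure(rbind(c(0, 0, 0), c(4, 4, 0), c(8, 0, 0)))
  sq$atoms$res_name <- c("GLU", "ALA", "ARG")
  expect_equal(tail_energy(sq)$elec, -exp(-8 / 10) / 8, tolerance = 1e-9)

  expect_error(tail_energy(s3, crosslinks("A", 1, "A", 99)),
               "missing residue: A:99")
})

test_that("sampling is deterministic and preserves chain constraints", {
  sys <- small_sys()
  xl <- simulate_crosslinks(sys, 2, 0, seed = 1)
  sch <- anneal_schedule(stage1_steps = 300, stage2_steps = 150)
  start <- extended_start(sys)
  m1 <- sample_tail(start, sys$tail_res, xl, n_models = 3, base_seed = 7,
                    schedule = sch)
  m2 <- sample_tail(start, sys$tail_res, xl, n_models = 3, base_seed = 7,
                    schedule = sch)
  expect_identical(ca_coords(m1[[2]]$structure), ca_coords(m2[[2]]$structure))
  expect_identical(m1[[2]]$energy, m2[[2]]$energy)

  core_xyz <- ca_coords(sys$core)
  for (m in m1) {
    xyz <- ca_coords(m$structure)
    bonds <- sqrt(rowSums(diff(xyz)^2))
    expect_lt(max(abs(bonds - 3.8)), 0.01)
    # core immobility is exact
    expect_identical(xyz[rownames(core_xyz), ], core_xyz)
    # reported energy equals re-evaluation on the emitted structure
    e <- tail_energy(m$structure, xl)
    expect_equal(m$energy, e$total, tolerance = 1e-6)
  }
})

test_that("helix segments move as rigid bodies during sampling", {
  core <- build_core(2)
  sys <- attach_truth_tail(core, tail_sequence = "SGEDEDESGKGLAAAG",
                           helix_ranges = list(c(9, 15)), seed = 8)
  xl <- simulate_crosslinks(sys, 2, 0, seed = 2)
  m <- sample_tail(extended_start(sys), sys$tail_res, xl, n_models = 2,
                   base_seed = 3,
                   schedule = anneal_schedule(stage1_steps = 300,
                                              stage2_steps = 100),
                   helix_ranges = sys$helix_ranges)
  ref <- ca_coords(sys$tail_truth)[paste0("A:", sys$helix_ranges[[1]]), ]
  for (mm in m) {
    hp <- ca_coords(mm$structure)[paste0("A:", sys$helix_ranges[[1]]), ]
    # internal distances of the helix are those of the ideal helix
    expect_equal(as.vector(dist(hp)), as.vector(dist(ref)),
                 tolerance = 1e-6)
  }
})

test_that("a strong core-tail-tip restraint is satisfied by most models", {
  sys <- small_sys()
  tip <- max(sys$tail_res)
  anchor <- 30                      # a core residue near the patch
  lk <- crosslinks("A", anchor, "A", tip)
  m <- sample_tail(extended_start(sys), sys$tail_res, lk, n_models = 50,
                   base_seed = 11)
  d <- vapply(m, function(mm)
    ca_distance(mm$structure, "A", anchor, "A", tip), numeric(1))
  expect_gte(mean(d < 30), 0.8)
})

test_that("restraints shorten restrained distances relative to none", {
  sys <- small_sys()
  tip <- max(sys$tail_res)
  lk <- crosslinks("A", 30, "A", tip)
  sch <- anneal_schedule(stage1_steps = 400, stage2_steps = 200)
  mean_d <- function(w_xl) {
    m <- sample_tail(extended_start(sys), sys$tail_res, lk, n_models = 50,
                     base_seed = 21, schedule = sch,
                     weights = energy_weights(w_xl = w_xl))
    mean(vapply(m, function(mm)
      ca_distance(mm$structure, "A", 30, "A", tip), numeric(1)))
  }
  expect_lt(mean_d(1), mean_d(0))
})

test_that("zero-weight sampling reduces to the unbiased pivot chain", {
  sys <- small_sys()
  sch <- anneal_schedule(stage1_steps = 250, stage2_steps = 0,
                         T_start = 1, T_end = 1, stage1_max_angle = 180,
                         n_scramble = 50, minimize_sweeps = 0)
  m <- sample_tail(extended_start(sys), sys$tail_res, NULL, n_models = 200,
                   base_seed = 31, schedule = sch,
                   weights = energy_weights(0, 0, 0))
  # every move accepted under zero energy
  expect_true(all(vapply(m, `[[`, integer(1), "accepted_moves") == 250L))

  tail_addr <- paste0("A:", range(sys$tail_res))
  e2e <- vapply(m, function(mm)
    ca_distance(mm$structure, "A", sys$tail_res[1], "A",
                max(sys$tail_res)), numeric(1))

  # independent reference: freely-jointed chain of the same length
  # (the pivot chain's stationary distribution has iid uniform steps)
  set.seed(99)
  n_steps <- length(sys$tail_res) - 1L
  ref <- replicate(200, {
    dirs <- matrix(rnorm(3 * n_steps), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2)) * 3.8
    sqrt(sum(colSums(dirs)^2))
  })
  ks <- suppressWarnings(ks.test(e2e, ref))
  expect_lt(unname(ks$statistic), 0.15)
})

test_that("fixed-temperature sampling reproduces Boltzmann averages", {
  # single flat-harmonic restraint on a short free tail at T = 1, with all
  # other energy terms off; oracle = importance sampling over the uniform
  # freely-jointed ensemble
  core <- build_core(1)
  sys <- attach_truth_tail(core, tail_sequence = "GGGGG", seed = 4)
  lk <- crosslinks("A", 32, "A", max(sys$tail_res))
  xp <- flat_harmonic_params(x0 = 0, tolerance = 8, sigma = 3)
  sch <- anneal_schedule(stage1_steps = 0, stage2_steps = 400,
                         T_start = 1, T_end = 1, stage2_max_angle = 120,
                         n_scramble = 40, minimize_sweeps = 0)
  m <- sample_tail(extended_start(sys), sys$tail_res, lk, n_models = 400,
                   base_seed = 41, schedule = sch,
                   weights = energy_weights(0, 0, 1), xl_params = xp)
  e_obs <- mean(vapply(m, function(mm)
    flat_harmonic(ca_distance(mm$structure, "A", 32, "A",
                              max(sys$tail_res)), xp), numeric(1)))

  anchor <- ca_site(sys$tail_truth, "A", 32)
  start0 <- ca_site(sys$tail_truth, "A", sys$tail_res[1] - 1L)
  set.seed(123)
  n_steps <- length(sys$tail_res)
  E <- replicate(40000, {
    dirs <- matrix(rnorm(3 * n_steps), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2)) * 3.8
    tip <- start0 + colSums(dirs)
    flat_harmonic(sqrt(sum((tip - anchor)^2)), xp)
  })
  w <- exp(-E)                       # T = 1
  e_boltz <- sum(E * w) / sum(w)
  expect_equal(e_obs, e_boltz, tolerance = 0.05 / max(e_boltz, 0.2))
})
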