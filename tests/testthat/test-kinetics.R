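test_that("reference subtraction removes drift and non-specific signal", {
  tt <- simulate_bli(1.3e5, 0.031, Bmax = 1, concentrations = 1e-6,
                     t_assoc = 60, t_dissoc = 60,
                     noise = noise_spec(trace_sd = 0))
  ref0 <- trace_table(tt$t, ref = rep(0, nrow(tt)))
  expect_equal(reference_subtract(tt, ref0)[[2]], tt[[2]])

  self <- trace_table(tt$t, ref = tt[[2]])
  expect_equal(reference_subtract(tt, self)[[2]], rep(0, nrow(tt)))

  # planted linear drift is removed to within the noise level
  sdn <- 0.005
  drift <- 0.002 * tt$t
  noisy <- simulate_bli(1.3e5, 0.031, 1, 1e-6, 60, 60,
                        noise = noise_spec(trace_sd = sdn, seed = 3))
  drifted <- noisy
  drifted[[2]] <- drifted[[2]] + drift
  corr <- reference_subtract(drifted, trace_table(tt$t, ref = drift))
  expect_lt(sqrt(mean((corr[[2]] - tt[[2]])^2)), 2 * sdn)

  short <- trace_table(seq(200, 210), ref = rep(0, 11))
  expect_error(reference_subtract(tt, short), "time range")
})

test_that("dissociation fitting recovers the decay rate", {
  t <- seq(0, 120, by = 0.2)
  y <- 1.4 * exp(-0.031 * t)
  f <- fit_dissociation(trace_table(t, R = y))
  expect_equal(f$k_d, 0.031, tolerance = 1e-6 / 0.031)

  expect_error(fit_dissociation(trace_table(t, R = rep(1, length(t)))),
               "not decaying")

  set.seed(5)
  ests <- replicate(100, {
    yn <- y + rnorm(length(t), 0, 0.014)   # 1% of amplitude
    fit_dissociation(trace_table(t, R = yn))$k_d
  })
  expect_equal(mean(ests), 0.031, tolerance = 0.02)
})

test_that("association fitting applies the 1:1 rate relation", {
  # direct arithmetic on a synthetic trace with k_obs = 0.05
  t <- seq(0, 200, by = 0.2)
  y <- 0.8 * (1 - exp(-0.05 * t))
  f <- fit_association(trace_table(t, R = y), concentration = 1e-7,
                       k_d = 0.031)
  expect_equal(f$k_obs, 0.05, tolerance = 1e-6)
  expect_equal(f$k_a, (0.05 - 0.031) / 1e-7, tolerance = 1e-4)
  expect_equal(f$k_a, 1.9e5, tolerance = 1e-4)

  # generator truth at the study-scale rates: C = 1 uM
  tt <- simulate_bli(1.3e5, 0.031, Bmax = 1.2, concentrations = 1e-6,
                     t_assoc = 60, t_dissoc = 0,
                     noise = noise_spec(trace_sd = 0))
  truth <- attr(tt, "truth")[[1]]
  expect_equal(truth$k_obs, 0.161)
  fa <- fit_association(tt, concentration = 1e-6, k_d = 0.031)
  expect_equal(fa$k_obs, 0.161, tolerance = 5e-3)
  expect_equal(fa$k_a, 1.3e5, tolerance = 5e-3)

  # a trace rising slower than k_d is non-physical for the 1:1 model
  slow <- 0.8 * (1 - exp(-0.01 * t))
  expect_error(fit_association(trace_table(t, R = slow), 1e-6, k_d = 0.05),
               "non-physical")
})

test_that("replicate rates combine as mean k_d over mean k_a", {
  rc <- combine_kinetics(1.3e5, 0.031)
  expect_equal(rc$K_D, 0.031 / 1.3e5)
  expect_equal(round(rc$K_D * 1e6, 2), 0.24)

  expect_equal(combine_kinetics(2e5, 0.05)$k_a, 2e5)
  expect_equal(combine_kinetics(c(3, 3), c(1, 1))$k_a, 3)
  rc2 <- combine_kinetics(c(1e5, 1.6e5), c(0.03, 0.032))
  expect_equal(rc2$K_D, mean(c(0.03, 0.032)) / mean(c(1e5, 1.6e5)))
  expect_false(is.na(rc2$k_a_sd))
})

test_that("steady-state one-site fitting recovers K_D and Bmax", {
  KD <- 0.27e-6
  C <- c(0.05, 0.1, 0.25, 0.5, 1, 2, 5) * 1e-6
  R <- 2 * C / (KD + C)
  f <- fit_steady_state(C, R)
  expect_equal(f$K_D, KD, tolerance = 0.01)
  expect_equal(f$Bmax, 2, tolerance = 0.01)
  # fitted curve passes through Bmax/2 at C = K_D
  expect_equal(f$Bmax * f$K_D / (f$K_D + f$K_D), f$Bmax / 2)

  set.seed(8)
  ests <- replicate(200, {
    fit_steady_state(C, R + rnorm(length(C), 0, 0.02 * max(R)))$K_D
  })
  expect_equal(mean(ests), KD, tolerance = 0.03)

  expect_warning(fit_steady_state(C, 3e5 * C), "linear")
})

test_that("one-phase association fitting is exact on clean data", {
  t <- seq(0, 400, by = 1)
  y <- 5 + 3 * (1 - exp(-0.02 * t))
  f <- fit_one_phase(trace_table(t, F = y))
  expect_equal(f$k, 0.02, tolerance = 1e-6)
  expect_equal(f$y0, 5, tolerance = 1e-6)

  # invariance to a baseline offset
  f2 <- fit_one_phase(trace_table(t, F = y + 100))
  expect_equal(f2$k, f$k, tolerance = 1e-8)

  expect_error(fit_one_phase(trace_table(t, F = rep(5, length(t)))),
               "degenerate")
})

test_that("melting temperatures are recovered by both estimators", {
  mc <- simulate_melt(Tm = 52.5, slope = 2, noise = noise_spec(trace_sd = 0))
  f <- melt_tm(mc)
  expect_equal(f$Tm_sigmoid, 52.5, tolerance = 0.2 / 52.5)
  expect_equal(f$Tm_derivative, 52.5, tolerance = 0.2 / 52.5)
  expect_equal(f$Tm, f$Tm_sigmoid)

  # a 9-degree stabilization scenario
  m1 <- simulate_melt(45, 2, noise = noise_spec(trace_sd = 0.01, seed = 2))
  m2 <- simulate_melt(54, 2, noise = noise_spec(trace_sd = 0.01, seed = 3))
  dTm <- melt_tm(m2)$Tm - melt_tm(m1)$Tm
  expect_equal(dTm, 9, tolerance = 0.3 / 9)

  # temperature-axis equivariance
  sh <- mc; sh$t <- sh$t + 4
  expect_equal(melt_tm(sh)$Tm, f$Tm + 4, tolerance = 1e-6)

  flat <- trace_table(seq(25, 95, 0.5), F = rep(1, 141))
  expect_error(melt_tm(flat), "melt region|transition|inflection")
})

test_that("K_D fold changes reproduce the mutant-vs-wild-type ratio", {
  expect_equal(fold_change(2.3e-6, 24e-9), 95.83, tolerance = 1e-3)
  expect_equal(fold_change(1, 1), 1)
  expect_equal(fold_change(3, 7) * fold_change(7, 3), 1)
  expect_error(fold_change(-1, 2), "positive")
})

test_that("the full BLI pipeline recovers K_D within 5% at 1% noise", {
  k_a <- 1.3e5; k_d <- 0.031; Bmax <- 1
  concs <- c(0.25, 0.5, 1, 2) * 1e-6
  kds <- vapply(1:40, function(sd) {
    tt <- simulate_bli(k_a, k_d, Bmax, concs, t_assoc = 60, t_dissoc = 90,
                       noise = noise_spec(trace_sd = 0.01 * Bmax, seed = sd))
    drift <- 0.003 + 1e-4 * tt$t          # sensor drift on every channel
    for (j in seq_along(concs)) tt[[j + 1]] <- tt[[j + 1]] + drift
    tt2 <- reference_subtract(tt, trace_table(tt$t, ref = drift))
    ka_l <- numeric(0); kd_l <- numeric(0)
    for (j in seq_along(concs)) {
      col <- names(tt2)[j + 1]
      dis <- tt2[tt2$t > 60, c("t", col)]
      kd_i <- fit_dissociation(trace_table(dis$t, R = dis[[col]]))$k_d
      asc <- tt2[tt2$t <= 60, c("t", col)]
      ka_i <- fit_association(trace_table(asc$t, R = asc[[col]]),
                              concs[j], kd_i)$k_a
      ka_l <- c(ka_l, ka_i); kd_l <- c(kd_l, kd_i)
    }
    combine_kinetics(ka_l, kd_l)$K_D
  }, numeric(1))
  expect_equal(mean(kds), k_d / k_a, tolerance = 0.05)
})

test_that("fitted k_obs is affine in concentration with slope k_a", {
  k_a <- 1.3e5; k_d <- 0.031
  concs <- c(0.25, 0.5, 1, 2, 4) * 1e-6
  tt <- simulate_bli(k_a, k_d, 1, concs, t_assoc = 80, t_dissoc = 0,
                     noise = noise_spec(trace_sd = 0))
  kobs <- vapply(seq_along(concs), function(j) {
    fit_association(trace_table(tt$t, R = tt[[j + 1]]), concs[j],
                    k_d)$k_obs
  }, numeric(1))
  cf <- coef(lm(kobs ~ concs))
  expect_equal(unname(cf[2]), k_a, tolerance = 0.02)
  expect_equal(unname(cf[1]), k_d, tolerance = 0.02)

  # response-axis rescaling leaves the rates unchanged
  f1 <- fit_association(trace_table(tt$t, R = tt[[2]]), concs[1], k_d)
  f2 <- fit_association(trace_table(tt$t, R = 100 * tt[[2]]), concs[1], k_d)
  expect_equal(f2$k_obs, f1$k_obs, tolerance = 1e-8)
  expect_equal(f2$R_eq, 100 * f1$R_eq, tolerance = 1e-6)
})
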