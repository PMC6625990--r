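test_that("Debye profiles match closed forms and the brute-force oracle", {
  q <- seq(0.01, 0.3, by = 0.01)

  one <- point_structure(c(0, 0, 0))
  expect_equal(debye_profile(one, q, form = 3), rep(9, length(q)))

  two <- point_structure(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(debye_profile(two, q, form = 2),
               2 * 4 * (1 + sin(q * 10) / (q * 10)), tolerance = 1e-12)

  # 10 random sites vs an independent O(N^2) double loop
  s <- random_chain(10, seed = 5)
  f <- runif(10, 40, 80)
  xyz <- as.matrix(s$atoms[c("x", "y", "z")])
  oracle <- vapply(q, function(qq) {
    acc <- 0
    for (i in 1:10) for (j in 1:10) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      acc <- acc + f[i] * f[j] *
        (if (d == 0 || qq == 0) 1 else sin(qq * d) / (qq * d))
    }
    acc
  }, numeric(1))
  got <- debye_profile(s, q, form = f)
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_true(all(got > 0))
  # I(0) limit equals (sum f)^2
  expect_equal(debye_profile(s, c(0, 0.01), form = f)[1], sum(f)^2)
})

test_that("Guinier analysis recovers Rg from exact and model curves", {
  q <- seq(0.005, 0.2, by = 0.002)
  Rg <- 25
  cv <- saxs_curve(q, 100 * exp(-q^2 * Rg^2 / 3), rep(1, length(q)))
  g <- guinier(cv)
  expect_equal(g$Rg, 25, tolerance = 0.03 / 25)
  expect_equal(g$I0, 100, tolerance = 1e-3)
  expect_true(max(g$q_range) * g$Rg < 1.3 + 1e-6)

  # Debye profiles of generated structures vs coordinate Rg (globular
  # particles; strongly elongated ones carry the usual low-q Guinier bias)
  for (s in list(build_core(2), build_core(3), random_chain(30, seed = 5))) {
    rg_true <- coord_rg(s)
    I <- debye_profile(s, q)
    g2 <- guinier(saxs_curve(q, I, 0.01 * I))
    expect_equal(g2$Rg, rg_true, tolerance = 0.02)
  }

  # rising curve has no Guinier region
  expect_error(guinier(saxs_curve(q, exp(q^2 * 100), rep(1, length(q)))),
               "Guinier")
})

test_that("Guinier estimates average to truth under multiplicative noise", {
  q <- seq(0.005, 0.15, by = 0.002)
  Rg <- 25
  I0 <- exp(-q^2 * Rg^2 / 3) * 50
  set.seed(42)
  ests <- replicate(100, {
    guinier(saxs_curve(q, rnorm(length(q), I0, 0.02 * I0), 0.02 * I0))$Rg
  })
  expect_equal(mean(ests), Rg, tolerance = 0.01)
})

test_that("chi-square fitting uses the analytic scale", {
  q <- seq(0.01, 0.2, by = 0.01)
  I <- 100 * exp(-q^2 * 50)
  cv <- saxs_curve(q, I, 0.02 * I)
  f1 <- chi_square(I, cv)
  expect_equal(f1$scale, 1)
  expect_equal(f1$chi2, 0)

  f5 <- chi_square(I / 5, cv)    # experiment is 5x the model
  expect_equal(f5$scale, 5)
  expect_equal(f5$chi2, 0, tolerance = 1e-12)

  # 3-point hand computation, checked against a numeric minimizer
  cv3 <- saxs_curve(c(0.01, 0.02, 0.03), c(2, 1, 1), c(1, 1, 1))
  f3 <- chi_square(c(1, 1, 1), cv3)
  expect_equal(f3$scale, 4 / 3)
  expect_equal(f3$chi2, 1 / 3)
  obj <- function(cc) sum((c(2, 1, 1) - cc)^2) / 2
  opt <- optimize(obj, c(0, 10))
  expect_equal(f3$scale, opt$minimum, tolerance = 1e-5)
  expect_equal(f3$chi2, opt$objective, tolerance = 1e-9)

  expect_error(chi_square(I[-1], cv), "mismatch")
})

test_that("SEC-SAXS reduction averages peak frames and subtracts buffer", {
  q <- seq(0.01, 0.1, by = 0.01)
  sig <- function(I) pmax(0.05 * abs(I), 1e-3)
  signal <- 100 * exp(-q^2 * 30)
  bg <- rep(5, length(q))
  mkframe <- function(I) saxs_curve(q, I, sig(I))
  # identical peak frames over a zero-ish buffer: sigma shrinks as 1/sqrt(n)
  frames <- c(replicate(4, mkframe(signal), simplify = FALSE),
              list(saxs_curve(q, rep(0, length(q)), rep(1e-4, length(q)))))
  red <- reduce_sec_saxs(frames, peak_ids = 1:4, buffer_ids = 5)
  expect_equal(red$I, signal, tolerance = 1e-9)
  expect_equal(red$sigma, sqrt((sig(signal) / 2)^2 + 1e-8), tolerance = 1e-6)

  # buffer equal to peak cancels exactly
  red0 <- reduce_sec_saxs(list(mkframe(signal), mkframe(signal)), 1, 2)
  expect_equal(red0$I, rep(0, length(q)))

  # noisy frames: recovered signal within 3 sigma pointwise
  set.seed(7)
  noisy <- function(I) saxs_curve(q, rnorm(length(q), I, 0.5), rep(0.5, length(q)))
  fr <- c(lapply(1:6, function(i) noisy(signal + bg)),
          lapply(1:6, function(i) noisy(bg)))
  red2 <- reduce_sec_saxs(fr, 1:6, 7:12)
  expect_true(all(abs(red2$I - signal) < 3 * red2$sigma))

  expect_error(reduce_sec_saxs(fr, 1:6, 6:12), "overlap")

  # linearity in frame intensities
  fa <- mkframe(signal); fb <- mkframe(2 * signal)
  lhs <- reduce_sec_saxs(list(fa, fb, mkframe(bg)), 1:2, 3)$I
  expect_equal(lhs, (signal + 2 * signal) / 2 - bg, tolerance = 1e-9)
})

test_that("multi-state fitting recovers planted mixtures by enumeration", {
  q <- seq(0.01, 0.25, by = 0.005)
  # dumbbells with distinct separations give well-separated (oscillatory)
  # candidate profiles; closely similar smooth decays are not identifiable
  seps <- c(10, 20, 30, 40, 50, 60)
  pool <- lapply(seps, function(d)
    debye_profile(point_structure(rbind(c(0, 0, 0), c(d, 0, 0))), q))

  # experiment generated from candidate 4 alone
  Iexp <- 3 * pool[[4]]
  cv <- saxs_curve(q, Iexp, 0.01 * Iexp)
  f1 <- multistate_fit(pool, cv, max_states = 3)
  expect_equal(f1$members, 4L)
  expect_equal(sum(f1$weights), 1)
  expect_lt(f1$chi2, 0.05)

  # 50/50 mixture at 2% noise
  mix <- 0.5 * pool[[2]] + 0.5 * pool[[5]]
  set.seed(61)
  cvm <- saxs_curve(q, rnorm(length(q), mix, 0.02 * mix), 0.02 * mix)
  fm <- multistate_fit(pool, cvm, max_states = 2)
  expect_setequal(fm$members, c(2L, 5L))
  expect_true(all(abs(fm$weights - 0.5) <= 0.05))

  # nesting: best chi2 is non-increasing in max_states
  chis <- vapply(1:3, function(k) multistate_fit(pool, cvm, k)$chi2,
                 numeric(1))
  expect_true(all(diff(chis) <= 1e-9))

  # equals an independent brute-force enumeration: pair weights on a fine
  # grid with the analytic scale, singles in closed form
  A <- do.call(cbind, pool) / cvm$sigma
  b <- cvm$I / cvm$sigma
  brute_best <- Inf
  for (i in 1:6) {
    ci <- max(sum(A[, i] * b) / sum(A[, i]^2), 0)
    brute_best <- min(brute_best, sum((b - ci * A[, i])^2))
  }
  alpha <- seq(0, 1, by = 5e-4)
  for (sub in asplit(combn(6, 2), 2)) {
    for (a in alpha) {
      mprof <- a * A[, sub[1]] + (1 - a) * A[, sub[2]]
      cc <- max(sum(mprof * b) / sum(mprof^2), 0)
      brute_best <- min(brute_best, sum((b - cc * mprof)^2))
    }
  }
  brute_best <- brute_best / (length(q) - 1)
  f2 <- multistate_fit(pool, cvm, max_states = 2)
  expect_equal(f2$chi2, brute_best, tolerance = 1e-5)

  expect_error(multistate_fit(list(), cv), "empty")
})
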