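test_that("endpoint rate estimators follow the defining arithmetic", {
  # flat well: every rate zero
  flat <- data.frame(time_h = c(0, 48), n_nuclei = c(100, 100),
                     n_dead = c(0, 0))
  expect_equal(estimateRates(flat)[, c("k_p", "k_d", "k_b")],
               data.frame(k_p = 0, k_d = 0, k_b = 0))

  # division-wave counts: 320 -> 450 over 20 h, endpoint mean 385
  wave <- data.frame(time_h = c(0, 20), n_nuclei = c(320, 450),
                     n_dead = c(0, 0))
  est <- estimateRates(wave)
  expect_equal(est$k_p, 130 / (385 * 20))
  expect_equal(est$n_bar, 385)

  # net cell loss with matched dead-cell gain: k_b = 0
  loss <- data.frame(time_h = c(0, 10), n_nuclei = c(100, 90),
                     n_dead = c(0, 10))
  est <- estimateRates(loss)
  expect_equal(est$k_p, -10 / 950)
  expect_equal(est$k_d, 10 / 950)
  expect_equal(est$k_b, 0)
})

test_that("k_b = k_p + k_d exactly and per-capita rates ignore count rescaling", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(50:500, 2)
    m <- sort(sample(0:50, 2))
    traj <- data.frame(time_h = c(0, 24), n_nuclei = n, n_dead = m)
    est <- estimateRates(traj)
    expect_identical(est$k_b, est$k_p + est$k_d)
    scaled <- transform(traj, n_nuclei = n_nuclei * 7, n_dead = n_dead * 7)
    expect_equal(estimateRates(scaled)[, c("k_p", "k_d", "k_b")],
                 est[, c("k_p", "k_d", "k_b")])
  }
})

test_that("on exact exponentials the estimator equals (2/dt) tanh(r dt / 2)", {
  for (r in c(0.01, 0.033, 0.06)) {
    traj <- expTraj(r)
    est <- estimateRates(traj)
    dt <- 48
    expect_equal(est$k_p, (2 / dt) * tanh(r * dt / 2), tolerance = 1e-9)
    # hence relative bias is bounded by (r dt)^2 / 12
    expect_lt(abs(est$k_p - r) / r, (r * dt)^2 / 12 + 1e-9)
  }
})

test_that("the endpoint-sum compatibility convention halves the estimate", {
  traj <- expTraj(0.02)
  expect_equal(estimateRates(traj, convention = "sum")$k_p,
               estimateRates(traj)$k_p / 2)
})

test_that("window handling: endpoints must be sampled, degenerate input errors", {
  traj <- expTraj(0.02)
  sub <- estimateRates(traj, window = c(10, 30))
  expect_equal(unlist(sub[, c("t0", "tend")], use.names = FALSE), c(10, 30))
  expect_error(estimateRates(traj, window = c(1, 30)), "not a sampled time")
  expect_error(estimateRates(traj, window = c(30, 30)), "window")
  dead_well <- data.frame(time_h = c(0, 10), n_nuclei = c(0, 0),
                          n_dead = c(5, 5))
  expect_error(estimateRates(dead_well), "zero mean nuclei")
  noisy <- data.frame(time_h = 0:2, n_nuclei = c(10, 10, 10),
                      n_dead = c(3, 2, 3))
  expect_warning(estimateRates(noisy), "decrease")
})

test_that("fitExponential recovers generating rates on noiseless input", {
  fit <- fitExponential(expTraj(0.033))
  expect_equal(fit$k_p, 0.033, tolerance = 1e-8)
  expect_equal(fit$n0, 200, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # doubling time calibration: 21 h doubling -> k_p = ln 2 / 21
  dbl <- expTraj(log(2) / 21)
  expect_equal(log(2) / fitExponential(dbl)$k_p, 21, tolerance = 1e-6)

  flat <- data.frame(time_h = seq(0, 10, 2), n_nuclei = rep(50, 6),
                     n_dead = 0)
  expect_equal(fitExponential(flat)$k_p, 0)

  expect_error(fitExponential(expTraj(0.02)[1:2, ]), "insufficient")
  neg <- expTraj(0.02); neg$n_nuclei[3] <- 0
  expect_error(fitExponential(neg), "non-positive")
})

test_that("exponential fit and endpoint estimator agree when r dt is small", {
  r <- 0.033
  traj <- expTraj(r, dt = 1, horizon = 9)   # r * dt = 0.3
  expect_equal(estimateRates(traj)$k_p, fitExponential(traj)$k_p,
               tolerance = 0.02)
})

test_that("smoothed instantaneous rates recover constant and closed-form rates", {
  r <- 0.03
  ir <- instantaneousRates(expTraj(r))
  core <- ir[4:(nrow(ir) - 3), ]
  expect_true(all(abs(core$p_t - r) / r < 0.02))
  expect_equal(ir$b_t, ir$p_t + ir$d_t)

  # constant N with linearly growing M: d_t = slope / N
  m <- 0.5 * seq(0, 48, 2)
  traj <- data.frame(time_h = seq(0, 48, 2), n_nuclei = 100, n_dead = m)
  ir2 <- instantaneousRates(traj)
  expect_true(all(abs(ir2$d_t - 0.5 / 100) < 1e-10))

  # integral of p(t) approximates log(N_end / N_0) within 5%
  ir3 <- instantaneousRates(expTraj(0.02))
  integral <- sum(diff(ir3$time_h) * (ir3$p_t[-1] + ir3$p_t[-nrow(ir3)]) / 2)
  expect_equal(integral, log(expTraj(0.02)$n_nuclei[25] / 200),
               tolerance = 0.05)

  expect_error(instantaneousRates(expTraj(0.02)[1:4, ]), "at least 5")
})

test_that("phenotypes are rate differences vs plate-matched controls", {
  a <- data.frame(k_p = 0.01); b <- data.frame(k_p = 0.03)
  expect_equal(deltaVsControl(a, b), -0.02)
  expect_equal(deltaVsControl(b, b), 0)

  bits <- tinyScreenBits()
  des <- tinyDesign(inhibitorIds(bits$inhib), n_doses = 2, replicates = 2)
  scr <- simulateScreen(simConfig(noise = FALSE), des, bits$truth,
                        bits$inhib, seed = 8)
  rates <- estimateRates(scr)
  ph <- phenotypeTable(rates, plateMap(scr))
  expect_equal(nrow(ph), length(inhibitorIds(bits$inhib)) * 2)
  expect_true(all(ph$n_replicates == 2))

  # a plate lacking controls for its growth factor is an error
  pm <- plateMap(scr)
  pm$is_control <- FALSE
  expect_error(phenotypeTable(rates, pm), "no matched control")
})
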