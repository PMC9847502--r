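test_that("generatePanel places exactly the requested kinases above the filter", {
  for (case in list(c(369, 200), c(5, 0), c(8, 8))) {
    p <- generatePanel(case[1], case[2], seed = 1)
    expect_equal(nrow(p), case[1])
    expect_equal(sum(p$expression >= 1.5), case[2])
    expect_false(anyDuplicated(p$kinase_id) > 0)
    expect_true(all(p$expression >= 0))
  }
  expect_identical(generatePanel(50, 20, seed = 7),
                   generatePanel(50, 20, seed = 7))
  expect_error(generatePanel(5, 6, seed = 1), "n_expressed")
})

test_that("inhibition matrices have strong hits, weak background and full coverage", {
  p <- generatePanel(10, 10, seed = 2)
  m <- generateInhibitionMatrix(p, 10, hits_per_inhibitor = 1, seed = 2)
  r <- residualActivity(m)
  expect_true(all(r >= 0 & r <= 1))
  # with n_inhibitors * hits >= n_kinases every kinase is some inhibitor's hit
  hit_sets <- apply(r, 1, function(row) names(row)[row <= 0.2])
  expect_setequal(unique(unlist(hit_sets)), p$kinase_id)
  # zero hits: weak inhibition only
  m0 <- generateInhibitionMatrix(p, 3, hits_per_inhibitor = 0, seed = 3)
  expect_true(all(residualActivity(m0) >= 0.8))
  expect_error(generateInhibitionMatrix(data.frame(), 3), "non-empty")
})

test_that("dose mapping is single-site binding anchored at the reference point", {
  # hand-derived: residual 0.5 at 1 uM -> Kd = 1 uM -> 3/(3+1) at 3 uM
  expect_equal(inhibitionAtDose(0.5, 1, 3), 0.75)
  expect_equal(inhibitionAtDose(0.5, 1, 0), 0)
  # self-consistency: inhibition at the reference equals 1 - residual
  for (r in c(0.05, 0.3, 0.5, 0.9, 0.999))
    expect_equal(inhibitionAtDose(r, 1, 1), 1 - r, tolerance = 1e-6)
  # monotone non-decreasing in dose, for a spread of residuals
  doses <- c(0, 0.01, 0.1, 0.5, 1, 5, 50)
  for (r in c(0.02, 0.2, 0.8, 1)) {
    v <- inhibitionAtDose(r, 1, doses)
    expect_true(all(diff(v) >= 0))
    expect_true(all(v >= 0 & v <= 1))
  }
  expect_error(inhibitionAtDose(0.5, 1, -1), "non-negative")
})

test_that("ground truth respects sharing structure and eligibility", {
  bits <- tinyScreenBits()
  tr <- bits$truth
  expect_true(all(vapply(tr$weights, function(w)
    all(tr$shared_kinases %in% names(w)), logical(1))))
  expect_true(all(unlist(tr$weights) >= 0))
  expressed <- bits$panel$kinase_id[bits$panel$expression >= 1.5]
  expect_true(all(unlist(lapply(tr$weights, names)) %in% expressed))
})

test_that("a quiet well stays constant and a caspase-inhibited well never dies", {
  cfg <- simConfig(basal_death_rate = 0, noise = FALSE)
  traj <- simulateWell(cfg, list(gf_dose_ng_ml = 0), seed = 1)
  expect_true(all(traj$n_nuclei == traj$n_nuclei[1]))
  expect_true(all(traj$n_dead == 0))

  cfg2 <- simConfig(noise = FALSE)  # basal death present
  qvd <- simulateWell(cfg2, list(gf_dose_ng_ml = 0, caspase_inhibitor = TRUE),
                      seed = 2)
  expect_true(all(qvd$n_dead == 0))
})

test_that("trajectories conserve cells against the event log and M never decreases", {
  cfg <- simConfig(noise = FALSE)
  bits <- tinyScreenBits()
  conds <- list(
    list(growth_factor = "FGF2", gf_dose_ng_ml = 20),
    list(growth_factor = "FGF2", gf_dose_ng_ml = 0.2,
         inhibitor_id = inhibitorIds(bits$inhib)[1], inhibitor_dose_uM = 5),
    list(gf_dose_ng_ml = 0))
  for (s in 1:3) for (cond in conds) {
    traj <- simulateWell(cfg, cond, bits$truth, bits$inhib, seed = s)
    tc <- attr(traj, "true_counts"); ev <- attr(traj, "events")
    expect_equal(tc$n_nuclei + tc$n_dead - tc$n_nuclei[1], cumsum(ev$births))
    expect_true(all(diff(traj$n_dead) >= 0))
  }
  # with counting noise on, observed dead counts still never decrease
  traj <- simulateWell(simConfig(noise = TRUE),
                       list(growth_factor = "FGF2", gf_dose_ng_ml = 20),
                       bits$truth, bits$inhib, seed = 5)
  expect_true(all(diff(traj$n_dead) >= 0))
})

test_that("identical seeds reproduce wells and screens exactly", {
  cfg <- simConfig()
  cond <- list(growth_factor = "FGF2", gf_dose_ng_ml = 5)
  bits <- tinyScreenBits()
  expect_identical(simulateWell(cfg, cond, bits$truth, seed = 9),
                   simulateWell(cfg, cond, bits$truth, seed = 9))
  des <- tinyDesign(inhibitorIds(bits$inhib)[1:2])
  s1 <- simulateScreen(cfg, des, bits$truth, bits$inhib, seed = 3)
  s2 <- simulateScreen(cfg, des, bits$truth, bits$inhib, seed = 3)
  expect_identical(nucleiCounts(s1), nucleiCounts(s2))
  expect_identical(deadCounts(s1), deadCounts(s2))
})

test_that("simulateWell validates condition ids", {
  cfg <- simConfig()
  bits <- tinyScreenBits()
  expect_error(simulateWell(cfg, list(growth_factor = "EGF",
                                      gf_dose_ng_ml = 1), bits$truth),
               "unknown growth factor")
  expect_error(simulateWell(cfg, list(inhibitor_id = "nope",
                                      inhibitor_dose_uM = 1),
                            bits$truth, bits$inhib), "unknown inhibitor")
})

test_that("the default screen design matches the emulated protocol", {
  des <- screenDesign()
  trt <- des[!des$is_control, ]
  expect_equal(nrow(trt), 58 * 6 * 4 * 3)
  ladder <- sort(unique(trt$inhibitor_dose_uM), decreasing = TRUE)
  expect_length(ladder, 6)
  expect_equal(ladder[1], 5)
  expect_equal(ladder[-6] / ladder[-1], rep(3, 5), tolerance = 1e-12)
  # every plate carries vehicle controls for its growth factor
  expect_true(all(tapply(des$is_control, des$plate_id, any)))
  expect_true(all(table(des$plate_id) <= 384))
})

test_that("screen bookkeeping: well count equals design size, missing controls fail", {
  bits <- tinyScreenBits()
  des <- tinyDesign(inhibitorIds(bits$inhib)[1:2])
  scr <- simulateScreen(simConfig(), des, bits$truth, bits$inhib, seed = 1)
  expect_equal(ncol(scr), nrow(des))
  bad <- des[!des$is_control, ]
  expect_error(simulateScreen(simConfig(), bad, bits$truth, bits$inhib),
               "without vehicle controls")
})

test_that("mean final population is non-decreasing in growth-factor dose", {
  cfg <- simConfig(noise = FALSE)
  meanFinal <- function(dose) {
    mean(vapply(1:100, function(s) {
      tr <- simulateWell(cfg, list(growth_factor = "FGF2",
                                   gf_dose_ng_ml = dose),
                         tinyScreenBits()$truth, seed = s + dose * 1000)
      tr$n_nuclei[nrow(tr)]
    }, numeric(1)))
  }
  finals <- vapply(c(0, 0.3, 5), meanFinal, numeric(1))
  # non-decreasing within Monte-Carlo error (sem of ~1-2 cells)
  expect_true(all(diff(finals) > -3))
  expect_gt(finals[3], finals[1] + 30)  # saturating dose drives a real wave
})
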