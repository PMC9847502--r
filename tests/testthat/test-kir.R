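test_that("expression filtering keeps exactly the kinases at or above the cutoff", {
  r <- matrix(runif(6, 0.8, 1), 2, 3,
              dimnames = list(c("i1", "i2"), c("A", "B", "C")))
  m <- InhibitionMatrix(r)
  panel <- data.frame(kinase_id = c("A", "B", "C"),
                      expression = c(2.0, 1.0, 1.5))
  expect_identical(kinaseIds(filterByExpression(m, panel, 1.5)), c("A", "C"))
  expect_identical(kinaseIds(filterByExpression(m, panel, 0)),
                   c("A", "B", "C"))
  short <- data.frame(kinase_id = c("A", "B"), expression = c(2, 2))
  expect_error(filterByExpression(m, short), "absent from the expression")
})

test_that("the design matrix maps doses through single-site binding", {
  bits <- tinyScreenBits()
  ph <- simulatePhenotypes(bits$truth, bits$inhib, seed = 3)
  des <- buildDesign(bits$inhib, ph, "FGF2")
  expect_equal(nrow(des$X), length(inhibitorIds(bits$inhib)) * 6)
  expect_equal(ncol(des$X), length(kinaseIds(bits$inhib)))
  expect_true(all(des$X >= 0 & des$X <= 1))
  # one entry recomputed by hand
  i <- 17
  expect_equal(unname(des$X[i, 3]),
               inhibitionAtDose(
                 residualActivity(bits$inhib)[des$rows$inhibitor_id[i], 3],
                 assayConcentration(bits$inhib), des$rows$dose_uM[i]))
  # a dose-0 row would carry an all-zero feature row
  ph0 <- ph[ph$growth_factor == "FGF2", ][1, ]
  ph0$dose_uM <- 0
  expect_true(all(buildDesign(bits$inhib, ph0, "FGF2")$X == 0))
  # missing profiles are named
  ph_bad <- ph; ph_bad$inhibitor_id[1] <- "ghost"
  expect_error(buildDesign(bits$inhib, ph_bad, "FGF2"), "ghost")
})

test_that("elastic net at fixed lambda matches direct minimization of the objective", {
  set.seed(10)
  for (case in list(list(p = 4, n = 20, alpha = 0.15, lambda = 0.02),
                    list(p = 8, n = 30, alpha = 0.15, lambda = 0.005),
                    list(p = 6, n = 25, alpha = 0.5, lambda = 0.01),
                    list(p = 8, n = 30, alpha = 1, lambda = 0.03))) {
    X <- matrix(rnorm(case$n * case$p), case$n)
    colnames(X) <- paste0("K", seq_len(case$p))
    beta <- c(1.5, -2, rep(0, case$p - 2))
    y <- as.vector(X %*% beta + rnorm(case$n, 0, 0.3))
    ours <- enetCoef(X, y, case$alpha, case$lambda, standardize = FALSE)[, 1]
    oracle <- enetOracle(X, y, case$alpha, case$lambda)
    expect_lt(max(abs(ours - oracle)), 1e-4)
  }
})

test_that("penalty limits: huge lambda gives the null model, tiny lambda approaches OLS", {
  set.seed(11)
  X <- matrix(rnorm(40 * 5), 40); colnames(X) <- paste0("K", 1:5)
  y <- as.vector(X %*% c(1, -1, 0.5, 0, 0) + rnorm(40, 0, 0.1))
  hi <- enetCoef(X, y, 0.15, 1e6, standardize = FALSE)[, 1]
  expect_true(all(hi[-1] == 0))
  expect_equal(unname(hi[1]), mean(y))
  lo <- enetCoef(X, y, 0.01, 1e-8, standardize = FALSE)[, 1]
  ols <- coef(lm(y ~ X))
  expect_lt(max(abs(lo - ols)), 1e-3)
})

test_that("fitKir selects a planted kinase and is reproducible and order-invariant", {
  set.seed(12)
  bits <- tinyScreenBits(n_kinases = 6, n_expressed = 6, n_inhibitors = 6,
                         hits = 2)
  doses <- rep(5 / 3^(0:5), length.out = 102)
  inhs <- rep(inhibitorIds(bits$inhib), length.out = 102)
  ph <- data.frame(growth_factor = "FGF2", inhibitor_id = inhs,
                   dose_uM = doses, delta_kp = NA_real_)
  r <- residualActivity(bits$inhib)
  xa <- inhibitionAtDose(r[cbind(inhs, "KIN001")], 1, doses)
  ph$delta_kp <- -0.02 * xa      # noiseless single-kinase signal
  des <- buildDesign(bits$inhib, ph, "FGF2")
  rk <- fitKir(des, kirConfig(cv_folds = 5), seed = 3)
  expect_identical(rk$kinase_id[1], "KIN001")
  expect_lt(rk$coefficient[1], 0)
  expect_identical(rk, fitKir(des, kirConfig(cv_folds = 5), seed = 3))

  # permuting feature columns permutes nothing in the returned ranking
  des2 <- des
  perm <- rev(seq_len(ncol(des$X)))
  des2$X <- des$X[, perm]
  rk2 <- fitKir(des2, kirConfig(cv_folds = 5), seed = 3)
  expect_identical(rk$kinase_id, rk2$kinase_id)
  expect_equal(rk$coefficient, rk2$coefficient, tolerance = 1e-2)

  # degenerate response: empty ranking with a warning
  des$y <- rep(0, length(des$y))
  expect_warning(rk0 <- fitKir(des, kirConfig(cv_folds = 5), seed = 1),
                 "degenerate")
  expect_equal(nrow(rk0), 0)
})

test_that("rank-sum intersection follows the brute-force enumeration", {
  mk <- function(ids) data.frame(kinase_id = ids, coefficient = -1,
                                 rank = seq_along(ids))
  out <- intersectRankSum(list(g1 = mk(c("A", "B", "C")),
                               g2 = mk(c("B", "C", "D")),
                               g3 = mk(c("C", "B"))))
  expect_identical(out$kinase_id, c("B", "C"))   # B: 2+1+2=5 < C: 3+2+1=6
  expect_equal(out$rank_sum, c(5, 6))

  same <- intersectRankSum(list(a = mk(c("X", "Y")), b = mk(c("X", "Y"))))
  expect_identical(same$kinase_id, c("X", "Y"))

  none <- intersectRankSum(list(a = mk("A"), b = mk("B")))
  expect_equal(nrow(none), 0)

  # rank-sum ties break lexicographically by kinase id
  tie <- intersectRankSum(list(a = mk(c("Z", "A")), b = mk(c("A", "Z"))))
  expect_identical(tie$kinase_id, c("A", "Z"))

  expect_error(intersectRankSum(list(mk("A"))), "at least two")
})
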