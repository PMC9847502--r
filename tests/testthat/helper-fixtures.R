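# Fixtures are built in code: an exact exponential trajectory, a miniature
# screen (panel / inhibition matrix / ground truth), and siRNA datasets with
# planted effects.

expTraj <- function(r, n0 = 200, dt = 2, horizon = 48, m = 0) {
  t <- seq(0, horizon, by = dt)
  data.frame(time_h = t, n_nuclei = n0 * exp(r * t),
             n_dead = if (length(m) == 1L) rep(m, length(t)) else m)
}

tinyScreenBits <- function(n_kinases = 12, n_expressed = 10,
                           n_inhibitors = 6, hits = 2, seed = 42) {
  panel <- generatePanel(n_kinases, n_expressed, seed = seed)
  inhib <- generateInhibitionMatrix(panel, n_inhibitors,
                                    hits_per_inhibitor = hits, seed = seed + 1)
  truth <- generateGroundTruth(panel, c("FGF2", "VEGFA"), n_true = 2,
                               n_shared = 1, inhibition = inhib,
                               seed = seed + 2)
  list(panel = panel, inhib = inhib, truth = truth)
}

tinyDesign <- function(inhibitors, n_doses = 2, replicates = 2,
                       gfs = c(FGF2 = 1.25)) {
  screenDesign(growth_factors = gfs, inhibitors = inhibitors,
               dose_ladder = 5 / 3^(seq_len(n_doses) - 1),
               replicates = replicates, controls_per_plate = 4)
}

# Direct numerical minimizer of the elastic-net objective
#   (1/2n) sum (y - b0 - Xb)^2 + lambda (alpha |b|_1 + (1-alpha)/2 |b|_2^2)
# used as an independent oracle for the penalized fit. The L1 term is smoothed
# by sqrt(b^2 + eps) with eps far below the comparison tolerance.
enetOracle <- function(X, y, alpha, lambda, eps = 1e-14) {
  n <- nrow(X)
  obj <- function(par) {
    b0 <- par[1]; b <- par[-1]
    sum((y - b0 - X %*% b)^2) / (2 * n) +
      lambda * (alpha * sum(sqrt(b^2 + eps)) +
                  (1 - alpha) / 2 * sum(b^2))
  }
  gr <- function(par) {
    b0 <- par[1]; b <- par[-1]
    rsd <- as.vector(y - b0 - X %*% b)
    c(-sum(rsd) / n,
      -crossprod(X, rsd) / n +
        lambda * (alpha * b / sqrt(b^2 + eps) + (1 - alpha) * b))
  }
  fit <- optim(rep(0, ncol(X) + 1), obj, gr, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  fit$par
}

# siRNA replicate-level measurements: `reductions` is a named list
# gene -> fractional k_p reduction (0 = same as control).
sirnaMeasurements <- function(reductions, control_kp = 0.03, n_rep = 4,
                              noise_sd = 0, gf = "FGF2", seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(names(reductions), function(g) {
    do.call(rbind, lapply(1:3, function(si) data.frame(
      gene = g, sirna_index = si, growth_factor = gf,
      k_p = control_kp * (1 - reductions[[g]]) +
        rnorm(n_rep, 0, noise_sd))))
  }))
}
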