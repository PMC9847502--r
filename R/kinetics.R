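## Population-kinetics estimators. The per-capita proliferation rate p(t) is
## defined through dN/dt = p(t) N(t) and the death rate through
## dM/dt = D(t) N(t), where N is the live-nuclei count and M the cumulative
## dead-cell count; the birth rate is B(t) = p(t) + D(t). The per-well
## endpoint estimators are
##   kP = (N(tend) - N(t0)) / (Nbar (tend - t0)),
##   kD = (M(tend) - M(t0)) / (Nbar (tend - t0)),  kB = kP + kD,
## with Nbar the endpoint mean (N(t0) + N(tend)) / 2. On exact exponential
## data this estimator returns (2/dt) tanh(r dt / 2) -> r as dt -> 0; the
## variant with the endpoint SUM in the denominator (which converges to r/2)
## is available behind convention = "sum" for compatibility.

ratesFromEndpoints <- function(n0, n1, m0, m1, t0, t1, convention) {
  dt <- t1 - t0
  if (dt <= 0) stop("undefined rate: zero-length window", call. = FALSE)
  nbar <- switch(convention,
                 mean = (n0 + n1) / 2,
                 sum  = (n0 + n1))
  if (nbar <= 0) stop("undefined rate: zero mean nuclei count", call. = FALSE)
  k_p <- (n1 - n0) / (nbar * dt)
  k_d <- (m1 - m0) / (nbar * dt)
  data.frame(k_p = k_p, k_d = k_d, k_b = k_p + k_d, n_bar = nbar,
             t0 = t0, tend = t1)
}

resolveWindow <- function(times, window) {
  if (is.null(window)) return(c(times[1L], times[length(times)]))
  stopIfNot(length(window) == 2L && window[1L] < window[2L],
            "window must be (t0, tend) with t0 < tend")
  for (w in window)
    stopIfNot(any(abs(times - w) < 1e-8),
              sprintf("window endpoint %g is not a sampled time", w))
  window
}

#' Estimate per-well proliferation, death and birth rates
#'
#' Endpoint estimators of the per-capita proliferation rate
#' \eqn{k_P = \Delta N / (\bar N \Delta t)}, death rate
#' \eqn{k_D = \Delta M / (\bar N \Delta t)} and birth rate
#' \eqn{k_B = k_P + k_D} over a time window, with \eqn{\bar N} the endpoint
#' mean \eqn{(N(t_0) + N(t_{end}))/2}.
#'
#' @param x a trajectory data.frame (`time_h`, `n_nuclei`, `n_dead`) or a
#'   [ProliferationScreen-class] (one estimate per well).
#' @param window optional `c(t0, tend)`, both sampled times; defaults to the
#'   full trajectory for a data.frame and, for a screen, to the
#'   growth-factor-addition-to-end window when the screen metadata records a
#'   `gf_addition_time`.
#' @param convention `"mean"` (endpoint mean, the default: converges to the
#'   true rate on exponential data) or `"sum"` (endpoint sum denominator,
#'   which converges to half the rate; compatibility only).
#' @param ... unused.
#' @return data.frame with columns `k_p`, `k_d`, `k_b` (per hour), `n_bar`,
#'   `t0`, `tend`, plus `well_id` for the screen method.
#' @examples
#' traj <- data.frame(time_h = c(0, 20), n_nuclei = c(320, 450),
#'                    n_dead = c(0, 0))
#' estimateRates(traj)   # k_p = 130 / (385 * 20)
#' @rdname estimateRates
#' @export
setMethod("estimateRates", "data.frame",
  function(x, window = NULL, convention = c("mean", "sum"), ...) {
    convention <- match.arg(convention)
    stopIfNot(all(c("time_h", "n_nuclei", "n_dead") %in% names(x)),
              "trajectory needs columns time_h, n_nuclei, n_dead")
    stopIfNot(nrow(x) >= 2L, "need at least two time points")
    if (any(diff(x$n_dead) < 0))
      warning("dead-cell counts decrease within the trajectory")
    w <- resolveWindow(x$time_h, window)
    i0 <- which.min(abs(x$time_h - w[1L]))
    i1 <- which.min(abs(x$time_h - w[2L]))
    ratesFromEndpoints(x$n_nuclei[i0], x$n_nuclei[i1],
                       x$n_dead[i0], x$n_dead[i1],
                       x$time_h[i0], x$time_h[i1], convention)
  })

#' @rdname estimateRates
#' @export
setMethod("estimateRates", "ProliferationScreen",
  function(x, window = NULL, convention = c("mean", "sum"), ...) {
    convention <- match.arg(convention)
    tt <- timesHours(x)
    if (is.null(window)) {
      gat <- metadata(x)$config$gf_addition_time
      window <- if (!is.null(gat) && any(abs(tt - gat) < 1e-8))
        c(gat, tt[length(tt)]) else c(tt[1L], tt[length(tt)])
    }
    w <- resolveWindow(tt, window)
    i0 <- which.min(abs(tt - w[1L])); i1 <- which.min(abs(tt - w[2L]))
    nmat <- nucleiCounts(x); mmat <- deadCounts(x)
    out <- do.call(rbind, lapply(seq_len(ncol(x)), function(j)
      ratesFromEndpoints(nmat[i0, j], nmat[i1, j], mmat[i0, j], mmat[i1, j],
                         tt[i0], tt[i1], convention)))
    cbind(well_id = colnames(x), out)
  })

#' Fit an exponential growth model to a trajectory
#'
#' Least-squares fit of \eqn{\log N} against time, the solution
#' \eqn{N(t) = N_0 e^{k_P t}} of constant-rate growth. On noiseless
#' exponential input the generating rate is recovered to machine precision.
#'
#' @param traj trajectory data.frame (`time_h`, `n_nuclei`).
#' @param window optional `c(t0, tend)` restricting the fit.
#' @return data.frame with `n0`, `k_p`, `r_squared`.
#' @export
fitExponential <- function(traj, window = NULL) {
  stopIfNot(all(c("time_h", "n_nuclei") %in% names(traj)),
            "trajectory needs columns time_h, n_nuclei")
  w <- resolveWindow(traj$time_h, window)
  sel <- traj$time_h >= w[1L] - 1e-8 & traj$time_h <= w[2L] + 1e-8
  t <- traj$time_h[sel]; n <- traj$n_nuclei[sel]
  stopIfNot(length(t) >= 3L, "insufficient data: need >= 3 points")
  stopIfNot(all(n > 0), "invalid input: non-positive nuclei count in window")
  fit <- stats::lm(log(n) ~ t)
  ss_tot <- sum((log(n) - mean(log(n)))^2)
  # constant or perfectly fitted series count as r^2 = 1
  r2 <- if (ss_tot > 0) 1 - sum(stats::resid(fit)^2) / ss_tot else 1
  data.frame(n0 = exp(unname(stats::coef(fit)[1L])),
             k_p = unname(stats::coef(fit)[2L]),
             r_squared = r2)
}

#' Smoothed time-dependent proliferation, death and birth rates
#'
#' Counts are smoothed by a local-quadratic (Savitzky--Golay) filter with
#' reflect-padded ends; derivatives are taken by central differences on the
#' smoothed series; then \eqn{p(t) = N'(t)/N(t)}, \eqn{D(t) = M'(t)/N(t)} and
#' \eqn{B(t) = p(t) + D(t)}. Points where the smoothed nuclei count is
#' non-positive yield `NA` rates.
#'
#' @param x trajectory data.frame (`time_h`, `n_nuclei`, `n_dead`) with at
#'   least 5 points, uniformly sampled.
#' @param smooth_hours width of the smoothing window in hours (default 10,
#'   i.e. 5 samples at a 2 h imaging interval).
#' @param ... unused.
#' @return data.frame `time_h`, `p_t`, `d_t`, `b_t` with attribute
#'   `smoothing` describing the filter.
#' @rdname instantaneousRates
#' @export
setMethod("instantaneousRates", "data.frame",
  function(x, smooth_hours = 10, ...) {
    stopIfNot(all(c("time_h", "n_nuclei", "n_dead") %in% names(x)),
              "trajectory needs columns time_h, n_nuclei, n_dead")
    stopIfNot(nrow(x) >= 5L, "need at least 5 time points")
    dt <- stats::median(diff(x$time_h))
    win <- max(3L, as.integer(round(smooth_hours / dt)))
    if (win %% 2L == 0L) win <- win + 1L
    ns <- sgSmooth(x$n_nuclei, win)
    ms <- sgSmooth(x$n_dead, win)
    dn <- gridDeriv(ns, x$time_h)
    dm <- gridDeriv(ms, x$time_h)
    bad <- ns <= 0
    p_t <- ifelse(bad, NA_real_, dn / ns)
    d_t <- ifelse(bad, NA_real_, dm / ns)
    out <- data.frame(time_h = x$time_h, p_t = p_t, d_t = d_t,
                      b_t = p_t + d_t)
    attr(out, "smoothing") <-
      sprintf("local quadratic, %d samples (%.1f h), reflect-padded", win,
              win * dt)
    out
  })

#' Phenotype of a treated well relative to its plate-matched control
#'
#' @param case,control rate estimates ([estimateRates()] rows); `control` is
#'   typically the mean over the plate's vehicle-control wells.
#' @return the proliferation-rate difference `case$k_p - control$k_p`
#'   (per hour).
#' @export
deltaVsControl <- function(case, control) {
  stopIfNot(is.finite(control$k_p[1L]), "missing control estimate")
  case$k_p - control$k_p[1L]
}

#' Per-condition phenotype table from well rates
#'
#' Computes, for every (growth factor, inhibitor, dose) combination, the mean
#' proliferation-rate difference vs the matched vehicle-control wells on the
#' same plate and growth factor. Replicate wells are combined as the mean of
#' per-well rates.
#'
#' @param rates per-well rate table ([estimateRates()] on a screen).
#' @param platemap platemap data.frame aligned with `rates` by `well_id`.
#' @return data.frame `growth_factor`, `inhibitor_id`, `dose_uM`, `delta_kp`,
#'   `n_replicates`.
#' @export
phenotypeTable <- function(rates, platemap) {
  df <- merge(rates, platemap, by = "well_id")
  ctrl <- df[df$is_control %in% TRUE, ]
  trt <- df[!(df$is_control %in% TRUE) & !is.na(df$inhibitor_id), ]
  key <- function(d) paste(d$plate_id, d$growth_factor, sep = "\r")
  ctrl_mean <- tapply(ctrl$k_p, key(ctrl), mean)
  missing <- setdiff(unique(key(trt)), names(ctrl_mean))
  stopIfNot(length(missing) == 0L,
            paste("no matched control wells for plate/growth factor:",
                  paste(gsub("\r", "/", missing), collapse = ", ")))
  trt$delta <- trt$k_p - unname(ctrl_mean[key(trt)])
  agg <- stats::aggregate(
    delta ~ growth_factor + inhibitor_id + inhibitor_dose_uM, data = trt,
    FUN = mean)
  cnt <- stats::aggregate(
    delta ~ growth_factor + inhibitor_id + inhibitor_dose_uM, data = trt,
    FUN = length)
  out <- data.frame(growth_factor = agg$growth_factor,
                    inhibitor_id = agg$inhibitor_id,
                    dose_uM = agg$inhibitor_dose_uM,
                    delta_kp = agg$delta,
                    n_replicates = cnt$delta)
  out[order(out$growth_factor, out$inhibitor_id, -out$dose_uM), ]
}
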