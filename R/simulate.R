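## Stochastic well simulator. Cells occupy states {quiescent, committed,
## dead}. Growth-factor addition commits a dose-dependent fraction of
## quiescent cells to the cycle; committed cells exit G0 after a log-normal
## delay and divide once a cycle time later, producing the semi-synchronous
## division wave characteristic of G0-synchronized endothelial cells
## (population birth rate rising ~20 h and peaking ~30 h after stimulation).
## Death is a low basal apoptotic hazard, suppressed by growth factor and
## abolished by a caspase-inhibitor flag; strongly inhibited wells gain a
## toxicity hazard. Dynamics advance as a discrete-time tau-leap at the
## imaging interval with per-cell state.

#' Simulation configuration
#'
#' Assembles and validates the parameters of the stochastic well simulator.
#' The defaults reproduce the calibration of the assay being emulated: 255
#' cells plated per 384-plate well, growth factor added 24 h after plating,
#' imaging every 2 h for 48 h thereafter, a 21 h mean cell-cycle length, and a
#' G0-exit delay placing the first post-stimulation divisions near 29 h so the
#' population birth rate rises around 20 h and peaks around 30 h after
#' addition.
#'
#' @param n_cells cells plated per well (default 255).
#' @param imaging_interval hours between images (default 2).
#' @param horizon hours of imaging after growth-factor addition (default 48).
#' @param gf_addition_time hours after plating at which growth factor is added
#'   (default 24).
#' @param mean_cycle_length,cycle_sd mean and sd (hours) of the division-cycle
#'   time (defaults 21 and 2).
#' @param basal_death_rate basal apoptotic hazard per cell per hour in basal
#'   medium (default 0.0015).
#' @param residual_death_rate non-apoptotic death hazard remaining under
#'   caspase inhibition (default 0).
#' @param death_suppression maximal fractional suppression of the apoptotic
#'   hazard by saturating growth factor (default 0.9).
#' @param commitment_emax maximal fraction of quiescent cells committed to the
#'   cycle by saturating growth factor (default 0.45; even the most
#'   efficacious factor drives only a minority of the population to divide).
#' @param commitment_ec50 growth-factor dose (ng/ml) of half-maximal
#'   commitment (default 0.3).
#' @param g0_exit_delay_mean,g0_exit_delay_sd mean and sd (hours) of the
#'   log-normal delay between commitment and G0 exit (defaults 8 and 4).
#' @param tox_threshold,tox_rate above a ground-truth-weighted inhibition load
#'   of `tox_threshold`, inhibitors add `tox_rate` per-hour death (defaults
#'   0.8 and 0.05).
#' @param noise logical, apply counting noise (default TRUE): per-cell label
#'   detection with probability `detection_prob` plus multiplicative nuclei
#'   counting error of CV `count_cv`.
#' @param detection_prob,count_cv counting-noise parameters (defaults 0.97 and
#'   0.03, the labeling efficiency and counting error of the emulated assay).
#' @param seed default integer seed recorded with the configuration.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(n_cells = 255L, imaging_interval = 2, horizon = 48,
                      gf_addition_time = 24, mean_cycle_length = 21,
                      cycle_sd = 2, basal_death_rate = 0.0015,
                      residual_death_rate = 0, death_suppression = 0.9,
                      commitment_emax = 0.45, commitment_ec50 = 0.3,
                      g0_exit_delay_mean = 8, g0_exit_delay_sd = 4,
                      tox_threshold = 0.8, tox_rate = 0.05,
                      noise = TRUE, detection_prob = 0.97, count_cv = 0.03,
                      seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopIfNot(n_cells >= 0, "n_cells must be non-negative")
    stopIfNot(imaging_interval > 0 && horizon > 0 && gf_addition_time > 0 &&
              mean_cycle_length > 0, "times must be positive")
    stopIfNot(death_suppression >= 0 && death_suppression <= 1 &&
              commitment_emax >= 0 && commitment_emax <= 1 &&
              detection_prob >= 0 && detection_prob <= 1,
              "fractions must lie in [0, 1]")
    stopIfNot(basal_death_rate >= 0 && residual_death_rate >= 0 &&
              tox_rate >= 0, "rates must be non-negative")
  })
  structure(cfg, class = "SimConfig")
}

## log-normal parameters from target mean/sd
lnormPars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one well of the proliferation assay
#'
#' @param config a [simConfig()] list.
#' @param condition named list describing the well: `growth_factor` (id or
#'   NA), `gf_dose_ng_ml`, `inhibitor_id` (id or NA), `inhibitor_dose_uM`,
#'   optional `caspase_inhibitor` flag.
#' @param truth optional [generateGroundTruth()] object; required when the
#'   condition names an inhibitor together with a growth factor.
#' @param inhibition optional [InhibitionMatrix-class]; required with an
#'   inhibitor.
#' @param seed integer seed.
#' @return data.frame trajectory (`time_h`, `n_nuclei`, `n_dead`), timestamped
#'   in hours since plating. Attributes: `events` (per-interval true births
#'   and deaths), `true_counts` (noise-free N and M), `condition`.
#' @export
simulateWell <- function(config, condition, truth = NULL, inhibition = NULL,
                         seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  cond <- normalizeCondition(condition, truth, inhibition)
  set.seed(seed)
  dt <- config$imaging_interval
  times <- seq(0, config$gf_addition_time + config$horizon, by = dt)
  t_add <- config$gf_addition_time
  dose <- cond$gf_dose_ng_ml

  ## commitment probability: dose-dependent, scaled down by the ground-truth
  ## weighted inhibition load (linear effect, clipped at zero)
  load <- 0
  if (!is.na(cond$inhibitor_id) && !is.null(truth) &&
      !is.na(cond$growth_factor)) {
    load <- truthLoad(truth$weights[[cond$growth_factor]], inhibition,
                      cond$inhibitor_id, cond$inhibitor_dose_uM)
  }
  p_commit <- config$commitment_emax * hillSat(dose, config$commitment_ec50) *
    max(0, 1 - load)

  ## death hazards (per hour)
  h_basal <- if (isTRUE(cond$caspase_inhibitor)) config$residual_death_rate
             else config$basal_death_rate
  h_post <- h_basal *
    (1 - config$death_suppression * hillSat(dose, config$commitment_ec50))
  if (isTRUE(cond$caspase_inhibitor)) h_post <- config$residual_death_rate
  h_tox <- if (load > config$tox_threshold) config$tox_rate else 0

  lp <- lnormPars(config$g0_exit_delay_mean,
                  max(config$g0_exit_delay_sd, 1e-6))

  n0 <- config$n_cells
  alive <- rep(TRUE, n0)
  div_time <- rep(NA_real_, n0)       # scheduled division time, NA = none
  labeled <- if (config$noise)
    stats::runif(n0) < config$detection_prob else rep(TRUE, n0)
  dead_labeled <- 0L
  n_dead <- 0L
  nt <- length(times)
  N_true <- M_true <- N_obs <- M_obs <- integer(nt)
  births <- deaths <- integer(nt)     # events within (t[i-1], t[i]]

  record <- function(i) {
    N_true[i] <<- sum(alive)
    M_true[i] <<- n_dead
    nl <- sum(alive & labeled)
    if (config$noise)
      nl <- max(0L, as.integer(round(nl * (1 + stats::rnorm(1, 0, config$count_cv)))))
    N_obs[i] <<- nl
    M_obs[i] <<- dead_labeled
  }
  record(1L)

  for (i in 2L:nt) {
    t_prev <- times[i - 1L]; t_now <- times[i]
    ## growth-factor addition: commit a fraction of quiescent survivors
    if (t_prev < t_add && t_add <= t_now && p_commit > 0) {
      quies <- which(alive & is.na(div_time))
      commit <- quies[stats::runif(length(quies)) < p_commit]
      if (length(commit)) {
        delay <- stats::rlnorm(length(commit), lp$meanlog, lp$sdlog)
        cycle <- pmax(1, stats::rnorm(length(commit),
                                      config$mean_cycle_length,
                                      config$cycle_sd))
        div_time[commit] <- t_add + delay + cycle
      }
    }
    ## divisions scheduled in this interval (committed cells divide once;
    ## daughters are quiescent under a single growth-factor pulse)
    due <- which(alive & !is.na(div_time) & div_time > t_prev &
                   div_time <= t_now)
    if (length(due)) {
      div_time[due] <- NA_real_
      nb <- length(due)
      alive <- c(alive, rep(TRUE, nb))
      div_time <- c(div_time, rep(NA_real_, nb))
      labeled <- c(labeled, if (config$noise)
        stats::runif(nb) < config$detection_prob else rep(TRUE, nb))
      births[i] <- nb
    }
    ## deaths: tau-leap Bernoulli on the interval hazard
    h <- (if (t_now <= t_add) h_basal else h_post) + h_tox
    if (h > 0) {
      idx <- which(alive)
      p_die <- 1 - exp(-h * (t_now - t_prev))
      dies <- idx[stats::runif(length(idx)) < p_die]
      if (length(dies)) {
        alive[dies] <- FALSE
        n_dead <- n_dead + length(dies)
        dead_labeled <- dead_labeled + sum(labeled[dies])
        deaths[i] <- length(dies)
      }
    }
    record(i)
  }

  out <- data.frame(time_h = times, n_nuclei = N_obs, n_dead = M_obs)
  attr(out, "events") <- data.frame(time_h = times, births = births,
                                    deaths = deaths)
  attr(out, "true_counts") <- data.frame(time_h = times, n_nuclei = N_true,
                                         n_dead = M_true)
  attr(out, "condition") <- cond
  out
}

normalizeCondition <- function(condition, truth, inhibition) {
  cond <- utils::modifyList(
    list(growth_factor = NA_character_, gf_dose_ng_ml = 0,
         inhibitor_id = NA_character_, inhibitor_dose_uM = 0,
         caspase_inhibitor = FALSE),
    condition[!vapply(condition, function(v) length(v) == 1L && is.na(v),
                      logical(1))])
  if (!is.na(cond$growth_factor) && !is.null(truth))
    stopIfNot(cond$growth_factor %in% names(truth$weights),
              sprintf("unknown growth factor '%s'", cond$growth_factor))
  if (!is.na(cond$inhibitor_id)) {
    stopIfNot(!is.null(inhibition),
              "an inhibition matrix is required for inhibitor conditions")
    stopIfNot(cond$inhibitor_id %in% inhibitorIds(inhibition),
              sprintf("unknown inhibitor '%s'", cond$inhibitor_id))
  }
  cond
}

#' Default screen design
#'
#' The emulated screen: inhibitors at six concentrations (5 uM top, serial
#' 3-fold dilution), four replicates, in each growth factor, with
#' vehicle-control (DMSO) wells on every plate; plates hold 384 wells and one
#' growth factor each.
#'
#' @param growth_factors named numeric vector of growth-factor doses (ng/ml);
#'   the defaults are the assay concentrations FGF2 1.25, VEGFA 20, HGF 20.
#' @param inhibitors character vector of inhibitor ids.
#' @param dose_ladder inhibitor doses in micromolar (default
#'   `5 / 3^(0:5)`).
#' @param replicates replicate wells per condition (default 4).
#' @param controls_per_plate DMSO wells per plate (default 16).
#' @param plate_size wells per plate (default 384).
#' @return data.frame platemap with one row per well (columns `well_id`,
#'   `plate_id`, `growth_factor`, `gf_dose_ng_ml`, `inhibitor_id`,
#'   `inhibitor_dose_uM`, `sirna_id`, `replicate`, `is_control`).
#' @export
screenDesign <- function(growth_factors = c(FGF2 = 1.25, VEGFA = 20,
                                            HGF = 20),
                         inhibitors = sprintf("INH%02d", 1:58),
                         dose_ladder = 5 / 3^(0:5),
                         replicates = 4L, controls_per_plate = 16L,
                         plate_size = 384L) {
  stopIfNot(controls_per_plate >= 1L,
            "every plate needs at least one vehicle-control well")
  rows <- list()
  well <- 0L
  for (gf in names(growth_factors)) {
    conds <- expand.grid(inhibitor_id = inhibitors,
                         inhibitor_dose_uM = dose_ladder,
                         replicate = seq_len(replicates),
                         stringsAsFactors = FALSE)
    cap <- plate_size - controls_per_plate
    n_plates <- max(1L, ceiling(nrow(conds) / cap))
    for (p in seq_len(n_plates)) {
      plate_id <- sprintf("%s_P%d", gf, p)
      take <- conds[seq_len(nrow(conds)) > (p - 1L) * cap &
                      seq_len(nrow(conds)) <= p * cap, , drop = FALSE]
      ctrl <- data.frame(inhibitor_id = NA_character_, inhibitor_dose_uM = 0,
                         replicate = seq_len(controls_per_plate))
      blk <- rbind(take, ctrl)
      blk$is_control <- c(rep(FALSE, nrow(take)),
                          rep(TRUE, controls_per_plate))
      blk$plate_id <- plate_id
      blk$growth_factor <- gf
      blk$gf_dose_ng_ml <- unname(growth_factors[gf])
      rows[[length(rows) + 1L]] <- blk
    }
  }
  pm <- do.call(rbind, rows)
  pm$sirna_id <- NA_character_
  pm$well_id <- sprintf("W%05d", seq_len(nrow(pm)))
  rownames(pm) <- NULL
  pm[, c("well_id", "plate_id", "growth_factor", "gf_dose_ng_ml",
         "inhibitor_id", "inhibitor_dose_uM", "sirna_id", "replicate",
         "is_control")]
}

#' Simulate a full screen
#'
#' Runs [simulateWell()] for every row of a platemap and assembles the result
#' into a [ProliferationScreen-class]. Wells get independent seeds derived
#' deterministically from `seed`, so identical seeds give identical screens.
#'
#' @param config a [simConfig()].
#' @param design platemap data.frame ([screenDesign()]); every plate must
#'   contain control wells.
#' @param truth [generateGroundTruth()] ground truth.
#' @param inhibition [InhibitionMatrix-class].
#' @param seed integer seed.
#' @return a [ProliferationScreen-class]; metadata carries the config, seed
#'   and design summary.
#' @export
simulateScreen <- function(config, design, truth, inhibition,
                           seed = config$seed) {
  stopifnot(inherits(config, "SimConfig"))
  ctrl_by_plate <- tapply(design$is_control, design$plate_id, any)
  stopIfNot(all(ctrl_by_plate),
            paste("plates without vehicle controls:",
                  paste(names(ctrl_by_plate)[!ctrl_by_plate], collapse = ", ")))
  nt <- length(seq(0, config$gf_addition_time + config$horizon,
                   by = config$imaging_interval))
  nuclei <- dead <- matrix(0L, nrow = nt, ncol = nrow(design))
  times <- NULL
  for (w in seq_len(nrow(design))) {
    cond <- as.list(design[w, c("growth_factor", "gf_dose_ng_ml",
                                "inhibitor_id", "inhibitor_dose_uM")])
    traj <- simulateWell(config, cond, truth, inhibition,
                         seed = childSeed(seed, w))
    if (is.null(times)) times <- traj$time_h
    nuclei[, w] <- traj$n_nuclei
    dead[, w] <- traj$n_dead
  }
  ProliferationScreen(nuclei, dead, times, design,
                      metadata = list(config = unclass(config), seed = seed,
                                      n_wells = nrow(design)))
}

#' Simulate a phenotype table directly from the ground truth
#'
#' Generates the per-(growth factor, inhibitor, dose) proliferation-rate
#' difference vs control under the linear effect model the kinome regression
#' assumes: \eqn{\Delta k_p = -s \cdot \min(1, \sum_k w_k \, inh_k(d)) +
#' \epsilon}, with Gaussian noise whose sd is a stated fraction of the largest
#' true effect in the table. This is the calibrated test bed for
#' recovery studies of [fitKir()]; the stochastic well simulator provides the
#' end-to-end route.
#'
#' @param truth [generateGroundTruth()].
#' @param inhibition [InhibitionMatrix-class].
#' @param dose_ladder inhibitor doses in micromolar (default `5 / 3^(0:5)`).
#' @param effect_scale rate change (per hour) removed by complete inhibition
#'   of the full true-kinase complement (default 0.02, the magnitude of a
#'   typical growth-factor-driven rate gain).
#' @param noise_frac sd of the additive noise as a fraction of the maximal
#'   true effect magnitude (default 0.2).
#' @param seed integer seed.
#' @return data.frame phenotype table: `growth_factor`, `inhibitor_id`,
#'   `dose_uM`, `delta_kp`, `n_replicates` (1; the noise already represents
#'   replicate-averaged error).
#' @export
simulatePhenotypes <- function(truth, inhibition, dose_ladder = 5 / 3^(0:5),
                               effect_scale = 0.02, noise_frac = 0.2,
                               seed = 1L) {
  set.seed(seed)
  rows <- expand.grid(inhibitor_id = inhibitorIds(inhibition),
                      dose_uM = dose_ladder,
                      growth_factor = names(truth$weights),
                      stringsAsFactors = FALSE)
  load <- mapply(function(gf, inh, d)
    truthLoad(truth$weights[[gf]], inhibition, inh, d),
    rows$growth_factor, rows$inhibitor_id, rows$dose_uM)
  true_eff <- -effect_scale * pmin(1, load)
  sd_noise <- noise_frac * max(abs(true_eff))
  rows$delta_kp <- true_eff + stats::rnorm(nrow(rows), 0, sd_noise)
  rows$n_replicates <- 1L
  rows[, c("growth_factor", "inhibitor_id", "dose_uM", "delta_kp",
           "n_replicates")]
}
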