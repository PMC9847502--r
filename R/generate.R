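## Synthetic-screen generators: kinase panel, inhibitor biochemistry and
## ground-truth kinase weights. These emulate the statistical structure of a
## profiled kinase-inhibitor screen (a kinome-scale panel, promiscuous
## inhibitors characterized at one reference concentration, and a small set of
## kinases that genuinely set the proliferative response to each growth
## factor) so that the downstream regression can be tested against known
## truth.

#' Generate a kinase expression panel
#'
#' Draws a panel of kinases with expression values in arbitrary units such
#' that exactly `n_expressed` of them meet the conventional expression filter
#' (>= 1.5 a.u.). Expressed kinases get log-normal expression above the
#' threshold; the remainder fall below it.
#'
#' @param n_kinases number of kinases in the panel (screen default 369).
#' @param n_expressed number with expression >= 1.5 a.u. (0..n_kinases).
#' @param seed integer seed; the panel is deterministic given the seed.
#' @return data.frame with columns `kinase_id`, `expression`.
#' @examples
#' p <- generatePanel(369, 200, seed = 1)
#' sum(p$expression >= 1.5)
#' @export
generatePanel <- function(n_kinases, n_expressed, seed = 1L) {
  stopIfNot(n_kinases >= 0 && n_expressed >= 0 && n_expressed <= n_kinases,
            "need 0 <= n_expressed <= n_kinases")
  set.seed(seed)
  ids <- sprintf("KIN%03d", seq_len(n_kinases))
  expr <- numeric(n_kinases)
  hi <- seq_len(n_expressed)
  expr[hi] <- 1.5 + stats::rlnorm(n_expressed, meanlog = 0.8, sdlog = 1)
  if (n_expressed < n_kinases)
    expr[-hi] <- stats::runif(n_kinases - n_expressed, 0, 1.5 - 1e-6)
  data.frame(kinase_id = ids, expression = expr)
}

#' Generate an inhibitor x kinase inhibition matrix
#'
#' Each inhibitor is assigned a set of "hit" kinases which it inhibits
#' strongly at the reference concentration (residual activity drawn in
#' \eqn{[0.02, 0.2]}); all other kinases retain near-full activity (residual in
#' \eqn{[0.8, 1]}). Hits are dealt round-robin over a shuffled kinase order so
#' the panel covers the kinome evenly, as a screening panel chosen for kinome
#' coverage would: when `n_inhibitors * hits_per_inhibitor >= n_kinases` every
#' kinase is some inhibitor's hit.
#'
#' @param panel kinase panel from [generatePanel()].
#' @param n_inhibitors number of inhibitors (screen default 58).
#' @param hits_per_inhibitor strong targets per inhibitor (default 12, typical
#'   promiscuity of profiled tool compounds).
#' @param assay_conc reference profiling concentration in micromolar
#'   (default 1).
#' @param seed integer seed.
#' @return An [InhibitionMatrix-class].
#' @export
generateInhibitionMatrix <- function(panel, n_inhibitors,
                                     hits_per_inhibitor = 12L,
                                     assay_conc = 1, seed = 1L) {
  stopIfNot(is.data.frame(panel) && nrow(panel) > 0L,
            "panel must be a non-empty data.frame")
  stopIfNot(n_inhibitors > 0 && hits_per_inhibitor >= 0,
            "counts must be positive")
  set.seed(seed)
  nk <- nrow(panel)
  inh_ids <- sprintf("INH%02d", seq_len(n_inhibitors))
  ## weak background everywhere, with small jitter
  res <- matrix(stats::runif(n_inhibitors * nk, 0.8, 1.0),
                nrow = n_inhibitors,
                dimnames = list(inh_ids, panel$kinase_id))
  n_hits <- n_inhibitors * hits_per_inhibitor
  if (n_hits > 0L) {
    ## round-robin deal over shuffled kinase cycles -> even kinome coverage
    reps <- ceiling(n_hits / nk)
    targets <- unlist(lapply(seq_len(reps), function(i) sample.int(nk)))
    targets <- targets[seq_len(n_hits)]
    rows <- rep(seq_len(n_inhibitors), each = hits_per_inhibitor)
    res[cbind(rows, targets)] <- stats::runif(n_hits, 0.02, 0.2)
  }
  InhibitionMatrix(clip01(res), assayConc = assay_conc)
}

#' Map a reference-concentration residual activity to any dose
#'
#' Single-site binding: the dissociation constant is back-inferred from the
#' profiled point, \eqn{K_d = c_{ref} \cdot r/(1-r)} (capped when \eqn{r}
#' approaches 1), and the fractional inhibition at dose \eqn{d} is
#' \eqn{d/(d + K_d)}. The mapping is non-decreasing in dose, equals 0 at dose
#' 0 and recovers \eqn{1-r} at the reference concentration.
#'
#' @param residual_at_ref residual activity in \eqn{[0, 1]} at `ref_conc`.
#' @param ref_conc reference concentration (same units as `dose`, > 0).
#' @param dose dose(s) at which to evaluate fractional inhibition (>= 0).
#' @return fractional inhibition in \eqn{[0, 1]}, vectorized over any
#'   argument.
#' @examples
#' inhibitionAtDose(0.5, 1, 3)   # Kd = 1, 3/(3+1) = 0.75
#' @export
inhibitionAtDose <- function(residual_at_ref, ref_conc, dose) {
  stopIfNot(all(ref_conc > 0), "ref_conc must be positive")
  stopIfNot(all(dose >= 0), "dose must be non-negative")
  stopIfNot(all(residual_at_ref >= 0 & residual_at_ref <= 1),
            "residual_at_ref must lie in [0, 1]")
  r <- pmin(residual_at_ref, 1 - 1e-9)   # cap: fully-unaffected kinases
  kd <- ref_conc * r / (1 - r)
  out <- dose / (dose + kd)          # recycles over the longer argument
  out[rep_len(dose == 0, length(out))] <- 0
  clip01(out)
}

#' Generate ground-truth kinase weights per growth factor
#'
#' Chooses, for each growth factor, a small set of kinases that truly drive
#' proliferation, with a common core shared by every growth factor, and
#' assigns each a non-negative effect weight: full inhibition of a kinase with
#' weight \eqn{w} removes a fraction \eqn{w} of the growth-factor-driven
#' commitment to division. Kinases are drawn from those passing the
#' expression filter and (when an inhibition matrix is supplied) actually
#' covered by at least one inhibitor, so that recovery is well-posed.
#'
#' @param panel kinase panel ([generatePanel()]).
#' @param growth_factors character vector of growth-factor ids.
#' @param n_true true kinases per growth factor (default 5).
#' @param n_shared size of the core shared by all growth factors (default 3).
#' @param inhibition optional [InhibitionMatrix-class]; restricts eligible
#'   kinases to those strongly hit (residual <= 0.5) by some inhibitor.
#' @param weight_range range of effect weights (default 0.4--1).
#' @param expression_cutoff eligibility filter in arbitrary units
#'   (default 1.5).
#' @param seed integer seed.
#' @return A list of class `"GroundTruth"` with elements `weights` (named list
#'   per growth factor of named non-negative weights) and `shared_kinases`.
#' @export
generateGroundTruth <- function(panel, growth_factors, n_true = 5L,
                                n_shared = 3L, inhibition = NULL,
                                weight_range = c(0.4, 1),
                                expression_cutoff = 1.5, seed = 1L) {
  stopIfNot(n_shared <= n_true, "n_shared must not exceed n_true")
  set.seed(seed)
  eligible <- panel$kinase_id[panel$expression >= expression_cutoff]
  if (!is.null(inhibition)) {
    r <- residualActivity(inhibition)
    covered <- colnames(r)[apply(r, 2L, min) <= 0.5]
    eligible <- intersect(eligible, covered)
  }
  need <- n_shared + length(growth_factors) * (n_true - n_shared)
  stopIfNot(length(eligible) >= need,
            "not enough eligible kinases for the requested ground truth")
  picks <- sample(eligible, need)
  shared <- sort(picks[seq_len(n_shared)])
  rest <- picks[-seq_len(n_shared)]
  weights <- vector("list", length(growth_factors))
  names(weights) <- growth_factors
  for (i in seq_along(growth_factors)) {
    own <- if (n_true > n_shared)
      rest[seq_len(n_true - n_shared) + (i - 1L) * (n_true - n_shared)]
    else character()
    ks <- c(shared, own)
    w <- stats::runif(length(ks), weight_range[1L], weight_range[2L])
    weights[[i]] <- stats::setNames(w, ks)
  }
  structure(list(weights = weights, shared_kinases = shared),
            class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat("GroundTruth:", length(x$weights), "growth factors;",
      length(x$shared_kinases), "shared kinases (",
      paste(x$shared_kinases, collapse = ", "), ")\n")
  for (gf in names(x$weights))
    cat(" ", gf, ":", paste(sprintf("%s=%.2f", names(x$weights[[gf]]),
                                    x$weights[[gf]]), collapse = " "), "\n")
  invisible(x)
}

## Summed ground-truth inhibition load for one inhibitor row at a dose.
truthLoad <- function(weights, inhibition, inhibitor_id, dose_uM) {
  r <- residualActivity(inhibition)
  ks <- intersect(names(weights), colnames(r))
  if (!length(ks)) return(0)
  inh <- inhibitionAtDose(r[inhibitor_id, ks],
                          assayConcentration(inhibition), dose_uM)
  sum(weights[ks] * inh)
}
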