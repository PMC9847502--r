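## Pipeline orchestration and file interchange. All tables are plain
## comma-separated UTF-8 with a header row; times in hours, rates per hour,
## inhibitor doses in micromolar, growth-factor doses in ng/ml. Every stage
## writes a sidecar manifest recording the seed and an MD5 of the
## configuration actually used.

writeTable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

writeManifest <- function(outdir, stage, seed, config, extra = list()) {
  cfgjson <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE)
  tf <- tempfile(fileext = ".json"); on.exit(unlink(tf))
  writeLines(as.character(cfgjson), tf)
  manifest <- c(list(stage = stage, seed = seed,
                     config_md5 = unname(tools::md5sum(tf)),
                     config = config),
                extra)
  jsonlite::write_json(manifest,
                       file.path(outdir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
}

#' Write / read a screen as counts + platemap CSV files
#'
#' Long-format counts (`well_id`, `time_h`, `n_nuclei`, `n_dead`) and a
#' platemap table, the on-disk interchange format of the pipeline.
#'
#' @param screen a [ProliferationScreen-class].
#' @param counts_path,platemap_path file paths.
#' @return `writeScreenCsv` returns the paths invisibly; `readScreenCsv`
#'   returns a [ProliferationScreen-class].
#' @export
writeScreenCsv <- function(screen, counts_path, platemap_path) {
  nm <- nucleiCounts(screen); dm <- deadCounts(screen)
  long <- data.frame(
    well_id = rep(colnames(nm), each = nrow(nm)),
    time_h = rep(timesHours(screen), times = ncol(nm)),
    n_nuclei = as.vector(nm), n_dead = as.vector(dm))
  writeTable(long, counts_path)
  writeTable(plateMap(screen), platemap_path)
  invisible(c(counts_path, platemap_path))
}

#' @rdname writeScreenCsv
#' @export
readScreenCsv <- function(counts_path, platemap_path) {
  long <- utils::read.csv(counts_path)
  pm <- utils::read.csv(platemap_path)
  times <- sort(unique(long$time_h))
  wells <- pm$well_id
  shape <- function(col) {
    m <- matrix(NA_real_, length(times), length(wells),
                dimnames = list(NULL, wells))
    m[cbind(match(long$time_h, times), match(long$well_id, wells))] <-
      long[[col]]
    m
  }
  ProliferationScreen(shape("n_nuclei"), shape("n_dead"), times, pm)
}

#' Pipeline stage: simulate a screen to disk
#'
#' Simulates the configured screen and writes `counts.csv`, `platemap.csv`,
#' `inhibition.csv` (inhibitor rows x kinase columns, residual activity),
#' `expression.csv`, `truth.json` and a manifest into `outdir`.
#'
#' @param outdir output directory (created if needed).
#' @param config a [simConfig()].
#' @param design platemap ([screenDesign()]).
#' @param panel,truth,inhibition screen biology ([generatePanel()],
#'   [generateGroundTruth()], [generateInhibitionMatrix()]).
#' @param seed integer seed.
#' @return invisibly, the named vector of file paths.
#' @export
runSimulate <- function(outdir, config = simConfig(),
                        design = screenDesign(), panel, truth, inhibition,
                        seed = config$seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  screen <- simulateScreen(config, design, truth, inhibition, seed = seed)
  paths <- c(counts = file.path(outdir, "counts.csv"),
             platemap = file.path(outdir, "platemap.csv"),
             inhibition = file.path(outdir, "inhibition.csv"),
             expression = file.path(outdir, "expression.csv"),
             truth = file.path(outdir, "truth.json"))
  writeScreenCsv(screen, paths["counts"], paths["platemap"])
  ri <- as.data.frame(residualActivity(inhibition))
  ri <- cbind(inhibitor_id = rownames(ri), ri)
  writeTable(ri, paths["inhibition"])
  writeTable(data.frame(kinase_id = panel$kinase_id,
                        expression_au = panel$expression),
             paths["expression"])
  jsonlite::write_json(list(weights = lapply(truth$weights, as.list),
                            shared_kinases = truth$shared_kinases),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  writeManifest(outdir, "simulate", seed, unclass(config),
                extra = list(n_wells = nrow(design),
                             assay_conc_uM = assayConcentration(inhibition)))
  invisible(paths)
}

#' Pipeline stage: per-well rates and phenotype table
#'
#' Reads the counts and platemap CSVs, estimates per-well rates over the
#' post-stimulation window, and writes `rates.csv` (per well) and
#' `phenotypes.csv` (per growth factor x inhibitor x dose, delta k_p vs
#' plate-matched control).
#'
#' @param outdir directory holding `counts.csv` and `platemap.csv`; outputs
#'   are written alongside.
#' @param window optional estimator window `c(t0, tend)` in hours; default
#'   growth-factor addition to end of imaging.
#' @param gf_addition_time hours; used when `window` is NULL (default 24).
#' @param convention endpoint-mean (`"mean"`, default) or endpoint-sum
#'   (`"sum"`) denominator.
#' @return invisibly, the named vector of output paths.
#' @export
runRates <- function(outdir, window = NULL, gf_addition_time = 24,
                     convention = "mean") {
  screen <- readScreenCsv(file.path(outdir, "counts.csv"),
                          file.path(outdir, "platemap.csv"))
  tt <- timesHours(screen)
  if (is.null(window)) {
    window <- if (any(abs(tt - gf_addition_time) < 1e-8))
      c(gf_addition_time, tt[length(tt)]) else c(tt[1L], tt[length(tt)])
  }
  rates <- estimateRates(screen, window = window, convention = convention)
  fits <- lapply(colnames(screen), function(w)
    tryCatch(fitExponential(wellTrajectory(screen, w), window = window),
             error = function(e) data.frame(n0 = NA, k_p = NA,
                                            r_squared = NA)))
  rates$fit_r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
  names(rates)[names(rates) == "t0"] <- "window_start_h"
  names(rates)[names(rates) == "tend"] <- "window_end_h"
  writeTable(rates, file.path(outdir, "rates.csv"))
  pm <- plateMap(screen)
  paths <- c(rates = file.path(outdir, "rates.csv"))
  if (any(!is.na(pm$inhibitor_id))) {
    ph <- phenotypeTable(rates, pm)
    writeTable(ph, file.path(outdir, "phenotypes.csv"))
    paths["phenotypes"] <- file.path(outdir, "phenotypes.csv")
  }
  writeManifest(outdir, "rates", NA,
                list(window = window, convention = convention))
  invisible(paths)
}

#' Pipeline stage: kinome regression and intersection
#'
#' Reads `phenotypes.csv`, `inhibition.csv` and `expression.csv`, filters
#' kinases by expression, fits the elastic-net kinome regression per growth
#' factor and writes `ranking_<GF>.csv`, `intersection.csv` and
#' `kir_diagnostics.json` (lambda grid, CV MSE, chosen lambda per growth
#' factor).
#'
#' @param outdir directory with the stage inputs; outputs written alongside.
#' @param config a [kirConfig()].
#' @param seed integer seed (CV fold assignment).
#' @return invisibly, a list with the rankings and the intersection.
#' @export
runKir <- function(outdir, config = kirConfig(), seed = 1L) {
  ph <- utils::read.csv(file.path(outdir, "phenotypes.csv"))
  ri <- utils::read.csv(file.path(outdir, "inhibition.csv"),
                        check.names = FALSE)
  expr <- utils::read.csv(file.path(outdir, "expression.csv"))
  rmat <- as.matrix(ri[, -1L, drop = FALSE])
  rownames(rmat) <- ri$inhibitor_id
  inhibition <- InhibitionMatrix(rmat)
  panel <- data.frame(kinase_id = expr$kinase_id,
                      expression = expr$expression_au)
  filtered <- filterByExpression(inhibition, panel,
                                 cutoff = config$expression_cutoff)
  gfs <- unique(ph$growth_factor)
  rankings <- list(); diag <- list()
  for (gf in gfs) {
    des <- buildDesign(filtered, ph, gf)
    rk <- fitKir(des, config, seed = seed)
    rankings[[gf]] <- rk
    writeTable(as.data.frame(rk), file.path(outdir,
                                            paste0("ranking_", gf, ".csv")))
    diag[[gf]] <- list(lambda = attr(rk, "lambda"),
                       alpha = attr(rk, "alpha"),
                       cv = attr(rk, "cv"))
  }
  inter <- if (length(rankings) >= 2L) intersectRankSum(rankings)
           else as.data.frame(rankings[[1L]])
  writeTable(inter, file.path(outdir, "intersection.csv"))
  jsonlite::write_json(diag, file.path(outdir, "kir_diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  writeManifest(outdir, "kir", seed, unclass(config))
  invisible(list(rankings = rankings, intersection = inter))
}

#' Pipeline stage: siRNA validation statistics
#'
#' Reads `rates.csv` and `platemap.csv` (with an `sirna_id` column encoding
#' `<gene>_si<index>`; control wells have no siRNA), normalizes per-gene
#' effects to the no-siRNA control within each growth factor, runs the
#' many-to-one tests and writes `sirna_results.csv`.
#'
#' @param outdir directory with the stage inputs.
#' @return invisibly, the results data.frame.
#' @export
runSirna <- function(outdir) {
  rates <- utils::read.csv(file.path(outdir, "rates.csv"))
  pm <- utils::read.csv(file.path(outdir, "platemap.csv"))
  df <- merge(rates, pm, by = "well_id")
  has_si <- !is.na(df$sirna_id) & df$sirna_id != ""
  ctrl <- df[!has_si & df$is_control %in% TRUE, ]
  trt <- df[has_si, ]
  stopIfNot(nrow(trt) > 0L, "no siRNA wells in the platemap")
  parts <- regmatches(trt$sirna_id,
                      regexec("^(.*)_si([0-9]+)$", trt$sirna_id))
  trt$gene <- vapply(parts, `[`, character(1), 2L)
  trt$sirna_index <- as.integer(vapply(parts, `[`, character(1), 3L))
  meas <- data.frame(gene = trt$gene, sirna_index = trt$sirna_index,
                     growth_factor = trt$growth_factor, k_p = trt$k_p)
  ctrl_kp <- tapply(ctrl$k_p, ctrl$growth_factor, mean)
  eff <- normalizeSirna(meas, ctrl_kp)
  tests <- do.call(rbind, lapply(names(ctrl_kp), function(gf)
    testSirnaEffects(meas, ctrl$k_p[ctrl$growth_factor == gf],
                     growth_factor = gf)))
  out <- merge(eff, tests, by = c("gene", "growth_factor"))
  writeTable(out, file.path(outdir, "sirna_results.csv"))
  invisible(out)
}

#' Dose-response summary of growth-factor titration wells
#'
#' Per-(growth factor, dose) means and standard deviations of the
#' proliferation, birth and death rates across replicate wells, for wells
#' carrying no inhibitor or siRNA.
#'
#' @param rates per-well rate table ([estimateRates()]).
#' @param platemap platemap data.frame; dose read from `gf_dose_ng_ml`.
#' @return data.frame `growth_factor`, `gf_dose_ng_ml`, `n_wells`, mean and
#'   sd of `k_p`, `k_b`, `k_d`. Empty (with a warning) when there are no
#'   titration wells.
#' @export
summarizeDoseResponse <- function(rates, platemap) {
  df <- merge(rates, platemap, by = "well_id")
  tit <- df[is.na(df$inhibitor_id) &
              (is.na(df$sirna_id) | df$sirna_id == ""), ]
  if (!nrow(tit)) {
    warning("no titration wells found")
    return(data.frame(growth_factor = character(),
                      gf_dose_ng_ml = numeric(), n_wells = integer(),
                      k_p_mean = numeric(), k_p_sd = numeric(),
                      k_b_mean = numeric(), k_b_sd = numeric(),
                      k_d_mean = numeric(), k_d_sd = numeric()))
  }
  out <- do.call(rbind, lapply(
    split(tit, tit[c("growth_factor", "gf_dose_ng_ml")], drop = TRUE),
    function(d) data.frame(
      growth_factor = d$growth_factor[1L],
      gf_dose_ng_ml = d$gf_dose_ng_ml[1L],
      n_wells = nrow(d),
      k_p_mean = mean(d$k_p), k_p_sd = stats::sd(d$k_p),
      k_b_mean = mean(d$k_b), k_b_sd = stats::sd(d$k_b),
      k_d_mean = mean(d$k_d), k_d_sd = stats::sd(d$k_d))))
  out <- out[order(out$growth_factor, out$gf_dose_ng_ml), ]
  rownames(out) <- NULL
  out
}
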