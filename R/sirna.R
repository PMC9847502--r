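## siRNA validation statistics: proliferation rates under gene knockdown are
## normalized to the no-siRNA control, averaged over the three independent
## siRNAs per gene, and tested per growth factor by one-way ANOVA followed by
## many-to-one (Dunnett) comparisons against the control.

#' Normalize siRNA proliferation rates to the no-siRNA control
#'
#' The effect of knocking down a gene in a growth-factor context is the mean,
#' over its (up to three) siRNAs, of each siRNA's replicate-mean
#' proliferation rate divided by the control rate; the s.e.m. is taken across
#' the siRNA means. A gene with fewer than three siRNAs is averaged over
#' those available, with a warning.
#'
#' @param measurements data.frame with columns `gene`, `sirna_index` (1..3),
#'   `growth_factor`, `k_p` (one row per replicate well).
#' @param control_kp named numeric vector: the no-siRNA control proliferation
#'   rate (per hour, > 0) for each growth factor.
#' @return data.frame `gene`, `growth_factor`, `effect` (1 = control),
#'   `sem`, `n_sirna`.
#' @export
normalizeSirna <- function(measurements, control_kp) {
  stopIfNot(all(c("gene", "sirna_index", "growth_factor", "k_p") %in%
                  names(measurements)),
            "measurements need gene, sirna_index, growth_factor, k_p")
  gfs <- unique(measurements$growth_factor)
  stopIfNot(all(gfs %in% names(control_kp)),
            "control_kp must name every growth factor")
  if (any(control_kp[gfs] <= 0))
    stop("undefined normalization: control k_p must be positive",
         call. = FALSE)
  ## siRNA-level means, then gene-level mean/sem of the normalized values
  sm <- stats::aggregate(k_p ~ gene + growth_factor + sirna_index,
                         data = measurements, FUN = mean)
  sm$norm <- sm$k_p / unname(control_kp[sm$growth_factor])
  out <- do.call(rbind, lapply(split(sm, sm[c("gene", "growth_factor")],
                                     drop = TRUE), function(d) {
    if (nrow(d) < 3L)
      warning(sprintf("gene %s in %s has only %d siRNA(s); averaging those",
                      d$gene[1L], d$growth_factor[1L], nrow(d)))
    data.frame(gene = d$gene[1L], growth_factor = d$growth_factor[1L],
               effect = mean(d$norm),
               sem = if (nrow(d) > 1L)
                 stats::sd(d$norm) / sqrt(nrow(d)) else 0,
               n_sirna = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$growth_factor, out$gene), ]
}

#' Test siRNA effects against the control within one growth factor
#'
#' One-way ANOVA across genes plus the no-siRNA control, followed by
#' many-to-one comparisons of each gene against the control with family-wise
#' adjustment (Dunnett, via \pkg{multcomp}; falls back to Holm-adjusted
#' two-sided Welch tests if the Dunnett fit fails). Replicate wells are the
#' unit of analysis, pooled across a gene's siRNAs, so every group shares the
#' well-level error variance the pooled ANOVA assumes; the reported effect
#' sizes ([normalizeSirna()]) still average the three siRNA means.
#'
#' @param measurements as in [normalizeSirna()], one growth factor's rows or
#'   filtered by `growth_factor`.
#' @param control_values numeric vector of control-well proliferation rates
#'   (>= 2 values).
#' @param growth_factor optional id used to filter `measurements` and label
#'   the output.
#' @param method `"dunnett"` (default) or `"holm-welch"`.
#' @return data.frame `gene`, `growth_factor`, `estimate` (gene mean minus
#'   control mean, per hour), `p_adj`, `significant` (adjusted p < 0.05),
#'   `method`.
#' @export
testSirnaEffects <- function(measurements, control_values,
                             growth_factor = NULL,
                             method = c("dunnett", "holm-welch")) {
  method <- match.arg(method)
  if (!is.null(growth_factor))
    measurements <-
      measurements[measurements$growth_factor %in% growth_factor, ,
                   drop = FALSE]
  stopIfNot(nrow(measurements) > 0L, "no measurements to test")
  stopIfNot(length(control_values) >= 2L,
            "need at least two control replicates")
  stopIfNot(all(table(measurements$gene) >= 2L),
            "need at least two replicate wells per gene")
  dat <- rbind(data.frame(group = "control", k_p = control_values),
               data.frame(group = measurements$gene,
                          k_p = measurements$k_p))
  dat$group <- stats::relevel(factor(dat$group), ref = "control")
  genes <- setdiff(levels(dat$group), "control")
  est <- tapply(dat$k_p, dat$group, mean)[genes] - mean(control_values)

  p_adj <- NULL
  if (method == "dunnett") {
    p_adj <- tryCatch({
      fit <- stats::aov(k_p ~ group, data = dat)
      gl <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
      p <- summary(gl)$test$pvalues
      stats::setNames(as.numeric(p), genes)
    }, error = function(e) NULL)
    if (is.null(p_adj)) method <- "holm-welch"
  }
  if (method == "holm-welch") {
    raw <- vapply(genes, function(g)
      stats::t.test(dat$k_p[dat$group == g], control_values)$p.value,
      numeric(1))
    p_adj <- stats::p.adjust(raw, method = "holm")
  }
  data.frame(gene = genes,
             growth_factor = if (is.null(growth_factor)) NA_character_
                             else growth_factor,
             estimate = unname(est),
             p_adj = unname(p_adj[genes]),
             significant = unname(p_adj[genes]) < 0.05,
             method = method)
}

#' Receptor-knockdown specificity check
#'
#' A receptor knockdown is called specific when it significantly reduces
#' proliferation in the presence of its cognate growth factor but in none of
#' the others (FGFR1 is cognate to FGF2, VEGFR2 to VEGFA, MET to HGF).
#'
#' @param effects data.frame `gene`, `growth_factor`, `effect` (control-
#'   normalized) and `significant` (e.g. a merge of [normalizeSirna()] and
#'   [testSirnaEffects()] output).
#' @param receptor_map named character vector receptor -> cognate growth
#'   factor (default `c(FGFR1 = "FGF2", VEGFR2 = "VEGFA", MET = "HGF")`).
#' @return data.frame `receptor`, `cognate_gf`, `cognate_effect`,
#'   `noncognate_mean_effect`, `specific`.
#' @export
receptorSpecificity <- function(effects,
                                receptor_map = c(FGFR1 = "FGF2",
                                                 VEGFR2 = "VEGFA",
                                                 MET = "HGF")) {
  stopIfNot(all(c("gene", "growth_factor", "effect", "significant") %in%
                  names(effects)),
            "effects need gene, growth_factor, effect, significant")
  receptors <- intersect(unique(effects$gene), names(receptor_map))
  unmapped <- setdiff(unique(effects$gene), names(receptor_map))
  stopIfNot(length(unmapped) == 0L,
            paste("unmapped receptor(s):", paste(unmapped, collapse = ", ")))
  out <- do.call(rbind, lapply(receptors, function(rc) {
    d <- effects[effects$gene == rc, ]
    cg <- receptor_map[[rc]]
    cog <- d[d$growth_factor == cg, ]
    non <- d[d$growth_factor != cg, ]
    stopIfNot(nrow(cog) == 1L,
              sprintf("missing cognate measurement for %s", rc))
    data.frame(receptor = rc, cognate_gf = cg,
               cognate_effect = cog$effect,
               noncognate_mean_effect = if (nrow(non)) mean(non$effect)
                                        else NA_real_,
               specific = isTRUE(cog$significant) && cog$effect < 1 &&
                 !any(non$significant))
  }))
  rownames(out) <- NULL
  out
}
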