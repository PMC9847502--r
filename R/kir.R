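## Kinome regression (KIR): relate the phenotype measured under each
## (inhibitor, dose) to that treatment's kinase-inhibition profile by
## elastic-net regression. Features are fractional inhibitions (1 - residual
## activity, dose-mapped by single-site binding), so a kinase whose
## inhibition lowers the proliferation rate carries a negative coefficient;
## kinases are ranked by coefficient magnitude. Lambda is chosen at the
## minimum of the cross-validated mean squared error.

#' Kinome-regression configuration
#'
#' @param alpha elastic-net mixing weight in \eqn{[0, 1]} (default 0.15;
#'   mostly-ridge with a sparse component).
#' @param standardize scale features to unit variance before fitting
#'   (default TRUE); coefficients are reported on the original scale.
#' @param cv_folds cross-validation folds (default 10).
#' @param expression_cutoff expression filter in arbitrary units
#'   (default 1.5).
#' @param nlambda,lambda_min_ratio penalty grid: `nlambda` log-spaced values
#'   from the smallest all-zero lambda down `-log10(lambda_min_ratio)`
#'   decades (defaults 100 and 1e-4).
#' @return list of class `"KirConfig"`.
#' @export
kirConfig <- function(alpha = 0.15, standardize = TRUE, cv_folds = 10L,
                      expression_cutoff = 1.5, nlambda = 100L,
                      lambda_min_ratio = 1e-4) {
  stopIfNot(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  stopIfNot(cv_folds >= 2L, "need at least 2 CV folds")
  stopIfNot(expression_cutoff >= 0, "cutoff must be non-negative")
  structure(list(alpha = alpha, standardize = standardize,
                 cv_folds = as.integer(cv_folds),
                 expression_cutoff = expression_cutoff,
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio),
            class = "KirConfig")
}

#' Filter an inhibition matrix to expressed kinases
#'
#' Retains exactly the kinase columns whose expression meets the cutoff
#' (>= comparison, so a kinase at exactly the cutoff is kept), preserving
#' column order.
#'
#' @param inhibition [InhibitionMatrix-class].
#' @param panel expression panel (`kinase_id`, `expression`); must cover every
#'   kinase of the matrix.
#' @param cutoff expression threshold in arbitrary units (default 1.5).
#' @return the column-subset [InhibitionMatrix-class].
#' @export
filterByExpression <- function(inhibition, panel, cutoff = 1.5) {
  r <- residualActivity(inhibition)
  missing <- setdiff(colnames(r), panel$kinase_id)
  stopIfNot(length(missing) == 0L,
            paste("kinases absent from the expression panel:",
                  paste(utils::head(missing, 5L), collapse = ", ")))
  expr <- panel$expression[match(colnames(r), panel$kinase_id)]
  keep <- expr >= cutoff
  InhibitionMatrix(r[, keep, drop = FALSE],
                   assayConc = assayConcentration(inhibition))
}

#' Build the KIR design matrix for one growth factor
#'
#' One row per (inhibitor, dose) phenotype observation; entry (row, kinase)
#' is the fractional inhibition of that kinase at that dose, mapped from the
#' reference-concentration residual activity by [inhibitionAtDose()]. The
#' response is the replicate-averaged proliferation-rate difference vs
#' control.
#'
#' @param inhibition [InhibitionMatrix-class], typically already filtered by
#'   [filterByExpression()].
#' @param phenotypes phenotype table (`growth_factor`, `inhibitor_id`,
#'   `dose_uM`, `delta_kp`).
#' @param growth_factor growth factor whose rows to use.
#' @return list of class `"KirDesign"`: `X` (rows x kinases), `y`
#'   (delta k_p per hour), `rows` (inhibitor, dose), `growth_factor`.
#' @export
buildDesign <- function(inhibition, phenotypes, growth_factor) {
  ph <- phenotypes[phenotypes$growth_factor == growth_factor, , drop = FALSE]
  stopIfNot(nrow(ph) > 0L,
            sprintf("no phenotype rows for growth factor '%s'", growth_factor))
  r <- residualActivity(inhibition)
  missing <- setdiff(unique(ph$inhibitor_id), rownames(r))
  stopIfNot(length(missing) == 0L,
            paste("missing inhibition profiles for:",
                  paste(missing, collapse = ", ")))
  conc <- assayConcentration(inhibition)
  X <- t(vapply(seq_len(nrow(ph)), function(i)
    inhibitionAtDose(r[ph$inhibitor_id[i], ], conc, ph$dose_uM[i]),
    numeric(ncol(r))))
  colnames(X) <- colnames(r)
  structure(list(X = X, y = ph$delta_kp,
                 rows = ph[, c("inhibitor_id", "dose_uM")],
                 growth_factor = growth_factor),
            class = "KirDesign")
}

#' Elastic-net coefficients at a fixed penalty
#'
#' Solves the elastic-net problem
#' \deqn{\min_{b_0, b} \frac{1}{2n}\sum_i (y_i - b_0 - x_i^T b)^2 +
#'   \lambda\left(\alpha \|b\|_1 + \tfrac{1-\alpha}{2}\|b\|_2^2\right)}
#' at one or more fixed lambda values (glmnet's objective and scaling).
#'
#' @param X,y design matrix and response.
#' @param alpha elastic-net mixing weight.
#' @param lambda penalty value(s).
#' @param standardize standardize features internally (coefficients are
#'   returned on the original scale).
#' @return matrix of coefficients (intercept in row 1), one column per
#'   lambda.
#' @export
enetCoef <- function(X, y, alpha, lambda, standardize = TRUE) {
  ## glmnet internally rescales y to unit variance, which leaves the L1 term
  ## of the documented objective intact but divides the ridge term by sd(y).
  ## Solving on y/sd(y) with a compensating (alpha, lambda) pair makes the
  ## returned coefficients minimize the objective exactly as written.
  n <- nrow(X)
  sy <- sqrt(mean((y - mean(y))^2))
  if (sy == 0) sy <- 1
  ys <- y / sy
  one <- function(lam) {
    l1 <- lam * alpha / sy          # L1 weight on the scaled problem
    l2 <- lam * (1 - alpha)         # ridge weight on the scaled problem
    lam_s <- l1 + l2
    alpha_s <- if (lam_s > 0) l1 / lam_s else 1
    ## coordinate descent is run along a warm-started geometric path ending
    ## exactly at the requested lambda (a solitary fixed lambda is
    ## unreliable)
    probe <- glmnet::glmnet(X, ys, alpha = alpha_s,
                            standardize = standardize, nlambda = 5)
    top <- max(max(probe$lambda), lam_s * 1.01)
    path <- exp(seq(log(top), log(lam_s), length.out = 60L))
    fit <- glmnet::glmnet(X, ys, alpha = alpha_s, lambda = path,
                          standardize = standardize, thresh = 1e-14,
                          maxit = 1e7)
    as.matrix(stats::coef(fit, s = lam_s))[, 1L] * sy
  }
  vapply(lambda, one, numeric(ncol(X) + 1L))
}

#' Fit the kinome regression and rank kinases
#'
#' Computes the elastic-net regularization path, selects lambda at the lowest
#' K-fold cross-validated mean squared error (folds assigned by the seeded
#' shuffle, so results are reproducible), refits on all rows at that lambda
#' and returns the kinases with non-zero coefficients ranked by decreasing
#' coefficient magnitude (ties broken by kinase id).
#'
#' @param design a [buildDesign()] object.
#' @param config a [kirConfig()].
#' @param seed integer seed controlling fold assignment.
#' @return data.frame of class `"KinaseRanking"`: `kinase_id`, `coefficient`,
#'   `rank`, with attributes `growth_factor`, `lambda`, `alpha`, and
#'   `cv` (data.frame of the lambda grid and CV MSE). A zero-variance
#'   response yields an empty ranking with a warning.
#' @export
fitKir <- function(design, config = kirConfig(), seed = 1L) {
  stopifnot(inherits(design, "KirDesign"))
  X <- design$X; y <- design$y
  stopIfNot(nrow(X) >= 2L * config$cv_folds,
            "need at least 2 rows per CV fold")
  stopIfNot(!anyNA(X) && !anyNA(y), "design contains missing values")
  empty <- data.frame(kinase_id = character(), coefficient = numeric(),
                      rank = integer())
  if (stats::var(y) == 0) {
    warning("degenerate response (zero variance): empty ranking")
    return(structure(empty, class = c("KinaseRanking", "data.frame"),
                     growth_factor = design$growth_factor))
  }
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(config$cv_folds), nrow(X)))
  cvfit <- glmnet::cv.glmnet(X, y, alpha = config$alpha,
                             standardize = config$standardize,
                             foldid = foldid, nlambda = config$nlambda,
                             lambda.min.ratio = config$lambda_min_ratio)
  lam <- cvfit$lambda.min
  beta <- as.matrix(stats::coef(cvfit, s = lam))[-1L, 1L]
  nz <- which(beta != 0)
  ord <- nz[order(-abs(beta[nz]), names(beta)[nz])]
  out <- data.frame(kinase_id = names(beta)[ord],
                    coefficient = unname(beta[ord]),
                    rank = seq_along(ord))
  structure(out, class = c("KinaseRanking", "data.frame"),
            growth_factor = design$growth_factor, lambda = lam,
            alpha = config$alpha,
            cv = data.frame(lambda = cvfit$lambda, cv_mse = cvfit$cvm))
}

#' Intersect kinase rankings across growth factors by rank sum
#'
#' Keeps the kinases present in every ranking and orders them by the
#' ascending sum of their per-ranking ranks; ties are broken
#' lexicographically by kinase id.
#'
#' @param rankings list of two or more [fitKir()] rankings; names (or the
#'   rankings' `growth_factor` attributes) label the per-ranking rank
#'   columns.
#' @return data.frame `kinase_id`, one `rank_<label>` column per input
#'   ranking, and `rank_sum`, ordered by increasing `rank_sum`.
#' @export
intersectRankSum <- function(rankings) {
  stopIfNot(is.list(rankings) && length(rankings) >= 2L,
            "need at least two rankings")
  labels <- names(rankings)
  if (is.null(labels))
    labels <- vapply(rankings, function(r) {
      gf <- attr(r, "growth_factor")
      if (is.null(gf)) NA_character_ else gf
    }, character(1))
  labels[is.na(labels) | labels == ""] <-
    paste0("r", which(is.na(labels) | labels == ""))
  common <- Reduce(intersect, lapply(rankings, function(r) r$kinase_id))
  if (!length(common))
    return(data.frame(kinase_id = character(), rank_sum = integer()))
  rk <- vapply(rankings, function(r) r$rank[match(common, r$kinase_id)],
               numeric(length(common)))
  rk <- matrix(rk, nrow = length(common),
               dimnames = list(NULL, paste0("rank_", labels)))
  out <- data.frame(kinase_id = common, rk, rank_sum = rowSums(rk))
  out <- out[order(out$rank_sum, out$kinase_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
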