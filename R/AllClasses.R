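#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' InhibitionMatrix: biochemical kinase-inhibition profiles
#'
#' Stores the fractional residual activity of each kinase in the presence of
#' each inhibitor at a single reference assay concentration. Rows are
#' inhibitors, columns kinases; entries lie in \eqn{[0, 1]} where 1 means the
#' kinase is fully active (uninhibited) and 0 fully inhibited.
#'
#' @slot residual numeric matrix (inhibitor x kinase) of residual activities
#'   in \eqn{[0, 1]}, with dimnames.
#' @slot assayConc positive scalar, the concentration (micromolar) at which the
#'   profiles were measured.
#'
#' @seealso [InhibitionMatrix()], [inhibitionAtDose()], [filterByExpression()]
#' @export
setClass("InhibitionMatrix",
  representation(residual = "matrix", assayConc = "numeric"))

setValidity("InhibitionMatrix", function(object) {
  r <- object@residual
  msg <- character()
  if (!is.numeric(r)) msg <- c(msg, "residual must be a numeric matrix")
  if (is.null(rownames(r)) || is.null(colnames(r)))
    msg <- c(msg, "residual must have inhibitor rownames and kinase colnames")
  if (anyDuplicated(rownames(r)) || anyDuplicated(colnames(r)))
    msg <- c(msg, "inhibitor and kinase ids must be unique")
  if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
    msg <- c(msg, "residual activities must lie in [0, 1]")
  if (length(object@assayConc) != 1L || !is.finite(object@assayConc) ||
      object@assayConc <= 0)
    msg <- c(msg, "assayConc must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an InhibitionMatrix
#'
#' @param residual numeric inhibitor-by-kinase matrix of residual activities in
#'   \eqn{[0, 1]}, with dimnames.
#' @param assayConc reference assay concentration in micromolar (default 1).
#' @return An [InhibitionMatrix-class] object.
#' @examples
#' m <- matrix(c(0.1, 0.9, 0.95, 0.05), 2,
#'             dimnames = list(c("i1", "i2"), c("KIN1", "KIN2")))
#' InhibitionMatrix(m, assayConc = 1)
#' @export
InhibitionMatrix <- function(residual, assayConc = 1) {
  new("InhibitionMatrix", residual = as.matrix(residual),
      assayConc = as.numeric(assayConc))
}

#' ProliferationScreen: time-lapse well counts with plate metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' time-lapse proliferation screen: two assays, `"nuclei"` (live nuclei count
#' N) and `"dead"` (cumulative dead-cell count M), with rows indexed by imaging
#' time point and columns by well. `rowData` carries `time_h` (hours since
#' plating); `colData` is the platemap (growth factor, doses, inhibitor, siRNA,
#' replicate, control flag).
#'
#' @seealso [ProliferationScreen()], [estimateRates()], [simulateScreen()]
#' @export
setClass("ProliferationScreen", contains = "SummarizedExperiment")

setValidity("ProliferationScreen", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("nuclei", "dead") %in% an))
    return("assays 'nuclei' and 'dead' are required")
  if (!"time_h" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain 'time_h'")
  else {
    tt <- rowData(object)$time_h
    if (any(diff(tt) <= 0)) msg <- c(msg, "time_h must be strictly increasing")
  }
  if (!"well_id" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'well_id'")
  nmat <- assay(object, "nuclei"); mmat <- assay(object, "dead")
  if (any(nmat < 0, na.rm = TRUE) || any(mmat < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a ProliferationScreen
#'
#' @param nuclei,dead integer matrices (time point x well) of live-nuclei and
#'   cumulative dead-cell counts.
#' @param time_h numeric vector of imaging times in hours since plating,
#'   strictly increasing, one per row.
#' @param platemap data.frame with one row per well; must contain `well_id`.
#'   The conventional columns are `plate_id`, `growth_factor`, `gf_dose_ng_ml`,
#'   `inhibitor_id`, `inhibitor_dose_uM`, `sirna_id`, `replicate`,
#'   `is_control`.
#' @param metadata optional named list stored in the object metadata (e.g. the
#'   simulation configuration and seed).
#' @return A [ProliferationScreen-class] object. Wells whose dead-cell series
#'   decreases anywhere (possible with noisy counting) are kept but flagged
#'   with a warning.
#' @export
ProliferationScreen <- function(nuclei, dead, time_h, platemap,
                                metadata = list()) {
  nuclei <- as.matrix(nuclei); dead <- as.matrix(dead)
  stopIfNot(nrow(nuclei) == length(time_h) && all(dim(nuclei) == dim(dead)),
            "nuclei/dead dimensions must match length(time_h)")
  stopIfNot(nrow(platemap) == ncol(nuclei),
            "platemap must have one row per well (column)")
  colnames(nuclei) <- colnames(dead) <- platemap$well_id
  bad <- which(apply(dead, 2L, function(m) any(diff(m) < 0)))
  if (length(bad))
    warning(sprintf("dead-cell counts decrease in %d well(s) (e.g. %s); kept as-is",
                    length(bad), platemap$well_id[bad[1L]]))
  se <- SummarizedExperiment(
    assays = list(nuclei = nuclei, dead = dead),
    rowData = DataFrame(time_h = as.numeric(time_h)),
    colData = DataFrame(platemap, row.names = platemap$well_id),
    metadata = metadata)
  new("ProliferationScreen", se)
}
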