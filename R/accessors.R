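#' @rdname InhibitionMatrix-class
#' @export
setMethod("residualActivity", "InhibitionMatrix", function(x) x@residual)

#' @rdname InhibitionMatrix-class
#' @export
setMethod("assayConcentration", "InhibitionMatrix", function(x) x@assayConc)

#' @rdname InhibitionMatrix-class
#' @export
setMethod("inhibitorIds", "InhibitionMatrix", function(x) rownames(x@residual))

#' @rdname InhibitionMatrix-class
#' @export
setMethod("kinaseIds", "InhibitionMatrix", function(x) colnames(x@residual))

setMethod("show", "InhibitionMatrix", function(object) {
  r <- object@residual
  cat("InhibitionMatrix:", nrow(r), "inhibitors x", ncol(r), "kinases\n")
  cat("  assay concentration:", object@assayConc, "uM\n")
  cat(sprintf("  residual activity: min %.3f, median %.3f, max %.3f\n",
              min(r), stats::median(r), max(r)))
  cat(sprintf("  strong inhibition (<= 0.2): %d entries\n", sum(r <= 0.2)))
})

#' @rdname ProliferationScreen-class
#' @export
setMethod("nucleiCounts", "ProliferationScreen",
          function(x) assay(x, "nuclei"))

#' @rdname ProliferationScreen-class
#' @export
setMethod("deadCounts", "ProliferationScreen", function(x) assay(x, "dead"))

#' @rdname ProliferationScreen-class
#' @export
setMethod("timesHours", "ProliferationScreen",
          function(x) rowData(x)$time_h)

#' @rdname ProliferationScreen-class
#' @export
setMethod("plateMap", "ProliferationScreen",
          function(x) as.data.frame(colData(x)))

setMethod("show", "ProliferationScreen", function(object) {
  pm <- plateMap(object)
  tt <- timesHours(object)
  cat("ProliferationScreen:", ncol(object), "wells,", nrow(object),
      "time points (", min(tt), "-", max(tt), "h )\n")
  if ("growth_factor" %in% names(pm))
    cat("  growth factors:",
        paste(sort(unique(stats::na.omit(pm$growth_factor))), collapse = ", "),
        "\n")
  if ("inhibitor_id" %in% names(pm))
    cat("  inhibitors:", length(unique(stats::na.omit(pm$inhibitor_id))),
        " control wells:", sum(isTRUE0(pm$is_control)), "\n")
})

isTRUE0 <- function(x) if (is.null(x)) logical(0) else x %in% TRUE

#' Extract one well's trajectory
#'
#' @param screen a [ProliferationScreen-class].
#' @param well_id well identifier (a `colData` `well_id`).
#' @return data.frame with columns `time_h`, `n_nuclei`, `n_dead` plus the
#'   well's platemap fields as attributes (`condition`).
#' @export
wellTrajectory <- function(screen, well_id) {
  stopIfNot(well_id %in% colnames(screen),
            sprintf("unknown well '%s'", well_id))
  out <- data.frame(time_h = timesHours(screen),
                    n_nuclei = nucleiCounts(screen)[, well_id],
                    n_dead = deadCounts(screen)[, well_id])
  attr(out, "condition") <- as.list(plateMap(screen)[well_id, ])
  out
}
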