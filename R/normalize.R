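## Per-plate normalization against negative controls, and Z'-factor QC.

## Floor zero raw values before taking logs: counts at a pseudo-count,
## viability at the smallest positive observed value. Both configurable.
.floorZeros <- function(w, pseudocountCount = 1,
                        pseudocountViability = NULL) {
  zero <- w$raw_value == 0
  if (!any(zero)) return(w)
  isCount <- w$readout %in% c("count2d", "sphere3d")
  w$raw_value[zero & isCount] <- pseudocountCount
  if (any(zero & !isCount)) {
    floorViab <- pseudocountViability
    if (is.null(floorViab)) {
      pos <- w$raw_value[!isCount & w$raw_value > 0]
      floorViab <- if (length(pos)) min(pos) else pseudocountCount
    }
    w$raw_value[zero & !isCount] <- floorViab
  }
  warning(sprintf("%d zero raw value(s) floored to a pseudo-count", sum(zero)),
          call. = FALSE)
  w
}

#' Normalize raw readouts to per-plate log2 fold changes
#'
#' Converts each well's raw value to
#' \code{log2fc = log2(raw) - center(log2 of the plate's siNC wells)},
#' computed independently per (cell line, readout, plate, replicate): each
#' replicate plate is normalized against its own negative controls. With the
#' default mean center (the geometric mean on the raw scale) the mean log2fc
#' over a plate's siNC wells is exactly zero, and a negative value means the
#' readout decreased more than the negative controls. Normalization is
#' invariant to any global rescaling of a plate's raw values.
#'
#' @param raw a \linkS4class{RawScreen}.
#' @param center \code{"mean"} (default) or \code{"median"} of the siNC log2
#'   values.
#' @param pseudocountCount value replacing zero counts before the log
#'   (default 1).
#' @param pseudocountViability value replacing zero viability readouts;
#'   default is the smallest positive observed viability value.
#' @return A \linkS4class{NormalizedScreen}.
#' @export
#' @examples
#' cfg <- SimulationConfig(nGenes = 40, wellsPerPlate = 64,
#'                         noiseSd2d = 0, noiseSd3d = 0,
#'                         spherePoisson = FALSE, seed = 5)
#' norm <- normalizePlates(simulateCampaign(cfg))
#' norm
normalizePlates <- function(raw, center = c("mean", "median"),
                            pseudocountCount = 1,
                            pseudocountViability = NULL) {
  stopifnot(is(raw, "RawScreen"))
  center <- match.arg(center)
  w <- .floorZeros(wellData(raw), pseudocountCount, pseudocountViability)
  key <- interaction(w$cell_line, w$readout, w$plate, w$replicate,
                     drop = TRUE, sep = "\r")
  logv <- log2(w$raw_value)

  isNC <- w$gene_id == "siNC"
  ncPerKey <- tapply(w$raw_value[isNC] > 0, key[isNC], sum)
  allKeys <- levels(key)
  missing <- setdiff(allKeys, names(ncPerKey)[!is.na(ncPerKey) & ncPerKey >= 2])
  if (length(missing)) {
    lab <- gsub("\r", "/", missing[1], fixed = TRUE)
    stop(sprintf("QC error: plate group %s has fewer than 2 positive siNC wells",
                 lab), call. = FALSE)
  }
  centerFun <- if (center == "mean") mean else stats::median
  centers <- tapply(logv[isNC], key[isNC], centerFun)
  v <- w
  v$log2fc <- as.vector(logv - centers[as.character(key)])
  v$raw_value <- NULL
  new("NormalizedScreen", values = v[.NORM_COLUMNS])
}

#' Z'-factor of a control pair
#'
#' The screening-window statistic
#' \code{Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|}, computed on
#' log2-scale values with sample (n-1) standard deviations. Z' <= 1 always;
#' it is undefined (NA) when the control means coincide. Z' is invariant
#' under positive-slope affine transformation of the values.
#'
#' @param negValues log2-scale values of the negative-control (siNC) wells.
#' @param posValues log2-scale values of the positive-control (siPLK1) wells.
#' @return The Z'-factor, or NA when undefined.
#' @export
#' @examples
#' zPrime(c(0, 0.05, -0.05), c(-2, -2.1, -1.9))
zPrime <- function(negValues, posValues) {
  negValues <- negValues[is.finite(negValues)]
  posValues <- posValues[is.finite(posValues)]
  if (length(negValues) < 2L || length(posValues) < 2L) {
    warning("Z' requires >= 2 wells of each control", call. = FALSE)
    return(NA_real_)
  }
  delta <- abs(mean(posValues) - mean(negValues))
  if (delta == 0) return(NA_real_)
  1 - 3 * (stats::sd(posValues) + stats::sd(negValues)) / delta
}

#' Per-plate Z'-factor QC report
#'
#' Computes, for every (cell line, readout, plate), the Z'-factor between
#' siPLK1 and siNC wells on the log2 scale (all replicates pooled), together
#' with control counts, means and standard deviations. Plates whose control
#' means coincide report a missing Z'.
#'
#' @inheritParams normalizePlates
#' @return data.frame with columns \code{cell_line}, \code{readout},
#'   \code{plate}, \code{zprime}, \code{n_siNC}, \code{n_siPLK1},
#'   \code{siNC_mean}, \code{siNC_sd}, \code{siPLK1_mean}, \code{siPLK1_sd}.
#' @export
qcReport <- function(raw, pseudocountCount = 1, pseudocountViability = NULL) {
  stopifnot(is(raw, "RawScreen"))
  w <- .floorZeros(wellData(raw), pseudocountCount, pseudocountViability)
  ctrl <- w[w$gene_id %in% .CONTROLS, ]
  if (!nrow(ctrl)) stop("QC error: no control wells present", call. = FALSE)
  groups <- .splitBy(ctrl, c("cell_line", "readout", "plate"))
  rows <- lapply(groups, function(g) {
    neg <- log2(g$raw_value[g$gene_id == "siNC"])
    pos <- log2(g$raw_value[g$gene_id == "siPLK1"])
    data.frame(
      cell_line = g$cell_line[1], readout = g$readout[1], plate = g$plate[1],
      zprime = if (length(neg) >= 2 && length(pos) >= 2)
        suppressWarnings(zPrime(neg, pos)) else NA_real_,
      n_siNC = length(neg), n_siPLK1 = length(pos),
      siNC_mean = mean(neg), siNC_sd = stats::sd(neg),
      siPLK1_mean = if (length(pos)) mean(pos) else NA_real_,
      siPLK1_sd = if (length(pos) >= 2) stats::sd(pos) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_line, out$readout, out$plate), ]
  rownames(out) <- NULL
  out
}
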