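## Multiplexing the cell-count and total-viability readouts into per-cell
## viability, and labeling susceptibility/resistance discordance.

#' Per-cell viability on the log2 scale
#'
#' Per-cell viability is total viability divided by cell count per well; on
#' the log2 fold-change scale that is simply the difference
#' \code{log2fc_viability_total - log2fc_count}. Missing inputs propagate to
#' missing outputs.
#'
#' @param log2fcViabilityTotal,log2fcCount numeric vectors of log2 fold
#'   changes.
#' @return \code{log2fcViabilityTotal - log2fcCount}.
#' @export
#' @examples
#' viabilityPerCell(-1, -1)      # 0: viability tracks count
#' viabilityPerCell(-0.5, -1.5)  # +1: surviving cells doubled their viability
viabilityPerCell <- function(log2fcViabilityTotal, log2fcCount) {
  log2fcViabilityTotal - log2fcCount
}

#' Dissect count vs viability readouts into per-cell viability records
#'
#' For every cell line carrying both a 2D cell-count and a 2D total-viability
#' screen, matches wells across the two readouts (same plate, well and
#' replicate), computes per-replicate per-cell viability as the log2
#' difference, aggregates replicates by the mean, and tests three directions
#' against the siNC wells of the gene's plate with pooled one-sided t-tests:
#' count decrease, total-viability decrease, and per-cell viability increase.
#' Each gene is then labeled:
#' \describe{
#'   \item{viability_up_resistant}{count hit whose per-cell viability rose
#'     above \code{perCellUpThreshold} with p below the p threshold — the
#'     surviving cells' resistance response;}
#'   \item{concordant_inhibitor}{count hit that is also a total-viability
#'     hit;}
#'   \item{count_only_inhibitor}{count hit without a significant
#'     total-viability decrease;}
#'   \item{neutral}{no hit on either readout;}
#'   \item{other}{remainder (e.g. viability-only hits).}
#' }
#' Labels are assigned in that order, so they are mutually exclusive. The
#' identity \code{log2fc_viability_per_cell + log2fc_count =
#' log2fc_viability_total} holds exactly for every record.
#'
#' @param normalized a \linkS4class{NormalizedScreen} containing both
#'   \code{count2d} and \code{viability2d} rows for at least one cell line.
#' @param thresholds a \linkS4class{HitThresholds}.
#' @param perCellUpThreshold log2 increase in per-cell viability required for
#'   the resistant label (default +0.5, about a 1.4-fold increase; validated
#'   resistant knockdowns show 2-4-fold single-cell increases).
#' @param pooled pooled-variance Student t (default) or Welch.
#' @return data.frame with one row per (cell_line, gene) and columns
#'   \code{cell_line}, \code{gene_id}, \code{log2fc_count},
#'   \code{log2fc_viability_total}, \code{log2fc_viability_per_cell},
#'   \code{p_count}, \code{p_viability}, \code{p_per_cell_up},
#'   \code{count_hit}, \code{viability_hit}, \code{per_cell_up},
#'   \code{discordance_label}.
#' @export
dissectViability <- function(normalized, thresholds = hitThresholds(),
                             perCellUpThreshold = 0.5, pooled = TRUE) {
  stopifnot(is(normalized, "NormalizedScreen"), is(thresholds, "HitThresholds"))
  v <- wellData(normalized)
  lines <- intersect(unique(v$cell_line[v$readout == "count2d"]),
                     unique(v$cell_line[v$readout == "viability2d"]))
  if (!length(lines))
    stop("no cell line carries both count2d and viability2d screens",
         call. = FALSE)

  perLine <- lapply(lines, function(cl) {
    cts <- v[v$cell_line == cl & v$readout == "count2d", ]
    vb <- v[v$cell_line == cl & v$readout == "viability2d", ]
    key <- function(d) paste(d$plate, d$well, d$replicate, sep = "\r")
    idx <- match(key(cts), key(vb))
    if (anyNA(idx))
      stop(sprintf("cell line %s: count and viability wells do not match", cl),
           call. = FALSE)
    d <- data.frame(plate = cts$plate, gene_id = cts$gene_id,
                    fc_count = cts$log2fc, fc_viab = vb$log2fc[idx],
                    stringsAsFactors = FALSE)
    d$fc_pc <- viabilityPerCell(d$fc_viab, d$fc_count)

    isNC <- d$gene_id == "siNC"
    ctrl <- split(d[isNC, c("fc_count", "fc_viab", "fc_pc")], d$plate[isNC])
    lib <- d[!(d$gene_id %in% .CONTROLS), ]
    perGene <- split(lib, lib$gene_id)
    rows <- lapply(names(perGene), function(g) {
      gd <- perGene[[g]]
      cv <- ctrl[[gd$plate[1]]]
      testP <- function(x, y, alt) {
        if (length(x) < 2L || is.null(y) || nrow(cv) < 2L) NA_real_
        else .twoSampleP(mean(x), stats::var(x), length(x),
                         mean(y), stats::var(y), length(y), alt, pooled)
      }
      data.frame(
        cell_line = cl, gene_id = g,
        log2fc_count = mean(gd$fc_count),
        log2fc_viability_total = mean(gd$fc_viab),
        log2fc_viability_per_cell = mean(gd$fc_pc),
        p_count = testP(gd$fc_count, cv$fc_count, "less"),
        p_viability = testP(gd$fc_viab, cv$fc_viab, "less"),
        p_per_cell_up = testP(gd$fc_pc, cv$fc_pc, "greater"),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  rec <- do.call(rbind, perLine)

  p <- thresholds@p
  rec$count_hit <- !is.na(rec$p_count) & rec$p_count < p &
    rec$log2fc_count < thresholds@fc[["count2d"]]
  rec$viability_hit <- !is.na(rec$p_viability) & rec$p_viability < p &
    rec$log2fc_viability_total < thresholds@fc[["viability2d"]]
  rec$per_cell_up <- !is.na(rec$p_per_cell_up) & rec$p_per_cell_up < p &
    rec$log2fc_viability_per_cell > perCellUpThreshold

  lab <- rep("other", nrow(rec))
  lab[!rec$count_hit & !rec$viability_hit] <- "neutral"
  lab[rec$count_hit & !rec$viability_hit] <- "count_only_inhibitor"
  lab[rec$count_hit & rec$viability_hit] <- "concordant_inhibitor"
  lab[rec$count_hit & rec$per_cell_up] <- "viability_up_resistant"
  rec$discordance_label <- lab
  rec <- rec[order(rec$cell_line, rec$log2fc_count), ]
  rownames(rec) <- NULL
  rec
}

#' Fraction of count hits lacking a viability hit
#'
#' The percentage of cell-count hits that did not also show a significant
#' total-viability decrease, rounded half-up to the nearest integer — the
#' headline measure of count/viability discordance.
#'
#' @param records data.frame from [dissectViability()] (any table with
#'   logical \code{count_hit} and \code{viability_hit} columns).
#' @return Percentage (integer-valued), or NA when there are no count hits.
#' @export
#' @examples
#' rec <- data.frame(count_hit = rep(TRUE, 195),
#'                   viability_hit = rep(c(FALSE, TRUE), c(107, 88)))
#' discordanceFraction(rec)  # 55
discordanceFraction <- function(records) {
  .checkColumns(records, c("count_hit", "viability_hit"), "dissection table")
  nCount <- sum(records$count_hit %in% TRUE)
  if (nCount == 0L) return(NA_real_)
  nDisc <- sum(records$count_hit %in% TRUE & !(records$viability_hit %in% TRUE))
  roundHalfUp(100 * nDisc / nCount, 0)
}
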