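## Cross-screen classification of hits: the common-vs-selective 2D dichotomy
## and the four-group 2D/3D taxonomy.

.FOUR_GROUPS <- c("two_d_only", "three_d_only", "common_2d_3d",
                  "selective_2d_3d")

#' Cross-screen profiles over 2D cell-count screens
#'
#' Collects, per gene, the mean and standard deviation of the per-screen mean
#' log2 fold changes across a list of 2D cell-count screens, plus the
#' per-screen values. The mean/sd pair is what the common-vs-selective
#' dichotomy and the 2D-only rule operate on; it is only defined for genes
#' measured in at least two screens.
#'
#' @param hitTables list of hit tables from [callHits()], one per 2D
#'   cell-count screen.
#' @return data.frame with columns \code{gene_id}, \code{mean_2d},
#'   \code{sd_2d}, \code{n_screens}, and one \code{log2fc.<cell_line>}
#'   column per screen.
#' @export
crossScreenProfiles <- function(hitTables) {
  stopifnot(is.list(hitTables), length(hitTables) >= 1L)
  genes <- sort(unique(unlist(lapply(hitTables, `[[`, "gene_id"))))
  fc <- vapply(hitTables, function(h)
    h$log2fc_mean[match(genes, h$gene_id)], numeric(length(genes)))
  fc <- matrix(fc, nrow = length(genes))
  labels <- vapply(seq_along(hitTables), function(i) {
    cl <- unique(hitTables[[i]]$cell_line)
    if (length(cl) == 1L) cl else sprintf("screen%d", i)
  }, "")
  colnames(fc) <- paste0("log2fc.", labels)
  n <- rowSums(!is.na(fc))
  prof <- data.frame(
    gene_id = genes,
    mean_2d = ifelse(n >= 2, rowMeans(fc, na.rm = TRUE), NA_real_),
    sd_2d = ifelse(n >= 2, apply(fc, 1, stats::sd, na.rm = TRUE), NA_real_),
    n_screens = n, stringsAsFactors = FALSE)
  cbind(prof, as.data.frame(fc))
}

#' Common-vs-selective dichotomy of 2D cell-count hits
#'
#' Splits genes by the consistency of their inhibition across 2D cell-count
#' screens: \code{sample_independent_common} for a strong consistent
#' reduction (mean log2fc below \code{commonMean}, i.e. >4-fold by default,
#' with cross-line s.d. below \code{commonSd}), \code{sample_selective} for
#' strong but variable inhibition (mean below \code{selectiveMean}, >2-fold,
#' with s.d. above \code{selectiveSd}), and \code{none} otherwise. All
#' boundaries are strict. Genes without a defined mean/sd (fewer than two
#' screens) are labeled \code{none} with a warning.
#'
#' @param profiles data.frame from [crossScreenProfiles()].
#' @param commonMean,commonSd cutoffs for the common label (defaults -2, 1).
#' @param selectiveMean,selectiveSd cutoffs for the selective label
#'   (defaults -1, 1).
#' @return \code{profiles} with an added \code{dichotomy} column.
#' @export
#' @examples
#' prof <- data.frame(gene_id = c("a", "b", "c"),
#'                    mean_2d = c(-2.5, -1.5, -2.5),
#'                    sd_2d = c(0.5, 1.5, 1.0), n_screens = 3)
#' classifyDichotomy(prof)$dichotomy
classifyDichotomy <- function(profiles, commonMean = -2, commonSd = 1,
                              selectiveMean = -1, selectiveSd = 1) {
  .checkColumns(profiles, c("gene_id", "mean_2d", "sd_2d"), "profile table")
  m <- profiles$mean_2d; s <- profiles$sd_2d
  undef <- is.na(m) | is.na(s)
  if (any(undef))
    warning(sprintf("%d gene(s) lack >= 2 screens; labeled 'none'",
                    sum(undef)), call. = FALSE)
  lab <- rep("none", nrow(profiles))
  lab[!undef & m < commonMean & s < commonSd] <- "sample_independent_common"
  lab[!undef & m < selectiveMean & s > selectiveSd &
        lab == "none"] <- "sample_selective"
  profiles$dichotomy <- lab
  profiles
}

#' Four-group 2D/3D classification of screen hits
#'
#' Partitions the hit universe (genes flagged as a hit in at least one
#' included screen) into four mutually exclusive groups:
#' \describe{
#'   \item{common_2d_3d}{strong consistent 2D inhibition (mean 2D log2fc
#'     below \code{mean2dMax} with cross-line s.d. below \code{sd2dMin}) and
#'     a 3D sphere hit in at least one 3D screen;}
#'   \item{two_d_only}{strong but sample-variable 2D inhibition (mean below
#'     \code{mean2dMax}, s.d. above \code{sd2dMin}) with no 3D hit — in
#'     screens of this design, consistent 2D inhibitors also suppress sphere
#'     formation, so the exclusively-2D genes are the sample-variable ones;}
#'   \item{three_d_only}{a sphere hit (log2fc below the sphere threshold
#'     with p below the p threshold) in every 3D screen, with no 2D
#'     cell-count hit;}
#'   \item{selective_2d_3d}{remaining genes hit in at least one screen but
#'     captured by none of the above (cell-line- or condition-selective
#'     patterns).}
#' }
#' All other genes are labeled \code{none}. All boundaries are strict.
#' \code{mode = "difference"} replaces the 3D-hit criterion by the literal
#' reading "difference between the 3D sphere log2 fold changes greater than
#' \code{diff3d}" with p below the p threshold in at least one 3D screen.
#'
#' @param hits2d list of [callHits()] tables for the 2D cell-count screens.
#' @param hits3d list of [callHits()] tables for the 3D sphere screens.
#' @param thresholds a \linkS4class{HitThresholds}; its p threshold governs
#'   the difference mode (hit flags already encode the per-screen criteria).
#' @param mean2dMax,sd2dMin 2D mean/spread cutoffs (defaults -1 and 1).
#' @param mode \code{"inhibition"} (default) or \code{"difference"}.
#' @param diff3d difference cutoff for \code{mode = "difference"} (default 1).
#' @return data.frame with columns \code{gene_id}, \code{group},
#'   \code{mean_2d}, \code{sd_2d}, \code{hit_2d_any}, \code{hit_3d_any}.
#' @export
classifyFourGroups <- function(hits2d, hits3d, thresholds = hitThresholds(),
                               mean2dMax = -1, sd2dMin = 1,
                               mode = c("inhibition", "difference"),
                               diff3d = 1) {
  mode <- match.arg(mode)
  stopifnot(is.list(hits2d), is.list(hits3d))
  if (!length(hits2d) || !length(hits3d))
    stop("configuration error: both 2D and 3D hit tables are required",
         call. = FALSE)
  stopifnot(is(thresholds, "HitThresholds"))

  prof <- crossScreenProfiles(hits2d)
  genes <- sort(unique(c(prof$gene_id,
                         unlist(lapply(hits3d, `[[`, "gene_id")))))
  prof <- prof[match(genes, prof$gene_id), c("gene_id", "mean_2d", "sd_2d")]
  prof$gene_id <- genes

  flagMat <- function(tables) {
    m <- vapply(tables, function(h) {
      f <- h$hit_flag[match(genes, h$gene_id)]
      f %in% TRUE
    }, logical(length(genes)))
    matrix(m, nrow = length(genes))
  }
  f2d <- flagMat(hits2d)
  f3d <- flagMat(hits3d)
  hit2dAny <- rowSums(f2d) > 0
  hit3dAny <- rowSums(f3d) > 0
  measured3d <- vapply(hits3d, function(h)
    !is.na(match(genes, h$gene_id)), logical(length(genes)))
  measured3d <- matrix(measured3d, nrow = length(genes))
  hit3dAll <- rowSums(f3d) == ncol(f3d) & rowSums(measured3d) == ncol(f3d)

  if (mode == "difference") {
    fc3 <- vapply(hits3d, function(h)
      h$log2fc_mean[match(genes, h$gene_id)], numeric(length(genes)))
    fc3 <- matrix(fc3, nrow = length(genes))
    p3 <- vapply(hits3d, function(h)
      h$p_value[match(genes, h$gene_id)], numeric(length(genes)))
    p3 <- matrix(p3, nrow = length(genes))
    spread <- apply(fc3, 1, function(z)
      if (all(is.na(z))) NA_real_ else diff(range(z, na.rm = TRUE)))
    anySig <- apply(p3, 1, function(z) any(z < thresholds@p, na.rm = TRUE))
    crit3d <- !is.na(spread) & spread > diff3d & anySig
    hit3dAll <- crit3d
    hit3dAny <- hit3dAny | crit3d
  }

  m <- prof$mean_2d; s <- prof$sd_2d
  strong2d <- !is.na(m) & !is.na(s) & m < mean2dMax & s < sd2dMin
  varied2d <- !is.na(m) & !is.na(s) & m < mean2dMax & s > sd2dMin

  group <- rep("none", length(genes))
  isCommon <- strong2d & hit3dAny
  is2dOnly <- varied2d & !hit3dAny & !isCommon
  is3dOnly <- hit3dAll & !hit2dAny & !isCommon & !is2dOnly
  hitAny <- hit2dAny | hit3dAny
  group[isCommon] <- "common_2d_3d"
  group[is2dOnly] <- "two_d_only"
  group[is3dOnly] <- "three_d_only"
  group[group == "none" & hitAny] <- "selective_2d_3d"

  data.frame(gene_id = genes, group = group, mean_2d = m, sd_2d = s,
             hit_2d_any = hit2dAny, hit_3d_any = hit3dAny,
             stringsAsFactors = FALSE)
}

#' Count group assignments
#'
#' @param assignments data.frame from [classifyFourGroups()] (or any table
#'   with \code{group}).
#' @return list with \code{counts} (named integer vector over the four
#'   groups plus \code{none}) and \code{total}, the number of classified
#'   hits (sum over the four groups, excluding \code{none}).
#' @export
#' @examples
#' g <- data.frame(group = rep(c("two_d_only", "three_d_only",
#'                               "common_2d_3d", "selective_2d_3d"),
#'                             c(7, 16, 49, 5)))
#' groupSizes(g)$total  # 77
groupSizes <- function(assignments) {
  .checkColumns(assignments, "group", "assignment table")
  lev <- c(.FOUR_GROUPS, "none")
  counts <- table(factor(assignments$group, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  list(counts = counts, total = sum(counts[.FOUR_GROUPS]))
}
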