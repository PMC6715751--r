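#' Accessors for screen containers
#'
#' \code{wellData} returns the long per-well table of a
#' \linkS4class{RawScreen} or \linkS4class{NormalizedScreen};
#' \code{truthClasses} and \code{truthEffects} return the planted class
#' labels and effect table of a \linkS4class{ScreenTruth}; \code{geneSets}
#' and \code{setDescriptions} return the member lists and descriptions of a
#' \linkS4class{GeneSetCollection}; \code{geneIds} lists the library genes
#' (controls excluded) of a screen-like object.
#'
#' @param x the object.
#' @return \code{wellData}, \code{truthEffects}: a data.frame;
#'   \code{truthClasses}, \code{setDescriptions}, \code{geneIds}: a character
#'   vector; \code{geneSets}: a named list.
#' @name accessors
#' @aliases wellData truthClasses truthEffects geneSets setDescriptions geneIds
#' @examples
#' cfg <- SimulationConfig(nGenes = 20, wellsPerPlate = 48, seed = 7)
#' truth <- assignEffectClasses(cfg)
#' head(truthClasses(truth))
NULL

#' @rdname accessors
#' @export
setGeneric("wellData", function(x) standardGeneric("wellData"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("truthClasses", function(x) standardGeneric("truthClasses"))

#' @rdname accessors
#' @export
setGeneric("truthEffects", function(x) standardGeneric("truthEffects"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

setMethod("wellData", "RawScreen", function(x) x@wells)
setMethod("wellData", "NormalizedScreen", function(x) x@values)

setMethod("geneIds", "RawScreen", function(x)
  setdiff(unique(x@wells$gene_id), .CONTROLS))
setMethod("geneIds", "NormalizedScreen", function(x)
  setdiff(unique(x@values$gene_id), .CONTROLS))
setMethod("geneIds", "ScreenTruth", function(x) names(x@classes))

setMethod("truthClasses", "ScreenTruth", function(x) x@classes)
setMethod("truthEffects", "ScreenTruth", function(x) x@effects)

setMethod("geneSets", "GeneSetCollection", function(x) x@sets)
setMethod("setDescriptions", "GeneSetCollection", function(x) x@descriptions)

#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "RawScreen", function(object) {
  w <- object@wells
  cat(sprintf("RawScreen: %d wells, %d gene(s), %d plate(s)\n",
              nrow(w), length(geneIds(object)), length(unique(w$plate))))
  if (nrow(w)) {
    combos <- unique(w[, c("cell_line", "readout")])
    cat("  screens:",
        paste(sprintf("%s/%s", combos$cell_line, combos$readout), collapse = ", "),
        "\n")
    cat(sprintf("  replicates: %d\n", length(unique(w$replicate))))
  }
})

setMethod("show", "NormalizedScreen", function(object) {
  v <- object@values
  cat(sprintf("NormalizedScreen: %d wells, %d gene(s)\n",
              nrow(v), length(geneIds(object))))
  if (nrow(v))
    cat(sprintf("  log2fc range: [%.2f, %.2f]\n",
                min(v$log2fc), max(v$log2fc)))
})

setMethod("show", "ScreenTruth", function(object) {
  cat(sprintf("ScreenTruth: %d gene(s)\n", length(object@classes)))
  if (length(object@classes))
    print(table(factor(object@classes, levels = .EFFECT_CLASSES)))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d set(s)\n", length(object@sets)))
  if (length(object@sets)) {
    sz <- vapply(object@sets, length, 1L)
    cat(sprintf("  member counts: min %d, median %d, max %d\n",
                min(sz), as.integer(stats::median(sz)), max(sz)))
  }
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d genes, %d-well plates (%d siNC + %d siPLK1), ",
    "%d replicate(s)\n"),
    object@nGenes, object@wellsPerPlate, object@nSiNC, object@nSiPLK1,
    object@nReplicates))
  cat(sprintf("  noise sd (log2): 2D %.3g, 3D %.3g; seed %d\n",
              object@noiseSd2d, object@noiseSd3d, object@seed))
  cat(sprintf("  2D lines: %s; 3D lines: %s\n",
              paste(object@cellLines2d, collapse = ", "),
              paste(object@cellLines3d, collapse = ", ")))
})

setMethod("show", "HitThresholds", function(object) {
  cat(sprintf("HitThresholds: p < %g; log2fc < %s\n", object@p,
              paste(sprintf("%g (%s)", object@fc, names(object@fc)),
                    collapse = ", ")))
})
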