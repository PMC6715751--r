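#' @import methods
NULL

## Canonical vocabularies used throughout the package.
.READOUTS <- c("count2d", "viability2d", "sphere3d")
.CONTROLS <- c("siNC", "siPLK1")
.EFFECT_CLASSES <- c("neutral", "common_essential", "two_d_only",
                     "three_d_only", "selective", "count_down_viability_up")
.RAW_COLUMNS <- c("cell_line", "readout", "plate", "well", "gene_id",
                  "replicate", "raw_value")
.NORM_COLUMNS <- c("cell_line", "readout", "plate", "well", "gene_id",
                   "replicate", "log2fc")

#' Supported phenotypic readouts
#'
#' The three well-level measures a campaign can carry: imaged nuclei count in
#' 2D monolayer culture (\code{count2d}), total metabolic viability signal per
#' well in 2D (\code{viability2d}), and spheroid count under low-attachment 3D
#' culture (\code{sphere3d}).
#'
#' @return Character vector of readout labels.
#' @export
#' @examples
#' screenReadouts()
screenReadouts <- function() .READOUTS

#' Planted effect classes of the synthetic generator
#'
#' @return Character vector of class labels.
#' @export
effectClasses <- function() .EFFECT_CLASSES

## ---------------------------------------------------------------------------
## RawScreen
## ---------------------------------------------------------------------------

#' RawScreen: per-well raw readouts of a screening campaign
#'
#' A long table with one row per (cell line, readout, plate, well, replicate):
#' the universal input of the pipeline. Control wells carry the reserved gene
#' labels \code{siNC} (non-targeting negative control) and \code{siPLK1}
#' (essential-gene positive control).
#'
#' @slot wells data.frame with columns \code{cell_line}, \code{readout},
#'   \code{plate}, \code{well}, \code{gene_id}, \code{replicate},
#'   \code{raw_value}.
#'
#' @seealso [RawScreen()], [readRawScreen()], [simulateCampaign()]
#' @exportClass RawScreen
setClass("RawScreen", slots = c(wells = "data.frame"))

setValidity("RawScreen", function(object) {
  w <- object@wells
  missing <- setdiff(.RAW_COLUMNS, names(w))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (!is.numeric(w$raw_value))
    return("raw_value must be numeric")
  if (nrow(w) && any(!is.finite(w$raw_value) | w$raw_value < 0))
    return("raw_value must be finite and >= 0")
  if (nrow(w) && !all(w$readout %in% .READOUTS))
    return(sprintf("unknown readout label(s): %s",
                   paste(unique(setdiff(w$readout, .READOUTS)), collapse = ", ")))
  if (!is.numeric(w$replicate))
    return("replicate must be an integer index")
  TRUE
})

#' Construct a RawScreen from a data.frame
#'
#' @param wells data.frame with the seven canonical columns (see
#'   \linkS4class{RawScreen}). Control labels are recognized
#'   case-insensitively and canonicalized to \code{siNC}/\code{siPLK1}.
#' @return A \linkS4class{RawScreen}.
#' @export
#' @examples
#' df <- data.frame(cell_line = "A", readout = "count2d", plate = "P1",
#'                  well = c("A1", "A2"), gene_id = c("G1", "sinc"),
#'                  replicate = 1L, raw_value = c(900, 1000))
#' RawScreen(df)
RawScreen <- function(wells) {
  wells <- as.data.frame(wells)
  wells$gene_id <- canonicalizeControls(as.character(wells$gene_id))
  wells$readout <- as.character(wells$readout)
  wells$cell_line <- as.character(wells$cell_line)
  wells$plate <- as.character(wells$plate)
  wells$well <- as.character(wells$well)
  rownames(wells) <- NULL
  new("RawScreen", wells = wells)
}

#' Canonicalize control labels
#'
#' Maps any case variant of the reserved control labels onto \code{siNC} and
#' \code{siPLK1}; all other labels pass through unchanged (gene symbols are
#' treated as opaque, case-sensitive strings).
#'
#' @param x character vector of gene/control labels.
#' @return Character vector with canonical control spelling.
#' @export
canonicalizeControls <- function(x) {
  lx <- tolower(x)
  x[lx == "sinc"] <- "siNC"
  x[lx == "siplk1"] <- "siPLK1"
  x
}

## ---------------------------------------------------------------------------
## NormalizedScreen
## ---------------------------------------------------------------------------

#' NormalizedScreen: per-well log2 fold changes against plate negative controls
#'
#' @slot values data.frame with columns \code{cell_line}, \code{readout},
#'   \code{plate}, \code{well}, \code{gene_id}, \code{replicate},
#'   \code{log2fc}. By construction the mean \code{log2fc} over the siNC
#'   wells of each plate (per readout, cell line and replicate) is zero.
#'
#' @seealso [normalizePlates()]
#' @exportClass NormalizedScreen
setClass("NormalizedScreen", slots = c(values = "data.frame"))

setValidity("NormalizedScreen", function(object) {
  v <- object@values
  missing <- setdiff(.NORM_COLUMNS, names(v))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (!is.numeric(v$log2fc)) return("log2fc must be numeric")
  TRUE
})

## ---------------------------------------------------------------------------
## ScreenTruth
## ---------------------------------------------------------------------------

#' ScreenTruth: planted ground truth of a simulated campaign
#'
#' Records, for every simulated library gene, its effect class and the
#' per-cell-line log2 effects planted on each readout. Per-cell viability
#' effects are cell-line independent.
#'
#' @slot classes named character vector: gene_id -> effect class (one of
#'   [effectClasses()]).
#' @slot effects data.frame with columns \code{gene_id}, \code{cell_line},
#'   \code{count_effect} (log2 shift on 2D cell count),
#'   \code{sphere_effect} (log2 shift on 3D sphere count) and
#'   \code{vpc_effect} (log2 shift on per-cell viability).
#'
#' @seealso [assignEffectClasses()]
#' @exportClass ScreenTruth
setClass("ScreenTruth", slots = c(classes = "character", effects = "data.frame"))

setValidity("ScreenTruth", function(object) {
  if (is.null(names(object@classes)) && length(object@classes))
    return("classes must be named by gene_id")
  if (length(object@classes) && !all(object@classes %in% .EFFECT_CLASSES))
    return("unknown effect class label")
  need <- c("gene_id", "cell_line", "count_effect", "sphere_effect", "vpc_effect")
  missing <- setdiff(need, names(object@effects))
  if (length(missing))
    return(sprintf("effects missing column(s): %s", paste(missing, collapse = ", ")))
  if (!setequal(unique(object@effects$gene_id), names(object@classes)))
    return("effects table must cover exactly the genes in classes")
  TRUE
})

#' Construct a ScreenTruth
#'
#' @param classes named character vector gene_id -> effect class.
#' @param effects data.frame of per-gene, per-cell-line planted log2 effects
#'   (see \linkS4class{ScreenTruth}).
#' @return A \linkS4class{ScreenTruth}.
#' @export
ScreenTruth <- function(classes, effects) {
  effects <- as.data.frame(effects)
  rownames(effects) <- NULL
  new("ScreenTruth", classes = classes, effects = effects)
}

## ---------------------------------------------------------------------------
## GeneSetCollection
## ---------------------------------------------------------------------------

#' GeneSetCollection: named gene sets with descriptions
#'
#' In-memory form of a GMT file: unique set names, a free-text description
#' per set, and de-duplicated member gene labels.
#'
#' @slot sets named list of character vectors (members per set).
#' @slot descriptions named character vector, parallel to \code{sets}.
#'
#' @seealso [readGmt()], [GeneSetCollection()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection", slots = c(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      return("set names must be present and unique")
    if (any(!vapply(object@sets, length, 1L)))
      return("member lists must be non-empty")
    if (any(vapply(object@sets, anyDuplicated, 1L) > 0))
      return("duplicate members within a set must be collapsed")
    if (!identical(names(object@sets), names(object@descriptions)))
      return("descriptions must be named in parallel with sets")
  }
  TRUE
})

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of member genes; duplicates
#'   within a set are collapsed.
#' @param descriptions optional named character vector of descriptions
#'   (defaults to empty strings).
#' @return A \linkS4class{GeneSetCollection}.
#' @export
#' @examples
#' GeneSetCollection(list(S1 = c("A", "B"), S2 = c("B", "C")))
GeneSetCollection <- function(sets, descriptions = NULL) {
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  } else {
    descriptions <- descriptions[names(sets)]
    names(descriptions) <- names(sets)
    descriptions[is.na(descriptions)] <- ""
  }
  new("GeneSetCollection", sets = sets, descriptions = descriptions)
}

## ---------------------------------------------------------------------------
## SimulationConfig
## ---------------------------------------------------------------------------

#' SimulationConfig: parameters of a synthetic screening campaign
#'
#' See [SimulationConfig()] for the constructor and defaults.
#'
#' @slot nGenes number of library genes.
#' @slot wellsPerPlate plate format (default 384).
#' @slot nSiNC,nSiPLK1 control wells per plate.
#' @slot nReplicates replicate measurements per well position.
#' @slot classProportions named probability vector over [effectClasses()].
#' @slot noiseSd2d,noiseSd3d s.d. of Gaussian noise on log2 readouts.
#' @slot baselineCount,baselineSphere expected raw values for untreated wells.
#' @slot positiveControlEffect log2 shift applied to siPLK1 wells.
#' @slot cellLines2d,cellLines3d cell-line labels available per condition.
#' @slot spherePoisson draw sphere counts from a Poisson whose log2 mean
#'   carries the effect (TRUE), or return the mean deterministically (FALSE).
#' @slot seed integer seed; all campaign randomness flows from it.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig", slots = c(
  nGenes = "integer", wellsPerPlate = "integer",
  nSiNC = "integer", nSiPLK1 = "integer", nReplicates = "integer",
  classProportions = "numeric",
  noiseSd2d = "numeric", noiseSd3d = "numeric",
  baselineCount = "numeric", baselineSphere = "numeric",
  positiveControlEffect = "numeric",
  cellLines2d = "character", cellLines3d = "character",
  spherePoisson = "logical", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (object@nGenes < 1L) return("nGenes must be positive")
  if (object@nReplicates < 1L) return("nReplicates must be positive")
  if (object@nSiNC < 8L) return("need >= 8 siNC wells per plate")
  if (object@nSiPLK1 < 2L) return("need >= 2 siPLK1 wells per plate")
  if (object@wellsPerPlate <= object@nSiNC + object@nSiPLK1)
    return("wellsPerPlate must exceed the number of control wells")
  p <- object@classProportions
  if (!setequal(names(p), .EFFECT_CLASSES))
    return("classProportions must be named by the six effect classes")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    return("classProportions must be nonnegative and sum to 1 (tol 1e-9)")
  if (object@noiseSd2d < 0 || object@noiseSd3d < 0)
    return("noise standard deviations must be >= 0")
  if (object@baselineCount <= 0 || object@baselineSphere <= 0)
    return("baselines must be positive")
  if (!length(object@cellLines2d) && !length(object@cellLines3d))
    return("at least one cell line is required")
  TRUE
})

#' Construct a SimulationConfig
#'
#' Defaults emulate the assay design of a druggable-targetome siRNA screen:
#' 384-well plates carrying library genes plus 16 siNC and 8 siPLK1 control
#' wells, triplicate measurements, multiplicative log-normal well noise that
#' is larger for the 3D sphere readout than for 2D readouts, and a strong
#' negative siPLK1 effect (PLK1 is cell-cycle essential).
#'
#' @param nGenes library size.
#' @param wellsPerPlate wells per plate (default 384).
#' @param nSiNC,nSiPLK1 negative/positive control wells per plate
#'   (defaults 16 and 8).
#' @param nReplicates replicates per well (default 3, i.e. triplicate).
#' @param classProportions named probability vector over [effectClasses()];
#'   default is a mostly-neutral library with 2\% of genes in each
#'   non-neutral class.
#' @param noiseSd2d,noiseSd3d log2-scale noise s.d. (defaults 0.15 and 0.4;
#'   3D > 2D because sphere counts are small).
#' @param baselineCount,baselineSphere expected untreated raw values
#'   (defaults 2000 cells and 60 spheres).
#' @param positiveControlEffect siPLK1 log2 shift (default -2, a 4-fold drop).
#' @param cellLines2d,cellLines3d cell-line labels per culture condition.
#' @param spherePoisson logical; see \linkS4class{SimulationConfig}.
#' @param seed integer seed.
#' @return A \linkS4class{SimulationConfig}.
#' @export
#' @examples
#' cfg <- SimulationConfig(nGenes = 100, seed = 1)
#' cfg
SimulationConfig <- function(nGenes,
                             wellsPerPlate = 384L,
                             nSiNC = 16L, nSiPLK1 = 8L,
                             nReplicates = 3L,
                             classProportions = c(
                               neutral = 0.90, common_essential = 0.02,
                               two_d_only = 0.02, three_d_only = 0.02,
                               selective = 0.02,
                               count_down_viability_up = 0.02),
                             noiseSd2d = 0.15, noiseSd3d = 0.4,
                             baselineCount = 2000, baselineSphere = 60,
                             positiveControlEffect = -2,
                             cellLines2d = c("A549", "HT29", "U87"),
                             cellLines3d = c("U87", "OVCAR8"),
                             spherePoisson = TRUE,
                             seed = 1L) {
  new("SimulationConfig",
      nGenes = as.integer(nGenes), wellsPerPlate = as.integer(wellsPerPlate),
      nSiNC = as.integer(nSiNC), nSiPLK1 = as.integer(nSiPLK1),
      nReplicates = as.integer(nReplicates),
      classProportions = classProportions[.EFFECT_CLASSES],
      noiseSd2d = noiseSd2d, noiseSd3d = noiseSd3d,
      baselineCount = baselineCount, baselineSphere = baselineSphere,
      positiveControlEffect = positiveControlEffect,
      cellLines2d = cellLines2d, cellLines3d = cellLines3d,
      spherePoisson = spherePoisson, seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## HitThresholds
## ---------------------------------------------------------------------------

#' HitThresholds: hit-calling cutoffs
#'
#' @slot p one-sided p-value cutoff (strict: hits require p < p).
#' @slot fc named numeric of log2 fold-change cutoffs per readout
#'   (strict: hits require log2fc_mean < fc[readout]).
#'
#' @exportClass HitThresholds
setClass("HitThresholds", slots = c(p = "numeric", fc = "numeric"))

setValidity("HitThresholds", function(object) {
  if (object@p <= 0 || object@p >= 1) return("p threshold must be in (0,1)")
  if (any(object@fc >= 0)) return("fold-change thresholds must be < 0 (log2)")
  if (!all(names(object@fc) %in% .READOUTS)) return("fc must be named by readouts")
  TRUE
})

#' Construct hit-calling thresholds
#'
#' Defaults: p < 0.01 with log2 fold change below -1 for cell counts and
#' sphere counts (a 2-fold decrease) and below -0.6 for the total-viability
#' readout. The \code{"uniform2fold"} preset applies the 2-fold rule to all
#' three readouts instead.
#'
#' @param p p-value cutoff, default 0.01.
#' @param count2d,viability2d,sphere3d per-readout log2fc cutoffs.
#' @param preset \code{"default"} or \code{"uniform2fold"}.
#' @return A \linkS4class{HitThresholds}.
#' @export
#' @examples
#' hitThresholds()
#' hitThresholds(preset = "uniform2fold")
hitThresholds <- function(p = 0.01, count2d = -1, viability2d = -0.6,
                          sphere3d = -1,
                          preset = c("default", "uniform2fold")) {
  preset <- match.arg(preset)
  if (preset == "uniform2fold") viability2d <- -1
  new("HitThresholds", p = p,
      fc = c(count2d = count2d, viability2d = viability2d, sphere3d = sphere3d))
}
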