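## Synthetic screening campaigns with planted ground truth.
##
## The generator emulates the assay design of a multiplexed druggable-targetome
## siRNA screen: 384-well plates holding library genes plus siNC/siPLK1
## control wells, triplicate measurements, multiplicative log-normal well
## noise (additive Gaussian on the log2 scale), and per-gene planted effects
## on 2D cell count, per-cell viability, and 3D sphere count.

## Planted effect magnitudes per class, drawn uniformly from the ranges below
## (log2 scale). Ranges are chosen so that, with three 2D lines and two 3D
## lines and zero noise, the downstream four-group classifier recovers the
## planted class exactly (see the methods vignette).
.EFFECT_RANGES <- list(
  common_essential = list(count = c(-3.5, -2.0), sphere = c(-2.5, -1.1)),
  two_d_only = list(count_base = c(-1.3, -1.05), count_strong = c(-4.2, -3.5)),
  three_d_only = list(sphere = c(-2.5, -1.2)),
  selective = list(count = c(-2.8, -2.2), sphere = c(-2.5, -1.5)),
  count_down_viability_up = list(count = c(-2.0, -1.2), vpc = c(0.5, 2.0))
)

#' Assign planted effect classes and magnitudes to a simulated library
#'
#' Each gene draws an effect class from \code{classProportions} and
#' class-specific log2 effect magnitudes: common-essential genes are strongly
#' inhibitory in every 2D line (count effect <= -2) and in every 3D line
#' (sphere effect <= -1); 2D-only genes inhibit all 2D lines (<= -1) with one
#' line much more strongly hit, so their cross-line spread exceeds 1; 3D-only
#' genes inhibit sphere formation only; selective genes carry a strong effect
#' in exactly one randomly chosen (cell line, condition) slot;
#' count-down/viability-up genes reduce cell count while raising per-cell
#' viability by at least +0.5. Deterministic given \code{config@seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{ScreenTruth} covering exactly the simulated library.
#' @seealso [simulateCampaign()]
#' @export
#' @examples
#' truth <- assignEffectClasses(SimulationConfig(nGenes = 50, seed = 3))
#' table(truthClasses(truth))
assignEffectClasses <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  genes <- sprintf("GENE%05d", seq_len(config@nGenes))
  classes <- sample(.EFFECT_CLASSES, config@nGenes, replace = TRUE,
                    prob = config@classProportions[.EFFECT_CLASSES])
  names(classes) <- genes

  l2d <- config@cellLines2d
  l3d <- config@cellLines3d
  allLines <- union(l2d, l3d)
  countEff <- matrix(0, config@nGenes, length(allLines),
                     dimnames = list(genes, allLines))
  sphereEff <- matrix(0, config@nGenes, length(allLines),
                      dimnames = list(genes, allLines))
  vpcEff <- stats::setNames(numeric(config@nGenes), genes)

  runifRange <- function(n, r) stats::runif(n, r[1], r[2])
  ## one (line, condition) slot per selective gene
  slots2d <- if (length(l2d)) paste0(l2d, "\r2d") else character()
  slots3d <- if (length(l3d)) paste0(l3d, "\r3d") else character()
  slots <- c(slots2d, slots3d)

  for (i in seq_len(config@nGenes)) {
    cls <- classes[i]
    if (cls == "neutral") next
    rg <- .EFFECT_RANGES[[cls]]
    if (cls == "common_essential") {
      countEff[i, l2d] <- runifRange(length(l2d), rg$count)
      sphereEff[i, l3d] <- runifRange(length(l3d), rg$sphere)
    } else if (cls == "two_d_only") {
      e <- runifRange(length(l2d), rg$count_base)
      if (length(l2d)) {
        strong <- sample.int(length(l2d), 1L)
        e[strong] <- runifRange(1L, rg$count_strong)
      }
      countEff[i, l2d] <- e
    } else if (cls == "three_d_only") {
      sphereEff[i, l3d] <- runifRange(length(l3d), rg$sphere)
    } else if (cls == "selective") {
      slot <- strsplit(sample(slots, 1L), "\r", fixed = TRUE)[[1]]
      if (slot[2] == "2d") {
        countEff[i, slot[1]] <- runifRange(1L, rg$count)
      } else {
        sphereEff[i, slot[1]] <- runifRange(1L, rg$sphere)
      }
    } else if (cls == "count_down_viability_up") {
      countEff[i, l2d] <- runifRange(length(l2d), rg$count)
      vpcEff[i] <- runifRange(1L, rg$vpc)
    }
  }

  effects <- data.frame(
    gene_id = rep(genes, times = length(allLines)),
    cell_line = rep(allLines, each = config@nGenes),
    count_effect = as.vector(countEff),
    sphere_effect = as.vector(sphereEff),
    vpc_effect = rep(unname(vpcEff), times = length(allLines)),
    stringsAsFactors = FALSE)
  ScreenTruth(classes = classes, effects = effects)
}

#' Study-design layout of screens for a simulated campaign
#'
#' One row per (cell line, readout) screen. The default mirrors the
#' multiplexed design: a 2D cell-count screen for every 2D line, a matched
#' 2D total-viability screen for the first two 2D lines, and a 3D sphere
#' screen for every 3D line.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return data.frame with columns \code{cell_line}, \code{readout}.
#' @export
campaignLayout <- function(config) {
  l2d <- config@cellLines2d
  viab <- utils::head(l2d, 2L)
  data.frame(
    cell_line = c(l2d, viab, config@cellLines3d),
    readout = c(rep("count2d", length(l2d)),
                rep("viability2d", length(viab)),
                rep("sphere3d", length(config@cellLines3d))),
    stringsAsFactors = FALSE)
}

## plate layout: genes fill plates sequentially in library order; every plate
## additionally carries nSiNC + nSiPLK1 control wells at its tail.
.plateMap <- function(config, genes) {
  nLib <- config@wellsPerPlate - config@nSiNC - config@nSiPLK1
  nPlates <- ceiling(length(genes) / nLib)
  wellLabels <- function(n) {
    if (config@wellsPerPlate == 384L) {
      lab <- as.vector(t(outer(LETTERS[1:16], 1:24, paste0)))
      lab[seq_len(n)]
    } else sprintf("W%03d", seq_len(n))
  }
  maps <- lapply(seq_len(nPlates), function(p) {
    idx <- ((p - 1L) * nLib + 1L):min(p * nLib, length(genes))
    ids <- c(genes[idx], rep("siNC", config@nSiNC),
             rep("siPLK1", config@nSiPLK1))
    data.frame(plate = sprintf("P%03d", p), well = wellLabels(length(ids)),
               gene_id = ids, stringsAsFactors = FALSE)
  })
  do.call(rbind, maps)
}

#' Simulate raw readouts for a screening campaign
#'
#' For every requested (cell line, readout) screen, raw well values follow
#' \code{baseline * 2^(planted_effect + noise)} with Gaussian noise on the
#' log2 scale (noise s.d. \code{noiseSd2d} for 2D readouts, \code{noiseSd3d}
#' for 3D). Total 2D viability is coupled to the realized cell count of the
#' same well: \code{viability = count_raw * 2^(vpc_effect + noise)}, so that
#' per-cell viability (viability / count) carries the planted per-cell
#' effect. Sphere counts are drawn from a Poisson distribution whose mean
#' carries the log2 effect (or returned as the deterministic mean when
#' \code{spherePoisson} is FALSE). siNC wells use effect 0 and siPLK1 wells
#' use \code{positiveControlEffect}; controls are present on every plate.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param truth a \linkS4class{ScreenTruth} covering the config's genes;
#'   defaults to \code{assignEffectClasses(config)}.
#' @param layout data.frame of (cell_line, readout) screens to simulate;
#'   defaults to [campaignLayout()].
#' @return A \linkS4class{RawScreen}.
#' @export
#' @examples
#' cfg <- SimulationConfig(nGenes = 40, wellsPerPlate = 64, seed = 11)
#' raw <- simulateCampaign(cfg)
#' raw
simulateCampaign <- function(config, truth = assignEffectClasses(config),
                             layout = campaignLayout(config)) {
  stopifnot(is(config, "SimulationConfig"), is(truth, "ScreenTruth"))
  validObject(config); validObject(truth)
  genes <- geneIds(truth)
  if (length(genes) != config@nGenes)
    stop("truth must cover exactly the config's nGenes library genes")
  bad2d <- layout$readout %in% c("count2d", "viability2d") &
    !(layout$cell_line %in% config@cellLines2d)
  bad3d <- layout$readout == "sphere3d" &
    !(layout$cell_line %in% config@cellLines3d)
  if (any(bad2d | bad3d))
    stop(sprintf("layout requests screens not in the config: %s",
                 paste(sprintf("%s/%s", layout$cell_line, layout$readout)
                       [bad2d | bad3d], collapse = ", ")))
  if (!all(layout$readout %in% .READOUTS))
    stop("unknown readout in layout")

  eff <- truthEffects(truth)
  effMat <- function(col) {
    lines <- unique(eff$cell_line)
    m <- matrix(0, length(genes), length(lines),
                dimnames = list(genes, lines))
    m[cbind(match(eff$gene_id, genes), match(eff$cell_line, lines))] <-
      eff[[col]]
    m
  }
  countEff <- effMat("count_effect")
  sphereEff <- effMat("sphere_effect")
  vpc <- eff$vpc_effect[match(genes, eff$gene_id)]
  names(vpc) <- genes

  map <- .plateMap(config, genes)
  nW <- nrow(map)
  nR <- config@nReplicates
  isNC <- map$gene_id == "siNC"
  isPC <- map$gene_id == "siPLK1"
  isLib <- !isNC & !isPC

  wellEffects <- function(m, line) {
    e <- numeric(nW)
    e[isPC] <- config@positiveControlEffect
    e[isLib] <- m[map$gene_id[isLib], line]
    e
  }

  set.seed(config@seed + 1L)
  countRaw <- list()  # cache per 2D line, for viability coupling
  drawCount <- function(line) {
    if (!is.null(countRaw[[line]])) return(countRaw[[line]])
    e <- wellEffects(countEff, line)
    noise <- matrix(stats::rnorm(nW * nR, 0, config@noiseSd2d), nW, nR)
    raw <- config@baselineCount * 2^(e + noise)
    countRaw[[line]] <<- raw
    raw
  }

  out <- vector("list", nrow(layout))
  for (j in seq_len(nrow(layout))) {
    line <- layout$cell_line[j]
    rd <- layout$readout[j]
    raw <- switch(rd,
      count2d = drawCount(line),
      viability2d = {
        cts <- drawCount(line)
        e <- numeric(nW)
        e[isLib] <- vpc[map$gene_id[isLib]]
        noise <- matrix(stats::rnorm(nW * nR, 0, config@noiseSd2d), nW, nR)
        cts * 2^(e + noise)
      },
      sphere3d = {
        e <- wellEffects(sphereEff, line)
        noise <- matrix(stats::rnorm(nW * nR, 0, config@noiseSd3d), nW, nR)
        lambda <- config@baselineSphere * 2^(e + noise)
        if (config@spherePoisson)
          matrix(stats::rpois(nW * nR, lambda), nW, nR)
        else lambda
      })
    out[[j]] <- data.frame(
      cell_line = line, readout = rd,
      plate = rep(map$plate, times = nR),
      well = rep(map$well, times = nR),
      gene_id = rep(map$gene_id, times = nR),
      replicate = rep(seq_len(nR), each = nW),
      raw_value = as.vector(raw),
      stringsAsFactors = FALSE)
  }
  RawScreen(do.call(rbind, out))
}

#' Generate a synthetic gene-set annotation coupled to planted effect classes
#'
#' Builds a GMT-style collection in which, for every non-neutral effect class
#' present in the truth table, a few sets draw a fraction \code{coupling} of
#' their members from that class's genes (the remainder from the whole
#' library), plus purely random background sets. Such annotations let
#' enrichment and similarity-network stages be exercised against a known
#' class structure.
#'
#' @param truth a \linkS4class{ScreenTruth}.
#' @param nSetsPerClass sets coupled to each non-neutral class (default 4).
#' @param nBackground uncoupled random sets (default 10).
#' @param setSize inclusive range of set sizes (default 10 to 40).
#' @param coupling fraction of members drawn from the coupled class,
#'   capped by class size (default 0.8).
#' @param seed integer seed.
#' @return A \linkS4class{GeneSetCollection}; descriptions record the coupled
#'   class (synthetic annotation, not real GO terms).
#' @export
simulateGeneSets <- function(truth, nSetsPerClass = 4L, nBackground = 10L,
                             setSize = c(10L, 40L), coupling = 0.8,
                             seed = 1L) {
  stopifnot(is(truth, "ScreenTruth"))
  set.seed(seed)
  genes <- geneIds(truth)
  cls <- truthClasses(truth)
  sets <- list(); desc <- character()
  addSet <- function(members, label) {
    members <- unique(members)
    if (length(members) < 2L) return()
    nm <- sprintf("GS%03d", length(sets) + 1L)
    sets[[nm]] <<- members
    desc[nm] <<- label
  }
  for (cl in setdiff(.EFFECT_CLASSES, "neutral")) {
    pool <- names(cls)[cls == cl]
    if (!length(pool)) next
    for (k in seq_len(nSetsPerClass)) {
      s <- sample(setSize[1]:setSize[2], 1L)
      nIn <- min(length(pool), round(coupling * s))
      inside <- sample(pool, nIn)
      outside <- sample(setdiff(genes, inside), max(0L, s - nIn))
      addSet(c(inside, outside), sprintf("synthetic; coupled to %s", cl))
    }
  }
  for (k in seq_len(nBackground)) {
    s <- sample(setSize[1]:setSize[2], 1L)
    addSet(sample(genes, min(s, length(genes))), "synthetic background")
  }
  GeneSetCollection(sets, desc)
}
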