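## End-to-end orchestration: simulate (or load) a campaign, then QC,
## normalization, hit calling, classification, dissection, similarity
## network and enrichment, writing one TSV artifact per stage plus a run
## manifest.

#' Assemble a pipeline configuration
#'
#' Bundles every stage's settings. Input is either a raw screen TSV
#' (\code{rawPath}) or, by default, a simulated campaign defined by
#' \code{simulation}; annotation is either a GMT path (\code{gmtPath}) or,
#' for simulated runs, a synthetic class-coupled collection. The seed is
#' mandatory and drives every stochastic stage.
#'
#' @param outDir output directory (created if needed).
#' @param simulation a \linkS4class{SimulationConfig} (ignored when
#'   \code{rawPath} is given).
#' @param layout screen layout data.frame, default [campaignLayout()].
#' @param rawPath optional path to a raw screen TSV.
#' @param gmtPath optional path to a GMT annotation file.
#' @param thresholds a \linkS4class{HitThresholds}.
#' @param mean2dMax,sd2dMin four-group classification cutoffs.
#' @param perCellUpThreshold per-cell viability increase for the resistant
#'   label.
#' @param minScore Tanimoto edge threshold.
#' @param gseaWeight,nPerm GSEA settings.
#' @param seed integer seed.
#' @return A list with class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(outDir,
                           simulation = SimulationConfig(nGenes = 500L,
                                                         seed = seed),
                           layout = campaignLayout(simulation),
                           rawPath = NULL, gmtPath = NULL,
                           thresholds = hitThresholds(),
                           mean2dMax = -1, sd2dMin = 1,
                           perCellUpThreshold = 0.5,
                           minScore = 0.2, gseaWeight = 1, nPerm = 1000L,
                           seed = 1L) {
  structure(list(outDir = outDir, simulation = simulation, layout = layout,
                 rawPath = rawPath, gmtPath = gmtPath,
                 thresholds = thresholds, mean2dMax = mean2dMax,
                 sd2dMin = sd2dMin, perCellUpThreshold = perCellUpThreshold,
                 minScore = minScore, gseaWeight = gseaWeight,
                 nPerm = as.integer(nPerm), seed = as.integer(seed)),
            class = "PipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full screen-analysis pipeline
#'
#' Executes every stage on one campaign and writes, under
#' \code{config$outDir}: \code{qc.tsv}, \code{norm.tsv}, \code{hits.tsv},
#' \code{groups.tsv}, \code{dissection.tsv}, \code{edges.tsv},
#' \code{enrich.tsv} and \code{manifest.json} (a config echo with package
#' version and seed); simulated runs additionally write \code{raw.tsv} and
#' \code{truth.tsv}. Stages whose inputs are absent from the campaign (e.g.
#' dissection without a paired viability screen) write a header-only table.
#' The run is deterministic for a fixed config: repeating it reproduces the
#' TSV artifacts byte for byte.
#'
#' @param config a configuration from [pipelineConfig()].
#' @param quiet suppress per-stage progress messages (default FALSE).
#' @return Invisibly, a named list of artifact paths.
#' @export
#' @examples
#' cfg <- pipelineConfig(outDir = file.path(tempdir(), "demo"),
#'                       simulation = SimulationConfig(nGenes = 60,
#'                                                     wellsPerPlate = 96,
#'                                                     seed = 4),
#'                       nPerm = 50, seed = 4)
#' paths <- runPipeline(cfg, quiet = TRUE)
#' names(paths)
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(config$seed)) stop("configuration error: seed is mandatory",
                                 call. = FALSE)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$outDir, f)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  artifacts <- list()

  if (!is.null(config$rawPath)) {
    say("stage load: %s", config$rawPath)
    raw <- .stage("load", readRawScreen(config$rawPath))
    truth <- NULL
  } else {
    say("stage simulate: %d genes", config$simulation@nGenes)
    truth <- .stage("simulate", assignEffectClasses(config$simulation))
    raw <- .stage("simulate",
                  simulateCampaign(config$simulation, truth, config$layout))
    artifacts$raw <- writeRawScreen(raw, path("raw.tsv"))
    artifacts$truth <- writeScreenTruth(truth, path("truth.tsv"))
  }

  say("stage qc")
  qc <- .stage("qc", qcReport(raw))
  artifacts$qc <- .writeTsv(qc, path("qc.tsv"))

  say("stage normalize")
  norm <- .stage("normalize", normalizePlates(raw))
  artifacts$norm <- writeNormalizedScreen(norm, path("norm.tsv"))

  say("stage call-hits")
  hits <- .stage("call-hits", callHits(norm, config$thresholds))
  artifacts$hits <- writeResultTable(hits, path("hits.tsv"))

  say("stage classify")
  screens <- .splitBy(hits, c("cell_line", "readout"))
  hits2d <- screens[vapply(screens, function(s) s$readout[1] == "count2d",
                           NA)]
  hits3d <- screens[vapply(screens, function(s) s$readout[1] == "sphere3d",
                           NA)]
  groups <- if (length(hits2d) && length(hits3d)) {
    .stage("classify",
           classifyFourGroups(unname(hits2d), unname(hits3d),
                              config$thresholds, config$mean2dMax,
                              config$sd2dMin))
  } else {
    data.frame(gene_id = character(), group = character(),
               mean_2d = numeric(), sd_2d = numeric(),
               hit_2d_any = logical(), hit_3d_any = logical())
  }
  artifacts$groups <- .writeTsv(groups, path("groups.tsv"))

  say("stage dissect")
  v <- wellData(norm)
  hasPair <- length(intersect(
    unique(v$cell_line[v$readout == "count2d"]),
    unique(v$cell_line[v$readout == "viability2d"]))) > 0
  dissection <- if (hasPair) {
    .stage("dissect", dissectViability(norm, config$thresholds,
                                       config$perCellUpThreshold))
  } else {
    data.frame(cell_line = character(), gene_id = character(),
               log2fc_count = numeric(), log2fc_viability_total = numeric(),
               log2fc_viability_per_cell = numeric(), p_count = numeric(),
               p_viability = numeric(), p_per_cell_up = numeric(),
               count_hit = logical(), viability_hit = logical(),
               per_cell_up = logical(), discordance_label = character())
  }
  artifacts$dissection <- .writeTsv(dissection, path("dissection.tsv"))

  say("stage annotation")
  sets <- if (!is.null(config$gmtPath)) {
    .stage("annotation", readGmt(config$gmtPath))
  } else if (!is.null(truth)) {
    .stage("annotation", simulateGeneSets(truth, seed = config$seed))
  } else {
    GeneSetCollection(list())
  }

  say("stage network")
  hitGenes <- sort(unique(hits$gene_id[hits$hit_flag]))
  netGenes <- if (nrow(groups)) groups$gene_id[groups$group != "none"]
              else hitGenes
  edges <- .stage("network",
                  buildSimilarityNetwork(netGenes, sets, config$minScore))
  artifacts$edges <- writeEdgeList(edges, path("edges.tsv"))

  say("stage enrich")
  universe <- sort(unique(hits$gene_id))
  ora <- if (length(sets) && length(hitGenes)) {
    .stage("enrich", hypergeometricEnrichment(hitGenes, universe, sets))
  } else {
    hypergeometricEnrichment(character(), if (length(universe)) universe
                             else "none", GeneSetCollection(list()))
  }
  ora$method <- rep("ora", nrow(ora))
  gsea <- NULL
  if (length(sets) && nrow(dissection)) {
    d1 <- dissection[dissection$cell_line == dissection$cell_line[1], ]
    ranking <- stats::setNames(d1$log2fc_viability_per_cell, d1$gene_id)
    gsea <- .stage("enrich",
                   gseaCollection(ranking, sets, weight = config$gseaWeight,
                                  nPerm = config$nPerm, seed = config$seed))
    if (nrow(gsea)) gsea$method <- "gsea"
  }
  enrich <- if (!is.null(gsea) && nrow(gsea)) {
    cols <- union(names(ora), names(gsea))
    fill <- function(d) { d[setdiff(cols, names(d))] <- NA; d[cols] }
    rbind(fill(ora), fill(gsea))
  } else ora
  enrich <- enrich[order(enrich$method, enrich$p_value, enrich$set_name), ]
  artifacts$enrich <- .writeTsv(enrich, path("enrich.tsv"))

  manifest <- list(
    package = "ScreenMux",
    version = as.character(utils::packageVersion("ScreenMux")),
    seed = config$seed,
    thresholds = list(p = config$thresholds@p,
                      fc = as.list(config$thresholds@fc)),
    classification = list(mean2dMax = config$mean2dMax,
                          sd2dMin = config$sd2dMin),
    perCellUpThreshold = config$perCellUpThreshold,
    minScore = config$minScore,
    gsea = list(weight = config$gseaWeight, nPerm = config$nPerm),
    simulated = is.null(config$rawPath))
  if (is.null(config$rawPath)) {
    sim <- config$simulation
    manifest$simulation <- list(
      nGenes = sim@nGenes, wellsPerPlate = sim@wellsPerPlate,
      nSiNC = sim@nSiNC, nSiPLK1 = sim@nSiPLK1,
      nReplicates = sim@nReplicates,
      classProportions = as.list(sim@classProportions),
      noiseSd2d = sim@noiseSd2d, noiseSd3d = sim@noiseSd3d,
      baselineCount = sim@baselineCount, baselineSphere = sim@baselineSphere,
      positiveControlEffect = sim@positiveControlEffect,
      cellLines2d = sim@cellLines2d, cellLines3d = sim@cellLines3d,
      spherePoisson = sim@spherePoisson, seed = sim@seed)
  }
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  artifacts$manifest <- path("manifest.json")
  say("done: %d artifacts in %s", length(artifacts), config$outDir)
  invisible(artifacts)
}
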