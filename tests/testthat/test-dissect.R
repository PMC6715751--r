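# Two-readout normalized screen built directly from per-gene replicate
# (count, viability) log2fc pairs; controls sit at zero with tiny spread.
dissectFixture <- function(genePairs, ctrlSpread = 0.02,
                           ctrlViabShift = rep(0, 8)) {
  rows <- list()
  wi <- 0L
  addRows <- function(gene, well, fcCount, fcViab) {
    for (rd in c("count2d", "viability2d")) {
      v <- if (rd == "count2d") fcCount else fcViab
      rows[[paste(gene, rd, well)]] <<- data.frame(
        cell_line = "A549", readout = rd, plate = "P001", well = well,
        gene_id = gene, replicate = seq_along(v), log2fc = v,
        stringsAsFactors = FALSE)
    }
  }
  for (g in names(genePairs)) {
    wi <- wi + 1L
    addRows(g, sprintf("W%02d", wi), genePairs[[g]]$count,
            genePairs[[g]]$viab)
  }
  ctrl <- ctrlSpread * c(-1, 1, 0, 0.5, -0.5, 0.25, -0.25, 0)
  for (i in seq_along(ctrl))
    addRows("siNC", sprintf("NC%02d", i), rep(ctrl[i], 3),
            rep(ctrl[i] + ctrlViabShift[i], 3) +
              ctrlSpread * c(0.1, -0.1, 0))
  methods::new("NormalizedScreen", values = do.call(rbind, rows))
}

test_that("per-cell viability is the log2 difference of the two readouts", {
  expect_equal(viabilityPerCell(-1, -1), 0)
  expect_equal(viabilityPerCell(-0.5, -1.5), 1.0)
  expect_true(is.na(viabilityPerCell(NA, -1)))
})

test_that("the per-cell identity holds exactly for every record", {
  cfg <- SimulationConfig(nGenes = 60, wellsPerPlate = 96, seed = 14)
  rec <- dissectViability(normalizePlates(simulateCampaign(cfg)))
  expect_lt(max(abs(rec$log2fc_viability_per_cell + rec$log2fc_count -
                      rec$log2fc_viability_total)), 1e-9)
})

test_that("discordance archetypes receive their labels", {
  norm <- dissectFixture(list(
    conc = list(count = c(-2.0, -2.05, -1.95), viab = c(-1.8, -1.85, -1.75)),
    resist = list(count = c(-1.5, -1.55, -1.45), viab = c(-0.3, -0.35, -0.25)),
    quiet = list(count = c(0.01, -0.01, 0), viab = c(0.02, 0, -0.02))))
  rec <- dissectViability(norm)
  lab <- setNames(rec$discordance_label, rec$gene_id)
  # count -2, viability -1.8, per-cell +0.2: concordant (below the +0.5 bar)
  expect_identical(lab[["conc"]], "concordant_inhibitor")
  # count hit whose per-cell viability rose by 1.2
  expect_identical(lab[["resist"]], "viability_up_resistant")
  expect_identical(lab[["quiet"]], "neutral")
  expect_gt(rec$log2fc_viability_per_cell[rec$gene_id == "resist"], 0.5)

  # count hit with a flat viability readout on a noisy viability assay:
  # neither the viability decrease nor the per-cell rise is significant,
  # so the gene is a count-only inhibitor
  noisy <- dissectFixture(
    list(countOnly = list(count = c(-1.7, -1.75, -1.65),
                          viab = c(-0.3, -0.35, -0.25))),
    ctrlViabShift = c(-2, 2, 0, 1.4, -1.4, 0.7, -0.7, 0))
  recN <- dissectViability(noisy)
  expect_identical(recN$discordance_label[recN$gene_id == "countOnly"],
                   "count_only_inhibitor")
  expect_true(recN$count_hit[1])
  expect_false(recN$viability_hit[1])
  expect_gt(recN$p_per_cell_up[1], 0.01)
})

test_that("zero-noise dissection recovers the planted per-cell effect", {
  cfg <- zeroNoiseConfig(nGenes = 30, seed = 16,
                         props = c(neutral = 0.5, common_essential = 0,
                                   two_d_only = 0, three_d_only = 0,
                                   selective = 0,
                                   count_down_viability_up = 0.5))
  truth <- assignEffectClasses(cfg)
  # pin one gene's per-cell effect to a known value
  eff <- truthEffects(truth)
  target <- names(truthClasses(truth))[
    truthClasses(truth) == "count_down_viability_up"][1]
  eff$vpc_effect[eff$gene_id == target] <- 0.8
  truth <- ScreenTruth(truthClasses(truth), eff)
  rec <- dissectViability(normalizePlates(simulateCampaign(cfg, truth)))
  got <- rec[rec$cell_line == "A549" & rec$gene_id == target, ]
  expect_equal(got$log2fc_viability_per_cell, 0.8, tolerance = 1e-9)
  expect_identical(got$discordance_label, "viability_up_resistant")
})

test_that("planted resistant genes are recalled at realistic noise", {
  cfg <- SimulationConfig(nGenes = 800, wellsPerPlate = 384, seed = 19,
                          cellLines2d = "A549", cellLines3d = character(0),
                          classProportions = c(
                            neutral = 0.95, common_essential = 0,
                            two_d_only = 0, three_d_only = 0, selective = 0,
                            count_down_viability_up = 0.05))
  truth <- assignEffectClasses(cfg)
  layout <- data.frame(cell_line = "A549",
                       readout = c("count2d", "viability2d"))
  rec <- dissectViability(normalizePlates(simulateCampaign(cfg, truth,
                                                           layout)))
  planted <- names(truthClasses(truth))[
    truthClasses(truth) == "count_down_viability_up"]
  recall <- mean(rec$discordance_label[match(planted, rec$gene_id)] ==
                   "viability_up_resistant")
  expect_gte(recall, 0.9)
})

test_that("resistant labels are calibrated under the all-neutral null", {
  cfg <- SimulationConfig(nGenes = 700, wellsPerPlate = 384, seed = 26,
                          cellLines2d = "A549", cellLines3d = character(0),
                          classProportions = c(
                            neutral = 1, common_essential = 0,
                            two_d_only = 0, three_d_only = 0, selective = 0,
                            count_down_viability_up = 0))
  layout <- data.frame(cell_line = "A549",
                       readout = c("count2d", "viability2d"))
  rec <- dissectViability(normalizePlates(simulateCampaign(cfg,
                                                           layout = layout)))
  expect_lte(mean(rec$discordance_label == "viability_up_resistant"), 0.01)
})

test_that("a global viability rescaling leaves count-hit calls unchanged", {
  cfg <- SimulationConfig(nGenes = 60, wellsPerPlate = 96, seed = 33)
  raw <- simulateCampaign(cfg)
  rec1 <- dissectViability(normalizePlates(raw))
  w <- wellData(raw)
  w$raw_value[w$readout == "viability2d"] <-
    4 * w$raw_value[w$readout == "viability2d"]
  rec2 <- dissectViability(normalizePlates(RawScreen(w)))
  expect_identical(rec1$count_hit, rec2$count_hit)
  # per-plate normalization also absorbs the rescaling entirely
  expect_equal(rec1$log2fc_viability_total, rec2$log2fc_viability_total,
               tolerance = 1e-9)
})

test_that("the discordance fraction reproduces printed ratios", {
  rec <- data.frame(count_hit = rep(TRUE, 195),
                    viability_hit = rep(c(FALSE, TRUE), c(107, 88)))
  expect_identical(discordanceFraction(rec), 55)
  rec21 <- data.frame(count_hit = rep(TRUE, 21),
                      viability_hit = rep(c(FALSE, TRUE), c(10, 11)))
  expect_identical(discordanceFraction(rec21), 48)
  allBoth <- data.frame(count_hit = TRUE, viability_hit = TRUE)
  expect_identical(discordanceFraction(allBoth), 0)
  none <- data.frame(count_hit = FALSE, viability_hit = FALSE)
  expect_true(is.na(discordanceFraction(none)))
})
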