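test_that("the 2D dichotomy applies strict mean/spread cutoffs", {
  prof <- data.frame(
    gene_id = c("common", "selective", "boundary", "weak", "noisyweak"),
    mean_2d = c(-2.5, -1.5, -2.5, -0.5, -0.9),
    sd_2d = c(0.5, 1.5, 1.0, 0.2, 1.4),
    n_screens = 3L)
  lab <- setNames(classifyDichotomy(prof)$dichotomy, prof$gene_id)
  expect_identical(lab[["common"]], "sample_independent_common")
  expect_identical(lab[["selective"]], "sample_selective")
  # sd exactly 1 fails both strict rules
  expect_identical(lab[["boundary"]], "none")
  expect_identical(lab[["weak"]], "none")
  expect_identical(lab[["noisyweak"]], "none")
  # undefined profiles fall to none with a warning
  prof$mean_2d[1] <- NA
  expect_warning(out <- classifyDichotomy(prof), "none")
  expect_identical(out$dichotomy[1], "none")
})

test_that("cross-screen profiles aggregate per-screen means", {
  tabs <- list(hitRow(c("a", "b"), fc = c(-3, -1), p = 1e-4, cell_line = "L1"),
               hitRow(c("a", "b"), fc = c(-2, 0), p = 1e-4, cell_line = "L2"))
  prof <- crossScreenProfiles(tabs)
  expect_equal(prof$mean_2d[prof$gene_id == "a"], -2.5)
  expect_equal(prof$sd_2d[prof$gene_id == "b"], sd(c(-1, 0)))
  expect_identical(prof$n_screens, c(2, 2))
  expect_true(all(c("log2fc.L1", "log2fc.L2") %in% names(prof)))
  # a gene present in one screen only has no mean/sd
  tabs[[2]] <- tabs[[2]][tabs[[2]]$gene_id != "b", ]
  prof <- crossScreenProfiles(tabs)
  expect_true(is.na(prof$mean_2d[prof$gene_id == "b"]))
})

test_that("constructed archetypes land in their four-group classes", {
  h2d <- lapply(c("L1", "L2", "L3"), function(cl) rbind(
    hitRow("commonGene", fc = -3 + 0.2 * match(cl, c("L1", "L2", "L3")),
           p = 1e-5, cell_line = cl),
    hitRow("only3d", fc = -0.1, p = 0.6, cell_line = cl),
    hitRow("only2d", fc = c(L1 = -4, L2 = -1.2, L3 = -1.1)[[cl]],
           p = 1e-5, cell_line = cl),
    hitRow("quiet", fc = 0, p = 0.5, cell_line = cl)))
  h3d <- lapply(c("L4", "L5"), function(cl) rbind(
    hitRow("commonGene", fc = -1.6, p = 1e-4, cell_line = cl,
           readout = "sphere3d"),
    hitRow("only3d", fc = -1.8, p = 1e-4, cell_line = cl,
           readout = "sphere3d"),
    hitRow("only2d", fc = 0, p = 0.8, cell_line = cl, readout = "sphere3d"),
    hitRow("quiet", fc = 0.1, p = 0.9, cell_line = cl,
           readout = "sphere3d")))
  g <- classifyFourGroups(h2d, h3d)
  lab <- setNames(g$group, g$gene_id)
  expect_identical(lab[["commonGene"]], "common_2d_3d")
  expect_identical(lab[["only3d"]], "three_d_only")
  expect_identical(lab[["only2d"]], "two_d_only")
  expect_identical(lab[["quiet"]], "none")
  # a gene hit in a single 3D screen only is selective, not 3D-only
  h3d[[1]] <- rbind(h3d[[1]], hitRow("oneline3d", fc = -2, p = 1e-4,
                                     cell_line = "L4", readout = "sphere3d"))
  h3d[[2]] <- rbind(h3d[[2]], hitRow("oneline3d", fc = -0.1, p = 0.7,
                                     cell_line = "L5", readout = "sphere3d"))
  for (i in 1:3) h2d[[i]] <- rbind(h2d[[i]], hitRow(
    "oneline3d", fc = 0, p = 0.5, cell_line = c("L1", "L2", "L3")[i]))
  g <- classifyFourGroups(h2d, h3d)
  expect_identical(g$group[g$gene_id == "oneline3d"], "selective_2d_3d")
})

test_that("zero-noise campaigns are classified exactly as planted", {
  cfg <- zeroNoiseConfig(nGenes = 250, seed = 41)
  truth <- assignEffectClasses(cfg)
  hits <- callHits(normalizePlates(simulateCampaign(cfg, truth)))
  sc <- split(hits, paste(hits$cell_line, hits$readout))
  g <- classifyFourGroups(unname(sc[grep("count2d", names(sc))]),
                          unname(sc[grep("sphere3d", names(sc))]))
  expected <- unname(plantedGroupMap[truthClasses(truth)[g$gene_id]])
  expect_identical(g$group, expected)
})

test_that("the four groups partition the hit universe", {
  cfg <- SimulationConfig(nGenes = 200, wellsPerPlate = 96, seed = 51)
  hits <- callHits(normalizePlates(simulateCampaign(cfg)))
  sc <- split(hits, paste(hits$cell_line, hits$readout))
  h2d <- unname(sc[grep("count2d", names(sc))])
  h3d <- unname(sc[grep("sphere3d", names(sc))])
  g <- classifyFourGroups(h2d, h3d)
  inGroup <- g$gene_id[g$group != "none"]
  hitAnywhere <- sort(unique(unlist(lapply(c(h2d, h3d), function(h)
    h$gene_id[h$hit_flag]))))
  # every flagged gene is in exactly one group...
  expect_true(all(hitAnywhere %in% inGroup))
  expect_identical(anyDuplicated(g$gene_id), 0L)
  # ...and unflagged genes join only via the strong-mean 2D rules
  extras <- setdiff(inGroup, hitAnywhere)
  expect_true(all(g$mean_2d[match(extras, g$gene_id)] < -1))
})

test_that("classification is invariant to screen and gene order", {
  cfg <- SimulationConfig(nGenes = 120, wellsPerPlate = 96, seed = 61)
  hits <- callHits(normalizePlates(simulateCampaign(cfg)))
  sc <- split(hits, paste(hits$cell_line, hits$readout))
  h2d <- unname(sc[grep("count2d", names(sc))])
  h3d <- unname(sc[grep("sphere3d", names(sc))])
  g1 <- classifyFourGroups(h2d, h3d)
  g2 <- classifyFourGroups(rev(h2d), rev(h3d))
  shuffled <- lapply(h2d, function(h) h[sample(nrow(h)), ])
  g3 <- classifyFourGroups(shuffled, h3d)
  expect_identical(g1, g2)
  expect_identical(g1, g3)
})

test_that("tightening thresholds never moves genes out of none", {
  cfg <- SimulationConfig(nGenes = 150, wellsPerPlate = 96, seed = 71)
  hits <- callHits(normalizePlates(simulateCampaign(cfg)))
  sc <- split(hits, paste(hits$cell_line, hits$readout))
  h2d <- unname(sc[grep("count2d", names(sc))])
  h3d <- unname(sc[grep("sphere3d", names(sc))])
  loose <- classifyFourGroups(h2d, h3d, mean2dMax = -1)
  tight <- classifyFourGroups(h2d, h3d, mean2dMax = -1.5)
  wasNone <- loose$gene_id[loose$group == "none"]
  expect_true(all(tight$group[match(wasNone, tight$gene_id)] == "none"))
})

test_that("the literal 3D-difference mode is available", {
  h2d <- lapply(c("L1", "L2"), function(cl)
    hitRow("g1", fc = 0, p = 0.9, cell_line = cl))
  h3d <- list(hitRow("g1", fc = -2.5, p = 1e-4, cell_line = "U87",
                     readout = "sphere3d"),
              hitRow("g1", fc = -0.2, p = 0.5, cell_line = "OVCAR8",
                     readout = "sphere3d"))
  # inhibition mode: not hit in both 3D screens, so selective
  g1 <- classifyFourGroups(h2d, h3d)
  expect_identical(g1$group, "selective_2d_3d")
  # difference mode: |(-2.5) - (-0.2)| > 1 with one significant screen
  g2 <- classifyFourGroups(h2d, h3d, mode = "difference")
  expect_identical(g2$group, "three_d_only")
})

test_that("group sizes add up", {
  g <- data.frame(group = rep(c("two_d_only", "three_d_only", "common_2d_3d",
                                "selective_2d_3d", "none"),
                              c(7, 16, 49, 5, 100)))
  gs <- groupSizes(g)
  expect_identical(gs$total, 77L)
  expect_identical(gs$counts[["none"]], 100L)
  empty <- groupSizes(data.frame(group = character()))
  expect_true(all(empty$counts == 0L))
  expect_identical(empty$total, 0L)
})

test_that("planted group counts are recovered exactly at zero noise", {
  cfg <- zeroNoiseConfig(nGenes = 150, seed = 81)
  truth <- assignEffectClasses(cfg)
  hits <- callHits(normalizePlates(simulateCampaign(cfg, truth)))
  sc <- split(hits, paste(hits$cell_line, hits$readout))
  g <- classifyFourGroups(unname(sc[grep("count2d", names(sc))]),
                          unname(sc[grep("sphere3d", names(sc))]))
  got <- groupSizes(g)$counts
  expectedLab <- plantedGroupMap[truthClasses(truth)]
  for (grp in names(got))
    expect_identical(got[[grp]], sum(expectedLab == grp))
})
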