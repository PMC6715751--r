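test_that("degenerate all-neutral mixture plants no effects", {
  cfg <- SimulationConfig(nGenes = 30, wellsPerPlate = 48, seed = 1,
                          classProportions = c(
                            neutral = 1, common_essential = 0,
                            two_d_only = 0, three_d_only = 0, selective = 0,
                            count_down_viability_up = 0))
  truth <- assignEffectClasses(cfg)
  expect_true(all(truthClasses(truth) == "neutral"))
  eff <- truthEffects(truth)
  expect_true(all(eff$count_effect == 0))
  expect_true(all(eff$sphere_effect == 0))
  expect_true(all(eff$vpc_effect == 0))
})

test_that("generation is deterministic given the seed", {
  cfg <- SimulationConfig(nGenes = 40, wellsPerPlate = 48, seed = 99)
  t1 <- assignEffectClasses(cfg)
  t2 <- assignEffectClasses(cfg)
  expect_identical(truthClasses(t1), truthClasses(t2))
  expect_identical(truthEffects(t1), truthEffects(t2))
  r1 <- simulateCampaign(cfg, t1)
  r2 <- simulateCampaign(cfg, t2)
  expect_identical(wellData(r1), wellData(r2))
})

test_that("class draw matches an independent draw and binomial expectation", {
  props <- c(neutral = 0.9, common_essential = 0.1, two_d_only = 0,
             three_d_only = 0, selective = 0, count_down_viability_up = 0)
  cfg <- SimulationConfig(nGenes = 1000, seed = 1, classProportions = props)
  truth <- assignEffectClasses(cfg)
  nEss <- sum(truthClasses(truth) == "common_essential")
  # same generator, same seed, replayed independently of the class machinery
  set.seed(1)
  oracle <- sample(effectClasses(), 1000, replace = TRUE,
                   prob = props[effectClasses()])
  expect_identical(nEss, sum(oracle == "common_essential"))
  # 99.9% binomial interval around 1000 * 0.1
  expect_gte(nEss, qbinom(0.0005, 1000, 0.1))
  expect_lte(nEss, qbinom(0.9995, 1000, 0.1))
})

test_that("planted effects satisfy the class invariants", {
  for (seed in 1:4) {
    cfg <- zeroNoiseConfig(nGenes = 120, seed = seed)
    truth <- assignEffectClasses(cfg)
    cls <- truthClasses(truth)
    eff <- truthEffects(truth)
    e2d <- eff[eff$cell_line %in% cfg@cellLines2d, ]
    e3d <- eff[eff$cell_line %in% cfg@cellLines3d, ]
    pick <- function(d, class) d[cls[d$gene_id] == class, ]
    expect_true(all(pick(eff, "neutral")$count_effect == 0))
    expect_true(all(pick(e2d, "common_essential")$count_effect <= -2))
    expect_true(all(pick(e3d, "common_essential")$sphere_effect <= -1))
    expect_true(all(pick(e2d, "two_d_only")$count_effect <= -1))
    expect_true(all(pick(eff, "two_d_only")$sphere_effect == 0))
    expect_true(all(pick(e3d, "three_d_only")$sphere_effect <= -1))
    expect_true(all(pick(eff, "three_d_only")$count_effect == 0))
    cdv <- pick(e2d, "count_down_viability_up")
    expect_true(all(cdv$count_effect <= -1))
    expect_true(all(cdv$vpc_effect >= 0.5))
    # selective: strong effect in exactly one (line, condition) slot
    sel <- names(cls)[cls == "selective"]
    for (g in sel) {
      ge <- eff[eff$gene_id == g, ]
      nSlots <- sum(ge$count_effect[ge$cell_line %in% cfg@cellLines2d] != 0) +
        sum(ge$sphere_effect[ge$cell_line %in% cfg@cellLines3d] != 0)
      expect_identical(nSlots, 1L)
    }
  }
})

test_that("zero-noise raw values equal baseline times 2^effect", {
  cfg <- zeroNoiseConfig(nGenes = 20, seed = 2,
                         props = c(neutral = 0.5, common_essential = 0,
                                   two_d_only = 0.5, three_d_only = 0,
                                   selective = 0,
                                   count_down_viability_up = 0))
  truth <- assignEffectClasses(cfg)
  raw <- simulateCampaign(cfg, truth)
  w <- wellData(raw)
  cnt <- w[w$readout == "count2d", ]
  neutral <- names(truthClasses(truth))[truthClasses(truth) == "neutral"]
  expect_true(all(cnt$raw_value[cnt$gene_id %in% neutral] ==
                    cfg@baselineCount))
  # a planted log2 effect of e gives exactly baseline * 2^e
  eff <- truthEffects(truth)
  key <- paste(cnt$gene_id, cnt$cell_line)
  ekey <- paste(eff$gene_id, eff$cell_line)
  planted <- eff$count_effect[match(key, ekey)]
  lib <- !is.na(planted)
  expect_equal(cnt$raw_value[lib], cfg@baselineCount * 2^planted[lib],
               tolerance = 1e-12)
  # siNC at baseline, siPLK1 shifted by the positive-control effect
  expect_true(all(cnt$raw_value[cnt$gene_id == "siNC"] == cfg@baselineCount))
  expect_equal(unique(cnt$raw_value[cnt$gene_id == "siPLK1"]),
               cfg@baselineCount * 2^cfg@positiveControlEffect)
})

test_that("log2-scale noise has the configured spread on siNC wells", {
  cfg <- SimulationConfig(nGenes = 500, wellsPerPlate = 48, nSiNC = 40,
                          nSiPLK1 = 2, noiseSd2d = 0.2, seed = 10)
  raw <- simulateCampaign(cfg, layout = data.frame(cell_line = "A549",
                                                   readout = "count2d"))
  w <- wellData(raw)
  nc <- w$raw_value[w$gene_id == "siNC"]
  expect_gt(length(nc), 10000)
  s <- sd(log2(nc / cfg@baselineCount))
  expect_gte(s, 0.19)
  expect_lte(s, 0.21)
})

test_that("replicate means are unbiased for the planted effects", {
  cfg <- SimulationConfig(nGenes = 10, wellsPerPlate = 34, nReplicates = 100,
                          seed = 6,
                          classProportions = c(
                            neutral = 0.3, common_essential = 0.4,
                            two_d_only = 0.3, three_d_only = 0,
                            selective = 0, count_down_viability_up = 0))
  truth <- assignEffectClasses(cfg)
  raw <- simulateCampaign(cfg, truth,
                          layout = data.frame(cell_line = "A549",
                                              readout = "count2d"))
  norm <- normalizePlates(raw)
  v <- wellData(norm)
  lib <- v[!(v$gene_id %in% c("siNC", "siPLK1")), ]
  means <- tapply(lib$log2fc, lib$gene_id, mean)
  eff <- truthEffects(truth)
  planted <- eff$count_effect[eff$cell_line == "A549"][
    match(names(means), eff$gene_id[eff$cell_line == "A549"])]
  # s.e. of the mean plus the control-center error
  se <- cfg@noiseSd2d * sqrt(1 / 100 + 1 / (16 * 100))
  expect_true(all(abs(means - planted) < 3 * se))
})

test_that("siPLK1 wells fall below siNC whenever the control effect is negative", {
  cfg <- SimulationConfig(nGenes = 50, wellsPerPlate = 96, seed = 3)
  raw <- simulateCampaign(cfg)
  norm <- normalizePlates(raw)
  v <- wellData(norm)
  for (s in split(v, paste(v$cell_line, v$readout))) {
    expect_lt(mean(s$log2fc[s$gene_id == "siPLK1"]),
              mean(s$log2fc[s$gene_id == "siNC"]))
  }
})

test_that("plate layout places genes sequentially with controls everywhere", {
  cfg <- SimulationConfig(nGenes = 100, wellsPerPlate = 48, seed = 5)
  raw <- simulateCampaign(cfg, layout = data.frame(cell_line = "A549",
                                                   readout = "count2d"))
  w <- wellData(raw)
  w1 <- w[w$replicate == 1L, ]
  perPlate <- split(w1, w1$plate)
  expect_length(perPlate, ceiling(100 / (48 - 16 - 8)))
  for (p in perPlate) {
    expect_identical(sum(p$gene_id == "siNC"), cfg@nSiNC)
    expect_identical(sum(p$gene_id == "siPLK1"), cfg@nSiPLK1)
  }
  libGenes <- w1$gene_id[!(w1$gene_id %in% c("siNC", "siPLK1"))]
  expect_identical(libGenes, sort(libGenes))
})

test_that("requesting a screen outside the configured lines errors", {
  cfg <- SimulationConfig(nGenes = 10, wellsPerPlate = 48, seed = 1)
  expect_error(
    simulateCampaign(cfg, layout = data.frame(cell_line = "OVCAR8",
                                              readout = "count2d")),
    "not in the config")
  expect_error(
    simulateCampaign(cfg, layout = data.frame(cell_line = "A549",
                                              readout = "sphere3d")),
    "not in the config")
})

test_that("invalid configurations are rejected", {
  expect_error(SimulationConfig(nGenes = 10, classProportions = c(
    neutral = 0.7, common_essential = 0.2, two_d_only = 0, three_d_only = 0,
    selective = 0, count_down_viability_up = 0)), "sum to 1")
  expect_error(SimulationConfig(nGenes = 10, noiseSd2d = -1), ">= 0")
  expect_error(SimulationConfig(nGenes = 10, nSiNC = 4), "siNC")
})

test_that("synthetic gene sets are coupled to their effect class", {
  cfg <- zeroNoiseConfig(nGenes = 200, seed = 8)
  truth <- assignEffectClasses(cfg)
  sets <- simulateGeneSets(truth, coupling = 0.8, seed = 2)
  expect_s4_class(sets, "GeneSetCollection")
  cls <- truthClasses(truth)
  desc <- setDescriptions(sets)
  coupled <- grep("coupled to", desc, value = TRUE)
  expect_gt(length(coupled), 0)
  for (nm in names(coupled)) {
    class <- sub(".*coupled to ", "", coupled[nm])
    members <- geneSets(sets)[[nm]]
    frac <- mean(cls[members] == class)
    # well above the library-wide prevalence of any single class
    expect_gt(frac, 2 * mean(cls == class))
  }
})
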