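# Builders for in-code fixtures; no data files.

# Noise-free campaign config: planted effects propagate exactly.
zeroNoiseConfig <- function(nGenes = 60, seed = 1, props = NULL, ...) {
  if (is.null(props))
    props <- c(neutral = 0.4, common_essential = 0.15, two_d_only = 0.15,
               three_d_only = 0.15, selective = 0.1,
               count_down_viability_up = 0.05)
  SimulationConfig(nGenes = nGenes, wellsPerPlate = 96,
                   noiseSd2d = 0, noiseSd3d = 0, spherePoisson = FALSE,
                   classProportions = props, seed = seed, ...)
}

# Expected four-group label of each planted class under zero noise with the
# study geometry (3 x 2D count lines, 2 x 3D lines).
plantedGroupMap <- c(
  neutral = "none",
  common_essential = "common_2d_3d",
  two_d_only = "two_d_only",
  three_d_only = "three_d_only",
  selective = "selective_2d_3d",
  count_down_viability_up = "selective_2d_3d")

# Hand-made raw plate: 8 siNC wells at raw 1000, 2 siPLK1, plus custom genes.
tinyRawPlate <- function(geneValues, cell_line = "A549", readout = "count2d",
                         plate = "P001", replicate = 1L,
                         sincValues = rep(1000, 8),
                         plkValues = c(250, 250)) {
  ids <- c(names(geneValues), rep("siNC", length(sincValues)),
           rep("siPLK1", length(plkValues)))
  data.frame(cell_line = cell_line, readout = readout, plate = plate,
             well = sprintf("W%02d", seq_along(ids)), gene_id = ids,
             replicate = replicate,
             raw_value = c(unname(geneValues), sincValues, plkValues),
             stringsAsFactors = FALSE)
}

# Normalized screen assembled directly from per-gene replicate log2fc values
# and a shared plate siNC pool (one well per replicate value).
normFromValues <- function(geneValues, ctrlValues,
                           cell_line = "A549", readout = "count2d",
                           plate = "P001") {
  rows <- list()
  wi <- 0L
  for (g in names(geneValues)) {
    v <- geneValues[[g]]
    wi <- wi + 1L
    rows[[g]] <- data.frame(cell_line = cell_line, readout = readout,
                            plate = plate, well = sprintf("W%03d", wi),
                            gene_id = g, replicate = seq_along(v),
                            log2fc = v, stringsAsFactors = FALSE)
  }
  nc <- lapply(seq_along(ctrlValues), function(i) {
    data.frame(cell_line = cell_line, readout = readout, plate = plate,
               well = sprintf("NC%03d", i), gene_id = "siNC", replicate = 1L,
               log2fc = ctrlValues[i], stringsAsFactors = FALSE)
  })
  methods::new("NormalizedScreen",
               values = do.call(rbind, c(rows, nc)))
}

# Minimal hit table row(s) for classification tests.
hitRow <- function(gene, fc, p, cell_line = "X", readout = "count2d",
                   hit = p < 0.01 & fc < ifelse(readout == "viability2d",
                                                -0.6, -1)) {
  data.frame(cell_line = cell_line, readout = readout, gene_id = gene,
             log2fc_mean = fc, log2fc_sd = 0.1, n_replicates = 3L,
             p_value = p, hit_flag = hit, stringsAsFactors = FALSE)
}
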