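## Replicate aggregation, one-sided significance versus negative controls,
## fold-change thresholds, and screen comparison.

## pooled-variance two-sample t, lower/upper tail; closed form so the
## zero-variance degenerate case (noise-free simulations) stays defined:
## with no spread, any mean difference is taken as infinitely significant in
## its direction, and no difference gives p = 0.5.
.twoSampleP <- function(m1, s1sq, n1, m2, s2sq, n2,
                        alternative = "less", pooled = TRUE) {
  if (pooled) {
    df <- n1 + n2 - 2
    spsq <- ((n1 - 1) * s1sq + (n2 - 1) * s2sq) / df
    se <- sqrt(spsq * (1 / n1 + 1 / n2))
  } else {
    a <- s1sq / n1; b <- s2sq / n2
    se <- sqrt(a + b)
    df <- if (se > 0) (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1)) else n1 + n2 - 2
  }
  d <- m1 - m2
  if (se == 0) {
    p <- if (d == 0) 0.5 else if (d < 0) 0 else 1
    return(if (alternative == "less") p else 1 - p)
  }
  stats::pt(d / se, df, lower.tail = (alternative == "less"))
}

#' One-sided two-sample Student's t-test
#'
#' Pooled-variance two-sample t statistic with a one-sided p-value; the
#' default alternative \code{"less"} gives the lower-tail probability (first
#' group's mean below the second's), the direction in which inhibitory siRNA
#' hits are tested. Welch's unequal-variance form is available with
#' \code{pooled = FALSE}.
#'
#' @param x,y numeric vectors (e.g. a gene's replicate log2 fold changes and
#'   the siNC log2 fold changes of its plate). Each needs >= 2 values;
#'   otherwise NA is returned with a warning.
#' @param alternative \code{"less"} (default) or \code{"greater"}.
#' @param pooled use the pooled-variance Student form (default TRUE).
#' @return The one-sided p-value.
#' @export
#' @examples
#' oneSidedTTest(c(-1.2, -1.0, -1.1), c(0.0, 0.1, -0.1))
oneSidedTTest <- function(x, y, alternative = c("less", "greater"),
                          pooled = TRUE) {
  alternative <- match.arg(alternative)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L) {
    warning("t-test requires >= 2 values per group; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  .twoSampleP(mean(x), stats::var(x), length(x),
              mean(y), stats::var(y), length(y),
              alternative = alternative, pooled = pooled)
}

#' Call hits from a normalized screen
#'
#' Aggregates replicate log2 fold changes per gene within each
#' (cell line, readout) screen, tests each gene for a significant decrease
#' against the siNC wells of its own plate with a one-sided pooled-variance
#' t-test, and flags hits whose mean log2 fold change falls below the
#' readout-specific threshold with p below the p threshold (both strict).
#' Records are sorted by ascending mean log2 fold change (strongest
#' inhibition first).
#'
#' @param normalized a \linkS4class{NormalizedScreen}.
#' @param thresholds a \linkS4class{HitThresholds} (default [hitThresholds()]).
#' @param adjust p-value adjustment across genes within a screen:
#'   \code{"none"} (default, raw p as in threshold-based screening practice)
#'   or \code{"BH"} (Benjamini-Hochberg).
#' @param pooled pooled-variance Student t (default) or Welch.
#' @return data.frame with one row per (cell_line, readout, gene) and columns
#'   \code{cell_line}, \code{readout}, \code{gene_id}, \code{log2fc_mean},
#'   \code{log2fc_sd}, \code{n_replicates}, \code{p_value}, \code{hit_flag}.
#' @export
#' @examples
#' cfg <- SimulationConfig(nGenes = 40, wellsPerPlate = 64, seed = 2)
#' hits <- callHits(normalizePlates(simulateCampaign(cfg)))
#' head(hits)
callHits <- function(normalized, thresholds = hitThresholds(),
                     adjust = c("none", "BH"), pooled = TRUE) {
  stopifnot(is(normalized, "NormalizedScreen"), is(thresholds, "HitThresholds"))
  adjust <- match.arg(adjust)
  v <- wellData(normalized)
  screens <- .splitBy(v, c("cell_line", "readout"))
  res <- lapply(screens, function(s) {
    isNC <- s$gene_id == "siNC"
    ## control pool statistics per plate, reused by all genes of the plate
    ctrlStats <- lapply(split(s$log2fc[isNC], s$plate[isNC]), function(cv) {
      list(m = mean(cv), v = stats::var(cv), n = length(cv))
    })
    lib <- s[!(s$gene_id %in% .CONTROLS), ]
    perGene <- split(lib[c("log2fc", "plate")], lib$gene_id)
    rows <- lapply(names(perGene), function(g) {
      gv <- perGene[[g]]$log2fc
      plates <- unique(perGene[[g]]$plate)
      p <- if (length(gv) < 2L) {
        warning(sprintf("gene %s has fewer than 2 replicates; p set to NA", g),
                call. = FALSE)
        NA_real_
      } else {
        cs <- ctrlStats[[plates[1]]]
        if (length(plates) > 1L) {
          cv <- s$log2fc[isNC & s$plate %in% plates]
          cs <- list(m = mean(cv), v = stats::var(cv), n = length(cv))
        }
        if (is.null(cs) || cs$n < 2L) NA_real_
        else .twoSampleP(mean(gv), stats::var(gv), length(gv),
                         cs$m, cs$v, cs$n, "less", pooled)
      }
      data.frame(cell_line = s$cell_line[1], readout = s$readout[1],
                 gene_id = g, log2fc_mean = mean(gv),
                 log2fc_sd = if (length(gv) > 1) stats::sd(gv) else NA_real_,
                 n_replicates = length(gv), p_value = p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
    fcThr <- thresholds@fc[[out$readout[1]]]
    out$hit_flag <- !is.na(out$p_value) & out$p_value < thresholds@p &
      out$log2fc_mean < fcThr
    out[order(out$log2fc_mean), ]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Hit rate as a printed percentage
#'
#' \code{100 * nHits / nLibrary}, rounded half-up to the requested number of
#' decimals (2 by default, matching per-screen summary style; 1 decimal is
#' used for summary rows).
#'
#' @param nHits number of hits (0 <= nHits <= nLibrary).
#' @param nLibrary library size (> 0).
#' @param digits decimals to keep (default 2).
#' @return The percentage as a number.
#' @export
#' @examples
#' hitRate(195, 4786)      # 4.07
#' hitRate(302, 4786, 1)   # 6.3
hitRate <- function(nHits, nLibrary, digits = 2) {
  if (any(nLibrary <= 0)) stop("nLibrary must be positive", call. = FALSE)
  if (any(nHits < 0 | nHits > nLibrary))
    stop("nHits must lie in [0, nLibrary]", call. = FALSE)
  roundHalfUp(100 * nHits / nLibrary, digits)
}

#' Spearman rank correlation between two screens
#'
#' Pearson correlation of average-tied ranks over the genes present in both
#' screens. Returns NA with a warning when fewer than 3 genes are shared.
#'
#' @param screenA,screenB named numeric vectors of per-gene scores
#'   (e.g. log2 fold changes), named by gene.
#' @return Spearman's rho.
#' @export
#' @examples
#' a <- c(g1 = -2, g2 = 0.1, g3 = -1, g4 = 0.5)
#' spearmanCorrelation(a, a^3)
spearmanCorrelation <- function(screenA, screenB) {
  shared <- intersect(names(screenA), names(screenB))
  if (length(shared) < 3L) {
    warning("fewer than 3 shared genes; correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(screenA[shared], screenB[shared], method = "spearman",
             use = "complete.obs")
}

#' Common hits between two screens
#'
#' @param hitsA,hitsB hit tables as returned by [callHits()] (or any
#'   data.frame with \code{gene_id} and \code{hit_flag} columns).
#' @return list with the intersection \code{genes} and its \code{count}.
#' @export
commonHits <- function(hitsA, hitsB) {
  .checkColumns(hitsA, c("gene_id", "hit_flag"), "hit table A")
  .checkColumns(hitsB, c("gene_id", "hit_flag"), "hit table B")
  genes <- intersect(hitsA$gene_id[hitsA$hit_flag %in% TRUE],
                     hitsB$gene_id[hitsB$hit_flag %in% TRUE])
  list(genes = sort(genes), count = length(genes))
}
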