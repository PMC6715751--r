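## Gene-set over-representation (hypergeometric) and rank-based GSEA-style
## enrichment on per-gene scores.

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, tests whether the hit list contains at least the
#' observed number of set members by the hypergeometric upper tail
#' \code{P(X >= k)} for drawing \code{n} hits from a universe of \code{N}
#' genes of which \code{K} belong to the set. The gene ratio \code{k / K}
#' (hits in the set over set size) is the reported effect size. Two-sided
#' reporting doubles the smaller tail, capped at 1. The EASE variant
#' recomputes the upper tail after removing one observed hit (k - 1), a
#' deliberately conservative score.
#'
#' @param hitGenes character vector of hit gene labels (intersected with the
#'   universe; genes outside it are dropped with a warning).
#' @param universe character vector of all screened genes (non-empty).
#' @param sets a \linkS4class{GeneSetCollection}; members are intersected
#'   with the universe, and sets left empty are skipped.
#' @param alternative \code{"over"} (upper tail, default) or
#'   \code{"two.sided"}.
#' @param ease use the EASE k-1 adjustment (default FALSE).
#' @return data.frame with columns \code{set_name}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{gene_ratio}, \code{p_value}, sorted by
#'   ascending p then set name.
#' @export
#' @examples
#' sets <- GeneSetCollection(list(S1 = c("g1", "g2", "g3")))
#' hypergeometricEnrichment(c("g1", "g2"), paste0("g", 1:20), sets)
hypergeometricEnrichment <- function(hitGenes, universe, sets,
                                     alternative = c("over", "two.sided"),
                                     ease = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(is(sets, "GeneSetCollection"))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("universe must be non-empty", call. = FALSE)
  hitGenes <- unique(as.character(hitGenes))
  outside <- setdiff(hitGenes, universe)
  if (length(outside)) {
    warning(sprintf("%d hit gene(s) outside the universe dropped",
                    length(outside)), call. = FALSE)
    hitGenes <- intersect(hitGenes, universe)
  }
  N <- length(universe)
  n <- length(hitGenes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(geneSets(sets)[[nm]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, hitGenes))
    kEff <- if (ease) max(0L, k - 1L) else k
    pUpper <- stats::phyper(kEff - 1L, K, N - K, n, lower.tail = FALSE)
    p <- if (alternative == "over") pUpper else {
      pLower <- stats::phyper(k, K, N - K, n)
      min(1, 2 * min(pUpper, pLower))
    }
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               gene_ratio = k / K, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_name = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), gene_ratio = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out
}

## weighted Kolmogorov running-sum enrichment score. scores must be sorted
## decreasing; isMember marks set members along that order.
.gseaES <- function(scores, isMember, weight) {
  N <- length(scores)
  K <- sum(isMember)
  w <- abs(scores)^weight
  hitW <- ifelse(isMember, w, 0)
  sumW <- sum(hitW)
  if (sumW == 0) hitW <- ifelse(isMember, 1 / K, 0) else hitW <- hitW / sumW
  pHit <- cumsum(hitW)
  pMiss <- if (N > K) cumsum(!isMember) / (N - K) else numeric(N)
  run <- pHit - pMiss
  run[which.max(abs(run))]
}

#' GSEA-style rank enrichment of one gene set
#'
#' Computes the weighted Kolmogorov running-sum enrichment score (ES) of a
#' gene set along a ranked gene list: walking down the ranking, the sum
#' increments by the member's \code{|score|^weight} (normalized over
#' members) at member genes and decrements by \code{1/(N-K)} elsewhere; ES
#' is the maximum signed deviation from zero. Significance and
#' normalization come from gene-label permutation: NES is ES divided by the
#' mean |ES| of same-sign permutations, and the p-value is the fraction of
#' same-sign permutations at least as extreme. Deterministic given
#' \code{seed}.
#'
#' @param rankedScores named numeric vector of per-gene scores; genes are
#'   ranked by decreasing score. Duplicate gene names are an error.
#' @param setMembers character vector of the set's member genes; members
#'   absent from the ranking are ignored, and a set disjoint from the
#'   ranking yields a missing result with a warning.
#' @param setName label to report (default "set").
#' @param weight weighting exponent on |score| (default 1; 0 gives the
#'   classic unweighted Kolmogorov statistic).
#' @param nPerm number of gene-label permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @return one-row data.frame with columns \code{set_name}, \code{size}
#'   (members in the ranking), \code{es}, \code{nes}, \code{p_value},
#'   \code{direction} (\code{"high"}: enriched toward high scores),
#'   \code{n_permutations}.
#' @export
#' @examples
#' scores <- stats::setNames(seq(2, -2, length.out = 20), paste0("g", 1:20))
#' gseaEnrichment(scores, paste0("g", 1:4), nPerm = 200, seed = 1)
gseaEnrichment <- function(rankedScores, setMembers, setName = "set",
                           weight = 1, nPerm = 1000L, seed = 1L) {
  if (anyDuplicated(names(rankedScores)))
    stop("ranking has duplicate gene names", call. = FALSE)
  ord <- order(rankedScores, decreasing = TRUE)
  scores <- rankedScores[ord]
  isMember <- names(scores) %in% setMembers
  K <- sum(isMember)
  N <- length(scores)
  if (K == 0L || K == N) {
    warning(sprintf("set '%s' leaves no contrast with the ranking (%d of %d)",
                    setName, K, N), call. = FALSE)
    return(data.frame(set_name = setName, size = K, es = NA_real_,
                      nes = NA_real_, p_value = NA_real_,
                      direction = NA_character_,
                      n_permutations = as.integer(nPerm),
                      stringsAsFactors = FALSE))
  }
  es <- .gseaES(scores, isMember, weight)
  set.seed(seed)
  permEs <- vapply(seq_len(nPerm), function(b) {
    mask <- logical(N)
    mask[sample.int(N, K)] <- TRUE
    .gseaES(scores, mask, weight)
  }, 1)
  ## significance is judged against the same-sign half of the permutation
  ## null, the standard GSEA convention; this keeps p uniform under random
  ## rankings for either direction
  sameSign <- if (es >= 0) permEs >= 0 else permEs <= 0
  nes <- if (any(sameSign)) es / mean(abs(permEs[sameSign])) else NA_real_
  p <- if (es == 0) 1
       else if (!any(sameSign)) 1 / nPerm
       else sum(sameSign & abs(permEs) >= abs(es)) / sum(sameSign)
  data.frame(set_name = setName, size = K, es = es, nes = nes, p_value = p,
             direction = if (es >= 0) "high" else "low",
             n_permutations = as.integer(nPerm), stringsAsFactors = FALSE)
}

#' GSEA-style enrichment of a whole collection
#'
#' Runs [gseaEnrichment()] for every set of a collection against one
#' ranking, with per-set seeds derived from \code{seed} so the result is
#' deterministic and independent of set order.
#'
#' @inheritParams gseaEnrichment
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param minSize skip sets with fewer members in the ranking (default 2).
#' @return data.frame, one row per evaluated set, sorted by ascending p.
#' @export
gseaCollection <- function(rankedScores, sets, weight = 1, nPerm = 1000L,
                           seed = 1L, minSize = 2L) {
  stopifnot(is(sets, "GeneSetCollection"))
  rows <- lapply(seq_along(names(sets)), function(i) {
    nm <- names(sets)[i]
    members <- intersect(geneSets(sets)[[nm]], names(rankedScores))
    if (length(members) < minSize) return(NULL)
    gseaEnrichment(rankedScores, members, setName = nm, weight = weight,
                   nPerm = nPerm, seed = seed + i)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_name = character(), size = integer(),
                      es = numeric(), nes = numeric(), p_value = numeric(),
                      direction = character(), n_permutations = integer(),
                      stringsAsFactors = FALSE))
  out <- out[order(out$p_value, out$set_name), ]
  rownames(out) <- NULL
  out
}
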