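## Annotation-overlap (Tanimoto/Jaccard) similarity networks over hit genes.

#' Tanimoto score between two annotation term sets
#'
#' The ratio of the intersection over the union of two genes' annotation
#' term sets, \code{|A n B| / |A u B|}; defined as 0 when both sets are
#' empty. Symmetric, in [0, 1], and equal to 1 exactly for identical
#' non-empty sets.
#'
#' @param termsA,termsB character vectors of annotation terms (duplicates
#'   ignored).
#' @return The Tanimoto (Jaccard) score.
#' @export
#' @examples
#' tanimoto(c("a", "b", "c"), c("b", "c", "d"))  # 0.5
tanimoto <- function(termsA, termsB) {
  a <- unique(termsA); b <- unique(termsB)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Invert a gene-set collection to gene -> terms
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @return named list mapping each annotated gene to the character vector of
#'   set names it belongs to.
#' @export
invertGeneSets <- function(collection) {
  stopifnot(is(collection, "GeneSetCollection"))
  sets <- geneSets(collection)
  if (!length(sets)) return(list())
  pairs <- data.frame(
    term = rep(names(sets), vapply(sets, length, 1L)),
    gene = unlist(sets, use.names = FALSE), stringsAsFactors = FALSE)
  split(pairs$term, pairs$gene)
}

#' Build the pairwise Tanimoto similarity network over a gene list
#'
#' Scores every unordered pair of the given genes by the Tanimoto overlap of
#' their annotation term sets and keeps pairs scoring at least
#' \code{minScore}. Genes with no annotation participate with score 0 to all
#' partners (and so never pass a positive threshold); self-pairs are
#' excluded and each pair appears once.
#'
#' @param genes character vector of gene labels.
#' @param annotation a \linkS4class{GeneSetCollection} (inverted internally)
#'   or a named list gene -> terms.
#' @param minScore minimum Tanimoto score to keep an edge (default 0.2, a
#'   legibility default; fully configurable).
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{tanimoto_score}, sorted by decreasing score.
#' @export
#' @examples
#' ann <- list(g1 = c("t1", "t2"), g2 = c("t1", "t2"), g3 = "t3")
#' buildSimilarityNetwork(c("g1", "g2", "g3"), ann, minScore = 0.5)
buildSimilarityNetwork <- function(genes, annotation, minScore = 0.2) {
  if (is(annotation, "GeneSetCollection"))
    annotation <- invertGeneSets(annotation)
  stopifnot(is.list(annotation))
  genes <- unique(as.character(genes))
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      tanimoto_score = numeric(), stringsAsFactors = FALSE)
  if (length(genes) < 2L) return(empty)
  terms <- lapply(genes, function(g) unique(annotation[[g]]))
  n <- length(genes)
  idx <- utils::combn(n, 2L)
  scores <- vapply(seq_len(ncol(idx)), function(k) {
    tanimoto(terms[[idx[1, k]]], terms[[idx[2, k]]])
  }, 1)
  keep <- scores >= minScore
  if (!any(keep)) return(empty)
  out <- data.frame(gene_a = genes[idx[1, keep]],
                    gene_b = genes[idx[2, keep]],
                    tanimoto_score = scores[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$tanimoto_score, out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}
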