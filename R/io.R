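## Readers and writers for every table the pipeline touches. All tables are
## tab-separated UTF-8 with a single header line; GMT follows the standard
## MSigDB dialect. Gene labels are opaque case-sensitive strings except the
## control labels siNC/siPLK1, which are recognized case-insensitively.

.readTsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

.checkColumns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    .schemaStop("%s is missing column(s): %s", what,
                paste(missing, collapse = ", "))
}

#' Read and write raw screen tables
#'
#' The on-disk form of a \linkS4class{RawScreen}: a TSV with header
#' \code{cell_line readout plate well gene_id replicate raw_value}. Reading
#' validates the schema strictly — a missing column, a negative or
#' non-numeric raw value, or an unknown readout label raises a schema error
#' naming the offending row; control labels are recognized
#' case-insensitively.
#'
#' @param path file path.
#' @param x a \linkS4class{RawScreen} (for writing).
#' @return \code{readRawScreen}: a \linkS4class{RawScreen};
#'   \code{writeRawScreen}: the path, invisibly.
#' @export
readRawScreen <- function(path) {
  df <- .readTsv(path)
  .checkColumns(df, .RAW_COLUMNS, "raw screen table")
  df$raw_value <- suppressWarnings(as.numeric(df$raw_value))
  badVal <- which(!is.finite(df$raw_value) | df$raw_value < 0)
  if (length(badVal))
    .schemaStop("raw_value must be a nonnegative number (row %d)", badVal[1])
  badRd <- which(!(df$readout %in% .READOUTS))
  if (length(badRd))
    .schemaStop("unknown readout label '%s' (row %d)",
                df$readout[badRd[1]], badRd[1])
  df$replicate <- as.integer(df$replicate)
  RawScreen(df[.RAW_COLUMNS])
}

#' @rdname readRawScreen
#' @export
writeRawScreen <- function(x, path) {
  stopifnot(is(x, "RawScreen"))
  .writeTsv(wellData(x), path)
}

#' Read and write normalized screen tables
#'
#' TSV serialization of a \linkS4class{NormalizedScreen} (header
#' \code{cell_line readout plate well gene_id replicate log2fc}).
#'
#' @param path file path.
#' @param x a \linkS4class{NormalizedScreen} (for writing).
#' @return \code{readNormalizedScreen}: a \linkS4class{NormalizedScreen};
#'   \code{writeNormalizedScreen}: the path, invisibly.
#' @export
readNormalizedScreen <- function(path) {
  df <- .readTsv(path)
  .checkColumns(df, .NORM_COLUMNS, "normalized screen table")
  df$log2fc <- as.numeric(df$log2fc)
  df$replicate <- as.integer(df$replicate)
  df$gene_id <- canonicalizeControls(as.character(df$gene_id))
  new("NormalizedScreen", values = df[.NORM_COLUMNS])
}

#' @rdname readNormalizedScreen
#' @export
writeNormalizedScreen <- function(x, path) {
  stopifnot(is(x, "NormalizedScreen"))
  .writeTsv(wellData(x), path)
}

#' Read and write planted truth tables
#'
#' TSV serialization of a \linkS4class{ScreenTruth}: one row per
#' (gene, cell line) with the class label repeated per gene.
#'
#' @param path file path.
#' @param x a \linkS4class{ScreenTruth} (for writing).
#' @return \code{readScreenTruth}: a \linkS4class{ScreenTruth};
#'   \code{writeScreenTruth}: the path, invisibly.
#' @export
readScreenTruth <- function(path) {
  df <- .readTsv(path)
  need <- c("gene_id", "class_label", "cell_line", "count_effect",
            "sphere_effect", "vpc_effect")
  .checkColumns(df, need, "truth table")
  cls <- df$class_label[!duplicated(df$gene_id)]
  names(cls) <- df$gene_id[!duplicated(df$gene_id)]
  ScreenTruth(cls, df[c("gene_id", "cell_line", "count_effect",
                        "sphere_effect", "vpc_effect")])
}

#' @rdname readScreenTruth
#' @export
writeScreenTruth <- function(x, path) {
  stopifnot(is(x, "ScreenTruth"))
  eff <- truthEffects(x)
  eff$class_label <- truthClasses(x)[eff$gene_id]
  .writeTsv(eff[c("gene_id", "class_label", "cell_line", "count_effect",
                  "sphere_effect", "vpc_effect")], path)
}

#' Read a GMT gene-set file
#'
#' Standard MSigDB dialect: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member...}. Members are de-duplicated
#' within each set. A line with fewer than three fields raises a parse error
#' with its line number. An empty file yields an empty collection.
#'
#' @param path file path.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(GeneSetCollection(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short))
    stop(sprintf("GMT parse error: line %d has fewer than 3 fields", short[1]),
         call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("GMT parse error: duplicate set names", call. = FALSE)
  desc <- stats::setNames(vapply(parts, `[`, "", 2L), names(sets))
  GeneSetCollection(sets, desc)
}

#' Write a GMT gene-set file
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "GeneSetCollection"))
  lines <- vapply(names(x), function(nm) {
    paste(c(nm, setDescriptions(x)[[nm]], geneSets(x)[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write Tanimoto similarity edge lists
#'
#' TSV with columns \code{gene_a}, \code{gene_b}, \code{tanimoto_score};
#' scores are printed with 4 decimals. An empty edge set writes a header-only
#' file. This is the interchange format for network visualization tools.
#'
#' @param edges data.frame as returned by [buildSimilarityNetwork()].
#' @param path file path.
#' @return \code{readEdgeList}: a data.frame; \code{writeEdgeList}: the path,
#'   invisibly.
#' @export
writeEdgeList <- function(edges, path) {
  .checkColumns(edges, c("gene_a", "gene_b", "tanimoto_score"), "edge list")
  out <- edges[c("gene_a", "gene_b", "tanimoto_score")]
  out$tanimoto_score <- sprintf("%.4f", out$tanimoto_score)
  .writeTsv(out, path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
  df <- .readTsv(path)
  .checkColumns(df, c("gene_a", "gene_b", "tanimoto_score"), "edge list")
  df$tanimoto_score <- as.numeric(df$tanimoto_score)
  df
}

#' Read and write per-gene result tables
#'
#' TSV serialization of hit-calling results (one row per cell line, readout
#' and gene, with mean/sd log2 fold change, replicate count, p-value and hit
#' flag). Reading checks that p-values lie in [0, 1] and that a p-value is
#' only present with at least two replicates.
#'
#' @param table data.frame as returned by [callHits()].
#' @param path file path.
#' @return \code{readResultTable}: a data.frame; \code{writeResultTable}: the
#'   path, invisibly.
#' @export
writeResultTable <- function(table, path) {
  need <- c("cell_line", "readout", "gene_id", "log2fc_mean", "log2fc_sd",
            "n_replicates", "p_value", "hit_flag")
  .checkColumns(table, need, "result table")
  .writeTsv(table[need], path)
}

#' @rdname writeResultTable
#' @export
readResultTable <- function(path) {
  df <- .readTsv(path)
  need <- c("cell_line", "readout", "gene_id", "log2fc_mean", "log2fc_sd",
            "n_replicates", "p_value", "hit_flag")
  .checkColumns(df, need, "result table")
  for (col in c("log2fc_mean", "log2fc_sd", "p_value"))
    df[[col]] <- as.numeric(df[[col]])
  df$n_replicates <- as.integer(df$n_replicates)
  df$hit_flag <- as.logical(df$hit_flag)
  bad <- which(!is.na(df$p_value) & (df$p_value < 0 | df$p_value > 1))
  if (length(bad))
    .schemaStop("p_value outside [0,1] (row %d)", bad[1])
  bad <- which(!is.na(df$p_value) & df$n_replicates < 2L)
  if (length(bad))
    .schemaStop("p_value present with fewer than 2 replicates (row %d)", bad[1])
  df
}
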