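#' Round half away from zero
#'
#' Decimal rounding with ties going up in magnitude (the convention used for
#' printed screen summary percentages), unlike base \code{round}'s
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(2.5)        # 3, where round(2.5) is 2
#' roundHalfUp(4.0744, 2)  # 4.07
roundHalfUp <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

## stop() with a consistent prefix for schema problems, naming the offending
## row where known.
.schemaStop <- function(fmt, ...) stop(sprintf(paste0("schema error: ", fmt), ...),
                                       call. = FALSE)

## split a data.frame by interaction of columns, dropping unused levels
.splitBy <- function(df, cols) {
  split(df, interaction(df[cols], drop = TRUE, sep = "\r"), drop = TRUE)
}
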