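# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean of positive values
#'
#' Arithmetic mean of log10 values, back-transformed. Used for all affinity
#' summarisation: binding affinities span orders of magnitude, so summaries
#' live on the log scale.
#'
#' @param x numeric vector; non-positive and missing values are dropped.
#' @return A single number, or `NA_real_` if no usable value remains.
#' @export
geomMean <- function(x) {
  x <- x[!is.na(x) & x > 0]
  if (length(x) == 0L) return(NA_real_)
  10^mean(log10(x))
}

# Multi-valued TSV cells use "|" as the in-cell separator.
splitSet <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), "|", fixed = TRUE),
         function(v) v[nzchar(v)])
}

joinSet <- function(x) {
  vapply(x, function(v) paste(sort(unique(v)), collapse = "|"), character(1))
}

# Structured logging to stderr; quiet by default in tests via option.
dfiLog <- function(..., level = "INFO") {
  if (isTRUE(getOption("dfinet.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[dfinet %s] %s", level, paste0(...)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic ordering helper: order a data.frame by the given columns.
orderBy <- function(df, cols, decreasing = FALSE) {
  if (nrow(df) == 0L) return(df)
  ord <- do.call(order, c(unname(as.list(df[cols])),
                          list(method = "radix", decreasing = decreasing)))
  df[ord, , drop = FALSE]
}

emptyDf <- function(...) {
  spec <- list(...)
  as.data.frame(lapply(spec, function(type) vector(type, 0L)),
                stringsAsFactors = FALSE)
}

rowsDf <- function(df) if (is.null(df)) 0L else nrow(df)
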