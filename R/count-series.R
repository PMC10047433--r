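#' @include ginar-model.R
NULL

#' @rdname counts
#' @export
setMethod("counts", "CountSeries", function(object) object@values)

#' @rdname ginarModel
#' @export
setMethod("ginarModel", "CountSeries", function(object) object@model)

setMethod("show", "CountSeries", function(object) {
  cat(sprintf("CountSeries of length %d (mean %.4f)\n",
              length(object@values), mean(object@values)))
  if (!is.null(object@model))
    cat(sprintf("  simulated from GINAR(1) p = %g, rho = %g%s\n",
                geomParam(object@model), thinParam(object@model),
                if (is.null(object@seed)) ""
                else sprintf(", seed %d", object@seed)))
  utils::str(object@values)
  invisible(NULL)
})

#' Read and write count series
#'
#' Two plain-text layouts are supported: one non-negative integer per line,
#' or a single-column CSV with header \code{count}. The reader detects the
#' header; each writer mirrors the corresponding reader.
#'
#' @param path file path.
#' @param series a [CountSeries-class] or bare integer vector.
#' @param format \code{"plain"} (one value per line) or \code{"csv"}.
#' @return \code{readCountSeries} returns a [CountSeries-class];
#'   \code{writeCountSeries} returns \code{path} invisibly.
#' @export
readCountSeries <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) && identical(tolower(lines[1L]), "count"))
    lines <- lines[-1L]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals) || any(vals < 0) || any(vals != floor(vals)))
    stop("file must contain one non-negative integer per line ",
         "(optionally headed 'count')")
  new("CountSeries", values = as.integer(vals), model = NULL, seed = NULL)
}

#' @rdname readCountSeries
#' @export
writeCountSeries <- function(series, path, format = c("plain", "csv")) {
  format <- match.arg(format)
  x <- if (is(series, "CountSeries")) series@values else as.integer(series)
  lines <- as.character(x)
  if (format == "csv") lines <- c("count", lines)
  writeLines(lines, path)
  invisible(path)
}
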