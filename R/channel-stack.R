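#' Multi-channel 2D image stack
#'
#' A named collection of co-registered 2D intensity planes (one matrix per
#' fluorescence channel), the in-memory form of a multi-page TIFF. Pixel
#' coordinates are row-major and 0-based throughout the package: a centroid
#' `(y, x)` refers to matrix element `[y + 1, x + 1]`.
#'
#' @param ... named numeric matrices (e.g. `DAPI = m1, YFP = m2`), or a
#'   single named list of matrices.
#' @return object of class `channel_stack` (a named list of matrices).
#' @export
channel_stack <- function(...) {
  planes <- list(...)
  if (length(planes) == 1L && is.list(planes[[1]]) &&
      !is.matrix(planes[[1]])) planes <- planes[[1]]
  if (length(planes) == 0L || is.null(names(planes)) ||
      any(names(planes) == ""))
    stop("channel_stack needs named planes")
  dims <- lapply(planes, dim)
  if (!all(vapply(planes, is.matrix, logical(1))))
    stop("all planes must be 2D matrices")
  if (length(unique(dims)) != 1L)
    stop("all planes must have identical dimensions")
  if (any(vapply(planes, function(p) any(p < 0 | !is.finite(p)), logical(1))))
    stop("plane intensities must be finite and >= 0")
  structure(planes, class = "channel_stack")
}

## Fetch a plane by name, with a clear error when the channel is absent.
get_plane <- function(stack, name) {
  if (!name %in% names(stack))
    stop("channel '", name, "' missing from stack (has: ",
         paste(names(stack), collapse = ", "), ")")
  stack[[name]]
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x[[1]])
  cat("channel_stack:", paste(names(x), collapse = ", "),
      sprintf("(%d x %d px)\n", d[1], d[2]))
  invisible(x)
}
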