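#' Derive a child seed from a base seed
#'
#' All randomness in the package flows from explicit integer seeds. Stage- or
#' iteration-specific seeds are derived from one base seed with a fixed
#' integer hash so that no two stages share a stream and nothing touches the
#' global RNG state outside [withr::with_seed()] scopes.
#'
#' @param seed integer base seed.
#' @param ... integers identifying the consumer (stage index, epoch, ...).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  for (v in ids) h <- (h * 1000003 + (as.numeric(v) %% 2147483647)) %% 2147483647
  as.integer(h)
}

#' Bilinear or nearest-neighbour resize of a 2-D array
#'
#' @param m numeric or logical matrix.
#' @param size target `(rows, cols)`.
#' @param method "bilinear" for intensity images, "nearest" for masks
#'   (keeps masks binary).
#' @return matrix of dimension `size` (logical if the input was logical).
#' @export
resize2d <- function(m, size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(length(size) == 2, all(size >= 1))
  was_logical <- is.logical(m)
  if (all(dim(m) == size)) return(m)
  out <- EBImage::resize(matrix(as.numeric(m), nrow(m), ncol(m)),
                         w = size[1], h = size[2],
                         filter = if (method == "bilinear") "bilinear" else "none")
  out <- matrix(out, size[1], size[2])
  if (was_logical) out > 0.5 else out
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  if (max(lab) == 0) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0])
  matrix(lab == which.max(counts), nrow(mask), ncol(mask))
}

fill_holes <- function(mask) {
  f <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  matrix(f > 0.5, nrow(mask), ncol(mask))
}

#' @keywords internal
stop_fm <- function(...) stop(sprintf(...), call. = FALSE)
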