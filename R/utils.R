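# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(...) {
  stop(structure(class = c("pitchspace_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_malformed <- function(...) {
  stop(structure(class = c("pitchspace_malformed_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == trunc(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Polygon area by the shoelace formula
#'
#' @param xy two-column matrix of vertices in order (open ring).
#' @return Absolute enclosed area.
#' @noRd
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Convex-hull area of a point cloud
#'
#' Area of the convex hull of the rows of `xy`. Degenerate clouds
#' (fewer than three distinct non-collinear points) get area 0 and a
#' `degenerate` attribute.
#'
#' @param xy numeric matrix with columns x, y (meters).
#' @return Scalar area in square meters; attribute `degenerate` is TRUE
#'   when the points do not span a 2-D region.
#' @export
convex_hull_area <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2L)
  keep <- stats::complete.cases(xy)
  xy <- xy[keep, , drop = FALSE]
  if (nrow(xy) < 3L) return(structure(0, degenerate = TRUE))
  h <- grDevices::chull(xy[, 1L], xy[, 2L])
  if (length(h) < 3L) return(structure(0, degenerate = TRUE))
  a <- shoelace_area(xy[h, , drop = FALSE])
  if (a < 1e-9) return(structure(0, degenerate = TRUE))  # collinear cloud
  structure(a, degenerate = FALSE)
}

# Sample coefficient of variation, percent. Zero (or non-finite) mean is a
# flagged undefined value: NA_real_ with attribute, not an error.
#' Coefficient of variation (percent)
#'
#' `100 * sd(x) / mean(x)` with the sample standard deviation. A zero mean
#' makes the ratio undefined; the function then returns `NA` flagged with
#' attribute `undefined = TRUE` rather than raising an error, so downstream
#' tables can carry the value as missing.
#'
#' @param x numeric vector, `length(x) >= 2`.
#' @return Percent CV, or flagged `NA` when the mean is zero.
#' @examples
#' cv_percent(c(1, 2, 3))  # sd 1, mean 2 -> 50
#' @export
cv_percent <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop_usage("cv_percent needs at least 2 values")
  m <- mean(x)
  if (!is.finite(m) || m == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  100 * stats::sd(x) / m
}

# Deterministic local RNG: evaluate `expr` under a seed without disturbing
# the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
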