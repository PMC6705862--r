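#' Pitch specification
#'
#' Dimensions of the playing surface. Coordinates throughout the package use
#' an origin at one corner, x along the goal-to-goal (length) axis in
#' `[0, length_m]` and y along the touchline-to-touchline (width) axis in
#' `[0, width_m]`.
#'
#' @param length_m pitch length in meters (goal to goal); default 105.
#' @param width_m pitch width in meters (touchline to touchline); default 68.
#' @return An object of class `pitch_spec`.
#' @examples
#' pitch_spec()
#' pitch_spec(100, 64)
#' @export
pitch_spec <- function(length_m = 105, width_m = 68) {
  if (!is_scalar_num(length_m) || length_m <= 0)
    stop_usage("pitch length_m must be a positive number")
  if (!is_scalar_num(width_m) || width_m <= 0)
    stop_usage("pitch width_m must be a positive number")
  structure(list(length_m = as.numeric(length_m),
                 width_m = as.numeric(width_m)),
            class = "pitch_spec")
}

#' @export
print.pitch_spec <- function(x, ...) {
  cat(sprintf("<pitch_spec> %g x %g m (length x width)\n",
              x$length_m, x$width_m))
  invisible(x)
}

#' @export
format.pitch_spec <- function(x, ...) sprintf("%gx%g", x$length_m, x$width_m)
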