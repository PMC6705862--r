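feature_names <- c("duration_s", "ball_distance_m", "ball_speed_mean_kmh",
                   "ball_speed_cv_pct", "ball_speed_apen_au",
                   "ball_lw_ratio_au", "eps_mean_m2", "eps_cv_pct",
                   "game_length_mean_m", "game_length_cv_pct",
                   "game_width_mean_m", "game_width_cv_pct",
                   "deepest_location_m", "offensive_space_m2",
                   "n_opponents_in_space")

#' Names of the fifteen possession-level variables
#'
#' @return Character vector of the feature column names produced by
#'   [summarize_possession()].
#' @export
possession_feature_names <- function() feature_names

ball_slice <- function(seq) seq$tracking$ball_xy

#' Ball distance covered
#'
#' Sum of Euclidean frame-to-frame ball displacements over the possession.
#'
#' @param seq a `possession` (at least 2 frames).
#' @return Meters.
#' @export
ball_distance <- function(seq) {
  b <- ball_slice(seq)
  if (nrow(b) < 2L) stop_usage("ball_distance needs at least 2 frames")
  sum(sqrt(rowSums(diff(b)^2)))
}

#' Ball speed series
#'
#' Per-transition ball speed: displacement times the sampling rate, converted
#' to km/h. An optional centred moving average (odd window) smooths the
#' series; the default is the raw differences. The mean of this series is the
#' reported possession ball speed.
#'
#' @param seq a `possession`.
#' @param smoothing_window odd window length in frames; 1 (default) = none.
#' @return Numeric vector of length `frames - 1`, km/h.
#' @export
ball_speed_series <- function(seq, smoothing_window = 1L) {
  b <- ball_slice(seq)
  if (nrow(b) < 2L) stop_usage("ball_speed_series needs at least 2 frames")
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stop_usage("smoothing_window must be odd and >= 1")
  v <- sqrt(rowSums(diff(b)^2)) * seq$tracking$sampling_rate_hz * 3.6
  if (smoothing_window > 1L) {
    if (smoothing_window > length(v))
      stop_usage("smoothing_window larger than the speed series")
    sm <- stats::filter(v, rep(1 / smoothing_window, smoothing_window),
                        sides = 2)
    v <- ifelse(is.na(sm), v, as.numeric(sm))   # keep raw values at the edges
  }
  v
}

#' Ball length/width circulation ratio
#'
#' Cumulative absolute lengthwise displacement over cumulative absolute
#' widthwise displacement of the ball path (x = pitch-length axis after
#' attack-direction normalization). Values above 1 mean predominantly
#' lengthwise (direct) circulation. A path with zero widthwise movement has
#' an undefined ratio and returns `NA` flagged with `undefined = TRUE`.
#'
#' @param seq a `possession`.
#' @return Dimensionless ratio, or flagged `NA`.
#' @export
lw_ratio <- function(seq) {
  b <- ball_slice(seq)
  if (nrow(b) < 2L) stop_usage("lw_ratio needs at least 2 frames")
  dl <- sum(abs(diff(b[, 1L])))
  dw <- sum(abs(diff(b[, 2L])))
  if (dw == 0) return(structure(NA_real_, undefined = TRUE))
  dl / dw
}

team_xy_at <- function(seq, team, idx) {
  ids <- player_ids(seq$tracking, team, role = "outfield")
  t(seq$tracking$player_xy[idx, , ids])
}

opponent_of <- function(seq) {
  setdiff(unique(seq$tracking$roster$team), seq$team)[1L]
}

#' Effective playing space series
#'
#' Per-frame convex-hull area (m^2) of the in-possession team's ten outfield
#' players. Degenerate frames (collinear players) get area 0.
#'
#' @param seq a `possession`.
#' @param team team whose hull is computed; defaults to the possession team.
#' @return Numeric vector, one area per frame; attribute `degenerate` flags
#'   frames whose points did not span a 2-D region.
#' @export
eps_series <- function(seq, team = seq$team) {
  ids <- player_ids(seq$tracking, team, role = "outfield")
  xy <- seq$tracking$player_xy[, , ids, drop = FALSE]
  n <- dim(xy)[1L]
  out <- numeric(n); deg <- logical(n)
  for (i in seq_len(n)) {
    a <- convex_hull_area(t(xy[i, , ]))
    out[i] <- a
    deg[i] <- isTRUE(attr(a, "degenerate"))
  }
  structure(out, degenerate = deg)
}

#' Game length and width series
#'
#' Per-frame extents of all 20 outfield players (both teams): length is the
#' x range, width the y range.
#'
#' @param seq a `possession`.
#' @return List with numeric vectors `length` and `width` (m).
#' @export
game_bounds_series <- function(seq) {
  ids <- player_ids(seq$tracking, role = "outfield")
  x <- seq$tracking$player_xy[, 1L, ids, drop = FALSE]
  y <- seq$tracking$player_xy[, 2L, ids, drop = FALSE]
  list(length = apply(x, 1L, max) - apply(x, 1L, min),
       width = apply(y, 1L, max) - apply(y, 1L, min))
}

#' Deepest location at the end of possession
#'
#' Maximum x (pitch-length coordinate, after attack-direction normalization)
#' among the in-possession team's outfield players at the possession's end
#' frame.
#'
#' @param seq a `possession` whose tracking slice is attack-normalized.
#' @return Meters along the pitch length.
#' @export
deepest_location <- function(seq) {
  xy <- team_xy_at(seq, seq$team, dim(seq$tracking$player_xy)[1L])
  max(xy[, 1L])
}

#' Offensive available space
#'
#' Area between the deepest offensive outfield player and the opponents' goal
#' line at the end frame, taken as the full-pitch-width rectangle
#' `(length_m - deepest) * width_m`.
#'
#' @param seq a `possession` (attack-normalized).
#' @param pitch a [pitch_spec()]; defaults to the possession's pitch.
#' @return Square meters.
#' @export
offensive_available_space <- function(seq, pitch = seq$tracking$pitch) {
  (pitch$length_m - deepest_location(seq)) * pitch$width_m
}

#' Opponents inside the offensive available space
#'
#' Number of opposing outfield players strictly beyond the deepest attacker
#' at the end frame; the opposing goalkeeper is excluded.
#'
#' @param seq a `possession` (attack-normalized).
#' @return Integer count in 0..10.
#' @export
opponents_in_space <- function(seq) {
  deep <- deepest_location(seq)
  opp <- team_xy_at(seq, opponent_of(seq), dim(seq$tracking$player_xy)[1L])
  sum(opp[, 1L] > deep)
}

#' Compute the fifteen possession variables
#'
#' Populates every possession-level variable from one included possession:
#' duration, ball path metrics (distance, mean speed, speed CV%, speed
#' approximate entropy, length/width ratio), the in-possession team's
#' effective playing space (mean, CV%), game length and width over both
#' teams (mean, CV%), and the end-of-possession metrics (deepest location,
#' offensive available space, opponents in that space). Flagged-undefined
#' ratios propagate as `NA`.
#'
#' @param seq a `possession` spanning at least `min_frames` frames and
#'   attack-normalized for its team (set `normalize = TRUE` to apply the
#'   normalization here).
#' @param entropy_params an [apen_params()] for the ball-speed entropy.
#' @param smoothing_window passed to [ball_speed_series()].
#' @param min_frames inclusion minimum; default 200.
#' @param normalize apply [normalize_attack_direction()] for the possession
#'   team first? Default FALSE (the pipeline normalizes upstream).
#' @return One-row data frame with `possession_id`-free metadata columns
#'   (`team`, `start_frame`, `end_frame`) plus the 15 feature columns.
#' @export
summarize_possession <- function(seq, entropy_params = apen_params(),
                                 smoothing_window = 1L, min_frames = 200L,
                                 normalize = FALSE) {
  stopifnot(inherits(seq, "possession"))
  nfr <- dim(seq$tracking$player_xy)[1L]
  if (nfr < min_frames)
    stop_usage("possession has ", nfr, " frames, below the ", min_frames,
               "-frame inclusion minimum")
  if (normalize)
    seq$tracking <- normalize_attack_direction(seq$tracking, seq$team)
  sp <- ball_speed_series(seq, smoothing_window)
  e <- eps_series(seq)
  gb <- game_bounds_series(seq)
  as_na <- function(v) if (isTRUE(attr(v, "undefined"))) NA_real_ else
    as.numeric(v)
  data.frame(team = seq$team, start_frame = seq$start_frame,
             end_frame = seq$end_frame,
             duration_s = seq$duration_s,
             ball_distance_m = ball_distance(seq),
             ball_speed_mean_kmh = mean(sp),
             ball_speed_cv_pct = as_na(cv_percent(sp)),
             ball_speed_apen_au = normalized_apen(sp, entropy_params,
                                                  allow_short = TRUE),
             ball_lw_ratio_au = as_na(lw_ratio(seq)),
             eps_mean_m2 = mean(e),
             eps_cv_pct = as_na(cv_percent(e)),
             game_length_mean_m = mean(gb$length),
             game_length_cv_pct = as_na(cv_percent(gb$length)),
             game_width_mean_m = mean(gb$width),
             game_width_cv_pct = as_na(cv_percent(gb$width)),
             deepest_location_m = deepest_location(seq),
             offensive_space_m2 = offensive_available_space(seq),
             n_opponents_in_space = opponents_in_space(seq),
             stringsAsFactors = FALSE)
}

#' Feature table for a set of possessions
#'
#' Applies [summarize_possession()] to each included possession and binds the
#' rows into a `possession_features` data frame.
#'
#' @param possessions list of `possession` objects (e.g. from
#'   [segment_possessions()]).
#' @param ... passed to [summarize_possession()].
#' @return A data frame of class `possession_features`, one row per
#'   possession, with a `possession_id` column.
#' @export
possession_features <- function(possessions, ...) {
  rows <- lapply(possessions, summarize_possession, ...)
  out <- do.call(rbind, rows)
  out <- cbind(possession_id = seq_len(nrow(out)), out)
  class(out) <- c("possession_features", "data.frame")
  out
}

#' @export
print.possession_features <- function(x, ...) {
  cat(sprintf("<possession_features> %d possessions x %d variables\n",
              nrow(x), length(feature_names)))
  tt <- table(x$team)
  cat("  teams:", paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "),
      "\n")
  print.data.frame(utils::head(as.data.frame(x), 4), digits = 4)
  if (nrow(x) > 4) cat("  ...", nrow(x) - 4, "more rows\n")
  invisible(x)
}
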