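#' Segmentation configuration
#'
#' Inclusion criteria for team ball-possession sequences: a minimum duration
#' (8 s, i.e. 200 frames at 25 Hz — required for reliable approximate-entropy
#' estimates on the ball-speed series) and exclusion of any sequence
#' containing a set piece. Also carries the positional-heuristic parameters
#' used by [infer_possessions_from_touches()] when no event annotations are
#' available.
#'
#' @param min_duration_s minimum possession duration in seconds; default 8.
#' @param sampling_rate_hz frames per second used to convert the duration to
#'   frames; default 25.
#' @param exclude_set_pieces drop sequences containing a set piece? Default
#'   TRUE.
#' @param control_radius_m ball-control radius (m) for the fallback heuristic.
#' @param control_frames consecutive frames of control required before a
#'   possession is declared (hysteresis).
#' @param max_gap_frames longest tolerated run of missing player positions
#'   inside a possession; longer gaps reject the sequence.
#' @return An object of class `segmentation_config` with derived field
#'   `min_frames = round(min_duration_s * sampling_rate_hz)`.
#' @examples
#' segmentation_config()$min_frames  # 200
#' @export
segmentation_config <- function(min_duration_s = 8, sampling_rate_hz = 25,
                                exclude_set_pieces = TRUE,
                                control_radius_m = 1.5, control_frames = 5,
                                max_gap_frames = 5) {
  stopifnot(is_scalar_num(min_duration_s), min_duration_s > 0,
            is_scalar_num(sampling_rate_hz), sampling_rate_hz > 0,
            is_flag(exclude_set_pieces))
  structure(list(min_duration_s = min_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 min_frames = as.integer(round(min_duration_s *
                                                 sampling_rate_hz)),
                 exclude_set_pieces = exclude_set_pieces,
                 control_radius_m = control_radius_m,
                 control_frames = as.integer(control_frames),
                 max_gap_frames = as.integer(max_gap_frames)),
            class = "segmentation_config")
}

# Subset a tracking dataset to an inclusive frame span.
slice_tracking <- function(dataset, from_frame, to_frame) {
  idx <- which(dataset$frame >= from_frame & dataset$frame <= to_frame)
  dataset$frame <- dataset$frame[idx]
  dataset$time_s <- dataset$time_s[idx]
  dataset$ball_xy <- dataset$ball_xy[idx, , drop = FALSE]
  dataset$player_xy <- dataset$player_xy[idx, , , drop = FALSE]
  dataset
}

new_possession <- function(team, start_frame, end_frame, tracking,
                           end_reason = "lost", contains_set_piece = FALSE) {
  structure(list(team = team, start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame),
                 end_reason = end_reason,
                 contains_set_piece = contains_set_piece,
                 duration_s = (end_frame - start_frame + 1) /
                   tracking$sampling_rate_hz,
                 tracking = slice_tracking(tracking, start_frame, end_frame)),
            class = "possession")
}

#' @export
print.possession <- function(x, ...) {
  cat(sprintf("<possession> team %s, frames %d..%d (%.2f s), end: %s%s\n",
              x$team, x$start_frame, x$end_frame, x$duration_s, x$end_reason,
              if (x$contains_set_piece) ", contains set piece" else ""))
  invisible(x)
}

#' End frame of a possession
#'
#' For shot-ending possessions this is the frame of the shot itself, not the
#' frame the ball later crosses the line; the adjustment is applied during
#' segmentation.
#'
#' @param seq a `possession`.
#' @return Integer frame index.
#' @export
end_frame_of <- function(seq) {
  stopifnot(inherits(seq, "possession"))
  seq$end_frame
}

#' Segment a match into included ball-possession sequences
#'
#' Pairs `possession_start` / `possession_end` events per team, applies the
#' shot rule (a possession that ends with the ball out after a shot ends at
#' the shot frame), and filters by the inclusion criteria: span at least
#' `config$min_frames` frames, no set piece in the span, and no tracking gap
#' longer than `config$max_gap_frames` among the 20 outfield players.
#'
#' @param events an `event_stream` covering the same frame range as `tracking`.
#' @param tracking a `tracking_dataset`.
#' @param config a [segmentation_config()].
#' @return List of included `possession` objects ordered by start frame, with
#'   attribute `manifest`: a data frame describing every candidate sequence
#'   (included or not) with its exclusion reason.
#' @export
segment_possessions <- function(events, tracking,
                                config = segmentation_config(
                                  sampling_rate_hz = tracking$sampling_rate_hz)) {
  stopifnot(inherits(events, "event_stream"),
            inherits(tracking, "tracking_dataset"))
  rng <- range(tracking$frame)
  if (nrow(events) && (min(events$frame) < rng[1L] ||
                       max(events$frame) > rng[2L]))
    stop_malformed("events reference frames outside the tracking range")

  starts <- events[events$kind == "possession_start", , drop = FALSE]
  rows <- list(); poss <- list()
  for (i in seq_len(nrow(starts))) {
    tm <- starts$team[i]; s <- starts$frame[i]
    ends <- events[events$kind == "possession_end" & events$team == tm &
                     events$frame >= s, , drop = FALSE]
    e <- ends$frame[1L]                       # validated: always present
    reason <- "lost"
    shot <- events$frame[events$kind == "shot" & events$team == tm &
                           events$frame >= s & events$frame <= e]
    if (length(shot)) {
      out <- events$frame[events$kind == "ball_out" &
                            events$frame > shot[1L] & events$frame <= e]
      if (length(out)) { e <- shot[1L]; reason <- "ball_out_after_shot" }
    }
    sp <- any(events$kind == "set_piece" & events$frame >= s &
                events$frame <= e)
    span <- e - s + 1L
    excl <- NA_character_
    if (span < config$min_frames) excl <- "too_short"
    else if (config$exclude_set_pieces && sp) excl <- "set_piece"
    else {
      p <- new_possession(tm, s, e, tracking, reason, sp)
      if (!possession_complete(p)) excl <- "tracking_gap"
      else poss[[length(poss) + 1L]] <- p
    }
    rows[[i]] <- data.frame(possession_id = NA_integer_, team = tm,
                            start_frame = s, end_frame = e,
                            duration_s = span / tracking$sampling_rate_hz,
                            end_reason = reason, included = is.na(excl),
                            exclusion_reason = excl, stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(possession_id = integer(), team = character(),
               start_frame = integer(), end_frame = integer(),
               duration_s = numeric(), end_reason = character(),
               included = logical(), exclusion_reason = character())
  manifest <- manifest[order(manifest$start_frame), , drop = FALSE]
  manifest$possession_id <- seq_len(nrow(manifest))
  rownames(manifest) <- NULL
  poss <- poss[order(vapply(poss, function(p) p$start_frame, integer(1)))]
  structure(poss, manifest = manifest)
}

# Every frame of the slice must carry the ball and all outfield players of
# both teams (short gaps were already interpolated at read time).
possession_complete <- function(p) {
  of <- player_ids(p$tracking, role = "outfield")
  !anyNA(p$tracking$player_xy[, , of])
}

#' Possession manifest accessor
#'
#' @param possessions result of [segment_possessions()].
#' @return Data frame `possession_id, team, start_frame, end_frame,
#'   duration_s, end_reason, included, exclusion_reason`.
#' @export
possession_manifest <- function(possessions) attr(possessions, "manifest")

#' Infer possessions from ball control (positional fallback)
#'
#' When no event annotations exist, declares a team in possession once one of
#' its outfield players is the nearest to the ball within
#' `config$control_radius_m` for at least `config$control_frames` consecutive
#' frames (hysteresis against rapid alternation). Possession ends when the
#' other team earns control the same way or when the ball stays out of the
#' pitch bounds for more than `control_frames` frames. Deterministic given
#' its input. This heuristic is a fallback; annotated events are
#' authoritative when available.
#'
#' @param tracking a `tracking_dataset`.
#' @param config a [segmentation_config()].
#' @return An `event_stream` of `possession_start` / `possession_end` (and
#'   `ball_out`) events consumable by [segment_possessions()].
#' @export
infer_possessions_from_touches <- function(tracking,
                                           config = segmentation_config(
                                             sampling_rate_hz = tracking$sampling_rate_hz)) {
  stopifnot(inherits(tracking, "tracking_dataset"))
  L <- tracking$pitch$length_m; W <- tracking$pitch$width_m
  bx <- tracking$ball_xy[, 1L]; by <- tracking$ball_xy[, 2L]
  inb <- bx >= 0 & bx <= L & by >= 0 & by <= W
  of <- player_ids(tracking, role = "outfield")
  teams <- tracking$roster$team[match(of, tracking$roster$player_id)]
  dx <- tracking$player_xy[, 1L, of] - bx
  dy <- tracking$player_xy[, 2L, of] - by
  d2 <- dx * dx + dy * dy
  nearest <- max.col(-d2, ties.method = "first")
  nd <- sqrt(d2[cbind(seq_along(nearest), nearest)])
  state <- ifelse(!inb, "out",
                  ifelse(!is.na(nd) & nd <= config$control_radius_m,
                         teams[nearest], "none"))
  r <- rle(state)
  run_end <- cumsum(r$lengths); run_start <- run_end - r$lengths + 1L
  fr <- tracking$frame

  ev_frame <- integer(); ev_kind <- character(); ev_team <- character()
  cur <- NA_character_; cur_start <- NA_integer_
  emit <- function(f, k, tm) {
    ev_frame <<- c(ev_frame, f); ev_kind <<- c(ev_kind, k)
    ev_team <<- c(ev_team, tm)
  }
  for (k in seq_along(r$values)) {
    v <- r$values[k]; len <- r$lengths[k]
    if (v %in% c("none")) next
    if (v == "out") {
      if (!is.na(cur) && len > config$control_frames) {
        emit(fr[max(run_start[k] - 1L, cur_start)], "possession_end", cur)
        emit(fr[run_start[k]], "ball_out", "")
        cur <- NA_character_
      }
    } else if (len >= config$control_frames) {
      if (is.na(cur)) {
        cur <- v; cur_start <- run_start[k]
        emit(fr[run_start[k]], "possession_start", v)
      } else if (cur != v) {
        emit(fr[run_start[k] - 1L], "possession_end", cur)
        cur <- v; cur_start <- run_start[k]
        emit(fr[run_start[k]], "possession_start", v)
      }
    }
  }
  if (!is.na(cur)) emit(fr[length(fr)], "possession_end", cur)
  o <- order(ev_frame, ev_kind != "possession_end")
  event_stream(ev_frame[o], ev_kind[o], ev_team[o])
}
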