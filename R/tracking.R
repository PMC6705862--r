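#' Tracking dataset container
#'
#' Holds per-frame 2-D positions for the ball and every rostered player at a
#' fixed sampling rate, plus the pitch specification. Player positions are a
#' `frames x 2 x players` array; the ball is a `frames x 2` matrix. Frames
#' must be strictly increasing and gapless within the dataset (one playing
#' period), every frame must carry a ball position, and `time_s` must equal
#' `frame / sampling_rate_hz`.
#'
#' Short per-player dropouts (runs of missing positions no longer than
#' `max_gap` frames) are filled by linear interpolation at construction;
#' longer gaps are kept missing and cause the enclosing possession to be
#' rejected during segmentation.
#'
#' @param frame integer vector of frame indices, strictly increasing, gapless.
#' @param ball_xy numeric `n x 2` matrix of ball positions (m), no missing rows.
#' @param player_xy numeric `n x 2 x p` array; `dimnames[[3]]` are player ids.
#' @param roster data frame with columns `player_id`, `team`, `role`
#'   (`"outfield"` or `"goalkeeper"`).
#' @param sampling_rate_hz frames per second; default 25.
#' @param pitch a [pitch_spec()].
#' @param time_s seconds from period start; defaults to `frame / rate`.
#' @param margin meters by which coordinates may exceed the pitch rectangle
#'   (the ball can leave the pitch); default 5.
#' @param max_gap longest missing-position run (frames) filled by linear
#'   interpolation; default 5.
#' @return An object of class `tracking_dataset`.
#' @export
tracking_dataset <- function(frame, ball_xy, player_xy, roster,
                             sampling_rate_hz = 25, pitch = pitch_spec(),
                             time_s = NULL, margin = 5, max_gap = 5) {
  frame <- as.integer(frame)
  n <- length(frame)
  if (n == 0L) stop_malformed("tracking dataset has no frames")
  if (n > 1L && any(diff(frame) != 1L))
    stop_malformed("frame indices must be strictly increasing and gapless")
  ball_xy <- as.matrix(ball_xy)
  if (nrow(ball_xy) != n || ncol(ball_xy) != 2L)
    stop_malformed("ball_xy must be an n x 2 matrix")
  if (anyNA(ball_xy)) {
    bad <- frame[which(!stats::complete.cases(ball_xy))[1L]]
    stop_malformed("missing ball position at frame ", bad)
  }
  if (is.null(time_s)) time_s <- frame / sampling_rate_hz
  if (any(abs(time_s - frame / sampling_rate_hz) > 1e-9))
    stop_malformed("time_s inconsistent with frame / sampling_rate_hz")
  if (!is.data.frame(roster) ||
      !all(c("player_id", "team", "role") %in% names(roster)))
    stop_usage("roster needs columns player_id, team, role")
  roster$player_id <- as.character(roster$player_id)
  roster$team <- as.character(roster$team)
  roster$role <- as.character(roster$role)
  if (!all(roster$role %in% c("outfield", "goalkeeper")))
    stop_usage("roster roles must be 'outfield' or 'goalkeeper'")
  if (anyDuplicated(roster$player_id))
    stop_usage("duplicate player ids in roster")
  if (length(dim(player_xy)) != 3L || dim(player_xy)[1L] != n ||
      dim(player_xy)[2L] != 2L)
    stop_malformed("player_xy must be an n x 2 x p array")
  ids <- dimnames(player_xy)[[3L]]
  if (is.null(ids) || !setequal(ids, roster$player_id))
    stop_malformed("player_xy ids must match the roster")
  player_xy <- player_xy[, , roster$player_id, drop = FALSE]

  player_xy <- fill_short_gaps(player_xy, max_gap)

  lo_x <- -margin; hi_x <- pitch$length_m + margin
  lo_y <- -margin; hi_y <- pitch$width_m + margin
  allx <- c(ball_xy[, 1L], player_xy[, 1L, ])
  ally <- c(ball_xy[, 2L], player_xy[, 2L, ])
  if (any(allx < lo_x | allx > hi_x, na.rm = TRUE) ||
      any(ally < lo_y | ally > hi_y, na.rm = TRUE))
    stop_malformed("coordinates outside pitch bounds plus margin (", margin,
                   " m)")

  structure(list(frame = frame, time_s = as.numeric(time_s),
                 ball_xy = unname(ball_xy), player_xy = player_xy,
                 roster = roster,
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 pitch = pitch, margin = margin),
            class = "tracking_dataset")
}

# Linear interpolation of interior missing runs no longer than max_gap,
# per player and coordinate. Longer runs and edge runs stay NA.
fill_short_gaps <- function(player_xy, max_gap) {
  if (max_gap < 1L) return(player_xy)
  n <- dim(player_xy)[1L]
  if (n < 3L) return(player_xy)
  for (p in seq_len(dim(player_xy)[3L])) {
    for (d in 1:2) {
      v <- player_xy[, d, p]
      if (!anyNA(v)) next
      r <- rle(is.na(v))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths <= max_gap)) {
        i0 <- starts[k]; i1 <- ends[k]
        if (i0 == 1L || i1 == n) next       # edge gap: cannot interpolate
        a <- v[i0 - 1L]; b <- v[i1 + 1L]
        if (is.na(a) || is.na(b)) next
        w <- seq_len(i1 - i0 + 1L) / (i1 - i0 + 2L)
        v[i0:i1] <- a + w * (b - a)
      }
      player_xy[, d, p] <- v
    }
  }
  player_xy
}

#' @export
print.tracking_dataset <- function(x, ...) {
  cat(sprintf(
    "<tracking_dataset> %d frames @ %g Hz (%.1f s), %d players + ball, pitch %s m\n",
    length(x$frame), x$sampling_rate_hz,
    length(x$frame) / x$sampling_rate_hz, nrow(x$roster), format(x$pitch)))
  tt <- table(x$roster$team)
  cat("  teams:", paste(sprintf("%s (%d)", names(tt), tt), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
summary.tracking_dataset <- function(object, ...) {
  print(object)
  cat(sprintf("  frames %d..%d, missing player positions: %d\n",
              object$frame[1L], object$frame[length(object$frame)],
              sum(is.na(object$player_xy)) / 2L))
  invisible(object)
}

#' Player ids by team and role
#'
#' @param dataset a `tracking_dataset`.
#' @param team team label; `NULL` means all teams.
#' @param role `"outfield"`, `"goalkeeper"`, or `NULL` for both.
#' @return Character vector of player ids.
#' @export
player_ids <- function(dataset, team = NULL, role = "outfield") {
  r <- dataset$roster
  if (!is.null(team)) {
    if (!team %in% r$team) stop_usage("unknown team: ", team)
    r <- r[r$team == team, , drop = FALSE]
  }
  if (!is.null(role)) r <- r[r$role %in% role, , drop = FALSE]
  r$player_id
}

tracking_columns <- c("frame", "time_s", "entity_id", "team", "role", "x", "y")

#' Read tracking data
#'
#' Reads the long-form tracking dialect: CSV with header
#' `frame,time_s,entity_id,team,role,x,y` (the ball uses `entity_id` `ball`,
#' empty team, role `ball`), or a JSON document carrying the same fields plus
#' metadata. The sampling rate is inferred from the time deltas and checked
#' against a declared rate when one is given.
#'
#' @param path file to read.
#' @param format `"csv"` or `"json"`.
#' @param pitch a [pitch_spec()] (CSV carries no metadata; JSON overrides).
#' @param sampling_rate_hz declared rate to check against, or `NULL` to accept
#'   the inferred one.
#' @param margin,max_gap see [tracking_dataset()].
#' @return A `tracking_dataset`.
#' @export
read_tracking <- function(path, format = c("csv", "json"),
                          pitch = pitch_spec(), sampling_rate_hz = NULL,
                          margin = 5, max_gap = 5) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_usage("no such file: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(frame = "integer", time_s = "numeric",
                                         entity_id = "character",
                                         team = "character",
                                         role = "character",
                                         x = "numeric", y = "numeric"))
  } else {
    doc <- jsonlite::fromJSON(path)
    if (!identical(doc$meta$format, "pitchspace-tracking"))
      stop_usage("not a pitchspace tracking JSON document: ", path)
    pitch <- pitch_spec(doc$meta$pitch$length_m, doc$meta$pitch$width_m)
    if (is.null(sampling_rate_hz)) sampling_rate_hz <- doc$meta$sampling_rate_hz
    margin <- doc$meta$margin %||% margin
    df <- as.data.frame(doc$data, stringsAsFactors = FALSE)
  }
  if (!all(tracking_columns %in% names(df)))
    stop_malformed("tracking file must carry columns ",
                   paste(tracking_columns, collapse = ","))
  if (is.unsorted(df$frame))
    stop_malformed("non-monotone frame order in ", path)
  build_tracking_from_long(df, pitch, sampling_rate_hz, margin, max_gap)
}

build_tracking_from_long <- function(df, pitch, sampling_rate_hz, margin,
                                     max_gap) {
  df$team[is.na(df$team)] <- ""
  frames <- sort(unique(df$frame))
  n <- length(frames)
  ball <- df[df$entity_id == "ball", , drop = FALSE]
  if (nrow(ball) != n || !setequal(ball$frame, frames)) {
    missing <- setdiff(frames, ball$frame)
    stop_malformed("missing ball row in frame ",
                   if (length(missing)) missing[1L] else ball$frame[duplicated(ball$frame)][1L])
  }
  ball <- ball[order(ball$frame), , drop = FALSE]

  pl <- df[df$entity_id != "ball", , drop = FALSE]
  roster <- unique(pl[, c("entity_id", "team", "role")])  # appearance order
  names(roster)[1L] <- "player_id"
  rownames(roster) <- NULL

  ids <- roster$player_id
  player_xy <- array(NA_real_, dim = c(n, 2L, length(ids)),
                     dimnames = list(NULL, c("x", "y"), ids))
  fi <- match(pl$frame, frames)
  pi <- match(pl$entity_id, ids)
  player_xy[cbind(fi, 1L, pi)] <- pl$x
  player_xy[cbind(fi, 2L, pi)] <- pl$y

  # time/rate consistency
  tt <- ball$time_s
  if (n > 1L) {
    inferred <- 1 / stats::median(diff(tt))
    if (!is.null(sampling_rate_hz) &&
        abs(inferred - sampling_rate_hz) > 1e-6 * sampling_rate_hz)
      stop_malformed(sprintf(
        "declared rate %g Hz disagrees with inferred %g Hz", sampling_rate_hz,
        inferred))
    rate <- sampling_rate_hz %||% inferred
  } else rate <- sampling_rate_hz %||% 25

  tracking_dataset(frame = frames, ball_xy = cbind(ball$x, ball$y),
                   player_xy = player_xy, roster = roster,
                   sampling_rate_hz = rate, pitch = pitch, time_s = tt,
                   margin = margin, max_gap = max_gap)
}

tracking_to_long <- function(dataset, digits = 3) {
  n <- length(dataset$frame)
  r <- dataset$roster
  p <- nrow(r)
  ball <- data.frame(frame = dataset$frame, time_s = dataset$time_s,
                     entity_id = "ball", team = "", role = "ball",
                     x = round(dataset$ball_xy[, 1L], digits),
                     y = round(dataset$ball_xy[, 2L], digits),
                     stringsAsFactors = FALSE)
  pl <- data.frame(frame = rep(dataset$frame, times = p),
                   time_s = rep(dataset$time_s, times = p),
                   entity_id = rep(r$player_id, each = n),
                   team = rep(r$team, each = n),
                   role = rep(r$role, each = n),
                   x = round(as.vector(dataset$player_xy[, 1L, ]), digits),
                   y = round(as.vector(dataset$player_xy[, 2L, ]), digits),
                   stringsAsFactors = FALSE)
  # within each frame: ball first, then players in roster order, so a
  # read-back dataset reproduces the original roster ordering
  pos <- c(rep(0L, n), rep(seq_len(p), each = n))
  out <- rbind(ball, pl)
  out <- out[order(out$frame, pos), , drop = FALSE]
  out <- out[!is.na(out$x) & !is.na(out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write tracking data
#'
#' Writes the long-form CSV or JSON dialect readable by [read_tracking()].
#' Coordinates are stored at `digits` decimals (default 3, millimetre) and
#' round-trip exactly at that precision.
#'
#' @param dataset a `tracking_dataset`.
#' @param path destination file.
#' @param format `"csv"` or `"json"`.
#' @param digits decimal places for coordinates.
#' @export
write_tracking <- function(dataset, path, format = c("csv", "json"),
                           digits = 3) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "tracking_dataset"))
  if (length(dataset$frame) == 0L)
    stop_usage("refusing to write an empty tracking dataset")
  long <- tracking_to_long(dataset, digits)
  if (format == "csv") {
    utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  } else {
    doc <- list(meta = list(format = "pitchspace-tracking",
                            sampling_rate_hz = dataset$sampling_rate_hz,
                            pitch = list(length_m = dataset$pitch$length_m,
                                         width_m = dataset$pitch$width_m),
                            margin = dataset$margin, digits = digits),
                data = long)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Normalize attack direction
#'
#' Re-orients a dataset so the named team attacks toward increasing x (the
#' pitch-length axis), which makes end-of-possession depth comparable across
#' halves and venues. When a reflection is needed every coordinate maps
#' `(x, y) -> (length_m - x, width_m - y)` — a point reflection about the
#' pitch centre, hence an isometry. Idempotent when already oriented.
#'
#' The team's current attacking end is taken from `orientation`; the default
#' `"auto"` infers it from the team's goalkeeper mean position (the keeper
#' stands near their own goal).
#'
#' @param dataset a `tracking_dataset`.
#' @param team team label whose attack direction is normalized.
#' @param attacking_positive should the team end up attacking +x? Default TRUE.
#' @param orientation `"auto"`, or the team's current attacking direction
#'   (`"positive"` / `"negative"`) when known.
#' @return A `tracking_dataset`, reflected if necessary.
#' @export
normalize_attack_direction <- function(dataset, team,
                                       attacking_positive = TRUE,
                                       orientation = c("auto", "positive",
                                                       "negative")) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  orientation <- match.arg(orientation)
  if (!team %in% dataset$roster$team) stop_usage("unknown team: ", team)
  if (orientation == "auto") {
    gk <- player_ids(dataset, team, role = "goalkeeper")
    if (length(gk) == 0L)
      stop_usage("team ", team, " has no goalkeeper; pass orientation=")
    gx <- mean(dataset$player_xy[, 1L, gk], na.rm = TRUE)
    attacks_positive <- gx < dataset$pitch$length_m / 2
  } else {
    attacks_positive <- orientation == "positive"
  }
  if (attacks_positive == attacking_positive) return(dataset)
  reflect_dataset(dataset)
}

reflect_dataset <- function(dataset) {
  L <- dataset$pitch$length_m; W <- dataset$pitch$width_m
  dataset$ball_xy[, 1L] <- L - dataset$ball_xy[, 1L]
  dataset$ball_xy[, 2L] <- W - dataset$ball_xy[, 2L]
  dataset$player_xy[, 1L, ] <- L - dataset$player_xy[, 1L, ]
  dataset$player_xy[, 2L, ] <- W - dataset$player_xy[, 2L, ]
  dataset
}
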