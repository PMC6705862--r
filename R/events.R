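event_kinds <- c("touch", "possession_start", "possession_end", "set_piece",
                 "ball_out", "shot")

#' Event stream
#'
#' Ordered match annotations: touches, possession boundaries, set pieces,
#' ball-out and shot events. Frames must be non-decreasing and every
#' `possession_start` must be closed by a later `possession_end` for the
#' same team before that team starts another possession.
#'
#' @param frame integer frame indices, non-decreasing.
#' @param kind one of `touch`, `possession_start`, `possession_end`,
#'   `set_piece`, `ball_out`, `shot`.
#' @param team team label (may be `""` for neutral events such as ball_out).
#' @param player_id optional player id per event.
#' @return A data frame of class `event_stream`.
#' @export
event_stream <- function(frame, kind, team = "", player_id = NA_character_) {
  n <- length(frame)
  df <- data.frame(frame = as.integer(frame),
                   kind = rep_len(as.character(kind), n),
                   team = rep_len(as.character(team), n),
                   player_id = rep_len(as.character(player_id), n),
                   stringsAsFactors = FALSE)
  validate_event_stream(df)
}

validate_event_stream <- function(df) {
  if (nrow(df) && is.unsorted(df$frame))
    stop_malformed("event frames must be non-decreasing")
  bad <- setdiff(unique(df$kind), event_kinds)
  if (length(bad)) stop_malformed("unknown event kind(s): ",
                                  paste(bad, collapse = ", "))
  for (tm in unique(df$team[df$kind == "possession_start"])) {
    k <- df$kind[df$team == tm & df$kind %in%
                   c("possession_start", "possession_end")]
    # starts and ends must strictly alternate, starting with a start
    expect_start <- TRUE
    for (e in k) {
      if (expect_start && e != "possession_start" ||
          !expect_start && e != "possession_end")
        stop_malformed("unbalanced possession events for team ", tm)
      expect_start <- !expect_start
    }
    if (!expect_start)
      stop_malformed("possession_start without matching possession_end for team ",
                     tm)
  }
  class(df) <- c("event_stream", "data.frame")
  df
}

#' Read / write the event CSV dialect
#'
#' Header `frame,kind,team,player_id`.
#'
#' @param path file location.
#' @return [read_events()] returns an `event_stream`.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_usage("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(frame = "integer", kind = "character",
                                       team = "character",
                                       player_id = "character"))
  df$team[is.na(df$team)] <- ""
  validate_event_stream(df)
}

#' @rdname read_events
#' @param events an `event_stream`.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_stream"))
  utils::write.csv(as.data.frame(events), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
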