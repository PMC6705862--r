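#' Synthetic match scenario
#'
#' Parameters for the seeded match generator. Defaults emulate the study
#' conditions the analysis assumes: 25 Hz sampling on a 105 x 68 m pitch,
#' 10 outfield players plus a goalkeeper per team, possession durations
#' drawn log-normal around ~29 s with a realistic share of sub-8-s episodes,
#' occasional set pieces, and spatial targets on the scale of elite-match
#' possession data (in-possession convex-hull area near 985 m^2 for the
#' focal team and 909 m^2 for the opponents, a ~38 x 43 m game box, deepest
#' end-of-possession location near 83 m).
#'
#' @param n_possessions possessions per team; default 30.
#' @param pitch a [pitch_spec()].
#' @param sampling_rate_hz frames per second; default 25.
#' @param duration_meanlog,duration_sdlog log-normal possession-duration
#'   parameters (seconds); defaults `log(24)` and 0.6 give mean ~29 s and
#'   ~3% of episodes under 8 s.
#' @param max_duration_s cap on drawn durations; default 90.
#' @param eps_home,eps_away in-possession convex-hull area targets (m^2) for
#'   each team during its own possessions.
#' @param game_length,game_width targets (m) for the combined 20-player
#'   bounding box during possessions.
#' @param deepest end-of-possession deepest-attacker target (m along the
#'   105 m axis, attack-normalized).
#' @param ball_pass_speed_ms mean in-flight pass speed (m/s).
#' @param set_piece_prob probability a possession contains a set piece.
#' @param shot_prob probability a possession ends with a shot (ball out
#'   after the shot).
#' @param player_jitter_sd stationary SD (m) of the mean-reverting player
#'   noise around formation anchors.
#' @param seed integer seed; mandatory, the generator is fully reproducible.
#' @return An object of class `match_scenario`.
#' @export
match_scenario <- function(n_possessions = 30, pitch = pitch_spec(),
                           sampling_rate_hz = 25,
                           duration_meanlog = log(24), duration_sdlog = 0.6,
                           max_duration_s = 90,
                           eps_home = 985, eps_away = 909,
                           game_length = 38, game_width = 43,
                           deepest = 83, ball_pass_speed_ms = 12,
                           set_piece_prob = 0.1, shot_prob = 0.15,
                           player_jitter_sd = 1.2, seed) {
  if (missing(seed)) stop_usage("match_scenario requires an explicit seed")
  area <- pitch$length_m * pitch$width_m
  if (eps_home >= area || eps_away >= area)
    stop_usage("EPS target exceeds the pitch area")
  if (game_length >= pitch$length_m || game_width >= pitch$width_m)
    stop_usage("game box target exceeds the pitch")
  if (deepest <= 0 || deepest >= pitch$length_m)
    stop_usage("deepest-location target outside the pitch length")
  if (set_piece_prob < 0 || set_piece_prob > 1 ||
      shot_prob < 0 || shot_prob > 1)
    stop_usage("probabilities must lie in [0, 1]")
  # hull must fit inside its game box with some slack
  if (eps_home > 0.95 * game_length * game_width ||
      eps_away > 0.95 * game_length * game_width)
    stop_usage("EPS target too large for the game box targets")
  structure(list(n_possessions = as.integer(n_possessions), pitch = pitch,
                 sampling_rate_hz = sampling_rate_hz,
                 duration_meanlog = duration_meanlog,
                 duration_sdlog = duration_sdlog,
                 max_duration_s = max_duration_s,
                 eps = c(home = eps_home, away = eps_away),
                 game_length = game_length, game_width = game_width,
                 deepest = deepest, ball_pass_speed_ms = ball_pass_speed_ms,
                 set_piece_prob = set_piece_prob, shot_prob = shot_prob,
                 player_jitter_sd = player_jitter_sd,
                 seed = as.integer(seed)),
            class = "match_scenario")
}

# Octagonal 10-player formation with bounding box lx x ly centred on (0, 0).
# The corner-cut fraction is chosen so the anchor hull area equals `area`;
# two interior anchors fill the midfield.
formation_anchors <- function(lx, ly, area) {
  f <- area / (lx * ly)
  f <- min(max(f, 0.52), 0.98)
  cc <- sqrt(2 * (1 - f))
  hx <- lx / 2; hy <- ly / 2
  xs <- hx * (1 - cc); ys <- hy * (1 - cc)
  rbind(c(-xs, -hy), c(xs, -hy), c(hx, -ys), c(hx, ys),
        c(xs, hy), c(-xs, hy), c(-hx, ys), c(-hx, -ys),
        c(-hx / 4, 0), c(hx / 4, 0))
}

# Mean-reverting (AR(1)) noise, stationary sd `sd`, n frames x k players.
# phi near 1 keeps per-frame increments at realistic player speeds
# (~0.12 m/frame, i.e. ~3 m/s at 25 Hz) while the stationary spread stays sd.
ou_noise <- function(n, k, sd, phi = 0.995) {
  eps <- matrix(stats::rnorm(n * k, 0, sd * sqrt(1 - phi^2)), n, k)
  eps[1L, ] <- stats::rnorm(k, 0, sd)
  apply(eps, 2L, function(e) as.numeric(stats::filter(e, phi,
                                                      method = "recursive")))
}

# One-off Monte-Carlo estimate of how much OU jitter inflates the mean hull
# area of an anchor set; used to rescale anchors so the generated
# time-averaged hull hits the target.
hull_inflation <- function(anchors, sd, reps = 120L) {
  a0 <- convex_hull_area(anchors)
  areas <- vapply(seq_len(reps), function(i) {
    as.numeric(convex_hull_area(anchors +
                                  matrix(stats::rnorm(20, 0, sd), 10, 2)))
  }, numeric(1))
  mean(areas) / a0
}

#' Generate a synthetic match
#'
#' Simulates tracking and event data with the statistical structure the
#' possession analysis assumes. Players follow mean-reverting noise around
#' formation anchors that translate with the flow of each possession and are
#' scaled (with a Monte-Carlo correction for jitter inflation) so the
#' time-averaged in-possession hull area approaches the scenario's EPS
#' targets; the ball alternates dwells at the holder with straight passes
#' between attacking players, giving a realistically intermittent speed
#' series; possession boundaries, touches, set pieces and shot endings are
#' emitted as events; a ground-truth sidecar logs every possession. The
#' output is a deterministic function of the scenario (seed included).
#'
#' @param scenario a [match_scenario()].
#' @return List with `tracking` (a `tracking_dataset`), `events` (an
#'   `event_stream`), and `ground_truth` (data frame: `team`, `start_frame`,
#'   `end_frame` — shot-adjusted — `contains_set_piece`, `duration_s`,
#'   `expected_included`).
#' @export
generate_match <- function(scenario) {
  stopifnot(inherits(scenario, "match_scenario"))
  with_seed(scenario$seed, generate_match_impl(scenario))
}

generate_match_impl <- function(sc) {
  rate <- sc$sampling_rate_hz
  L <- sc$pitch$length_m; W <- sc$pitch$width_m
  teams <- rep(c("home", "away"), sc$n_possessions)
  np <- length(teams)
  dur <- pmin(pmax(stats::rlnorm(np, sc$duration_meanlog, sc$duration_sdlog),
                   3), sc$max_duration_s)
  nf <- as.integer(round(dur * rate))
  has_sp <- stats::runif(np) < sc$set_piece_prob
  has_shot <- stats::runif(np) < sc$shot_prob
  flight <- 25L                               # frames of post-shot ball flight

  # per-team formation geometry, calibrated for jitter inflation
  geom <- lapply(c(home = "home", away = "away"), function(tm) {
    lx <- sc$game_length - 3; ly <- sc$game_width - 3
    anchors <- formation_anchors(lx, ly, sc$eps[[tm]])
    rho <- hull_inflation(anchors, sc$player_jitter_sd)
    anchors * (1 / sqrt(rho))
  })

  ids <- c(paste0("h", 1:10), "hgk", paste0("a", 1:10), "agk")
  roster <- data.frame(
    player_id = ids,
    team = rep(c("home", "away"), each = 11L),
    role = rep(c(rep("outfield", 10), "goalkeeper"), 2L),
    stringsAsFactors = FALSE)

  blocks <- vector("list", np)
  ev <- list(frame = integer(), kind = character(), team = character(),
             player = character())
  gt <- vector("list", np)
  cursor <- 0L                                 # next free frame index

  for (k in seq_len(np)) {
    tm <- teams[k]; opp <- if (tm == "home") "away" else "home"
    dirn <- if (tm == "home") 1 else -1
    n <- nf[k]
    s <- cursor
    e <- s + n - 1L                            # nominal possession end
    anc_att <- geom[[tm]]
    anc_def <- geom[[opp]] * 0.9

    # attacking centroid drifts so the deepest anchor ends near the target
    half_lx <- max(anc_att[, 1L])
    deep_target <- if (dirn > 0) sc$deepest else L - sc$deepest
    cx_end <- deep_target - dirn * half_lx
    cx_start <- cx_end - dirn * stats::runif(1, 10, 18)
    clamp_x <- function(cx, anc) {
      lo <- 1.5 - min(anc[, 1L]); hi <- L - 1.5 - max(anc[, 1L])
      pmin(pmax(cx, lo), hi)
    }
    cx <- clamp_x(seq(cx_start, cx_end, length.out = n), anc_att)
    cy <- W / 2 + stats::runif(1, -2, 2)
    cx_def <- clamp_x(cx + dirn * 4, anc_def)

    jit <- function(kp) ou_noise(n, kp, sc$player_jitter_sd)
    att_x <- sweep(jit(10L), 1L, cx, "+")
    att_x <- sweep(att_x, 2L, anc_att[, 1L], "+")
    att_y <- jit(10L) + cy
    att_y <- sweep(att_y, 2L, anc_att[, 2L], "+")
    def_x <- sweep(jit(10L), 1L, cx_def, "+")
    def_x <- sweep(def_x, 2L, anc_def[, 1L], "+")
    def_y <- jit(10L) + cy
    def_y <- sweep(def_y, 2L, anc_def[, 2L], "+")
    gk_att_x <- (if (dirn > 0) 3 else L - 3) + ou_noise(n, 1L, 0.4)
    gk_def_x <- (if (dirn > 0) L - 3 else 3) + ou_noise(n, 1L, 0.4)
    gk_att_y <- W / 2 + ou_noise(n, 1L, 0.4)
    gk_def_y <- W / 2 + ou_noise(n, 1L, 0.4)

    clampL <- function(z) pmin(pmax(z, 0.5), L - 0.5)
    clampW <- function(z) pmin(pmax(z, 0.5), W - 0.5)
    att_x <- clampL(att_x); def_x <- clampL(def_x)
    att_y <- clampW(att_y); def_y <- clampW(def_y)

    # ball: dwell at holder, pass to a teammate, repeat
    bx <- numeric(n); by <- numeric(n)
    holder <- sample.int(10L, 1L)
    f <- 1L
    ev_push <- function(frame, kind, team, player = NA_character_) {
      ev$frame <<- c(ev$frame, frame); ev$kind <<- c(ev$kind, kind)
      ev$team <<- c(ev$team, team); ev$player <<- c(ev$player, player)
    }
    ev_push(s, "possession_start", tm)
    while (f <= n) {
      dwell <- min(sample(10:60, 1L), n - f + 1L)
      idx <- f:(f + dwell - 1L)
      # held ball trails the holder with damping: near-still between passes,
      # which gives the speed series its realistic intermittency
      bx[idx] <- att_x[f, holder] + 0.25 +
        0.3 * (att_x[idx, holder] - att_x[f, holder])
      by[idx] <- att_y[f, holder] +
        0.3 * (att_y[idx, holder] - att_y[f, holder])
      f <- f + dwell
      if (f > n) break
      # short passes: receiver among the nearest teammates
      dd <- (att_x[f, ] - att_x[f, holder])^2 +
        (att_y[f, ] - att_y[f, holder])^2
      near <- setdiff(order(dd), holder)[1:5]
      recv <- near[sample.int(5L, 1L)]
      p0 <- c(bx[f - 1L], by[f - 1L])
      p1 <- c(att_x[f, recv] + 0.25, att_y[f, recv])
      dist <- sqrt(sum((p1 - p0)^2))
      v <- max(stats::rnorm(1, sc$ball_pass_speed_ms, 3), 5)
      steps <- max(1L, min(round(dist / v * rate), n - f + 1L))
      idx <- f:(f + steps - 1L)
      frac <- seq_len(steps) / steps
      bx[idx] <- p0[1L] + frac * (p1[1L] - p0[1L])
      by[idx] <- p0[2L] + frac * (p1[2L] - p0[2L])
      ev_push(s + f - 1L, "touch", tm, paste0(substr(tm, 1, 1), holder))
      f <- f + steps
      holder <- recv
    }
    if (has_sp[k])
      ev_push(s + sample.int(n, 1L) - 1L, "set_piece", tm)

    gt_end <- e
    if (has_shot[k]) {
      # shot at the nominal end; ball flies out over `flight` extra frames
      fl <- flight
      goal_x <- if (dirn > 0) L + 2.5 else -2.5
      fx <- bx[n] + (goal_x - bx[n]) * seq_len(fl) / fl
      fy <- by[n] + (W / 2 - by[n]) * 0.3 * seq_len(fl) / fl
      out_at <- which(fx < 0 | fx > L)[1L]
      bx <- c(bx, fx); by <- c(by, fy)
      ext <- function(m) rbind(m, m[rep(n, fl), , drop = FALSE])
      att_x <- ext(att_x); att_y <- ext(att_y)
      def_x <- ext(def_x); def_y <- ext(def_y)
      gk_att_x <- c(gk_att_x, rep(gk_att_x[n], fl))
      gk_att_y <- c(gk_att_y, rep(gk_att_y[n], fl))
      gk_def_x <- c(gk_def_x, rep(gk_def_x[n], fl))
      gk_def_y <- c(gk_def_y, rep(gk_def_y[n], fl))
      ev_push(e, "shot", tm)
      ev_push(e + out_at, "ball_out", "")
      ev_push(e + fl, "possession_end", tm)
      n_blk <- n + fl
    } else {
      ev_push(e, "possession_end", tm)
      n_blk <- n
    }

    # assemble block in roster order: h1..h10, hgk, a1..a10, agk
    if (tm == "home") {
      px <- cbind(att_x, gk_att_x, def_x, gk_def_x)
      py <- cbind(att_y, gk_att_y, def_y, gk_def_y)
    } else {
      px <- cbind(def_x, gk_def_x, att_x, gk_att_x)
      py <- cbind(def_y, gk_def_y, att_y, gk_att_y)
    }
    blocks[[k]] <- list(bx = bx, by = by, px = px, py = py)
    gt[[k]] <- data.frame(team = tm, start_frame = s, end_frame = gt_end,
                          contains_set_piece = has_sp[k],
                          duration_s = (gt_end - s + 1L) / rate,
                          stringsAsFactors = FALSE)
    cursor <- s + n_blk
  }

  ball <- cbind(unlist(lapply(blocks, `[[`, "bx")),
                unlist(lapply(blocks, `[[`, "by")))
  px <- do.call(rbind, lapply(blocks, `[[`, "px"))
  py <- do.call(rbind, lapply(blocks, `[[`, "py"))
  ntot <- nrow(ball)
  player_xy <- array(NA_real_, dim = c(ntot, 2L, 22L),
                     dimnames = list(NULL, c("x", "y"), ids))
  player_xy[, 1L, ] <- px
  player_xy[, 2L, ] <- py

  tracking <- tracking_dataset(frame = 0:(ntot - 1L), ball_xy = ball,
                               player_xy = player_xy, roster = roster,
                               sampling_rate_hz = rate, pitch = sc$pitch,
                               margin = 5)
  o <- order(ev$frame, match(ev$kind, c("possession_start", "touch",
                                        "set_piece", "shot", "ball_out",
                                        "possession_end")))
  events <- event_stream(ev$frame[o], ev$kind[o], ev$team[o], ev$player[o])
  ground_truth <- do.call(rbind, gt)
  min_frames <- as.integer(round(8 * rate))
  ground_truth$expected_included <-
    (ground_truth$end_frame - ground_truth$start_frame + 1L) >= min_frames &
    !ground_truth$contains_set_piece
  list(tracking = tracking, events = events, ground_truth = ground_truth)
}

#' Build a possession with closed-form features
#'
#' Constructs a single possession from an explicit static player layout and
#' a ball polyline traversed at constant speed, so ball distance, the
#' length/width ratio, mean speed, hull area, game bounds, deepest location
#' and offensive space all follow from the construction. Used for fixture
#' design and worked examples.
#'
#' @param ball_path k x 2 matrix of polyline vertices (m), inside the pitch.
#' @param duration_s possession duration in seconds; must give at least 200
#'   frames unless `override` is set.
#' @param team_xy 10 x 2 matrix: the possession team's outfield players
#'   (static).
#' @param opp_xy 10 x 2 matrix: opposing outfield players (static).
#' @param team possession team label; default `"home"`.
#' @param pitch a [pitch_spec()].
#' @param sampling_rate_hz frames per second; default 25.
#' @param gk_xy,opp_gk_xy goalkeeper positions; defaults put each keeper by
#'   their goal (home attacking +x).
#' @param override allow fewer than 200 frames.
#' @return A `possession` whose tracking slice holds the scripted frames.
#' @export
scripted_possession <- function(ball_path, duration_s, team_xy, opp_xy,
                                team = "home", pitch = pitch_spec(),
                                sampling_rate_hz = 25, gk_xy = NULL,
                                opp_gk_xy = NULL, override = FALSE) {
  ball_path <- as.matrix(ball_path)
  n <- as.integer(round(duration_s * sampling_rate_hz))
  if (n < 200L && !override)
    stop_usage("scripted possession must span at least 200 frames ",
               "(use override = TRUE for shorter diagnostics)")
  L <- pitch$length_m; W <- pitch$width_m
  if (any(ball_path[, 1L] < 0 | ball_path[, 1L] > L |
          ball_path[, 2L] < 0 | ball_path[, 2L] > W))
    stop_usage("ball path leaves the pitch")
  gk_xy <- gk_xy %||% c(2, W / 2)
  opp_gk_xy <- opp_gk_xy %||% c(L - 2, W / 2)

  seg <- diff(ball_path)
  seglen <- sqrt(rowSums(seg^2))
  total <- sum(seglen)
  at <- c(0, cumsum(seglen))
  sdist <- total * (0:(n - 1L)) / (n - 1L)
  i <- findInterval(sdist, at, rightmost.closed = TRUE)
  i <- pmin(i, length(seglen))
  frac <- ifelse(seglen[i] > 0, (sdist - at[i]) / seglen[i], 0)
  ball <- ball_path[i, , drop = FALSE] + seg[i, , drop = FALSE] * frac

  opp <- if (team == "home") "away" else "home"
  ids <- c(paste0(substr(team, 1, 1), 1:10), paste0(substr(team, 1, 1), "gk"),
           paste0(substr(opp, 1, 1), 1:10), paste0(substr(opp, 1, 1), "gk"))
  roster <- data.frame(player_id = ids,
                       team = rep(c(team, opp), each = 11L),
                       role = rep(c(rep("outfield", 10), "goalkeeper"), 2L),
                       stringsAsFactors = FALSE)
  xy <- rbind(as.matrix(team_xy), matrix(gk_xy, 1L), as.matrix(opp_xy),
              matrix(opp_gk_xy, 1L))
  player_xy <- array(NA_real_, c(n, 2L, 22L),
                     dimnames = list(NULL, c("x", "y"), ids))
  for (p in 1:22) {
    player_xy[, 1L, p] <- xy[p, 1L]
    player_xy[, 2L, p] <- xy[p, 2L]
  }
  tracking <- tracking_dataset(frame = 0:(n - 1L), ball_xy = ball,
                               player_xy = player_xy, roster = roster,
                               sampling_rate_hz = sampling_rate_hz,
                               pitch = pitch)
  new_possession(team, 0L, n - 1L, tracking)
}

#' Two-group feature table with planted effects and factor structure
#'
#' Draws log-normal possession variables for two groups with specified
#' standardized mean differences (on the log scale) and a block latent-factor
#' structure, to exercise the comparison and PCA stages against known ground
#' truth.
#'
#' @param effects named numeric vector of standardized log-scale differences
#'   (group b minus group a) per variable; unnamed variables get 0.
#' @param n possessions per group.
#' @param seed integer seed.
#' @param n_factors latent factors behind the 15 variables (block
#'   assignment, round-robin); default 5.
#' @param loading latent-factor loading of each variable; default 0.85.
#' @param sigma_log log-scale SD of every variable; default 0.3.
#' @return Data frame with a `team` column (`"a"`, `"b"`) and the 15 feature
#'   columns, strictly positive.
#' @export
generate_two_group_features <- function(effects = numeric(), n = 200, seed,
                                        n_factors = 5, loading = 0.85,
                                        sigma_log = 0.3) {
  if (missing(seed)) stop_usage("generate_two_group_features requires a seed")
  if (n < 2L) stop_usage("n must be at least 2 per group")
  vars <- feature_names
  d <- stats::setNames(numeric(length(vars)), vars)
  if (length(effects)) {
    bad <- setdiff(names(effects), vars)
    if (length(bad)) stop_usage("unknown variable(s): ",
                                paste(bad, collapse = ", "))
    d[names(effects)] <- effects
  }
  mu <- stats::setNames(log(c(29, 170, 22, 92, 0.35, 1.7, 985, 17,
                              38, 11, 44, 11, 83, 1480, 1.4)), vars)
  block <- rep(seq_len(n_factors), length.out = length(vars))
  with_seed(seed, {
    draw <- function(nn, shift) {
      f <- matrix(stats::rnorm(nn * n_factors), nn)
      z <- f[, block, drop = FALSE] * loading +
        matrix(stats::rnorm(nn * length(vars)), nn) *
          sqrt(1 - loading^2)
      logv <- sweep(z + matrix(shift, nn, length(vars), byrow = TRUE),
                    2L, mu / sigma_log, "+") * sigma_log
      exp(logv)
    }
    a <- draw(n, 0); b <- draw(n, d)
    out <- as.data.frame(rbind(a, b))
    names(out) <- vars
    cbind(team = rep(c("a", "b"), each = n), out, stringsAsFactors = FALSE)
  })
}
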