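# Independent oracles, deliberately written with different algorithms than
# the package internals.

# Brute-force approximate entropy: explicit template loops, self-matches
# included, Chebyshev distance.
apen_bruteforce <- function(x, m = 2L, r_factor = 0.2) {
  n <- length(x)
  r <- r_factor * sd(x)
  phi <- function(k) {
    N <- n - k + 1L
    logC <- numeric(N)
    for (i in seq_len(N)) {
      cnt <- 0L
      ti <- x[i:(i + k - 1L)]
      for (j in seq_len(N)) {
        if (max(abs(ti - x[j:(j + k - 1L)])) <= r) cnt <- cnt + 1L
      }
      logC[i] <- log(cnt / N)
    }
    mean(logC)
  }
  if (sd(x) == 0) return(0)
  phi(m) - phi(m + 1L)
}

# Gift-wrapping (Jarvis march) convex hull + triangle-fan area.
hull_area_giftwrap <- function(xy) {
  xy <- unique(as.matrix(xy))
  n <- nrow(xy)
  if (n < 3L) return(0)
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  start <- which.min(xy[, 1] + xy[, 2] * 1e-9)
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1L) 2L else 1L
    for (r in seq_len(n)) {
      if (r == p) next
      cr <- cross(xy[p, ], xy[q, ], xy[r, ])
      if (q == p || cr < 0 ||
          (cr == 0 && sum((xy[r, ] - xy[p, ])^2) > sum((xy[q, ] - xy[p, ])^2)))
        q <- r
    }
    p <- q
    if (p == start || length(hull) > n) break
  }
  if (length(hull) < 3L) return(0)
  v <- xy[hull, , drop = FALSE]
  a <- 0
  for (i in 2:(nrow(v) - 1L))
    a <- a + cross(v[1L, ], v[i, ], v[i + 1L, ])
  abs(a) / 2
}

# Small fully-populated static tracking dataset: 10 outfield + keeper per
# team, ball given (or centre spot), all players static.
make_static_tracking <- function(n_frames, home_xy = NULL, away_xy = NULL,
                                 ball_xy = NULL, rate = 25,
                                 pitch = pitch_spec(),
                                 home_gk = c(3, 34), away_gk = c(102, 34)) {
  if (is.null(home_xy))
    home_xy <- cbind(seq(20, 50, length.out = 10), seq(10, 58, length.out = 10))
  if (is.null(away_xy))
    away_xy <- cbind(seq(55, 85, length.out = 10), seq(10, 58, length.out = 10))
  if (is.null(ball_xy))
    ball_xy <- matrix(rep(c(52.5, 34), each = n_frames), n_frames)
  ids <- c(paste0("h", 1:10), "hgk", paste0("a", 1:10), "agk")
  roster <- data.frame(player_id = ids,
                       team = rep(c("home", "away"), each = 11),
                       role = rep(c(rep("outfield", 10), "goalkeeper"), 2),
                       stringsAsFactors = FALSE)
  xy <- rbind(home_xy, matrix(home_gk, 1), away_xy, matrix(away_gk, 1))
  player_xy <- array(NA_real_, c(n_frames, 2, 22),
                     dimnames = list(NULL, c("x", "y"), ids))
  for (p in 1:22) {
    player_xy[, 1, p] <- xy[p, 1]
    player_xy[, 2, p] <- xy[p, 2]
  }
  tracking_dataset(frame = 0:(n_frames - 1), ball_xy = ball_xy,
                   player_xy = player_xy, roster = roster,
                   sampling_rate_hz = rate, pitch = pitch)
}

# Random valid tracking dataset for round-trip / isometry properties.
make_random_tracking <- function(n_frames = 4, seed = 1) {
  set.seed(seed)
  home <- cbind(runif(10, 5, 50), runif(10, 5, 63))
  away <- cbind(runif(10, 55, 100), runif(10, 5, 63))
  ball <- cbind(runif(n_frames, 1, 104), runif(n_frames, 1, 67))
  make_static_tracking(n_frames, home, away, ball)
}
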