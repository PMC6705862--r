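test_that("long CSV and JSON dialects round-trip a dataset at declared precision", {
  ds <- make_random_tracking(n_frames = 5, seed = 42)
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_tracking(ds, path, format = fmt)
    back <- read_tracking(path, format = fmt,
                          sampling_rate_hz = ds$sampling_rate_hz)
    expect_identical(back$frame, ds$frame)
    expect_equal(back$time_s, ds$time_s, tolerance = 1e-9)
    expect_equal(back$ball_xy, round(ds$ball_xy, 3))
    expect_equal(unname(back$player_xy), unname(round(ds$player_xy, 3)))
    expect_equal(back$roster, ds$roster)
    expect_equal(back$sampling_rate_hz, ds$sampling_rate_hz)
  }
})

test_that("coordinates are stored at the declared decimal precision", {
  ds <- make_static_tracking(2)
  ds$ball_xy[1, 1] <- 1.23456
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(ds, path, digits = 3)
  back <- read_tracking(path)
  expect_identical(back$ball_xy[1, 1], 1.235)
})

test_that("a frame without a ball row is a malformed-input error naming the frame", {
  ds <- make_static_tracking(2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(ds, path)
  df <- read.csv(path)
  df <- df[!(df$frame == 1 & df$entity_id == "ball"), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_error(read_tracking(path), "ball row in frame 1")
})

test_that("non-monotone frame order is rejected", {
  ds <- make_static_tracking(3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(ds, path)
  df <- read.csv(path)
  df <- df[rev(seq_len(nrow(df))), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_error(read_tracking(path), "monotone")
})

test_that("degenerate datasets are refused", {
  ds <- make_static_tracking(2)
  expect_error(tracking_dataset(integer(0), ds$ball_xy[0, , drop = FALSE],
                                ds$player_xy[0, , , drop = FALSE],
                                ds$roster),
               "no frames")
  ds$frame <- integer(0)
  expect_error(write_tracking(ds, tempfile()), "empty")
})

test_that("a declared rate that disagrees with time deltas is rejected", {
  ds <- make_static_tracking(4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(ds, path)
  expect_error(read_tracking(path, sampling_rate_hz = 10), "disagrees")
})

test_that("short player dropouts are interpolated, long ones kept missing", {
  ds <- make_static_tracking(20)
  raw <- ds$player_xy
  raw[, 1, "h1"] <- seq(10, 29, by = 1)
  raw[5:7, , "h1"] <- NA       # 3-frame gap -> filled
  raw[10:16, , "h2"] <- NA     # 7-frame gap -> kept missing
  ds2 <- tracking_dataset(ds$frame, ds$ball_xy, raw, ds$roster,
                          sampling_rate_hz = 25, max_gap = 5)
  expect_equal(ds2$player_xy[5:7, 1, "h1"], c(14, 15, 16))
  expect_true(all(is.na(ds2$player_xy[10:16, 1, "h2"])))
})

test_that("attack normalization reflects through the pitch centre", {
  # home keeper placed high-x: home currently attacks -x, so normalizing
  # home reflects; the player at (10, 5) maps to (95, 63)
  home <- cbind(c(10, seq(60, 95, length.out = 9)), seq(5, 60, length.out = 10))
  away <- cbind(seq(10, 45, length.out = 10), seq(6, 61, length.out = 10))
  ds <- make_static_tracking(2, home, away, home_gk = c(102, 34),
                             away_gk = c(3, 34))
  out <- normalize_attack_direction(ds, "home")
  expect_equal(unname(out$player_xy[1, , "h1"]), c(95, 63))
  # idempotent once oriented, and the double application equals the single
  again <- normalize_attack_direction(out, "home")
  expect_equal(again, out)
})

test_that("already-oriented datasets pass through unchanged", {
  ds <- make_static_tracking(2)          # home keeper at x = 3, attacks +x
  expect_equal(normalize_attack_direction(ds, "home"), ds)
  expect_error(normalize_attack_direction(ds, "nobody"), "unknown team")
})

test_that("the normalization reflection is an isometry", {
  for (seed in 1:5) {
    ds <- make_random_tracking(n_frames = 3, seed = seed)
    ref <- normalize_attack_direction(ds, "away")   # away attacks -x: reflect
    for (f in 1:3) {
      before <- t(ds$player_xy[f, , ])
      after <- t(ref$player_xy[f, , ])
      expect_equal(as.numeric(dist(after)), as.numeric(dist(before)),
                   tolerance = 1e-9)
    }
  }
})

test_that("frame count, rate and elapsed time are consistent", {
  ds <- make_static_tracking(250)
  n <- length(ds$frame)
  elapsed <- ds$time_s[n] - ds$time_s[1] + 1 / ds$sampling_rate_hz
  expect_equal(n / ds$sampling_rate_hz, elapsed, tolerance = 1e-6)
})
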