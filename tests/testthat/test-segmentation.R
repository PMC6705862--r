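test_that("inclusion criteria keep 200-frame possessions and drop short or set-piece ones", {
  ds <- make_static_tracking(800)
  ev <- event_stream(
    frame = c(0, 249, 250, 439, 440, 500, 739),
    kind = c("possession_start", "possession_end", "possession_start",
             "possession_end", "possession_start", "set_piece",
             "possession_end"),
    team = c("home", "home", "away", "away", "home", "home", "home"))
  seg <- segment_possessions(ev, ds)
  man <- possession_manifest(seg)

  # 250-frame home possession: included
  expect_length(seg, 1L)
  expect_identical(seg[[1]]$team, "home")
  expect_identical(seg[[1]]$start_frame, 0L)
  expect_identical(seg[[1]]$end_frame, 249L)
  # 190-frame away possession: below the 200-frame minimum
  expect_identical(man$exclusion_reason[man$start_frame == 250], "too_short")
  # 300-frame home possession containing a set piece: excluded
  expect_identical(man$exclusion_reason[man$start_frame == 440], "set_piece")
})

test_that("a possession that goes out after a shot ends at the shot frame", {
  ds <- make_static_tracking(400)
  ev <- event_stream(
    frame = c(0, 350, 380, 399),
    kind = c("possession_start", "shot", "ball_out", "possession_end"),
    team = c("home", "home", "", "home"))
  seg <- segment_possessions(ev, ds)
  expect_length(seg, 1L)
  expect_identical(end_frame_of(seg[[1]]), 350L)
  expect_identical(seg[[1]]$end_reason, "ball_out_after_shot")
})

test_that("possessions with long tracking dropouts are rejected", {
  ds <- make_static_tracking(300)
  ds$player_xy[100:110, , "a3"] <- NA
  ev <- event_stream(c(0, 299), c("possession_start", "possession_end"),
                     c("home", "home"))
  seg <- segment_possessions(ev, ds)
  expect_length(seg, 0L)
  expect_identical(possession_manifest(seg)$exclusion_reason, "tracking_gap")
})

test_that("events outside the tracking range are a consistency error", {
  ds <- make_static_tracking(100)
  ev <- event_stream(c(0, 250), c("possession_start", "possession_end"),
                     c("home", "home"))
  expect_error(segment_possessions(ev, ds), "outside the tracking range")
})

test_that("segmentation recovers the generator's ground-truth possession log", {
  sim <- generate_match(match_scenario(n_possessions = 12, seed = 11))
  seg <- segment_possessions(sim$events, sim$tracking)
  gt <- sim$ground_truth[sim$ground_truth$expected_included, ]
  expect_length(seg, nrow(gt))
  expect_identical(vapply(seg, `[[`, character(1), "team"), gt$team)
  expect_identical(vapply(seg, `[[`, integer(1), "start_frame"),
                   gt$start_frame)
  expect_identical(vapply(seg, `[[`, integer(1), "end_frame"), gt$end_frame)
})

test_that("raising the duration threshold monotonically shrinks the included set", {
  sim <- generate_match(match_scenario(n_possessions = 15, seed = 5))
  counts <- vapply(c(8, 12, 20, 30, 45), function(th) {
    cfg <- segmentation_config(min_duration_s = th)
    length(segment_possessions(sim$events, sim$tracking, cfg))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  seg8 <- segment_possessions(sim$events, sim$tracking)
  expect_true(all(vapply(seg8, `[[`, numeric(1), "duration_s") >= 8))
})

test_that("included sequences are pairwise disjoint per team", {
  sim <- generate_match(match_scenario(n_possessions = 15, seed = 6))
  seg <- segment_possessions(sim$events, sim$tracking)
  for (tm in c("home", "away")) {
    spans <- t(vapply(Filter(function(p) p$team == tm, seg),
                      function(p) c(p$start_frame, p$end_frame), integer(2)))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (nrow(spans) > 1)
      expect_true(all(spans[-1, 1] > spans[-nrow(spans), 2]))
  }
})

test_that("ball-control heuristic emits possessions with hysteresis", {
  # h1 alone near the ball for 4 s, then a1 for 4 s
  n <- 200
  ball <- cbind(c(rep(30, 100), rep(70, 100)), rep(34, n))
  home <- cbind(seq(20, 45, length.out = 10), seq(10, 58, length.out = 10))
  home[1, ] <- c(30.5, 34)
  away <- cbind(seq(55, 85, length.out = 10), seq(10, 58, length.out = 10))
  away[1, ] <- c(70.5, 34)
  ds <- make_static_tracking(n, home, away, ball)
  ev <- infer_possessions_from_touches(ds)
  ps <- ev[ev$kind == "possession_start", ]
  expect_identical(ps$team, c("home", "away"))
  expect_identical(ps$frame, c(0L, 100L))
  pe <- ev[ev$kind == "possession_end", ]
  expect_identical(pe$frame, c(99L, 199L))

  # alternation faster than the hysteresis window yields nothing
  ball2 <- cbind(rep(c(30.5, 70.5), length.out = n), rep(34, n))
  ds2 <- make_static_tracking(n, home, away, ball2)
  ev2 <- infer_possessions_from_touches(ds2)
  expect_identical(nrow(ev2), 0L)
})

test_that("ball leaving the pitch closes the inferred possession", {
  n <- 120
  ball <- cbind(c(rep(30, 60), rep(107, 60)), rep(34, n))
  home <- cbind(seq(20, 45, length.out = 10), seq(10, 58, length.out = 10))
  home[1, ] <- c(30.5, 34)
  ds <- make_static_tracking(n, home, ball_xy = ball)
  ev <- infer_possessions_from_touches(ds)
  expect_identical(ev$kind[1], "possession_start")
  expect_true("ball_out" %in% ev$kind)
  pe <- ev[ev$kind == "possession_end", ]
  expect_identical(pe$frame, 59L)
})
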