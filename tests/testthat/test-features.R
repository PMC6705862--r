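# Shared scripted layouts: possession team on a 10 x 10 m square (4 corners,
# 6 strictly inside), opponents spread ahead and behind the deepest attacker.
square_team <- function(x0 = 40, y0 = 20, side = 10) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side),
        cbind(runif(6, x0 + 2, x0 + side - 2), runif(6, y0 + 2, y0 + side - 2)))
}

test_that("ball path metrics have their closed-form values on scripted possessions", {
  set.seed(1)
  # L-shaped path: 30 m lengthwise then 15 m widthwise, 9 s at constant speed
  path <- rbind(c(30, 20), c(60, 20), c(60, 35))
  p <- scripted_possession(path, duration_s = 9, team_xy = square_team(),
                           opp_xy = square_team(60, 40))
  expect_equal(ball_distance(p), 45, tolerance = 3e-3)
  expect_equal(lw_ratio(p), 2.0, tolerance = 1e-9)        # 30 / 15
  expect_equal(mean(ball_speed_series(p)), 18, tolerance = 1e-2)  # 5 m/s
  # purely widthwise path: ratio hits zero; purely lengthwise: undefined
  pw <- scripted_possession(rbind(c(40, 10), c(40, 50)), 9,
                            square_team(), square_team(60, 40))
  expect_identical(lw_ratio(pw), 0)
  pl <- scripted_possession(rbind(c(10, 30), c(80, 30)), 9,
                            square_team(), square_team(60, 40))
  expect_true(is.na(lw_ratio(pl)))
  expect_true(attr(lw_ratio(pl), "undefined"))
})

test_that("a stationary ball has zero distance and an all-zero speed series", {
  set.seed(2)
  p <- scripted_possession(rbind(c(50, 30), c(50, 30)), 9,
                           square_team(), square_team(60, 40))
  expect_equal(ball_distance(p), 0)
  expect_equal(ball_speed_series(p), rep(0, 224))
})

test_that("speed smoothing validates its window and preserves the mean shape", {
  set.seed(3)
  p <- scripted_possession(rbind(c(30, 20), c(60, 20)), 9,
                           square_team(), square_team(60, 40))
  expect_error(ball_speed_series(p, smoothing_window = 2), "odd")
  expect_error(ball_speed_series(p, smoothing_window = 501), "larger")
  sm <- ball_speed_series(p, smoothing_window = 5)
  expect_length(sm, 224)
})

test_that("cv_percent matches the hand computation and its invariances", {
  expect_equal(cv_percent(c(1, 2, 3)), 50)        # sd 1, mean 2
  expect_equal(cv_percent(rep(4.2, 10)), 0)
  set.seed(4)
  for (i in 1:20) {
    x <- rlnorm(30)
    c1 <- cv_percent(x)
    # scale invariance and agreement with the definition
    expect_equal(cv_percent(x * runif(1, 0.1, 50)), c1, tolerance = 1e-9)
    expect_equal(c1, 100 * sd(x) / mean(x), tolerance = 1e-12)
  }
  z <- cv_percent(c(-1, 0, 1))
  expect_true(is.na(z) && attr(z, "undefined"))
})

test_that("EPS is the hull of the possession team and handles degeneracy", {
  set.seed(5)
  p <- scripted_possession(rbind(c(41, 21), c(49, 29)), 9,
                           team_xy = square_team(), opp_xy = square_team(60, 40))
  e <- eps_series(p)
  expect_equal(unique(round(e, 9)), 100)           # 10 x 10 square
  # all ten players collinear: zero area, flagged
  lin <- cbind(seq(30, 60, length.out = 10), seq(10, 40, length.out = 10))
  pl <- scripted_possession(rbind(c(41, 21), c(49, 29)), 9,
                            team_xy = lin, opp_xy = square_team(60, 40))
  el <- eps_series(pl)
  expect_equal(unique(as.numeric(el)), 0)
  expect_true(all(attr(el, "degenerate")))
})

test_that("hull area agrees with a gift-wrapping oracle on random frames", {
  set.seed(6)
  for (i in 1:100) {
    xy <- cbind(runif(10, 0, 105), runif(10, 0, 68))
    expect_equal(as.numeric(convex_hull_area(xy)), hull_area_giftwrap(xy),
                 tolerance = 1e-6)
  }
})

test_that("hull area never exceeds the game bounding box", {
  sim <- generate_match(match_scenario(n_possessions = 4, seed = 9))
  seg <- segment_possessions(sim$events, sim$tracking)
  p <- seg[[1]]
  e <- eps_series(p)
  gb <- game_bounds_series(p)
  expect_true(all(e <= gb$length * gb$width + 1e-9))
})

test_that("game bounds use all 20 outfield players and ignore translation", {
  set.seed(7)
  home <- cbind(seq(30, 60, length.out = 10), seq(10, 40, length.out = 10))
  away <- cbind(seq(40, 68, length.out = 10), seq(20, 53, length.out = 10))
  p <- scripted_possession(rbind(c(41, 21), c(49, 29)), 9, home, away)
  gb <- game_bounds_series(p)
  expect_equal(unique(gb$length), 38)   # x spans [30, 68]
  expect_equal(unique(gb$width), 43)    # y spans [10, 53]
  p2 <- scripted_possession(rbind(c(46, 26), c(54, 34)), 9, home + 5, away + 5)
  gb2 <- game_bounds_series(p2)
  expect_equal(gb2$length, gb$length)
  expect_equal(gb2$width, gb$width)
})

test_that("end-of-possession metrics follow the adopted definitions", {
  set.seed(8)
  team <- square_team()                      # deepest attacker at x = 50
  team[2, ] <- c(83.24, 30)                  # now deepest is 83.24
  opp <- square_team(60, 40)                 # strictly between 60 and 70
  opp[1, ] <- c(90, 10); opp[2, ] <- c(86, 50)   # two defenders beyond
  p <- scripted_possession(rbind(c(41, 21), c(49, 29)), 9, team, opp,
                           opp_gk_xy = c(103, 34))
  expect_equal(deepest_location(p), 83.24)
  # definitional rectangle: (105 - 83.24) * 68
  expect_equal(offensive_available_space(p), 1479.68, tolerance = 1e-9)
  # two defenders beyond the deepest attacker; keeper at x=103 not counted
  expect_identical(opponents_in_space(p), 2L)

  deep <- team; deep[2, ] <- c(105, 30)
  pd <- scripted_possession(rbind(c(41, 21), c(49, 29)), 9, deep, opp)
  expect_equal(offensive_available_space(pd), 0)
  expect_identical(opponents_in_space(pd), 0L)
})

test_that("lw_ratio inverts under an axis swap", {
  set.seed(9)
  sq <- pitch_spec(80, 80)
  path <- cbind(runif(6, 10, 70), runif(6, 10, 70))
  team <- cbind(runif(10, 20, 40), runif(10, 20, 40))
  opp <- cbind(runif(10, 40, 60), runif(10, 40, 60))
  p1 <- scripted_possession(path, 9, team, opp, pitch = sq,
                            gk_xy = c(2, 40), opp_gk_xy = c(78, 40))
  p2 <- scripted_possession(path[, 2:1], 9, team[, 2:1], opp[, 2:1],
                            pitch = sq, gk_xy = c(2, 40),
                            opp_gk_xy = c(78, 40))
  expect_equal(lw_ratio(p1), 1 / lw_ratio(p2), tolerance = 1e-9)
})

test_that("summarize_possession populates all fifteen variables with closed forms", {
  set.seed(10)
  team <- square_team()
  opp <- square_team(60, 40)
  opp[1, ] <- c(90, 10)
  path <- rbind(c(30, 20), c(60, 20), c(60, 35))
  p <- scripted_possession(path, 9, team, opp)
  ft <- summarize_possession(p, min_frames = 200)
  expect_setequal(intersect(possession_feature_names(), names(ft)),
                  possession_feature_names())
  expect_equal(ft$duration_s, 9)
  expect_equal(ft$ball_distance_m, 45, tolerance = 3e-3)
  expect_equal(ft$ball_speed_mean_kmh, 18, tolerance = 1e-2)
  expect_equal(ft$ball_lw_ratio_au, 2, tolerance = 1e-9)
  expect_equal(ft$eps_mean_m2, 100)
  expect_equal(ft$eps_cv_pct, 0)
  expect_equal(ft$game_length_mean_m, max(c(team[, 1], opp[, 1])) -
                 min(c(team[, 1], opp[, 1])))
  expect_equal(ft$deepest_location_m, 50)
  expect_equal(ft$offensive_space_m2, (105 - 50) * 68)
  expect_identical(ft$n_opponents_in_space, 10L)   # all opponents beyond 50
})

test_that("a constant-velocity straight-line ball gives zero speed variability and entropy", {
  set.seed(11)
  p <- scripted_possession(rbind(c(20, 30), c(80, 30)), 10, square_team(),
                           square_team(60, 40))
  ft <- summarize_possession(p, min_frames = 200)
  expect_equal(ft$ball_speed_cv_pct, 0, tolerance = 1e-6)
  expect_identical(ft$ball_speed_apen_au, 0)
})

test_that("sub-minimum sequences are refused by summarize_possession", {
  set.seed(12)
  p <- scripted_possession(rbind(c(30, 20), c(60, 20)), 7.96,
                           square_team(), square_team(60, 40),
                           override = TRUE)           # 199 frames
  expect_error(summarize_possession(p), "below the 200-frame")
})

test_that("features are invariant under the double normalization reflection", {
  sim <- generate_match(match_scenario(n_possessions = 4, seed = 13))
  seg <- segment_possessions(sim$events, sim$tracking)
  p <- seg[[1]]
  p$tracking <- normalize_attack_direction(p$tracking, p$team)
  once <- summarize_possession(p, min_frames = 200)
  p2 <- p
  p2$tracking <- pitchspace:::reflect_dataset(pitchspace:::reflect_dataset(p2$tracking))
  twice <- summarize_possession(p2, min_frames = 200)
  expect_equal(twice, once, tolerance = 1e-9)
})
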