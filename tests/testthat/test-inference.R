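test_that("summary-based t equals the raw-sample Welch and pooled tests", {
  set.seed(201)
  for (i in 1:10) {
    a <- rnorm(40, 10, 2); b <- rnorm(55, 11, 3)
    mine <- welch_t(group_summary(a), group_summary(b))
    ref <- t.test(b, a)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
    pooled <- welch_t(group_summary(a), group_summary(b), pooled = TRUE)
    refp <- t.test(b, a, var.equal = TRUE)
    expect_equal(pooled$t, unname(refp$statistic), tolerance = 1e-9)
  }
})

test_that("welch_t is antisymmetric in its groups and degenerate on constant data", {
  a <- group_summary(n = 30, mean = 5, sd = 1.2)
  b <- group_summary(n = 44, mean = 6.1, sd = 2.4)
  ab <- welch_t(a, b); ba <- welch_t(b, a)
  expect_equal(ab$t, -ba$t, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  z <- group_summary(n = 10, mean = 3, sd = 0)
  expect_true(is.na(welch_t(z, z)$t))
})

test_that("effect-size bands follow the standardized-difference thresholds", {
  mk <- function(m) group_summary(n = 50, mean = m, sd = 1)
  expect_identical(cohens_d(mk(0), mk(0))$band, "trivial")
  expect_identical(cohens_d(mk(0), mk(1))$band, "moderate")   # |d| = 1.0
  expect_identical(cohens_d(mk(0), mk(2.5))$band, "very large")
  expect_identical(cohens_d(mk(0), mk(0.2))$band, "small")    # boundary up
  expect_identical(cohens_d(mk(0), mk(1.2))$band, "large")
  d <- cohens_d(mk(0), mk(1))
  expect_lt(d$ci[1], d$d); expect_gt(d$ci[2], d$d)
})

test_that("MBI probabilities sum to one and the label respects rescaling", {
  set.seed(202)
  for (i in 1:10) {
    a <- rlnorm(60); b <- rlnorm(60, 0.1)
    r <- mbi_compare(a, b)
    expect_equal(sum(r$probs), 1, tolerance = 1e-9)
    c <- runif(1, 0.5, 20)
    r2 <- mbi_compare(c * a, c * b)
    expect_identical(r2$label, r$label)
    expect_equal(r2$probs, r$probs, tolerance = 1e-9)
    # label bookkeeping: unclear iff both substantial directions exceed 5%
    expect_identical(r$label == "unclear",
                     r$probs[["positive"]] > 0.05 &&
                       r$probs[["negative"]] > 0.05)
  }
})

test_that("extreme separation is most likely positive; huge null samples are most likely trivial", {
  set.seed(203)
  a <- rlnorm(100, 0, 0.1); b <- rlnorm(100, 10 * 0.1, 0.1)
  expect_identical(mbi_compare(a, b)$label, "most likely +")
  a0 <- rlnorm(10000, 1, 0.3); b0 <- rlnorm(10000, 1, 0.3)
  r0 <- mbi_compare(a0, b0)
  expect_gt(r0$probs[["trivial"]], 0.99)
  expect_identical(r0$label, "most likely trivial")
})

test_that("MBI validates its inputs", {
  expect_error(mbi_compare(c(1, 2), c(-1, 2)), "positive")
  expect_error(mbi_compare(1, c(1, 2)), "n >= 2")
  expect_silent(mbi_compare(c(1, -2, 3), c(2, 3, -4),
                            mbi_config(log_transform = FALSE)))
})

test_that("compare_all recovers planted effect directions on all variables", {
  eff <- setNames(rep(c(0.6, -0.6), length.out = 15),
                  possession_feature_names())
  tab <- generate_two_group_features(eff, n = 400, seed = 77)
  cmp <- compare_all(tab, group_col = "team", reference = "a")
  expect_s3_class(cmp, "mbi_comparison")
  expect_identical(nrow(cmp), 15L)
  expect_identical(sign(cmp$percent_diff), sign(unname(eff[cmp$variable])))
  # percent CLs bracket the estimate, probabilities are coherent
  expect_true(all(cmp$cl_lower < cmp$percent_diff &
                    cmp$percent_diff < cmp$cl_upper))
  expect_equal(cmp$p_positive + cmp$p_trivial + cmp$p_negative, rep(1, 15),
               tolerance = 1e-9)
})

test_that("compare_all rejects degenerate grouping", {
  tab <- generate_two_group_features(n = 20, seed = 5)
  one <- tab[tab$team == "a", ]
  expect_error(compare_all(one, group_col = "team"), "two groups")
  expect_error(compare_all(tab, group_col = "nope"), "grouping column")
})

test_that("optional multiplicity adjustment is off by default and monotone when on", {
  tab <- generate_two_group_features(n = 100, seed = 9)
  raw <- compare_all(tab, group_col = "team")
  expect_identical(raw$p_adjusted, raw$p)
  bh <- compare_all(tab, group_col = "team",
                    config = mbi_config(p_adjust = "BH"))
  expect_true(all(bh$p_adjusted >= bh$p - 1e-15))
})
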