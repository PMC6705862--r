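#' Group summary
#'
#' Sample size, mean and SD for one group — either computed from raw values
#' or entered directly from a published summary table.
#'
#' @param x raw sample values, or `NULL` when `n`, `mean`, `sd` are given.
#' @param n,mean,sd summary statistics (used when `x` is `NULL`).
#' @param label optional group label.
#' @return An object of class `group_summary`.
#' @examples
#' group_summary(n = 373, mean = 28.87, sd = 18.36, label = "Team")
#' @export
group_summary <- function(x = NULL, n = NULL, mean = NULL, sd = NULL,
                          label = NULL) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    n <- length(x); m <- base::mean(x); s <- stats::sd(x)
  } else {
    stopifnot(is_count(n), is_scalar_num(mean), is_scalar_num(sd), sd >= 0)
    m <- mean; s <- sd
  }
  if (n < 2L) stop_usage("group_summary needs n >= 2")
  structure(list(n = as.integer(n), mean = m, sd = s, values = x,
                 label = label), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary>%s n = %d, mean = %.4g, sd = %.4g\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              x$n, x$mean, x$sd))
  invisible(x)
}

#' Independent two-group t-test from summaries
#'
#' Welch's t (default) or pooled-variance t computed from group summaries:
#' `t = (mean_b - mean_a) / sqrt(sd_a^2/n_a + sd_b^2/n_b)` with
#' Welch–Satterthwaite degrees of freedom and a two-sided p-value. Both SDs
#' zero make the statistic undefined (`NA`, flagged).
#'
#' @param a,b [group_summary()] objects (a = reference group; a positive t
#'   means b has the larger mean).
#' @param pooled use the pooled-variance form instead of Welch.
#' @return List with `t`, `df`, `p`.
#' @examples
#' welch_t(group_summary(n = 373, mean = 28.87, sd = 18.36),
#'         group_summary(n = 369, mean = 31.88, sd = 22.52))
#' @export
welch_t <- function(a, b, pooled = FALSE) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$sd == 0 && b$sd == 0)
    return(list(t = structure(NA_real_, undefined = TRUE), df = NA_real_,
                p = NA_real_))
  if (pooled) {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (b$mean - a$mean) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

es_bands <- c(trivial = 0.2, small = 0.6, moderate = 1.2, large = 2.0)

es_band_label <- function(d) {
  ad <- abs(d)
  if (ad < 0.2) "trivial"
  else if (ad < 0.6) "small"
  else if (ad < 1.2) "moderate"
  else if (ad < 2.0) "large"
  else "very large"
}

#' Standardized mean difference (Cohen's d)
#'
#' `d = (mean_b - mean_a) / pooled SD` with a 95% CI from the usual
#' large-sample (noncentral-approximation) standard error, and the
#' qualitative band: < 0.2 trivial, 0.2–0.6 small, 0.6–1.2 moderate,
#' 1.2–2.0 large, above 2.0 very large.
#'
#' @inheritParams welch_t
#' @param cl_level confidence level; default 0.95.
#' @return List with `d`, `ci` (length 2), `band`.
#' @export
cohens_d <- function(a, b, cl_level = 0.95) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 == 0)
    return(list(d = structure(NA_real_, undefined = TRUE),
                ci = c(NA_real_, NA_real_), band = NA_character_))
  d <- (b$mean - a$mean) / sqrt(sp2)
  se <- sqrt((a$n + b$n) / (a$n * b$n) + d^2 / (2 * (a$n + b$n)))
  z <- stats::qnorm(1 - (1 - cl_level) / 2)
  list(d = d, ci = c(d - z * se, d + z * se), band = es_band_label(d))
}

#' Magnitude-based inference configuration
#'
#' The comparison is run on log-transformed values (to reduce non-uniformity
#' of error across the strictly positive possession variables), the smallest
#' worthwhile change is 0.2 between-subject standard deviations on the log
#' scale, and probabilities that the true difference is substantially
#' positive / trivial / substantially negative are mapped to the qualitative
#' vocabulary: <0.5% most unlikely, 0.5–5% very unlikely, 5–25% unlikely,
#' 25–75% possibly, 75–95% likely, 95–99% very likely, >99% most likely.
#'
#' @param swc_factor smallest-worthwhile-change multiplier on the
#'   between-subject SD; default 0.2.
#' @param cl_level confidence level for the percent-difference limits.
#' @param log_transform analyse on the log scale? Default TRUE.
#' @param pooled_t use pooled-variance t-tests in [compare_all()].
#' @param p_adjust multiple-testing correction for [compare_all()] p-values
#'   (`"none"`, the default, or any [stats::p.adjust()] method such as
#'   `"BH"`).
#' @return An object of class `mbi_config`.
#' @export
mbi_config <- function(swc_factor = 0.2, cl_level = 0.95,
                       log_transform = TRUE, pooled_t = FALSE,
                       p_adjust = "none") {
  stopifnot(is_scalar_num(swc_factor), swc_factor > 0,
            is_scalar_num(cl_level), cl_level > 0, cl_level < 1,
            is_flag(log_transform))
  structure(list(swc_factor = swc_factor, cl_level = cl_level,
                 log_transform = log_transform, pooled_t = pooled_t,
                 p_adjust = p_adjust,
                 band_edges = c(0.5, 5, 25, 75, 95, 99),
                 band_labels = c("most unlikely", "very unlikely", "unlikely",
                                 "possibly", "likely", "very likely",
                                 "most likely")),
            class = "mbi_config")
}

mbi_band_word <- function(prob_pct, config) {
  config$band_labels[findInterval(prob_pct, config$band_edges) + 1L]
}

#' Magnitude-based inference for two groups
#'
#' Computes the between-group difference on log-means, back-transformed to a
#' percent difference with confidence limits, then the probabilities that
#' the true difference exceeds +SWC, lies within the trivial band, or falls
#' below -SWC (SWC = `swc_factor` x pooled between-subject SD of the logs),
#' using the t distribution of the difference. The label is the band word
#' for the most probable outcome plus its direction (`+`, `-`, `trivial`);
#' when both substantial directions exceed 5% the effect is `unclear`.
#'
#' @param a_values,b_values raw samples for the two groups (a = reference;
#'   positive percent differences mean b is larger).
#' @param config an [mbi_config()].
#' @return List with `percent_diff`, `cl` (lower, upper percent limits),
#'   `swc_log`, `probs` (positive, trivial, negative; sums to 1), `label`.
#' @export
mbi_compare <- function(a_values, b_values, config = mbi_config()) {
  a_values <- a_values[!is.na(a_values)]
  b_values <- b_values[!is.na(b_values)]
  if (length(a_values) < 2L || length(b_values) < 2L)
    stop_usage("mbi_compare needs n >= 2 per group")
  if (config$log_transform) {
    if (any(a_values <= 0) || any(b_values <= 0))
      stop_usage("log transform requires strictly positive values")
    la <- log(a_values); lb <- log(b_values)
  } else {
    la <- a_values; lb <- b_values
  }
  na <- length(la); nb <- length(lb)
  diff <- mean(lb) - mean(la)
  va <- stats::var(la) / na; vb <- stats::var(lb) / nb
  se <- sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  sp <- sqrt(((na - 1) * stats::var(la) + (nb - 1) * stats::var(lb)) /
               (na + nb - 2))
  swc <- config$swc_factor * sp
  tcrit <- stats::qt(1 - (1 - config$cl_level) / 2, df)
  back <- function(z) if (config$log_transform) 100 * (exp(z) - 1) else z
  p_pos <- if (se == 0) as.numeric(diff > swc) else
    stats::pt((diff - swc) / se, df)
  p_neg <- if (se == 0) as.numeric(diff < -swc) else
    stats::pt((-swc - diff) / se, df)
  p_triv <- 1 - p_pos - p_neg
  probs <- c(positive = p_pos, trivial = p_triv, negative = p_neg)
  if (p_pos > 0.05 && p_neg > 0.05) {
    label <- "unclear"
  } else {
    k <- which.max(probs)
    word <- mbi_band_word(100 * probs[k], config)
    label <- paste(word, c("+", "trivial", "-")[k])
  }
  list(percent_diff = back(diff),
       cl = c(lower = back(diff - tcrit * se),
              upper = back(diff + tcrit * se)),
       swc_log = swc, probs = probs, label = label)
}

#' Compare all possession variables between two groups
#'
#' Runs the full two-group analysis — group summaries, percent difference
#' with confidence limits and magnitude-based label, Welch t-test, and
#' standardized difference with its band — for every possession variable,
#' mirroring a descriptive-plus-inferential comparison table. Missing values
#' are dropped listwise per variable, with counts recorded.
#'
#' @param features a data frame holding the feature columns and a group
#'   column.
#' @param group_col name of the two-level grouping column.
#' @param reference level of `group_col` to use as the reference (group a);
#'   defaults to the first level encountered.
#' @param variables feature columns to compare; defaults to the 15
#'   possession variables present in `features`.
#' @param config an [mbi_config()].
#' @return A data frame of class `mbi_comparison`, one row per variable,
#'   with group means/SDs, percent differences and confidence limits, MBI
#'   labels and probabilities, t statistics, effect sizes and bands.
#' @export
compare_all <- function(features, group_col = "team", reference = NULL,
                        variables = NULL, config = mbi_config()) {
  stopifnot(is.data.frame(features))
  if (!group_col %in% names(features))
    stop_usage("no grouping column '", group_col, "' in the feature table")
  g <- as.character(features[[group_col]])
  lev <- unique(g)
  if (length(lev) < 2L) stop_usage("need two groups, found ", length(lev))
  if (length(lev) > 2L) stop_usage("more than two groups in '", group_col, "'")
  if (is.null(reference)) reference <- lev[1L]
  if (!reference %in% lev) stop_usage("unknown reference group: ", reference)
  other <- setdiff(lev, reference)
  if (is.null(variables))
    variables <- intersect(feature_names, names(features))
  rows <- lapply(variables, function(v) {
    xa <- features[[v]][g == reference]
    xb <- features[[v]][g == other]
    n_missing <- sum(is.na(xa)) + sum(is.na(xb))
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L)
      stop_usage("group with n < 2 for variable ", v)
    a <- group_summary(xa, label = reference)
    b <- group_summary(xb, label = other)
    tt <- welch_t(a, b, pooled = config$pooled_t)
    es <- cohens_d(a, b, cl_level = config$cl_level)
    # variables with non-positive values (e.g. zero opponent counts) cannot
    # be log-transformed; they are compared on the raw scale instead
    cfg_v <- config
    if (config$log_transform && (any(xa <= 0) || any(xb <= 0)))
      cfg_v$log_transform <- FALSE
    mbi <- mbi_compare(xa, xb, cfg_v)
    data.frame(variable = v, group_a = reference, group_b = other,
               n_a = a$n, mean_a = a$mean, sd_a = a$sd,
               n_b = b$n, mean_b = b$mean, sd_b = b$sd,
               percent_diff = mbi$percent_diff,
               cl_lower = mbi$cl[["lower"]], cl_upper = mbi$cl[["upper"]],
               p_positive = mbi$probs[["positive"]],
               p_trivial = mbi$probs[["trivial"]],
               p_negative = mbi$probs[["negative"]],
               inference = mbi$label,
               mbi_scale = if (cfg_v$log_transform) "log" else "raw",
               t = as.numeric(tt$t), df = tt$df, p = tt$p,
               d = as.numeric(es$d), d_lower = es$ci[1L], d_upper = es$ci[2L],
               d_band = es$band, n_missing = n_missing,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = config$p_adjust)
  rownames(out) <- NULL
  class(out) <- c("mbi_comparison", "data.frame")
  out
}

#' @export
print.mbi_comparison <- function(x, digits = 2, ...) {
  cat(sprintf("<mbi_comparison> %s (n = %d) vs %s (n = %d)\n",
              x$group_a[1L], max(x$n_a), x$group_b[1L], max(x$n_b)))
  df <- data.frame(variable = x$variable,
                   a = sprintf("%.2f±%.2f", x$mean_a, x$sd_a),
                   b = sprintf("%.2f±%.2f", x$mean_b, x$sd_b),
                   `diff%` = sprintf("%.1f; ±%.1f", x$percent_diff,
                                     (x$cl_upper - x$cl_lower) / 2),
                   inference = x$inference,
                   t = round(x$t, 2),
                   p = format.pval(x$p, digits = 2, eps = .001),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
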