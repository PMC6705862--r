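#' Pipeline run configuration
#'
#' Describes a full analysis run: one entry per match, each labeled with
#' exactly one opponent-quality context (e.g. `"TOP"` or `"BOTTOM"`), either
#' a [match_scenario()] to simulate or paths to tracking/event files; plus
#' the focal team label, the module configurations, an output directory and
#' a seed.
#'
#' @param matches list of match entries. Each entry is a list with
#'   `context` (character label) and either `scenario` (a `match_scenario`)
#'   or `tracking` + `events` file paths (with optional `format`).
#' @param team label of the focal team whose possessions form the "team"
#'   group; default `"home"`.
#' @param out_dir directory for the run artifacts.
#' @param seed integer master seed; per-match seeds derive from it.
#' @param seg_config a [segmentation_config()].
#' @param apen_params an [apen_params()].
#' @param mbi a [mbi_config()].
#' @param fa an [fa_config()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(matches, team = "home", out_dir, seed,
                       seg_config = segmentation_config(),
                       apen_params = pitchspace::apen_params(),
                       mbi = mbi_config(), fa = fa_config()) {
  if (missing(seed)) stop_usage("run_config requires a seed")
  if (missing(out_dir)) stop_usage("run_config requires an output directory")
  if (!length(matches)) stop_usage("no matches in the configuration")
  for (i in seq_along(matches)) {
    m <- matches[[i]]
    ctx <- m$context
    if (is.null(ctx) || length(ctx) != 1L || is.na(ctx) || ctx == "")
      stop_usage("match ", i, " has no context label")
    if (is.null(m$scenario)) {
      if (is.null(m$tracking) || is.null(m$events))
        stop_usage("match ", i, " needs a scenario or tracking+events paths")
      if (!file.exists(m$tracking))
        stop_usage("match ", i, ": no such tracking file: ", m$tracking)
      if (!file.exists(m$events))
        stop_usage("match ", i, ": no such events file: ", m$events)
    } else stopifnot(inherits(m$scenario, "match_scenario"))
  }
  structure(list(matches = matches, team = team, out_dir = out_dir,
                 seed = as.integer(seed), seg_config = seg_config,
                 apen_params = apen_params, mbi = mbi, fa = fa),
            class = "run_config")
}

#' Run the full possession-analysis pipeline
#'
#' For every configured match: obtain tracking and events (simulating when a
#' scenario is given), segment possessions with the inclusion criteria,
#' attack-normalize each included possession, and compute the fifteen
#' possession variables. Then, per context, compare the focal team against
#' its opponents (descriptive summaries, percent differences with
#' magnitude-based labels, Welch t-tests, standardized differences) and fit
#' a varimax-rotated PCA per group. Artifacts written to `config$out_dir`:
#'
#' * `possessions.csv` — manifest of every candidate sequence per match;
#' * `features.csv` — one row per included possession;
#' * `comparison_<context>.csv` — the two-group comparison table;
#' * `factor_<group>_<context>.csv` — loadings tables (team and opponent per
#'   context);
#' * `manifest.json` — versions, seed, per-match and per-filter counts.
#'
#' The run is a pure function of (inputs, configuration, seed): repeated runs
#' produce identical artifacts.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `features`, `comparisons`, `factors`,
#'   `manifest` and the artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  feats <- list(); manifests <- list()
  for (i in seq_along(config$matches)) {
    m <- config$matches[[i]]
    if (!is.null(m$scenario)) {
      sc <- m$scenario
      sc$seed <- (config$seed + i) %% .Machine$integer.max
      sim <- generate_match(sc)
      tracking <- sim$tracking; events <- sim$events
    } else {
      tracking <- read_tracking(m$tracking, format = m$format %||% "csv")
      events <- read_events(m$events)
    }
    seg_cfg <- config$seg_config
    seg_cfg$sampling_rate_hz <- tracking$sampling_rate_hz
    seg_cfg$min_frames <- as.integer(round(seg_cfg$min_duration_s *
                                             tracking$sampling_rate_hz))
    poss <- segment_possessions(events, tracking, seg_cfg)
    man <- possession_manifest(poss)
    man <- cbind(match_id = i, context = m$context, man,
                 stringsAsFactors = FALSE)
    manifests[[i]] <- man
    if (length(poss)) {
      ft <- possession_features(poss, entropy_params = config$apen_params,
                                min_frames = seg_cfg$min_frames,
                                normalize = TRUE)
      ft <- cbind(match_id = i, context = m$context,
                  group = ifelse(ft$team == config$team, "team", "opponent"),
                  as.data.frame(ft), stringsAsFactors = FALSE)
      feats[[i]] <- ft
    }
  }
  features <- do.call(rbind, feats)
  manifest_df <- do.call(rbind, manifests)
  rownames(features) <- rownames(manifest_df) <- NULL

  utils::write.csv(manifest_df, file.path(config$out_dir, "possessions.csv"),
                   row.names = FALSE)
  utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                   row.names = FALSE)

  comparisons <- list(); factors <- list(); group_sizes <- list()
  for (ctx in unique(manifest_df$context)) {
    fx <- features[features$context == ctx, , drop = FALSE]
    cmp <- compare_all(fx, group_col = "group", reference = "team",
                       config = config$mbi)
    comparisons[[ctx]] <- cmp
    utils::write.csv(as.data.frame(cmp),
                     file.path(config$out_dir,
                               paste0("comparison_", ctx, ".csv")),
                     row.names = FALSE)
    group_sizes[[ctx]] <- table(fx$group)
    for (grp in c("team", "opponent")) {
      gx <- fx[fx$group == grp, feature_names, drop = FALSE]
      key <- paste0(grp, "_", ctx)
      fm <- withCallingHandlers(
        tryCatch(pca_varimax(gx, config$fa),
                 error = function(e) {
                   message("factor model ", key, " skipped: ",
                           conditionMessage(e))
                   NULL
                 }),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!is.null(fm)) {
        factors[[key]] <- fm
        write_factor_csv(fm, file.path(config$out_dir,
                                       paste0("factor_", key, ".csv")))
      }
    }
  }

  manifest <- list(
    package = "pitchspace",
    version = as.character(utils::packageVersion("pitchspace")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    team = config$team,
    n_matches = length(config$matches),
    contexts = lapply(group_sizes, function(tt)
      as.list(stats::setNames(as.integer(tt), names(tt)))),
    n_candidates = nrow(manifest_df),
    n_included = sum(manifest_df$included),
    exclusions = as.list(table(
      manifest_df$exclusion_reason[!manifest_df$included])),
    min_frames = config$seg_config$min_frames)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(features = features, manifest_df = manifest_df,
                 comparisons = comparisons, factors = factors,
                 manifest = manifest, out_dir = config$out_dir))
}
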