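---
title: "Possession-level spatiotemporal analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Possession-level spatiotemporal analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchspace)
```

## The analysis in one paragraph

`pitchspace` turns 25 Hz 2-D tracking of 22 players and the ball into a
possession-level description of collective behaviour. A match is cut into
team ball-possession sequences; each included sequence is summarized by
fifteen variables covering the ball path (distance, speed, speed
variability, speed regularity, length/width circulation ratio), the space
the teams occupy (convex-hull effective playing space of the team in
possession; length and width of the box containing all twenty outfield
players), and the situation when the possession ends (deepest attacker,
free space in front of them, defenders inside that space). Two statistical
stages follow: two-group comparisons of the focal team against its
opponents (Welch t-tests, standardized differences, and magnitude-based
inference on log-transformed values) and a correlation-matrix PCA with
varimax rotation that exposes the latent structure among the fifteen
variables. A seeded synthetic match generator reproduces the statistical
shape of elite-match tracking so that every stage is testable without
proprietary feeds.

## Coordinates and attack-direction normalization

Coordinates use a corner origin: x runs goal-to-goal in `[0, length_m]`
(default 105), y runs touchline-to-touchline in `[0, width_m]` (default
68). All depth-related metrics presuppose the possession team attacks
toward increasing x, so `normalize_attack_direction()` reflects the whole
frame set through the pitch centre, `(x, y) -> (L - x, W - y)`, whenever
needed. The reflection is an isometry, so every distance-, area- and
extent-based variable is unaffected; only depth coordinates change frame.
Which end a team is attacking is not something a raw coordinate file
declares, so the default (`orientation = "auto"`) infers it from the
goalkeeper's mean position — keepers stay near their own goal for
essentially the whole match — with explicit `"positive"` / `"negative"`
overrides for unusual data.

## Segmentation and inclusion criteria

A possession starts when a team gains the ball and ends when it is lost or,
for shot endings, at the frame of the shot itself (not when the ball later
crosses the line); `segment_possessions()` applies that adjustment when a
shot precedes a ball-out event. Inclusion requires:

* **duration of at least 8 s** — 200 frames at 25 Hz
  (`segmentation_config()$min_frames`). The limit exists for the entropy
  estimate: approximate entropy destabilizes on short records, so
  possessions below it are dropped entirely rather than padded;
* **no set piece anywhere in the sequence** — the whole sequence is
  excluded, not just the frames after the flag, because a restart changes
  the dynamics of the entire episode;
* **no tracking dropout longer than 5 frames** among the twenty outfield
  players. Dropouts of up to 5 frames (0.2 s) are linearly interpolated at
  read time, which is standard practice for optical tracking; longer gaps
  reject the sequence rather than risk splicing artefacts.

When no event annotations exist, `infer_possessions_from_touches()` offers
a positional fallback: a team is in possession once one of its outfield
players is nearest to the ball within 1.5 m for at least 5 consecutive
frames. The hysteresis (5 frames) prevents rapid alternation from
generating spurious possessions. Annotated events are always authoritative;
the heuristic is a stand-in.

## The fifteen variables

For a possession of the team attacking +x:

| variable | definition | units |
|---|---|---|
| `duration_s` | frame span / sampling rate | s |
| `ball_distance_m` | sum of frame-to-frame ball displacements | m |
| `ball_speed_mean_kmh` | mean of the per-transition speed series | km/h |
| `ball_speed_cv_pct` | 100 · sd / mean of that series | % |
| `ball_speed_apen_au` | normalized approximate entropy of that series | a.u. |
| `ball_lw_ratio_au` | Σ\|Δx\| / Σ\|Δy\| of the ball path | — |
| `eps_mean_m2`, `eps_cv_pct` | per-frame convex-hull area of the possession team's 10 outfield players: mean and CV% | m², % |
| `game_length_mean_m`, `game_length_cv_pct` | per-frame x-extent of all 20 outfield players | m, % |
| `game_width_mean_m`, `game_width_cv_pct` | per-frame y-extent of all 20 outfield players | m, % |
| `deepest_location_m` | max x among the possession team's outfield players at the end frame | m |
| `offensive_space_m2` | `(length_m − deepest) · width_m` at the end frame | m² |
| `n_opponents_in_space` | opposing outfield players with x strictly beyond the deepest attacker at the end frame | count |

Design choices worth spelling out:

* **Goalkeepers are excluded everywhere.** They are carried in the data
  (and used to infer attack direction) but all space metrics are defined on
  outfield players, whose positioning reflects collective tactics rather
  than a fixed role.
* **The length/width ratio uses cumulative absolute displacements**, not
  net displacement. A net ratio would be dominated by the start and end
  points and is undefined for closed paths; the cumulative form measures
  how the ball circulated throughout.
* **Offensive available space is a full-width rectangle** from the deepest
  attacker to the goal line, evaluated at the end frame. This is the
  simplest geometric reading of "the space in front of the deepest
  player", and it reproduces the tight inverse coupling between depth and
  free space that the factor models show (paired loadings of opposite
  sign). The cost of this simplicity is exact collinearity: the rectangle
  is an affine function of the deepest location, so the 15-variable
  correlation matrix of pipeline output is singular. The PCA itself is
  unaffected (one eigenvalue is zero); Bartlett's test and the KMO measure,
  which need a determinant and an inverse, are then reported as `NA` with a
  warning. On data where the two metrics are measured independently (as in
  published match tables, where the free-space means differ from the exact
  rectangle values), both statistics compute normally.
* **Ball speed uses raw frame differences by default.** An optional
  centred moving average (`smoothing_window`, odd) exists but is off: any
  smoothing alters CV% and entropy, so the documented default keeps those
  comparable across studies.
* **Undefined ratios become missing values.** A zero-mean series has no
  CV%; a purely lengthwise ball path has no length/width ratio. Both come
  back as flagged `NA`, are carried as missing in the feature table, and
  are removed listwise per variable downstream, with counts logged.

## Normalized approximate entropy

`apen()` implements the classic regularity statistic for a series
`x_1..x_n`: embed overlapping templates of length `m`, count for each
template the fraction of templates (itself included) within Chebyshev
distance `r`, average the log of those fractions into `Φ_m`, and report
`ApEn = Φ_m − Φ_{m+1}`. Defaults are the conventional `m = 2` and
`r = 0.2` standard deviations of the series. Because `r` scales with the
SD, the statistic is invariant to affine transforms of the series, and a
constant series returns exactly 0 — every distance is `0 ≤ 0`, so both `Φ`
terms vanish identically rather than approximately.

The normalization that makes possessions of different lengths comparable
is provided in two modes, because the literature's "normalized ApEn" admits
more than one reading:

* **amplitude normalization** (default): ApEn of the z-scored series. By
  the affine invariance this equals plain ApEn up to floating error (the
  implementation asserts it); its value is to make the normalization
  explicit in reports. Output is clipped into the contractual `[0, 2]`
  range.
* **shuffle-surrogate normalization** (`shuffles > 0`, default 20 when
  enabled, seeded): the series' ApEn divided by the mean ApEn of random
  permutations of itself, rescaled by 2. A structureless series is
  statistically indistinguishable from its own shuffles and lands near 2;
  strongly patterned series land near 0.

The 200-frame minimum possession length exists precisely to keep these
estimates stable; tests that need shorter series pass `allow_short = TRUE`
explicitly.

One empirical caveat the property tests encode: ApEn increases with the
noise level of a sine-plus-noise series only in the low-noise regime.
Because the tolerance scales with the total SD, the statistic saturates at
the white-noise plateau once noise dominates, so monotonicity is asserted
for noise amplitudes 0–0.4 on a unit carrier, not globally.

## Two-group statistics

`compare_all()` mirrors a descriptive-plus-inferential match table: for
each variable it reports group means and SDs, a Welch t-test (pooled form
by flag), a standardized mean difference with a 95% CI and the qualitative
bands (below 0.2 trivial, 0.2–0.6 small, 0.6–1.2 moderate, 1.2–2.0 large,
above 2.0 very large), and magnitude-based inference:

1. log-transform both samples (the possession variables are strictly
   positive and right-skewed; logs stabilize the error),
2. the difference of log-means back-transforms to a percent difference
   with confidence limits,
3. the smallest worthwhile change is 0.2 × the between-subject SD on the
   log scale. In a cross-sectional two-group design the between-subject SD
   is the pooled within-group SD, which is what the implementation uses,
4. the t distribution of the difference yields probabilities that the true
   effect is substantially positive, trivial, or substantially negative;
   the label is the band word for the most probable outcome
   (<0.5% most unlikely, 0.5–5% very unlikely, 5–25% unlikely, 25–75%
   possibly, 75–95% likely, 95–99% very likely, >99% most likely) plus its
   direction, or `unclear` when both substantial directions exceed 5%.

Opponent counts can be zero, which no log transform survives; such
variables fall back to a raw-scale comparison and the `mbi_scale` column
records which scale was used. No multiplicity correction is applied by
default, matching common practice for these descriptive tables; a
Benjamini–Hochberg option exists behind `mbi_config(p_adjust = "BH")`.

## Factor analysis

`pca_varimax()` follows the SPSS-style recipe: correlation matrix of the
complete-case rows, eigendecomposition, loadings as eigenvectors scaled by
the root eigenvalues, retention of components with eigenvalues strictly
greater than 1.0 (with a warning when they explain less than 60% of total
variance — the two rules can disagree and the eigenvalue rule is taken as
primary), and varimax rotation with Kaiser row normalization. Two
numerical details:

* a single `stats::varimax()` call can stop on a criterion plateau short
  of the optimum, so the rotation is restarted on its own output until the
  incremental rotation is the identity (1e-7) or the raw varimax criterion
  stops improving in relative terms (1e-7). Orthogonality — hence
  preservation of per-variable communalities — holds at every step;
* reported solutions are made deterministic by two conventions: each
  component's largest-magnitude loading is given a positive sign, and
  components are ordered by rotated variance.

Rotated loadings at or above 0.60 in magnitude are flagged as practically
significant; Bartlett's sphericity test and the overall and per-variable
KMO adequacy measures accompany every model.

## The synthetic match generator

`match_scenario()` fixes the study conditions the analysis assumes, and
`generate_match()` realizes them reproducibly from a seed:

* **sampling and geometry**: 25 Hz, 105 × 68 m pitch, 10 outfield players
  plus a goalkeeper per team;
* **possession durations**: log-normal with median 24 s and log-SD 0.6
  (mean ≈ 29 s), capped at 90 s, so a realistic ~3% of episodes fall under
  the 8 s inclusion bound and exercise the filter; set pieces hit a
  possession with probability 0.1, shots end one with probability 0.15;
* **player dynamics**: each team's ten outfield players follow
  mean-reverting (AR(1), φ = 0.995) noise with a 1.2 m stationary SD
  around the vertices of an octagonal formation. The formation's corner
  cut is chosen so the anchor hull matches the scenario's effective-
  playing-space target (defaults 985 m² for the focal team, 909 m² for
  opponents, the scale observed in elite matches), and a small Monte-Carlo
  calibration at generation time corrects for the hull inflation the
  jitter induces — time-averaged hull areas land within about 2% of
  target. φ near 1 keeps per-frame steps at realistic player speeds
  (~3 m/s). Formation centres drift forward through the possession so the
  deepest attacker ends near the 83 m target;
* **ball model**: the held ball trails its holder with damping (nearly
  still), then travels in straight passes to one of the five nearest
  teammates at ~12 m/s with jitter. This dwell/pass alternation is what
  gives the speed series its realistic intermittency — means near
  20–25 km/h with CV% around 85–110 — and a non-trivial entropy gradient;
* **ground truth**: every possession's team, span (shot-adjusted),
  set-piece flag and expected inclusion status are logged, which is what
  the segmentation recovery tests compare against.

What the generator does **not** emulate: tactical structure (pressing,
marking, transitions), player substitutions or fatigue, measurement noise
of a specific vendor, and any dependence of ball speed on pitch zone. Tests
that pass on this synthetic data therefore validate the *computational*
pipeline — geometry, filtering, statistics — not claims about real match
behaviour.

`generate_two_group_features()` skips the tracking layer entirely and
draws the fifteen variables directly as log-normals with a planted
standardized difference per variable and a block latent-factor structure
(5 factors by default, loadings 0.85). It drives the inference and factor
recovery tests, where ground truth must be exact by construction.

## Problem sizes and reproducibility

The test suite runs the heavier checks at sizes chosen to make the
statistical assertions stable: hull-vs-oracle on 1,000 random frames,
entropy-vs-oracle on 50 series of length 120, two-factor recovery at
n = 2,000, null magnitude-based inference at n = 10,000 per group,
permutation type-I control over 200 replicates, and generator parameter
recovery at 100 possessions per team. Every stochastic step is seeded:
`generate_match()` is a pure function of its scenario, and
`run_pipeline()` of (inputs, configuration, seed) — reruns produce
byte-identical artifacts, which the suite asserts.

## Known limitations

* The rectangle definition of offensive available space is a documented
  approximation; a visual/polygonal definition would decouple it from the
  deepest location and restore an invertible correlation matrix.
* Magnitude-based inference is reported in its spreadsheet-era form
  (probability bands over a smallest worthwhile change). It is included
  for comparability; the t-tests and standardized differences carry the
  conventional inferential weight.
* The positional possession heuristic has no notion of passes in flight:
  a long pass temporarily leaves no player in control and can fragment
  possessions that annotated events would keep whole.
* Single-period frame indexing: multi-period matches should be supplied
  as one dataset per period (frame indices must stay gapless within a
  dataset).
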