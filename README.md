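# warpnet

Symptom-network analysis for short panel time series via dynamic time
warping (DTW).

Longitudinal clinical cohorts — here the motivating case is an
eating-disorder intervention cohort measured at six waves on twelve
attributes (ED psychopathology, binge eating, vomiting, laxative use,
anxiety, depression, BMI, social support, self-efficacy, well-being,
quality of life, self-rated health) — raise two questions that ordinary
cross-sectional networks cannot answer: which attributes *change
together* within a person, and which attributes *change first*.
`warpnet` answers both with pairwise DTW at the individual level,
aggregated to the group:

- **Undirected network.** After reverse-coding inverted-valence
  attributes, centering within person and standardizing at the group
  level, each subject's attribute pairs are aligned with banded DTW
  (Sakoe–Chiba window *w* = 1, *symmetric2* step pattern:
  `g(i,j) = min(g(i−1,j−1) + 2c, g(i−1,j) + c, g(i,j−1) + c)`, cost
  `c = |xᵢ − yⱼ|`, normalized by `N + M`). Averaging distances over
  imputation replicates and subjects gives a group dissimilarity matrix;
  Ward clustering with silhouette-selected *k* partitions the attributes
  into *dimensions*, visualized as a network with similarity weights
  `1/(1 + d)` and valence-colored edges.
- **Directed network.** A forward-only lag-1 DTW maps each wave of a
  candidate leader onto the same or the next wave of a follower. The
  lead–lag contrast `δ(a→b) = D(b→a) − D(a→b)` is positive when `a`'s
  changes precede `b`'s; one-sided t-tests across subjects (α = 0.05)
  draw the arrows, and positive-part strength sums give each node a
  standardized **out-strength** (temporal lead) and **in-strength**
  (temporal lag) with 95% confidence intervals.
- **Synthetic cohorts.** A generator plants known dimensions (shared
  latent AR(1) factors), a known leader (followers read the leader's
  factor one wave late), inverted valences, monotone dropout, and
  imputation stacks — so recovery of every output can be tested against
  ground truth.
- The DTW dynamic programs ship with an exhaustive path-enumeration
  oracle (`oracle_min_cost()`) and agree with it to machine precision.

## Worked example

```r
library(warpnet)
library(dplyr)

sim <- generate_panel(reference_config(seed = 1))  # 300 subjects, 12 attributes,
fit <- dtw_network(sim$panel, sim$schema)          # planted dimensions 5/2/2/3
fit
#> <dtw_network> 300 subjects, 12 attributes, 1 imputation replicate(s)
#>   dimensions: k = 4 (mean silhouette 0.419, ward.D2 linkage)
#>   directed: 6 significant edge(s), 1 node(s) with significant out-strength
```

The silhouette rule picks k = 4 dimensions, matching the planted 5/2/2/3
structure exactly (`tidy(fit, "clusters")` recovers the planted
memberships; adjusted Rand index 1.0 against `sim$truth`):

```r
tidy(fit, "strengths") |> filter(significant)
#> # A tibble: 3 × 8
#>   node        kind  raw_mean estimate     se  ci_low ci_high significant
#>   <chr>       <fct>    <dbl>    <dbl>  <dbl>   <dbl>   <dbl> <lgl>
#> 1 anxiety     out       1.66   0.685  0.0497 0.587     0.782 TRUE
#> 2 edeq_global in        1.07   0.0944 0.0417 0.0124    0.176 TRUE
#> 3 depression  in        1.06   0.0923 0.0424 0.00893   0.176 TRUE
```

The planted leader (`anxiety`, whose cluster-mates track its latent
factor one wave late) is the only node with significant out-strength —
its standardized estimate 0.69 means its positive lead–lag contrasts sum
to 0.69 SD-units above the average node in the same subjects' networks —
and two of its followers show significant in-strength, i.e., their
changes follow. `autoplot(fit, "strengths")` draws the forest plot;
`"network"`, `"dendrogram"`, `"directed"`, and `"trajectories"` draw the
other standard figures.

File-level orchestration: `cmd_simulate()` (YAML config → cohort files),
`cmd_run()` (panel CSV → all artifacts: distance CSVs, Newick dendrogram,
GraphML/JSON networks, strength and edge tables, deterministic
`run_summary.json`), `cmd_report()` (artifacts → PNG figures + report).
`inst/cli/warpnet` exposes the three as shell subcommands.

Real data enter through `read_panel_long()` / `read_panel_wide()` (one
row per subject-wave-attribute observation) with an attribute schema
(`read_schema()`; a ready 12-attribute schema ships in
`inst/extdata/featback_schema.yaml` and as `default_schema()`).
Incomplete panels are imputed upstream (e.g., chained equations) and
supplied as a stacked CSV via `read_imputation_stack()`; analyses run per
replicate and are averaged.

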