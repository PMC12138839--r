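test_that("generation is bit-identical under a fixed config and seed", {
  cfg <- synthetic_config(n_subjects = 8, n_timepoints = 5,
                          dropout_hazard = 0.1, n_imputations = 2, seed = 42)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$factors, b$truth$factors)
})

test_that("noiseless cluster-mates have identical centered series", {
  cfg <- synthetic_config(
    n_subjects = 4, n_timepoints = 5,
    clusters = list(c1 = c("a", "b")),
    noise_sd = 0, loading = 1, lead_spec = NULL,
    reversed_attributes = character(),
    dropout_hazard = 0, n_imputations = 1, seed = 3
  )
  sim <- generate_panel(cfg)
  ct <- center_within_person(sim$panel)
  for (s in unique(ct$subject)) {
    va <- ct$value[ct$subject == s & ct$attribute == "a"]
    vb <- ct$value[ct$subject == s & ct$attribute == "b"]
    expect_equal(va, vb, tolerance = 1e-12)
    expect_equal(dtw_undirected(va, vb, window = 1)$distance, 0,
                 tolerance = 1e-12)
  }
})

test_that("a noiseless follower is the leader delayed by one step", {
  cfg <- synthetic_config(
    n_subjects = 6, n_timepoints = 6,
    clusters = list(c1 = c("lead", "follow")),
    noise_sd = 0, loading = 1,
    lead_spec = list(leader = "lead", followers = "follow",
                     lag = 1, coupling = 1),
    reversed_attributes = character(),
    dropout_hazard = 0, n_imputations = 1, seed = 4
  )
  sim <- generate_panel(cfg)
  fac <- sim$truth$factors
  for (si in 1:6) {
    lead_vals <- sim$panel$value[sim$panel$subject == sprintf("s%04d", si) &
                                   sim$panel$attribute == "lead"]
    follow_vals <- sim$panel$value[sim$panel$subject == sprintf("s%04d", si) &
                                     sim$panel$attribute == "follow"]
    # remove subject intercepts: differences must line up delayed
    expect_equal(diff(follow_vals)[-1], diff(lead_vals)[-5],
                 tolerance = 1e-12)
  }
  pre <- preprocess_panel(sim$panel, sim$schema)
  dl <- directed_deltas(pre)
  lead_deltas <- dl$delta[dl$from == "lead" & dl$to == "follow"]
  expect_true(all(lead_deltas > 0))
})

test_that("reversed attributes come out negated and valence-flagged", {
  cfg <- synthetic_config(
    n_subjects = 3, n_timepoints = 4,
    clusters = list(c1 = c("a", "b")),
    noise_sd = 0, lead_spec = NULL,
    reversed_attributes = "b",
    dropout_hazard = 0, n_imputations = 1, seed = 5
  )
  sim <- generate_panel(cfg)
  expect_false(sim$schema$higher_is_worse[sim$schema$name == "b"])
  # a and b share a factor and have no noise: b = -(a - intercept_a) + intercept_b,
  # so centered series are exact negatives
  ct <- center_within_person(sim$panel)
  for (s in unique(ct$subject)) {
    va <- ct$value[ct$subject == s & ct$attribute == "a"]
    vb <- ct$value[ct$subject == s & ct$attribute == "b"]
    expect_equal(vb, -va, tolerance = 1e-12)
  }
  # reverse coding by the generated schema restores alignment
  pre <- preprocess_panel(sim$panel, sim$schema)
  for (s in unique(pre$subject)) {
    va <- pre$value[pre$subject == s & pre$attribute == "a"]
    vb <- pre$value[pre$subject == s & pre$attribute == "b"]
    expect_equal(vb, va, tolerance = 1e-12)
  }
})

test_that("dropout is monotone with (1 - hazard)^t retention", {
  cfg <- synthetic_config(n_subjects = 1000, n_timepoints = 6,
                          dropout_hazard = 0, n_imputations = 1, seed = 6)
  sim <- generate_panel(cfg)
  expect_identical(apply_dropout(sim$panel, 0), sim$panel)

  hazard <- 0.075
  dropped <- apply_dropout(sim$panel, hazard, seed = 99)
  rep_tbl <- validate_panel(dropped)$timepoint_retention
  expect_equal(rep_tbl$retention[1], 1)    # baseline always observed
  for (t in 1:5) {
    p_expect <- (1 - hazard)^t
    se <- sqrt(p_expect * (1 - p_expect) / 1000)
    expect_lt(abs(rep_tbl$retention[t + 1] - p_expect), 3 * se)
  }
  # monotone: once missing, always missing
  obs <- dplyr::summarise(
    dplyr::group_by(dropped, subject, time),
    seen = any(!is.na(value)), .groups = "drop")
  bad <- dplyr::summarise(
    dplyr::group_by(obs, subject),
    monotone = all(diff(as.integer(seen)) <= 0), .groups = "drop")
  expect_true(all(bad$monotone))
})

test_that("naive imputation fills monotone gaps and preserves complete data", {
  cfg <- synthetic_config(n_subjects = 12, n_timepoints = 5,
                          dropout_hazard = 0, n_imputations = 1, seed = 7)
  sim <- generate_panel(cfg)
  reps <- naive_impute(sim$panel, n_imputations = 3, seed = 1)
  expect_length(reps, 3)
  for (r in reps) {
    expect_false(anyNA(r$value))
    expect_equal(r$value, sim$panel$value)   # nothing to fill
  }

  dropped <- apply_dropout(sim$panel, 0.3, seed = 2)
  reps2 <- naive_impute(dropped, n_imputations = 4, seed = 3)
  expect_length(reps2, 4)
  for (r in reps2) expect_false(anyNA(r$value))
  # observed cells are never perturbed
  obs_idx <- !is.na(dropped$value)
  for (r in reps2) expect_equal(r$value[obs_idx], dropped$value[obs_idx])
})

test_that("LOCF with zero residual SD carries the last observation forward", {
  ds <- panel_from_series(list(
    s1 = cbind(a = c(2, 2, 2, NA), b = c(1, 3, 2, 4)),
    s2 = cbind(a = c(2, 2, 2, 2), b = c(0, 1, 0, 1))
  ))
  # attribute a has constant observed one-step changes (all zero) => sd 0
  reps <- naive_impute(ds, n_imputations = 2, seed = 5)
  for (r in reps) {
    filled <- r$value[r$subject == "s1" & r$attribute == "a" & r$time == 3]
    expect_equal(filled, 2)
  }
})

test_that("noiseless planted clusters give block-ordered distance matrices", {
  cfg <- synthetic_config(
    n_subjects = 25, n_timepoints = 6,
    clusters = list(c1 = c("a1", "a2"), c2 = c("b1", "b2"),
                    c3 = c("c1", "c2")),
    noise_sd = 0, lead_spec = NULL, reversed_attributes = character(),
    dropout_hazard = 0, n_imputations = 1, seed = 8
  )
  sim <- generate_panel(cfg)
  pre <- preprocess_panel(sim$panel, sim$schema)
  gm <- dist_matrix(aggregate_distances(subject_distances(pre)))
  truth <- stats::setNames(sim$truth$cluster_labels$cluster,
                           sim$truth$cluster_labels$attribute)
  within <- gm[outer(truth[rownames(gm)], truth[colnames(gm)], "==") &
                 upper.tri(gm)]
  between <- gm[outer(truth[rownames(gm)], truth[colnames(gm)], "!=") &
                  upper.tri(gm)]
  expect_lt(max(within), min(between))   # strict block ordering
})
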