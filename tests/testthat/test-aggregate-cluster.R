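test_that("subject distance tables hold one DTW distance per attribute pair", {
  ds <- panel_from_series(list(
    s1 = cbind(a = c(0, 0, 0), b = c(1, 1, 1), c = c(0, 0, 0))
  ))
  d <- subject_distances(ds, window = 1)
  expect_equal(nrow(d), 3)          # K(K-1)/2 unique pairs
  look <- function(f, t) d$distance[d$from == f & d$to == t]
  expect_equal(look("a", "b"), 1)   # constant offset of 1
  expect_equal(look("a", "c"), 0)   # identical series
  expect_error(subject_distances(dplyr::mutate(ds, value = NA_real_)),
               "missing")
})

test_that("group aggregation averages replicates first, then subjects", {
  tbl <- tibble::tibble(
    imputation = c(1L, 2L, 1L, 2L),
    subject = c("s1", "s1", "s2", "s2"),
    from = "a", to = "b",
    distance = c(0.4, 0.6, 3, 3)
  )
  agg <- aggregate_distances(tbl)
  expect_equal(agg$per_subject$distance, c(0.5, 3))   # replicate pooling
  expect_equal(agg$group$distance, 1.75)              # subject mean
  expect_equal(agg$n_imputations_pooled, 2)

  # single subject, single replicate: identity
  one <- aggregate_distances(tibble::tibble(subject = "s1", from = "a",
                                            to = "b", distance = 0.7))
  expect_equal(one$group$distance, 0.7)
})

test_that("aggregation is invariant to subject and replicate order", {
  set.seed(21)
  tbl <- tidyr::expand_grid(imputation = 1:3, subject = paste0("s", 1:4),
                            from = "a", to = "b")
  tbl$distance <- runif(nrow(tbl))
  shuffled <- tbl[sample(nrow(tbl)), ]
  expect_equal(aggregate_distances(tbl)$group,
               aggregate_distances(shuffled)$group)
})

test_that("group matrix is recomputable from per-subject matrices", {
  set.seed(22)
  sim <- generate_panel(synthetic_config(n_subjects = 10, n_timepoints = 4,
                                         dropout_hazard = 0,
                                         n_imputations = 1, seed = 5))
  pre <- preprocess_panel(sim$panel, sim$schema)
  agg <- aggregate_distances(subject_distances(pre))
  manual <- dplyr::summarise(
    dplyr::group_by(agg$per_subject, from, to),
    distance = mean(distance), .groups = "drop")
  expect_equal(agg$group$distance, manual$distance, tolerance = 1e-12)
})

test_that("silhouette-guided clustering recovers planted blocks", {
  # 4 attributes, within-block distance 0.2, between-block 1.0:
  # at k = 2 every point has a = 0.2, b = 1.0, silhouette = 0.8
  m <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 0.2
  diag(m) <- 0
  sol <- cluster_attributes(m)
  expect_equal(sol$k, 2)
  expect_equal(sol$silhouette_by_k$mean_silhouette[sol$silhouette_by_k$k == 2],
               0.8)
  labs <- sol$labels
  expect_equal(labs$cluster[labs$attribute == "a"],
               labs$cluster[labs$attribute == "b"])
  expect_equal(labs$cluster[labs$attribute == "c"],
               labs$cluster[labs$attribute == "d"])
  expect_false(labs$cluster[labs$attribute == "a"] ==
                 labs$cluster[labs$attribute == "c"])
})

test_that("silhouette ties resolve to the smallest candidate k", {
  m <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  sol <- cluster_attributes(m)
  expect_equal(sol$k, 2)
})

test_that("an outlier attribute separates from a tight pair at k = 2", {
  m <- matrix(c(0, 0.1, 2,
                0.1, 0, 2,
                2, 2, 0), 3, 3,
              dimnames = list(c("a", "b", "z"), c("a", "b", "z")))
  sol <- cluster_attributes(m)   # k_range collapses to {2}
  expect_equal(sol$k, 2)
  labs <- sol$labels
  expect_equal(labs$cluster[labs$attribute == "a"],
               labs$cluster[labs$attribute == "b"])
  expect_false(labs$cluster[labs$attribute == "z"] ==
                 labs$cluster[labs$attribute == "a"])
})

test_that("merge heights never invert on pipeline-produced distances", {
  set.seed(23)
  sim <- generate_panel(reference_config(seed = 2))
  pre <- preprocess_panel(sim$panel, sim$schema)
  sol <- cluster_attributes(dist_matrix(aggregate_distances(
    subject_distances(pre))))
  expect_true(all(diff(sol$hclust$height) >= -1e-12))
  expect_equal(sort(unique(sol$labels$cluster)), seq_len(sol$k))
})

test_that("degenerate distance matrices are refused", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(cluster_attributes(z), "degenerate")
  expect_error(cluster_attributes(matrix(0, 2, 2)), "at least 3")
})

test_that("undirected network edges carry similarity weights and valence colors", {
  sch <- attribute_schema(c("depression", "anxiety", "wellbeing"),
                          higher_is_worse = c(TRUE, TRUE, FALSE))
  m <- matrix(c(0, 0, 1,
                0, 0, 1,
                1, 1, 0), 3, 3,
              dimnames = list(sch$name, sch$name))
  labels <- tibble::tibble(attribute = sch$name, cluster = c(1L, 1L, 2L))
  net <- undirected_network(m, labels, sch)
  dep_anx <- net[net$from == "depression" & net$to == "anxiety", ]
  expect_equal(dep_anx$weight, 1)          # d = 0 -> maximal similarity
  expect_equal(dep_anx$edge_color, "green")
  dep_wb <- net[net$from == "depression" & net$to == "wellbeing", ]
  expect_equal(dep_wb$weight, 0.5)         # 1 / (1 + 1)
  expect_equal(dep_wb$edge_color, "red")
  expect_equal(dep_wb$cluster_to, 2L)
})

test_that("trajectory summaries use observed values only", {
  ds <- panel_from_series(list(
    s1 = cbind(a = c(4, 5, 5), b = c(5, 5, 5)),
    s2 = cbind(a = c(6, NA, 5), b = c(5, 5, 5))
  ))
  tr <- trajectory_summary(ds)
  a0 <- tr[tr$attribute == "a" & tr$time == 0, ]
  expect_equal(a0$mean, 5)                 # mean of {4, 6}
  a1 <- tr[tr$attribute == "a" & tr$time == 1, ]
  expect_equal(a1$n, 1)                    # missing entry excluded
  expect_equal(a1$mean, 5)
  b <- tr[tr$attribute == "b", ]
  expect_equal(b$mean, rep(5, 3))
  expect_equal(b$se, rep(0, 3))
})

test_that("internal adjusted Rand index matches the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(24)
  for (rep in 1:25) {
    a <- sample(1:4, 20, replace = TRUE)
    b <- sample(1:3, 20, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, 1:5), 1)
})
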