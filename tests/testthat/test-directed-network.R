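test_that("lead-lag contrasts match the delayed-spike derivation and are antisymmetric", {
  ds <- panel_from_series(list(
    s1 = cbind(a = c(0, 1, 0, 0), b = c(0, 0, 1, 0), c = c(0, 1, 0, 0))
  ))
  dl <- directed_deltas(ds)
  get <- function(f, t) dl$delta[dl$from == f & dl$to == t]
  expect_equal(get("a", "b"), 0.25)   # b is a delayed: a leads
  expect_equal(get("b", "a"), -0.25)  # antisymmetry
  expect_equal(get("a", "c"), 0)      # identical series
  expect_equal(nrow(dl), 6)           # K(K-1) ordered pairs
})

test_that("antisymmetry holds exactly on generated cohorts", {
  set.seed(31)
  sim <- generate_panel(synthetic_config(n_subjects = 12, n_timepoints = 5,
                                         dropout_hazard = 0,
                                         n_imputations = 1, seed = 9))
  pre <- preprocess_panel(sim$panel, sim$schema)
  dl <- directed_deltas(pre)
  swapped <- dplyr::rename(dl, from = to, to = from)
  joined <- dplyr::inner_join(dl, swapped,
                              by = c("subject", "from", "to"),
                              suffix = c("", "_rev"))
  expect_equal(joined$delta, -joined$delta_rev, tolerance = 1e-12)

  pooled <- pool_deltas(dl)
  g <- pooled$group
  grev <- dplyr::rename(g, from = to, to = from)
  j2 <- dplyr::inner_join(g, grev, by = c("from", "to"),
                          suffix = c("", "_rev"))
  expect_equal(j2$mean_delta, -j2$mean_delta_rev, tolerance = 1e-12)
})

test_that("pooling averages replicates within subject before subjects", {
  tbl <- tibble::tibble(
    imputation = c(1L, 2L), subject = "s1", from = "a", to = "b",
    delta = c(0.2, 0.4)
  )
  tbl <- dplyr::bind_rows(tbl,
    dplyr::mutate(tbl, from = "b", to = "a", delta = -delta))
  pooled <- pool_deltas(tbl)
  expect_equal(pooled$per_subject$delta[pooled$per_subject$from == "a"], 0.3)

  # constant deltas across subjects have zero group SE
  many <- tibble::tibble(subject = paste0("s", 1:5), from = "a", to = "b",
                         delta = 0.3)
  expect_equal(pool_deltas(many)$group$se, 0)
})

test_that("directed edge tests flag positive-mean pairs one-sidedly", {
  set.seed(32)
  n <- 100
  deltas <- dplyr::bind_rows(
    tibble::tibble(subject = paste0("s", 1:n), from = "a", to = "b",
                   delta = 0.25 + rnorm(n, sd = 0.05)),
    tibble::tibble(subject = paste0("s", 1:n), from = "b", to = "a",
                   delta = -(0.25 + rnorm(n, sd = 0.05)))
  )
  res <- test_directed_edges(pool_deltas(deltas))
  ab <- res[res$from == "a" & res$to == "b", ]
  expect_true(ab$significant)
  # independent oracle: direct one-sided t-test
  ref <- stats::t.test(deltas$delta[deltas$from == "a"], mu = 0,
                       alternative = "greater")
  expect_equal(ab$p_value, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(ab$statistic, unname(ref$statistic), tolerance = 1e-12)
  # the reverse direction can never also be significant
  expect_false(res$significant[res$from == "b" & res$to == "a"])

  # flipping every subject's sign flips the edge
  flipped <- dplyr::mutate(deltas, delta = -delta)
  res_f <- test_directed_edges(pool_deltas(flipped))
  expect_true(res_f$significant[res_f$from == "b" & res_f$to == "a"])
  expect_false(res_f$significant[res_f$from == "a" & res_f$to == "b"])
})

test_that("edge tests handle degenerate all-zero and zero-variance cases", {
  zeros <- tibble::tibble(subject = paste0("s", 1:5),
                          from = "a", to = "b", delta = 0)
  zeros <- dplyr::bind_rows(zeros, dplyr::mutate(zeros, from = "b", to = "a"))
  res <- test_directed_edges(pool_deltas(zeros))
  expect_false(any(res$significant))
  expect_true(all(res$degenerate))

  pos <- dplyr::mutate(zeros, delta = ifelse(from == "a", 0.1, -0.1))
  res_pos <- test_directed_edges(pool_deltas(pos))
  ab <- res_pos[res_pos$from == "a", ]
  expect_true(ab$significant)     # positive mean, zero variance: by convention
  expect_true(ab$degenerate)      # ... and flagged
})

test_that("edge discovery is monotone in alpha", {
  set.seed(33)
  sim <- generate_panel(synthetic_config(n_subjects = 30, n_timepoints = 6,
                                         dropout_hazard = 0,
                                         n_imputations = 1, seed = 13))
  pre <- preprocess_panel(sim$panel, sim$schema)
  pooled <- pool_deltas(directed_deltas(pre))
  res_all <- test_directed_edges(pooled, alpha = 1)
  expect_true(all(res_all$significant[res_all$mean_delta > 0]))
  res_none <- test_directed_edges(pooled, alpha = 1e-300)
  expect_false(any(res_none$significant[!res_none$degenerate]))
  n_05 <- sum(test_directed_edges(pooled, alpha = 0.05)$significant)
  n_20 <- sum(test_directed_edges(pooled, alpha = 0.20)$significant)
  expect_lte(n_05, n_20)
})

test_that("strength centralities follow the positive-part definition", {
  # one subject pattern replicated 3x: delta(1->2)=0.3, delta(1->3)=0.2,
  # delta(2->3)=0 => raw out = (0.5, 0, 0), raw in = (0, 0.3, 0.2)
  one <- tibble::tibble(
    from = c("n1", "n1", "n2", "n2", "n3", "n3"),
    to = c("n2", "n3", "n1", "n3", "n1", "n2"),
    delta = c(0.3, 0.2, -0.3, 0, -0.2, 0)
  )
  deltas <- dplyr::bind_rows(lapply(1:3, function(s)
    dplyr::mutate(one, subject = paste0("s", s))))
  st <- strength_centrality(pool_deltas(deltas))
  outs <- st[st$kind == "out", ]
  expect_equal(outs$raw_mean[match(c("n1", "n2", "n3"), outs$node)],
               c(0.5, 0, 0))
  ins <- st[st$kind == "in", ]
  expect_equal(ins$raw_mean[match(c("n1", "n2", "n3"), ins$node)],
               c(0, 0.3, 0.2))
  # standardized: centered by the node mean 0.1666...
  expect_equal(outs$estimate[match(c("n1", "n2", "n3"), outs$node)],
               c(1, -0.5, -0.5) / 3, tolerance = 1e-12)
})

test_that("standardized strengths sum to zero across nodes within subject and kind", {
  set.seed(34)
  sim <- generate_panel(synthetic_config(n_subjects = 10, n_timepoints = 5,
                                         dropout_hazard = 0,
                                         n_imputations = 1, seed = 21))
  pre <- preprocess_panel(sim$panel, sim$schema)
  pooled <- pool_deltas(directed_deltas(pre))
  st <- strength_centrality(pooled)
  # group-level standardized estimates inherit the exact zero sum
  sums <- tapply(st$estimate, st$kind, sum)
  expect_equal(as.numeric(sums), c(0, 0), tolerance = 1e-12)
  expect_equal(nrow(st), 2 * 12)
  # significance is exactly "CI excludes zero from below"
  expect_equal(st$significant, st$ci_low > 0)
})

test_that("all-zero deltas give zero strengths and no significance", {
  zeros <- tidyr::expand_grid(subject = paste0("s", 1:4),
                              from = c("a", "b", "c"), to = c("a", "b", "c"))
  zeros <- dplyr::filter(zeros, from != to)
  zeros$delta <- 0
  st <- strength_centrality(pool_deltas(zeros))
  expect_true(all(st$raw_mean == 0))
  expect_true(all(st$estimate == 0))
  expect_false(any(st$significant))
})
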