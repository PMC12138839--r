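#' Per-subject pairwise DTW distance matrices
#'
#' For each subject (and imputation replicate, if present), computes the
#' undirected DTW distance between every unordered pair of attribute series
#' under the given Sakoe-Chiba band. Input must be complete (imputed) and
#' preprocessed.
#'
#' @param panel a complete, preprocessed panel tibble.
#' @param window Sakoe-Chiba band half-width (default 1).
#' @return A tidy tibble with columns `imputation` (if stacked), `subject`,
#'   `from`, `to`, `distance`, one row per unordered pair (`from < to` in
#'   attribute order).
#' @export
subject_distances <- function(panel, window = 1L) {
  if (anyNA(panel$value)) {
    abort_data("panel contains missing values; impute before computing distances")
  }
  a <- panel_array(panel)
  k <- length(a$attrs)
  if (k < 2) abort_data("need at least 2 attributes")
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  np <- nrow(pairs)
  n_slices <- a$n_subjects * a$n_imputations
  d <- matrix(NA_real_, np, n_slices)
  for (sl in seq_len(n_slices)) {
    mat <- a$array[, , sl]                 # K x T slice for one subject
    for (p in seq_len(np)) {
      d[p, sl] <- dtw_u_dist(mat[pairs[p, 1], ], mat[pairs[p, 2], ],
                             window = window)
    }
  }
  out <- tibble::tibble(
    subject = rep(rep(a$subjects, times = a$n_imputations), each = np),
    from = rep(a$attrs[pairs[, 1]], n_slices),
    to = rep(a$attrs[pairs[, 2]], n_slices),
    distance = as.vector(d)
  )
  if (a$n_imputations > 1) {
    out <- tibble::add_column(
      out,
      imputation = rep(a$imputations, each = np * a$n_subjects),
      .before = 1
    )
  }
  out
}

# reshape a complete canonical panel into a K x T x (S * M) value array,
# slices ordered subject-fastest then imputation
panel_array <- function(panel) {
  dims <- panel_dims(panel)
  attrs <- dims$attributes
  tps <- dims$timepoints
  subs <- dims$subjects
  has_imp <- "imputation" %in% names(panel)
  imps <- if (has_imp) sort(unique(panel$imputation)) else 1L
  k <- length(attrs); tt <- length(tps); s <- length(subs); m <- length(imps)
  if (nrow(panel) != k * tt * s * m) {
    abort_data("panel grid is incomplete; pass it through as_panel() first")
  }
  ord <- order(
    if (has_imp) match(panel$imputation, imps) else integer(nrow(panel)),
    match(panel$subject, subs),
    match(panel$time, tps),
    match(panel$attribute, attrs)
  )
  list(
    array = array(panel$value[ord], dim = c(k, tt, s * m)),
    attrs = attrs, timepoints = tps, subjects = subs, imputations = imps,
    n_subjects = s, n_imputations = m
  )
}

#' Aggregate subject distances to the group level
#'
#' Pools a tidy distance table in the pinned order: elementwise mean across
#' imputation replicates within each subject first, then elementwise mean
#' across subjects. (Both orders give identical means; the order is pinned
#' so intermediate artifacts are reproducible.)
#'
#' @param dist_tbl output of [subject_distances()], possibly over replicates.
#' @return A list of class `warpnet_distances`: `group` (tibble `from`,
#'   `to`, `distance`), `per_subject` (replicate-pooled tidy tibble), and
#'   `n_imputations_pooled`.
#' @export
aggregate_distances <- function(dist_tbl) {
  n_imp <- if ("imputation" %in% names(dist_tbl))
    length(unique(dist_tbl$imputation)) else 1L
  per_subject <- dplyr::summarise(
    dplyr::group_by(dist_tbl, .data$subject, .data$from, .data$to),
    distance = mean(.data$distance),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
  if (length(unique(per_subject$n_reps)) > 1) {
    abort_data("imputation replicates differ in shape across subjects")
  }
  per_subject$n_reps <- NULL
  group <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$from, .data$to),
    distance = mean(.data$distance),
    .groups = "drop"
  )
  structure(
    list(group = group, per_subject = per_subject,
         n_imputations_pooled = n_imp),
    class = "warpnet_distances"
  )
}

#' Convert a tidy pairwise distance table to a symmetric matrix
#'
#' @param dist_tbl tibble with `from`, `to`, `distance` (one row per
#'   unordered pair), or a `warpnet_distances` object (its group table).
#' @param attrs optional attribute ordering for rows/columns.
#' @return A symmetric K x K matrix with zero diagonal.
#' @export
dist_matrix <- function(dist_tbl, attrs = NULL) {
  if (inherits(dist_tbl, "warpnet_distances")) dist_tbl <- dist_tbl$group
  if (is.null(attrs)) attrs <- unique(c(dist_tbl$from, dist_tbl$to))
  k <- length(attrs)
  m <- matrix(0, k, k, dimnames = list(attrs, attrs))
  m[cbind(dist_tbl$from, dist_tbl$to)] <- dist_tbl$distance
  m[cbind(dist_tbl$to, dist_tbl$from)] <- dist_tbl$distance
  m
}

#' Hierarchically cluster attributes into dimensions
#'
#' Agglomerative clustering of the group-level DTW distance matrix. The
#' number of clusters k is chosen to maximize the mean silhouette width over
#' `k_range` (ties broken toward the smaller k), and labels come from
#' cutting the tree at that k. Ward linkage (`"ward.D2"`) is the default;
#' `"average"` and `"complete"` are also supported.
#'
#' @param group_matrix symmetric distance matrix (or `warpnet_distances`).
#' @param k_range integer candidate range for k; default `2:(K - 1)`.
#' @param linkage hclust linkage method.
#' @return A list of class `warpnet_clusters`: `hclust` tree, chosen `k`,
#'   `labels` tibble (`attribute`, `cluster`), and `silhouette_by_k` tibble.
#' @export
cluster_attributes <- function(group_matrix, k_range = NULL,
                               linkage = c("ward.D2", "average", "complete")) {
  linkage <- match.arg(linkage)
  if (inherits(group_matrix, "warpnet_distances")) {
    group_matrix <- dist_matrix(group_matrix)
  }
  k_attr <- nrow(group_matrix)
  if (k_attr < 3) abort_data("clustering needs at least 3 attributes")
  if (all(group_matrix == 0)) abort_data("degenerate distance matrix (all zeros)")
  if (is.null(k_range)) k_range <- 2:(k_attr - 1)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range > k_attr)) {
    abort_config("k_range must lie in [2, K]")
  }
  d <- stats::as.dist(group_matrix)
  tree <- stats::hclust(d, method = linkage)
  sil <- vapply(k_range, function(k) {
    labs <- stats::cutree(tree, k = k)
    mean(cluster::silhouette(labs, d)[, "sil_width"])
  }, numeric(1))
  k_best <- k_range[which.max(sil)]   # which.max returns the first (smallest k) on ties
  labs <- stats::cutree(tree, k = k_best)
  structure(
    list(
      hclust = tree,
      k = k_best,
      labels = tibble::tibble(attribute = names(labs),
                              cluster = as.integer(labs)),
      silhouette_by_k = tibble::tibble(k = k_range, mean_silhouette = sil),
      linkage = linkage
    ),
    class = "warpnet_clusters"
  )
}

#' @export
print.warpnet_clusters <- function(x, ...) {
  cat(sprintf("<warpnet_clusters> %d attributes, k = %d (%s linkage)\n",
              nrow(x$labels), x$k, x$linkage))
  print(x$labels)
  invisible(x)
}

#' Build the undirected co-occurrence network edge table
#'
#' Edge weight is the similarity transform `1 / (1 + d)` of the group DTW
#' distance (monotone decreasing, bounded in (0, 1]). Edge sign records
#' valence agreement of the two attributes' original coding: attributes with
#' the same raw valence get a "green" (positive association) edge, opposite
#' valences a "red" (negative) one. Nodes carry their cluster id.
#'
#' @param group_matrix group distance matrix (or `warpnet_distances`).
#' @param clusters a `warpnet_clusters` object (or labels tibble).
#' @param schema a `warpnet_schema`.
#' @return A tibble with columns `from`, `to`, `distance`, `weight`,
#'   `same_valence`, `sign`, `edge_color`, `cluster_from`, `cluster_to`.
#' @export
undirected_network <- function(group_matrix, clusters, schema) {
  schema <- check_schema(schema)
  if (inherits(group_matrix, "warpnet_distances")) {
    group_matrix <- dist_matrix(group_matrix)
  }
  labels <- if (inherits(clusters, "warpnet_clusters")) clusters$labels else
    tibble::as_tibble(clusters)
  attrs <- rownames(group_matrix)
  idx <- which(upper.tri(group_matrix), arr.ind = TRUE)
  valence <- stats::setNames(schema$higher_is_worse, schema$name)
  cl <- stats::setNames(labels$cluster, labels$attribute)
  from <- attrs[idx[, 1]]; to <- attrs[idx[, 2]]
  d <- group_matrix[idx]
  same <- unname(valence[from] == valence[to])
  tibble::tibble(
    from = from, to = to,
    distance = d,
    weight = 1 / (1 + d),
    same_valence = same,
    sign = ifelse(same, 1, -1),
    edge_color = ifelse(same, "green", "red"),
    cluster_from = unname(cl[from]),
    cluster_to = unname(cl[to])
  )
}

#' Per-timepoint trajectory summary
#'
#' Descriptive group-mean trajectories: observed-value mean and standard
#' error per attribute per timepoint (the plot-ready analogue of the mean
#' symptom-course figure). Missing entries are excluded from each
#' timepoint-specific mean.
#'
#' @param panel a raw (or preprocessed) panel tibble.
#' @return A tibble with `attribute`, `time`, `n`, `mean`, `se`.
#' @export
trajectory_summary <- function(panel) {
  out <- dplyr::summarise(
    dplyr::group_by(panel, .data$attribute, .data$time),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    se = stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    .groups = "drop"
  )
  out$mean[is.nan(out$mean)] <- NA_real_
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 = identical partitions, ~0 = chance agreement. Used to score recovery
#' of planted cluster structure.
#'
#' @param a,b label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort_data("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
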