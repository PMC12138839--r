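#' Fit the full DTW symptom-network analysis
#'
#' Runs the whole pipeline on a panel (or imputation stack): valence
#' alignment, within-person centering, group standardization; undirected
#' DTW distances per subject pooled across replicates and subjects;
#' hierarchical clustering of attributes into dimensions; the undirected
#' co-occurrence network; and (optionally) directed lead-lag contrasts,
#' group-level edge tests, and standardized out-/in-strength centralities
#' with confidence intervals.
#'
#' @param panel a canonical panel tibble, optionally stacked over
#'   imputation replicates (`imputation` column). Must be complete; impute
#'   first if there are missing values.
#' @param schema a `warpnet_schema` covering all attributes.
#' @param window Sakoe-Chiba band half-width for the undirected DTW
#'   (default 1).
#' @param max_lag forward lag bound for the directed DTW (default 1).
#' @param alpha significance level for directed edge tests (default 0.05).
#' @param k_range candidate numbers of clusters (default `2:(K - 1)`).
#' @param linkage hclust linkage (default `"ward.D2"`).
#' @param directed compute the directed stage (default TRUE).
#' @param edge_method `"t"` or `"wilcoxon"` for directed edge tests.
#' @param p_adjust multiple-testing correction for edge tests
#'   (default `"none"`).
#' @param conf_level confidence level for strength intervals.
#' @return An object of class `dtw_network` with elements `distances`
#'   (`warpnet_distances`), `clusters` (`warpnet_clusters`), `edges`
#'   (undirected edge tibble), `deltas` (`warpnet_deltas` or NULL),
#'   `directed_edges`, `strengths`, `trajectories`, `schema`, and
#'   `settings`.
#' @export
#' @examples
#' sim <- generate_panel(reference_config(seed = 1))
#' fit <- dtw_network(sim$panel, sim$schema)
#' glance(fit)
dtw_network <- function(panel, schema,
                        window = 1L, max_lag = 1L, alpha = 0.05,
                        k_range = NULL, linkage = "ward.D2",
                        directed = TRUE, edge_method = "t",
                        p_adjust = "none", conf_level = 0.95) {
  schema <- check_schema(schema)
  panel <- as_panel(panel, schema)
  if (anyNA(panel$value)) {
    abort_data("panel contains missing values; impute before fitting")
  }
  trajectories <- trajectory_summary(panel)
  pre <- preprocess_panel(panel, schema)
  distances <- aggregate_distances(subject_distances(pre, window = window))
  clusters <- cluster_attributes(dist_matrix(distances), k_range = k_range,
                                 linkage = linkage)
  edges <- undirected_network(dist_matrix(distances), clusters, schema)

  deltas <- directed_edges <- strengths <- NULL
  if (directed) {
    deltas <- pool_deltas(directed_deltas(pre, max_lag = max_lag))
    directed_edges <- test_directed_edges(deltas, alpha = alpha,
                                          method = edge_method,
                                          p_adjust = p_adjust)
    strengths <- strength_centrality(deltas, conf_level = conf_level)
  }

  structure(
    list(
      distances = distances, clusters = clusters, edges = edges,
      deltas = deltas, directed_edges = directed_edges,
      strengths = strengths, trajectories = trajectories, schema = schema,
      settings = list(window = as.integer(window),
                      max_lag = as.integer(max_lag), alpha = alpha,
                      k_range = clusters$silhouette_by_k$k,
                      linkage = linkage, directed = directed,
                      edge_method = edge_method, p_adjust = p_adjust,
                      conf_level = conf_level,
                      n_imputations = distances$n_imputations_pooled)
    ),
    class = "dtw_network"
  )
}

#' @export
print.dtw_network <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<dtw_network> %d subjects, %d attributes, %d imputation replicate(s)\n",
    g$n_subjects, g$n_attributes, g$n_imputations))
  cat(sprintf("  dimensions: k = %d (mean silhouette %.3f, %s linkage)\n",
              g$k, g$mean_silhouette, x$settings$linkage))
  if (!is.null(x$directed_edges)) {
    cat(sprintf("  directed: %d significant edge(s), %d node(s) with significant out-strength\n",
                g$n_significant_edges, g$n_significant_out))
  }
  invisible(x)
}

#' Tidy components of a fitted DTW network
#'
#' @param x a `dtw_network` object.
#' @param what which component to return: undirected `"edges"`,
#'   `"clusters"`, `"directed_edges"`, `"strengths"`, `"distances"`
#'   (group-level), or `"trajectories"`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy dtw_network
#' @export
tidy.dtw_network <- function(x, what = c("edges", "clusters",
                                         "directed_edges", "strengths",
                                         "distances", "trajectories"), ...) {
  what <- match.arg(what)
  out <- switch(what,
    edges = x$edges,
    clusters = x$clusters$labels,
    directed_edges = x$directed_edges,
    strengths = x$strengths,
    distances = x$distances$group,
    trajectories = x$trajectories
  )
  if (is.null(out)) {
    abort_compute(paste0("component '", what,
                         "' was not computed (directed = FALSE?)"))
  }
  tibble::as_tibble(out)
}

#' One-row summary of a fitted DTW network
#'
#' @param x a `dtw_network` object.
#' @param ... unused.
#' @return A one-row tibble: cohort size, attribute count, replicate count,
#'   chosen k and its mean silhouette width, and significant-edge and
#'   significant-strength counts.
#' @method glance dtw_network
#' @export
glance.dtw_network <- function(x, ...) {
  sil <- x$clusters$silhouette_by_k
  tibble::tibble(
    n_subjects = length(unique(x$distances$per_subject$subject)),
    n_attributes = nrow(x$clusters$labels),
    n_imputations = x$distances$n_imputations_pooled,
    k = x$clusters$k,
    mean_silhouette = sil$mean_silhouette[sil$k == x$clusters$k],
    n_significant_edges = if (is.null(x$directed_edges)) NA_integer_ else
      sum(x$directed_edges$significant),
    n_significant_out = if (is.null(x$strengths)) NA_integer_ else
      sum(x$strengths$significant[x$strengths$kind == "out"]),
    n_significant_in = if (is.null(x$strengths)) NA_integer_ else
      sum(x$strengths$significant[x$strengths$kind == "in"])
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Deterministic machine-readable run summary
#'
#' Everything needed to reproduce and audit a fit: all settings in effect,
#' the chosen number of dimensions and cluster memberships, significant
#' directed edges, and significant strengths. Contains no timestamps, so
#' two runs on identical input are byte-identical when serialized.
#'
#' @param fit a `dtw_network` object.
#' @param seed optional seed to record.
#' @return A named list, suitable for [jsonlite::write_json()].
#' @export
run_summary <- function(fit, seed = NULL) {
  sig_edges <- if (is.null(fit$directed_edges)) NULL else
    dplyr::filter(fit$directed_edges, .data$significant)
  sig_strengths <- if (is.null(fit$strengths)) NULL else
    dplyr::filter(fit$strengths, .data$significant)
  list(
    package_version = as.character(utils::packageVersion("warpnet")),
    seed = seed,
    settings = fit$settings,
    n_subjects = length(unique(fit$distances$per_subject$subject)),
    n_attributes = nrow(fit$clusters$labels),
    k = fit$clusters$k,
    silhouette_by_k = as.data.frame(fit$clusters$silhouette_by_k),
    cluster_labels = as.data.frame(fit$clusters$labels),
    significant_directed_edges = if (is.null(sig_edges)) NULL else
      as.data.frame(sig_edges[c("from", "to", "mean_delta", "p_value")]),
    significant_strengths = if (is.null(sig_strengths)) NULL else
      as.data.frame(sig_strengths[c("node", "kind", "estimate",
                                    "ci_low", "ci_high")])
  )
}
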