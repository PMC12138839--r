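#' Per-subject lead-lag contrasts for every ordered attribute pair
#'
#' For each subject and ordered pair (a, b) the lead-lag contrast is
#' `delta(a -> b) = D(b -> a) - D(a -> b)`, where `D(a -> b)` is the
#' forward-only directed DTW distance mapping a's timepoints onto same-time
#' or later timepoints of b (a in the leading role). If a's changes really
#' do precede b's, the forward alignment a -> b is cheap and the reverse is
#' expensive, so `delta(a -> b) > 0` means a temporally leads b. The
#' contrast is antisymmetric by construction:
#' `delta(a -> b) = -delta(b -> a)`.
#'
#' @param panel a complete, preprocessed panel tibble.
#' @param max_lag forward lag bound of the directed alignment (default 1).
#' @return A tidy tibble with columns `imputation` (if stacked), `subject`,
#'   `from`, `to`, `delta`, one row per ordered pair (`from != to`).
#' @export
directed_deltas <- function(panel, max_lag = 1L) {
  if (anyNA(panel$value)) {
    abort_data("panel contains missing values; impute before computing deltas")
  }
  a <- panel_array(panel)
  k <- length(a$attrs)
  if (k < 2) abort_data("need at least 2 attributes")
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  np <- nrow(pairs)
  n_slices <- a$n_subjects * a$n_imputations
  delta <- matrix(NA_real_, np, n_slices)
  for (sl in seq_len(n_slices)) {
    mat <- a$array[, , sl]
    for (p in seq_len(np)) {
      xa <- mat[pairs[p, 1], ]; xb <- mat[pairs[p, 2], ]
      delta[p, sl] <- dtw_d_dist(xb, xa, max_lag) - dtw_d_dist(xa, xb, max_lag)
    }
  }
  half <- tibble::tibble(
    subject = rep(rep(a$subjects, times = a$n_imputations), each = np),
    from = rep(a$attrs[pairs[, 1]], n_slices),
    to = rep(a$attrs[pairs[, 2]], n_slices),
    delta = as.vector(delta)
  )
  if (a$n_imputations > 1) {
    half <- tibble::add_column(
      half,
      imputation = rep(a$imputations, each = np * a$n_subjects),
      .before = 1
    )
  }
  mirror <- half
  mirror$from <- half$to
  mirror$to <- half$from
  mirror$delta <- -half$delta
  dplyr::bind_rows(half, mirror)
}

#' Pool lead-lag contrasts over imputation replicates and subjects
#'
#' Per-subject delta values are averaged elementwise across imputation
#' replicates first; the pooled per-subject values then yield the group
#' mean and its standard error across subjects for every ordered pair.
#'
#' @param delta_tbl output of [directed_deltas()], possibly over replicates.
#' @return A list of class `warpnet_deltas`: `per_subject` (replicate-pooled
#'   tidy tibble), `group` (tibble `from`, `to`, `mean_delta`, `se`, `n`),
#'   and `n_imputations_pooled`.
#' @export
pool_deltas <- function(delta_tbl) {
  n_imp <- if ("imputation" %in% names(delta_tbl))
    length(unique(delta_tbl$imputation)) else 1L
  per_subject <- dplyr::summarise(
    dplyr::group_by(delta_tbl, .data$subject, .data$from, .data$to),
    delta = mean(.data$delta),
    n_reps = dplyr::n(),
    .groups = "drop"
  )
  if (length(unique(per_subject$n_reps)) > 1) {
    abort_data("imputation replicates differ in shape across subjects")
  }
  per_subject$n_reps <- NULL
  group <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$from, .data$to),
    mean_delta = mean(.data$delta),
    se = stats::sd(.data$delta) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop"
  )
  structure(
    list(per_subject = per_subject, group = group,
         n_imputations_pooled = n_imp),
    class = "warpnet_deltas"
  )
}

#' Test directed edges at the group level
#'
#' For each ordered pair (a, b), a one-sided one-sample test across subjects
#' of H0: mean delta(a -> b) <= 0 against H1: > 0 at level `alpha`; an
#' arrow a -> b is drawn when the group-level contrast is significantly
#' larger than zero. By antisymmetry at most one of (a -> b), (b -> a) can
#' be significant. No multiple-testing correction is applied by default (the
#' node-level strength tests are the main outcome); Bonferroni or BH are
#' available via `p_adjust`. A Wilcoxon signed-rank alternative to the
#' t-test is available via `method`.
#'
#' @param deltas a `warpnet_deltas` object (or the tidy per-subject tibble).
#' @param alpha significance level (default 0.05).
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @param p_adjust multiple-testing correction passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return A tibble with one row per ordered pair: `from`, `to`,
#'   `mean_delta`, `se`, `n`, `statistic`, `p_value`, `significant`,
#'   `degenerate` (TRUE when all subject deltas are identical and the test
#'   falls back to the sign convention).
#' @export
test_directed_edges <- function(deltas, alpha = 0.05,
                                method = c("t", "wilcoxon"),
                                p_adjust = "none") {
  method <- match.arg(method)
  per_subject <- if (inherits(deltas, "warpnet_deltas"))
    deltas$per_subject else tibble::as_tibble(deltas)
  n_subj <- length(unique(per_subject$subject))
  if (n_subj < 3) abort_data("edge tests need at least 3 subjects")
  out <- dplyr::summarise(
    dplyr::group_by(per_subject, .data$from, .data$to),
    mean_delta = mean(.data$delta),
    se = stats::sd(.data$delta) / sqrt(dplyr::n()),
    n = dplyr::n(),
    statistic = one_sided_stat(.data$delta, method),
    p_value = one_sided_p(.data$delta, method),
    degenerate = stats::sd(.data$delta) == 0,
    .groups = "drop"
  )
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  out
}

one_sided_stat <- function(x, method) {
  if (method == "t") {
    s <- stats::sd(x)
    if (s == 0) return(ifelse(mean(x) > 0, Inf, -Inf))
    mean(x) / (s / sqrt(length(x)))
  } else {
    if (all(x == 0)) return(0)
    unname(stats::wilcox.test(x, alternative = "greater",
                              exact = FALSE, correct = TRUE)$statistic)
  }
}

one_sided_p <- function(x, method) {
  if (method == "t") {
    s <- stats::sd(x)
    # zero variance: positive mean is significant by convention (flagged via
    # the degenerate column), nonpositive mean is not
    if (s == 0) return(ifelse(mean(x) > 0, 0, 1))
    stats::pt(mean(x) / (s / sqrt(length(x))), df = length(x) - 1,
              lower.tail = FALSE)
  } else {
    if (all(x == 0)) return(1)
    stats::wilcox.test(x, alternative = "greater",
                       exact = FALSE, correct = TRUE)$p.value
  }
}

#' Standardized out- and in-strength centralities with confidence intervals
#'
#' Per subject, a node's raw out-strength is the sum of its positive
#' outgoing lead-lag contrasts, `sum_k max(delta(j -> k), 0)`, and its raw
#' in-strength the sum of positive incoming ones. Within each subject and
#' kind, strengths are standardized by centering on the subject's mean over
#' the K nodes, so a significantly positive standardized strength means
#' "above that subject's network average". The group estimate per node and
#' kind is the mean across subjects with a 95% t-interval
#' (`mean +/- t_{0.975, N-1} * SE`); a node is flagged significant when the
#' lower confidence bound exceeds zero.
#'
#' @param deltas a `warpnet_deltas` object (or tidy per-subject tibble).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return A tibble with 2K rows: `node`, `kind` (`"out"`/`"in"`),
#'   `raw_mean`, `estimate` (standardized mean), `se`, `ci_low`, `ci_high`,
#'   `significant`.
#' @export
strength_centrality <- function(deltas, conf_level = 0.95) {
  per_subject <- if (inherits(deltas, "warpnet_deltas"))
    deltas$per_subject else tibble::as_tibble(deltas)
  n_subj <- length(unique(per_subject$subject))
  if (n_subj < 3) abort_data("strength centralities need at least 3 subjects")
  pos <- dplyr::mutate(per_subject, pos_delta = pmax(.data$delta, 0))
  outs <- dplyr::summarise(
    dplyr::group_by(pos, .data$subject, node = .data$from),
    raw = sum(.data$pos_delta), .groups = "drop"
  )
  ins <- dplyr::summarise(
    dplyr::group_by(pos, .data$subject, node = .data$to),
    raw = sum(.data$pos_delta), .groups = "drop"
  )
  outs$kind <- "out"; ins$kind <- "in"
  both <- dplyr::bind_rows(outs, ins)
  both <- dplyr::mutate(
    dplyr::group_by(both, .data$subject, .data$kind),
    standardized = .data$raw - mean(.data$raw)
  )
  both <- dplyr::ungroup(both)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n_subj - 1)
  est <- dplyr::summarise(
    dplyr::group_by(both, .data$node, .data$kind),
    raw_mean = mean(.data$raw),
    estimate = mean(.data$standardized),
    se = stats::sd(.data$standardized) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  est$ci_low <- est$estimate - tq * est$se
  est$ci_high <- est$estimate + tq * est$se
  est$significant <- est$ci_low > 0
  est$kind <- factor(est$kind, levels = c("out", "in"))
  dplyr::arrange(est, .data$kind, dplyr::desc(.data$estimate))
}
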