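#' Pointwise local cost matrix
#'
#' Absolute-difference cost `c[i, j] = |x[i] - y[j]|`, the conventional
#' pointwise metric for univariate DTW.
#'
#' @param x,y numeric series without missing values.
#' @return An `N x M` nonnegative matrix.
#' @export
local_cost_matrix <- function(x, y) {
  check_series(x)
  check_series(y)
  abs(outer(x, y, "-"))
}

check_series <- function(x) {
  if (length(x) == 0) abort_data("empty series")
  if (anyNA(x)) abort_data("missing values in series; DTW runs on complete (imputed) data only")
  invisible(x)
}

#' Undirected DTW distance (symmetric2 step pattern, Sakoe-Chiba band)
#'
#' Dynamic-programming alignment of two series over monotone paths from
#' (1, 1) to (N, M) using steps (1,1), (1,0), (0,1), restricted to the
#' Sakoe-Chiba band `|i - j| <= window`. The symmetric2 weighting doubles
#' the diagonal step (and the initial cell: `g(1,1) = 2 c(1,1)`), and the
#' cumulative cost is normalized by `N + M`, so for equal-length series with
#' a diagonal-optimal alignment the distance equals the mean absolute
#' difference. The resulting distance is symmetric in its arguments.
#'
#' @param x,y numeric series, lengths N, M >= 2, no missing values.
#' @param window nonnegative integer band half-width; `|N - M|` must not
#'   exceed it or no path is admissible.
#' @return A list of class `warp_result`: `distance` (normalized), `path`
#'   (two-column 0-based index matrix), `normalization_constant` (`N + M`),
#'   and `raw_cost`.
#' @export
#' @examples
#' dtw_undirected(c(0, 0, 0), c(1, 1, 1), window = 1)$distance  # 1
dtw_undirected <- function(x, y, window = 1L) {
  check_series(x); check_series(y)
  n <- length(x); m <- length(y)
  if (n < 2 || m < 2) abort_data("series must have length >= 2")
  window <- as.integer(window)
  if (window < 0) abort_config("window must be >= 0")
  if (abs(n - m) > window) {
    abort_data(sprintf(
      "no admissible path: length difference %d exceeds band window %d",
      abs(n - m), window))
  }
  cm <- abs(outer(x, y, "-"))
  big <- Inf
  g <- matrix(big, n, m)
  g[1, 1] <- 2 * cm[1, 1]
  for (i in 1:n) {
    jlo <- max(1L, i - window); jhi <- min(m, i + window)
    for (j in jlo:jhi) {
      if (i == 1 && j == 1) next
      d <- if (i > 1 && j > 1) g[i - 1, j - 1] + 2 * cm[i, j] else big
      u <- if (i > 1) g[i - 1, j] + cm[i, j] else big
      l <- if (j > 1) g[i, j - 1] + cm[i, j] else big
      g[i, j] <- min(d, u, l)
    }
  }
  raw <- g[n, m]
  if (!is.finite(raw)) abort_data("no admissible path under the band")
  path <- backtrack_undirected(g, cm, n, m)
  structure(
    list(distance = raw / (n + m), path = path,
         normalization_constant = n + m, raw_cost = raw),
    class = "warp_result"
  )
}

# backtrack with ties broken toward the diagonal step (affects the reported
# path only, never the distance)
backtrack_undirected <- function(g, cm, n, m) {
  path <- matrix(NA_integer_, n + m, 2)
  k <- 1L
  i <- n; j <- m
  path[k, ] <- c(i, j)
  while (i > 1 || j > 1) {
    cand_d <- if (i > 1 && j > 1) g[i - 1, j - 1] + 2 * cm[i, j] else Inf
    cand_u <- if (i > 1) g[i - 1, j] + cm[i, j] else Inf
    cand_l <- if (j > 1) g[i, j - 1] + cm[i, j] else Inf
    best <- min(cand_d, cand_u, cand_l)
    if (cand_d <= best + 1e-12 && is.finite(cand_d)) {
      i <- i - 1L; j <- j - 1L
    } else if (cand_u <= best + 1e-12 && is.finite(cand_u)) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  path <- path[k:1, , drop = FALSE] - 1L   # expose 0-based
  colnames(path) <- c("i", "j")
  path
}

#' Directed (forward-only, lag-1) DTW distance
#'
#' Asymmetric alignment for detecting temporal precedence between two
#' equal-length series. Every index `i` of `x` is matched to exactly one
#' index `j(i)` of `y` with `j(i)` in `{i, ..., i + max_lag}` (capped at N):
#' `x` may align only with same-time (lag-0) or later (up to `max_lag`)
#' points of `y`, never earlier ones. The mapping must be non-decreasing
#' with steps `j(i) - j(i-1) <= max_lag + 1`, so at most `max_lag` target
#' points can be skipped per step. The minimized total cost
#' `sum_i |x[i] - y[j(i)]|` is normalized by N. A small distance means
#' changes in `x` co-occur with same-time or later changes in `y`, i.e.
#' `x` temporally leads `y`.
#'
#' @param x,y numeric series of equal length N >= 2, no missing values.
#' @param max_lag positive integer forward lag bound (default 1).
#' @return A `warp_result` list: `distance`, `path` (0-based `(i, j(i))`
#'   pairs), `normalization_constant` (`N`), `raw_cost`.
#' @export
#' @examples
#' # y is x delayed one step: x leads, forward alignment is free
#' dtw_directed(c(0, 1, 0, 0), c(0, 0, 1, 0))$distance  # 0
#' dtw_directed(c(0, 0, 1, 0), c(0, 1, 0, 0))$distance  # 0.25
dtw_directed <- function(x, y, max_lag = 1L) {
  check_series(x); check_series(y)
  n <- length(x)
  if (length(y) != n) abort_data("directed DTW needs equal-length series")
  if (n < 2) abort_data("series must have length >= 2")
  max_lag <- as.integer(max_lag)
  if (max_lag < 1) abort_config("max_lag must be >= 1")
  # DP over states (i, j) with j in {i, ..., min(i + max_lag, n)};
  # transitions from (i-1, j') with j' <= j and j - j' <= max_lag + 1
  width <- max_lag + 1L
  g <- matrix(Inf, n, width)          # g[i, k]: j = i + k - 1
  prev <- matrix(NA_integer_, n, width)
  for (k in 1:width) {
    j <- 1L + k - 1L
    if (j <= n && j <= 1L + max_lag) g[1, k] <- abs(x[1] - y[j])
  }
  for (i in 2:n) {
    for (k in 1:width) {
      j <- i + k - 1L
      if (j > n) next
      best <- Inf; arg <- NA_integer_
      for (kp in 1:width) {
        jp <- (i - 1L) + kp - 1L
        if (jp > n) next
        step <- j - jp
        if (step < 0L || step > max_lag + 1L) next
        v <- g[i - 1, kp]
        if (v < best) { best <- v; arg <- kp }
      }
      if (is.finite(best)) {
        g[i, k] <- best + abs(x[i] - y[j])
        prev[i, k] <- arg
      }
    }
  }
  kend <- 1L                           # j(n) is capped at n, so k = 1
  raw <- g[n, kend]
  if (!is.finite(raw)) abort_compute("no admissible directed mapping")
  js <- integer(n)
  k <- kend
  for (i in n:1) {
    js[i] <- i + k - 1L
    if (i > 1) k <- prev[i, k]
  }
  path <- cbind(i = seq_len(n) - 1L, j = js - 1L)
  structure(
    list(distance = raw / n, path = path,
         normalization_constant = n, raw_cost = raw),
    class = "warp_result"
  )
}

# distance-only DP kernels used by the bulk per-subject loops (no input
# checks, no path backtracking); must stay numerically identical to the
# exported functions, which the test suite asserts
dtw_u_dist <- function(x, y, window = 1L) {
  n <- length(x); m <- length(y)
  g <- matrix(Inf, n, m)
  g[1, 1] <- 2 * abs(x[1] - y[1])
  for (i in 1:n) {
    jlo <- max(1L, i - window); jhi <- min(m, i + window)
    for (j in jlo:jhi) {
      if (i == 1 && j == 1) next
      cij <- abs(x[i] - y[j])
      d <- if (i > 1 && j > 1) g[i - 1, j - 1] + 2 * cij else Inf
      u <- if (i > 1) g[i - 1, j] + cij else Inf
      l <- if (j > 1) g[i, j - 1] + cij else Inf
      g[i, j] <- min(d, u, l)
    }
  }
  g[n, m] / (n + m)
}

dtw_d_dist <- function(x, y, max_lag = 1L) {
  n <- length(x)
  width <- max_lag + 1L
  g <- matrix(Inf, n, width)
  for (k in 1:width) {
    j <- k
    if (j <= n) g[1, k] <- abs(x[1] - y[j])
  }
  for (i in 2:n) {
    for (k in 1:width) {
      j <- i + k - 1L
      if (j > n) next
      best <- Inf
      for (kp in 1:width) {
        jp <- i - 1L + kp - 1L
        if (jp > n) next
        step <- j - jp
        if (step < 0L || step > max_lag + 1L) next
        if (g[i - 1, kp] < best) best <- g[i - 1, kp]
      }
      g[i, k] <- best + abs(x[i] - y[j])
    }
  }
  g[n, 1] / n
}

#' @export
print.warp_result <- function(x, ...) {
  cat(sprintf("<warp_result> distance %.6g (raw %.6g / %d), path length %d\n",
              x$distance, x$raw_cost, x$normalization_constant,
              nrow(x$path)))
  invisible(x)
}

#' Exhaustive-enumeration oracle for DTW distances
#'
#' Brute-force minimum over every admissible warping path (undirected) or
#' forward mapping (directed), for use in tests only. Enumerates paths
#' recursively, so series are limited to length 8.
#'
#' @param x,y numeric series (N, M <= 8).
#' @param pattern `"undirected"` or `"directed"`.
#' @param window band half-width (undirected pattern).
#' @param max_lag forward lag bound (directed pattern).
#' @return The normalized minimum cost, identical in definition to the
#'   corresponding dynamic-programming distance.
#' @export
oracle_min_cost <- function(x, y, pattern = c("undirected", "directed"),
                            window = 1L, max_lag = 1L) {
  pattern <- match.arg(pattern)
  check_series(x); check_series(y)
  n <- length(x); m <- length(y)
  if (n > 8 || m > 8) abort_config("oracle limited to series of length <= 8")
  cm <- abs(outer(x, y, "-"))
  if (pattern == "undirected") {
    if (abs(n - m) > window) abort_data("no admissible path under the band")
    best <- Inf
    recurse <- function(i, j, acc) {
      if (acc >= best) return(invisible())
      if (i == n && j == m) { best <<- acc; return(invisible()) }
      if (i < n && j < m && abs((i + 1) - (j + 1)) <= window)
        recurse(i + 1, j + 1, acc + 2 * cm[i + 1, j + 1])
      if (i < n && abs((i + 1) - j) <= window)
        recurse(i + 1, j, acc + cm[i + 1, j])
      if (j < m && abs(i - (j + 1)) <= window)
        recurse(i, j + 1, acc + cm[i, j + 1])
    }
    recurse(1, 1, 2 * cm[1, 1])
    if (!is.finite(best)) abort_data("no admissible path under the band")
    best / (n + m)
  } else {
    if (m != n) abort_data("directed DTW needs equal-length series")
    best <- Inf
    recurse <- function(i, jprev, acc) {
      if (acc >= best) return(invisible())
      if (i > n) { best <<- acc; return(invisible()) }
      for (j in i:min(i + max_lag, n)) {
        if (j < jprev || j - jprev > max_lag + 1) next
        recurse(i + 1, j, acc + cm[i, j])
      }
    }
    recurse(1, 1L, 0)   # j(1) >= 1 and j(1) - "j(0)" unconstrained from 1
    best / n
  }
}
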