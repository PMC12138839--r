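#' Configuration for the synthetic panel generator
#'
#' Describes a cohort with the statistical structure the DTW network
#' analysis assumes: clusters of attributes driven by shared latent AR(1)
#' factors (dimensions), optional one-step temporal precedence of a leader
#' attribute over followers, large between-person level differences,
#' inverted-valence attributes, monotone dropout, and imputation stacks.
#' The defaults emulate a Featback-style cohort: 355 subjects, six
#' assessments, the 12-attribute [default_schema()] grouped into four
#' dimensions, per-wave dropout hazard 0.075 (about 68% retention at the
#' final wave), and 100 imputation replicates.
#'
#' @param n_subjects number of subjects.
#' @param n_timepoints number of equally indexed assessments (>= 3).
#' @param clusters list of character vectors of attribute names; each
#'   cluster shares one latent factor. Must be disjoint.
#' @param factor_ar AR(1) coefficient of the latent factors, in \[0, 1).
#' @param loading factor loading of each attribute on its cluster factor.
#' @param noise_sd SD of the attribute-level measurement noise.
#' @param lead_spec optional list `(leader, followers, lag, coupling)`:
#'   followers read the leader's cluster factor `lag` steps late (only
#'   `lag = 1` is supported), scaled by `coupling`.
#' @param reversed_attributes attributes emitted with inverted valence
#'   (negated), to exercise reverse coding.
#' @param dropout_hazard per-timepoint post-baseline dropout probability.
#' @param n_imputations replicates produced when imputing.
#' @param seed integer seed; same config + seed gives bit-identical data.
#' @return A list of class `warpnet_config`.
#' @export
synthetic_config <- function(n_subjects = 355,
                             n_timepoints = 6,
                             clusters = default_clusters(),
                             factor_ar = 0.4,
                             loading = 1,
                             noise_sd = 0.5,
                             lead_spec = default_lead_spec(clusters),
                             reversed_attributes = default_reversed(clusters),
                             dropout_hazard = 0.075,
                             n_imputations = 100,
                             seed = 1L) {
  attrs <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(attrs)) abort_config("cluster lists must be disjoint")
  if (n_timepoints < 3) abort_config("n_timepoints must be >= 3")
  if (factor_ar < 0 || factor_ar >= 1) abort_config("factor_ar must be in [0, 1)")
  if (noise_sd < 0) abort_config("noise_sd must be >= 0")
  if (loading <= 0) abort_config("loading must be > 0")
  if (dropout_hazard < 0 || dropout_hazard >= 1) {
    abort_config("dropout_hazard must be in [0, 1)")
  }
  if (!is.null(lead_spec)) {
    if (!all(c(lead_spec$leader, lead_spec$followers) %in% attrs)) {
      abort_config("lead_spec names unknown attributes")
    }
    if (lead_spec$leader %in% lead_spec$followers) {
      abort_config("leader cannot be its own follower")
    }
    if (!is.null(lead_spec$lag) && lead_spec$lag != 1) {
      abort_config("only lag = 1 lead_spec is supported")
    }
    if (is.null(lead_spec$coupling)) lead_spec$coupling <- 1
  }
  if (!all(reversed_attributes %in% attrs)) {
    abort_config("reversed_attributes names unknown attributes")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_timepoints = as.integer(n_timepoints),
         clusters = clusters, factor_ar = factor_ar, loading = loading,
         noise_sd = noise_sd, lead_spec = lead_spec,
         reversed_attributes = reversed_attributes,
         dropout_hazard = dropout_hazard,
         n_imputations = as.integer(n_imputations),
         seed = as.integer(seed)),
    class = "warpnet_config"
  )
}

#' @rdname synthetic_config
#' @export
default_clusters <- function() {
  s <- default_schema()$name
  # the four dimensions reported for this attribute set: psychological
  # health (5), psychosocial resilience (2), disordered eating behaviors
  # (2), weight management (3)
  list(
    psychological_health = c("anxiety", "depression", "hrqol",
                             "self_rated_health", "edeq_global"),
    psychosocial_resilience = c("social_support", "self_efficacy"),
    disordered_eating = c("vomiting", "binge_eating"),
    weight_management = c("laxative_use", "bmi", "wellbeing")
  )
}

# the leader heads the largest cluster; its cluster-mates follow it one
# assessment later, so precedence and cluster membership are consistent
default_lead_spec <- function(clusters) {
  sizes <- lengths(clusters)
  big <- clusters[[which.max(sizes)]]
  list(leader = big[1], followers = big[-1], lag = 1, coupling = 1)
}

default_reversed <- function(clusters) {
  sch <- default_schema()
  intersect(sch$name[!sch$higher_is_worse], unlist(clusters, use.names = FALSE))
}

#' Reference configuration for validation studies
#'
#' The pinned parameter-recovery setting used throughout the test suite:
#' 12 attributes in planted clusters of sizes 5/2/2/3, 300 subjects, 6
#' timepoints, AR coefficient 0.4, loading 1, noise SD 0.5, one leader with
#' coupling 1, complete data (no dropout), single replicate.
#'
#' @param seed integer seed.
#' @return A `warpnet_config`.
#' @export
reference_config <- function(seed = 1L) {
  synthetic_config(n_subjects = 300, n_timepoints = 6,
                   factor_ar = 0.4, loading = 1, noise_sd = 0.5,
                   dropout_hazard = 0, n_imputations = 1, seed = seed)
}

#' Null configuration: independent attributes, no leader
#'
#' Every attribute has its own latent factor and nothing temporally
#' precedes anything, so directed-edge discoveries are false positives by
#' construction. Used to check test calibration.
#'
#' @param n_subjects cohort size (default 100).
#' @param n_attributes number of independent attributes (default 6).
#' @param seed integer seed.
#' @return A `warpnet_config`.
#' @export
null_config <- function(n_subjects = 100, n_attributes = 6, seed = 1L) {
  attrs <- paste0("attr", seq_len(n_attributes))
  synthetic_config(
    n_subjects = n_subjects, n_timepoints = 6,
    clusters = as.list(stats::setNames(attrs, attrs)),
    factor_ar = 0.4, loading = 1, noise_sd = 0.5,
    lead_spec = NULL, reversed_attributes = character(),
    dropout_hazard = 0, n_imputations = 1, seed = seed
  )
}

# evaluate expr with a private RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic panel with known ground truth
#'
#' Per subject, each cluster receives a latent AR(1) factor trajectory with
#' standard-normal innovations and stationary initialization (variance
#' `1 / (1 - ar^2)`). An attribute's value is
#' `subject_intercept + loading * f_t + Normal(0, noise_sd)`; follower
#' attributes of a `lead_spec` read the leader's factor one step late
#' (`coupling * loading * f_{t-1}`), with the factor series started one
#' step before baseline so the follower's first assessment reads a
#' stationary value. Subject intercepts are Normal(0, sd = 2 * noise_sd + 1),
#' creating the large between-person level differences that within-person
#' centering must remove. Reversed attributes are emitted negated.
#' Deterministic under `config$seed`.
#'
#' @param config a `warpnet_config`.
#' @return A list with `panel` (complete canonical panel tibble), `truth`
#'   (list: `cluster_labels` tibble, `leader`, `followers`, `factors` array),
#'   and `schema` (a `warpnet_schema` for the generated attributes).
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "warpnet_config")) {
    abort_config("config must be built by synthetic_config()")
  }
  attrs <- unlist(config$clusters, use.names = FALSE)
  k <- length(attrs)
  tt <- config$n_timepoints
  s <- config$n_subjects
  nc <- length(config$clusters)
  cluster_of <- rep(seq_len(nc), lengths(config$clusters))
  names(cluster_of) <- attrs
  lead <- config$lead_spec
  leader_cluster <- if (!is.null(lead)) cluster_of[[lead$leader]] else NA_integer_

  with_seed(config$seed, {
    phi <- config$factor_ar
    # factors: time runs t = -1, 0, ..., T-1 (row 1 is the pre-baseline value
    # followers read at baseline)
    fac <- array(NA_real_, dim = c(tt + 1, nc, s))
    fac[1, , ] <- stats::rnorm(nc * s, sd = sqrt(1 / (1 - phi^2)))
    for (t in 2:(tt + 1)) {
      fac[t, , ] <- phi * fac[t - 1, , ] + stats::rnorm(nc * s)
    }
    intercepts <- matrix(stats::rnorm(s * k, sd = 2 * config$noise_sd + 1),
                         s, k, dimnames = list(NULL, attrs))
    noise <- array(stats::rnorm(s * tt * k, sd = config$noise_sd),
                   dim = c(tt, k, s))

    vals <- array(NA_real_, dim = c(tt, k, s))
    for (ai in seq_len(k)) {
      a <- attrs[ai]
      follows <- !is.null(lead) && a %in% lead$followers
      ci <- if (follows) leader_cluster else cluster_of[[a]]
      rows <- if (follows) 1:tt else 2:(tt + 1)   # lagged vs current factor
      scale <- if (follows) lead$coupling * config$loading else config$loading
      vals[, ai, ] <- rep(intercepts[, ai], each = tt) +
        scale * fac[rows, ci, ] + noise[, ai, ]
    }
    for (a in config$reversed_attributes) {
      vals[, match(a, attrs), ] <- -vals[, match(a, attrs), ]
    }

    panel <- tibble::tibble(
      subject = rep(sprintf("s%04d", seq_len(s)), each = tt * k),
      time = rep(rep(0:(tt - 1), each = k), times = s),
      attribute = rep(attrs, times = s * tt),
      value = as.vector(aperm(vals, c(2, 1, 3)))
    )
    panel <- as_panel(panel)

    schema <- attribute_schema(
      name = attrs,
      higher_is_worse = !(attrs %in% config$reversed_attributes),
      group_hint = names(config$clusters)[cluster_of]
    )
    truth <- list(
      cluster_labels = tibble::tibble(attribute = attrs,
                                      cluster = unname(cluster_of)),
      leader = if (!is.null(lead)) lead$leader else NULL,
      followers = if (!is.null(lead)) lead$followers else NULL,
      factors = fac
    )
    list(panel = panel, truth = truth, schema = schema)
  })
}

#' Impose monotone dropout on a panel
#'
#' Each subject independently drops out at each post-baseline wave with
#' probability `hazard`; from the dropout wave onward all attribute values
#' are missing. Baseline is always observed, so expected retention at wave
#' t is `(1 - hazard)^t`.
#'
#' @param panel a complete canonical panel tibble.
#' @param hazard per-wave dropout probability in \[0, 1).
#' @param seed integer seed.
#' @return The panel with missing values for dropped waves.
#' @export
apply_dropout <- function(panel, hazard, seed = 1L) {
  if (hazard < 0 || hazard >= 1) abort_config("hazard must be in [0, 1)")
  if (hazard == 0) return(panel)
  dims <- panel_dims(panel)
  tps <- dims$timepoints
  with_seed(seed, {
    # dropout wave per subject: first post-baseline wave whose hazard draw
    # fires; Inf = completes the study
    draws <- matrix(stats::runif(length(dims$subjects) * (length(tps) - 1)),
                    nrow = length(dims$subjects))
    first_fire <- apply(draws < hazard, 1, function(z)
      if (any(z)) which(z)[1] else Inf)
    dropout_time <- tps[-1][ifelse(is.finite(first_fire), first_fire, NA)]
    names(first_fire) <- dims$subjects
    cutoff <- stats::setNames(ifelse(is.finite(first_fire),
                                     dropout_time, Inf), dims$subjects)
    panel$value[panel$time >= cutoff[panel$subject]] <- NA_real_
    panel
  })
}

#' Naive imputation stack (test double)
#'
#' Fills monotone-missing values by last observation carried forward plus a
#' Normal(0, residual SD) perturbation, the residual SD estimated per
#' attribute from observed one-step within-person changes. This is a test
#' double standing in for a proper multiple-imputation model: it produces
#' stacks with the right shape and between-replicate variability, and is
#' not a recommended imputation method for real data.
#'
#' @param panel a panel tibble with monotone missingness.
#' @param n_imputations number of replicates M.
#' @param seed integer seed.
#' @return A list of M complete panel tibbles, each carrying its replicate
#'   index in the `imputation` column.
#' @export
naive_impute <- function(panel, n_imputations = 5, seed = 1L) {
  if ("imputation" %in% names(panel)) {
    abort_data("panel already carries an imputation column")
  }
  dims <- panel_dims(panel)
  ok <- dplyr::summarise(
    dplyr::group_by(panel, .data$subject, .data$attribute),
    any_obs = any(!is.na(.data$value)), .groups = "drop"
  )
  if (!all(ok$any_obs)) {
    abort_data("a subject has no observed values for an attribute; cannot impute")
  }
  # residual SD per attribute from observed consecutive one-step changes
  steps <- dplyr::mutate(
    dplyr::group_by(dplyr::arrange(panel, .data$subject, .data$attribute,
                                   .data$time),
                    .data$subject, .data$attribute),
    step = .data$value - dplyr::lag(.data$value)
  )
  steps <- dplyr::ungroup(steps)
  resid_sd <- dplyr::summarise(
    dplyr::group_by(steps, .data$attribute),
    sd = stats::sd(.data$step, na.rm = TRUE), .groups = "drop"
  )
  resid_sd$sd[is.na(resid_sd$sd)] <- 0
  sd_of <- stats::setNames(resid_sd$sd, resid_sd$attribute)

  locf <- dplyr::mutate(
    dplyr::group_by(dplyr::arrange(panel, .data$subject, .data$attribute,
                                   .data$time),
                    .data$subject, .data$attribute),
    filled = locf_fill(.data$value)
  )
  locf <- dplyr::ungroup(locf)
  miss <- is.na(locf$value)
  with_seed(seed, {
    lapply(seq_len(n_imputations), function(m) {
      rep_panel <- locf
      pert <- stats::rnorm(sum(miss), sd = sd_of[rep_panel$attribute[miss]])
      rep_panel$value <- rep_panel$filled
      rep_panel$value[miss] <- rep_panel$value[miss] + pert
      rep_panel$filled <- NULL
      rep_panel$imputation <- m
      as_panel(rep_panel)
    })
  })
}

locf_fill <- function(x) {
  for (i in seq_along(x)) {
    if (is.na(x[i]) && i > 1) x[i] <- x[i - 1]
  }
  x
}

#' Bind an imputation stack into one stacked panel
#'
#' @param reps list of complete panel tibbles with `imputation` columns.
#' @return A single stacked canonical panel tibble.
#' @export
bind_imputations <- function(reps) {
  as_panel(dplyr::bind_rows(reps))
}
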