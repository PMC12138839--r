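#' Align attribute valences by reverse coding
#'
#' Attributes flagged `higher_is_worse = FALSE` in the schema are negated so
#' that, afterwards, a higher score consistently indicates a worse outcome
#' for every attribute. Negation (rather than max-minus-score) is used
#' because the subsequent centering removes any additive constant, making
#' the two equivalent without needing scale bounds. Missing values stay
#' missing. Applying the function twice restores the input.
#'
#' @param panel a canonical panel tibble.
#' @param schema a `warpnet_schema` covering all attributes in the panel.
#' @return The panel with reversed attributes negated.
#' @export
reverse_code <- function(panel, schema) {
  schema <- check_schema(schema)
  unknown <- setdiff(unique(panel$attribute), schema$name)
  if (length(unknown) > 0) {
    abort_data(paste0("attribute(s) not in schema: ",
                      paste(unknown, collapse = ", ")))
  }
  reversed <- schema$name[!schema$higher_is_worse]
  dplyr::mutate(panel, value = ifelse(.data$attribute %in% reversed,
                                      -.data$value, .data$value))
}

#' Center each attribute within person
#'
#' Subtracts, for every (subject, attribute) series, the mean over that
#' subject's observed timepoints, removing between-person differences in
#' level so that only within-person change remains. Missing entries are
#' untouched; a series with no observed points stays all-missing. The
#' operation is idempotent.
#'
#' @param panel a canonical panel tibble.
#' @return The centered panel.
#' @export
center_within_person <- function(panel) {
  grp <- c(if ("imputation" %in% names(panel)) "imputation",
           "subject", "attribute")
  out <- dplyr::mutate(
    dplyr::group_by(panel, !!!rlang::syms(grp)),
    value = .data$value - mean(.data$value, na.rm = TRUE)
  )
  out <- dplyr::ungroup(out)
  out$value[is.nan(out$value)] <- NA_real_
  out
}

#' Standardize centered values at the group level
#'
#' Divides each attribute's (already within-person centered) values by the
#' population standard deviation (denominator n) of that attribute's pooled
#' centered values over all subjects and timepoints, computed on observed
#' values only. Afterwards every attribute's pooled SD is exactly 1, so DTW
#' distances weight within-person change equally across attributes. For an
#' imputation stack the SD is computed per replicate.
#'
#' @param panel a centered panel tibble.
#' @return The standardized panel.
#' @export
standardize_group <- function(panel) {
  grp <- c(if ("imputation" %in% names(panel)) "imputation", "attribute")
  pooled <- dplyr::summarise(
    dplyr::group_by(panel, !!!rlang::syms(grp)),
    pooled_sd = pop_sd(.data$value),
    .groups = "drop"
  )
  bad <- pooled$attribute[is.na(pooled$pooled_sd) | pooled$pooled_sd == 0]
  if (length(bad) > 0) {
    abort_data(paste0("zero group-level variance for attribute(s): ",
                      paste(unique(bad), collapse = ", ")))
  }
  out <- dplyr::left_join(panel, pooled, by = grp)
  out$value <- out$value / out$pooled_sd
  out$pooled_sd <- NULL
  out
}

# population SD (denominator n) over observed values; scale factor only, so
# the n vs n-1 choice cannot affect downstream results -- pinned for
# determinism
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Full preprocessing pipeline: reverse-code, center, standardize
#'
#' The pinned order of operations before any DTW distance is computed.
#'
#' @inheritParams reverse_code
#' @return The preprocessed panel.
#' @export
preprocess_panel <- function(panel, schema) {
  panel |>
    reverse_code(schema) |>
    center_within_person() |>
    standardize_group()
}
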