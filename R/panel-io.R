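#' Validate and canonicalize a long-format panel
#'
#' A panel is a long tibble with one row per (subject, time, attribute)
#' observation: columns `subject` (character), `time` (integer assessment
#' index, 0-based, assumed equally spaced), `attribute` (character, must
#' appear in the schema if one is supplied), `value` (double, `NA` =
#' missing), and optionally `imputation` (integer replicate index for
#' imputation stacks). Rows are sorted canonically by (imputation, subject,
#' time, attribute) and the grid is completed so every cell exists
#' explicitly (absent cells become `NA`).
#'
#' @param df a data frame with the columns above.
#' @param schema optional `warpnet_schema`; unknown attributes are an error.
#' @return A canonical panel tibble.
#' @export
as_panel <- function(df, schema = NULL) {
  required <- c("subject", "time", "attribute", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort_data(paste0("missing required column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  df <- tibble::as_tibble(df)
  df$subject <- as.character(df$subject)
  time_int <- suppressWarnings(as.integer(df$time))
  if (anyNA(time_int)) abort_data("time must parse to integer")
  df$time <- time_int
  df$attribute <- as.character(df$attribute)
  df$value <- as.double(df$value)
  has_imp <- "imputation" %in% names(df)
  if (has_imp) df$imputation <- as.integer(df$imputation)

  if (!is.null(schema)) {
    schema <- check_schema(schema)
    unknown <- setdiff(unique(df$attribute), schema$name)
    if (length(unknown) > 0) {
      abort_data(paste0("attribute(s) not in schema: ",
                        paste(unknown, collapse = ", ")))
    }
  }

  key_cols <- c(if (has_imp) "imputation", "subject", "time", "attribute")
  dup <- duplicated(df[key_cols])
  if (any(dup)) {
    first <- df[which(dup)[1L], key_cols]
    abort_data(paste0("duplicate record: ",
                      paste(unlist(first), collapse = ", ")))
  }

  n_time <- length(unique(df$time))
  if (n_time < 3) {
    abort_data("panel has fewer than 3 timepoints; DTW needs at least 3")
  }

  # complete the (subject x time x attribute) grid within each replicate
  attr_levels <- if (is.null(schema)) sort(unique(df$attribute)) else
    intersect(schema$name, unique(df$attribute))
  df <- tidyr::complete(df,
    !!!rlang::syms(if (has_imp) "imputation" else character()),
    subject = unique(df$subject),
    time = sort(unique(df$time)),
    attribute = attr_levels
  )
  df$attribute <- factor(df$attribute, levels = attr_levels)
  df <- dplyr::arrange(df, !!!rlang::syms(key_cols))
  df$attribute <- as.character(df$attribute)
  dplyr::relocate(df, !!!rlang::syms(c(key_cols, "value")))
}

panel_dims <- function(panel) {
  list(
    subjects = unique(panel$subject),
    timepoints = sort(unique(panel$time)),
    attributes = unique(panel$attribute),
    n_imputations = if ("imputation" %in% names(panel))
      length(unique(panel$imputation)) else 1L
  )
}

#' Read a long-format panel CSV
#'
#' Expects a header with subject, time, attribute, and value columns (names
#' configurable via `cols`); an empty field or `NA` marks a missing value.
#'
#' @param path CSV file path.
#' @param schema optional `warpnet_schema` used to validate attribute names.
#' @param cols named character vector mapping canonical names
#'   (`subject`, `time`, `attribute`, `value`, `imputation`) to the file's
#'   column names.
#' @return A canonical panel tibble.
#' @export
read_panel_long <- function(path, schema = NULL,
                            cols = c(subject = "subject", time = "time",
                                     attribute = "attribute", value = "value",
                                     imputation = "imputation")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  need <- cols[c("subject", "time", "attribute", "value")]
  missing_cols <- setdiff(unname(need), names(raw))
  if (length(missing_cols) > 0) {
    abort_data(paste0("missing required column(s): ",
                      paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(
    subject = raw[[need[["subject"]]]],
    time = raw[[need[["time"]]]],
    attribute = raw[[need[["attribute"]]]],
    value = raw[[need[["value"]]]]
  )
  imp_col <- cols[["imputation"]]
  if (!is.na(imp_col) && imp_col %in% names(raw)) {
    out$imputation <- raw[[imp_col]]
  }
  as_panel(out, schema)
}

#' Read a wide-format panel CSV
#'
#' Convenience reader for one-column-per-attribute exports: columns
#' `subject`, `time`, then one column per attribute. Normalized internally
#' to the canonical long form.
#'
#' @inheritParams read_panel_long
#' @return A canonical panel tibble.
#' @export
read_panel_wide <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!all(c("subject", "time") %in% names(raw))) {
    abort_data("wide panel needs 'subject' and 'time' columns")
  }
  long <- tidyr::pivot_longer(tibble::as_tibble(raw),
                              cols = -dplyr::all_of(c("subject", "time")),
                              names_to = "attribute", values_to = "value")
  as_panel(long, schema)
}

#' Write a panel to the canonical long CSV dialect
#'
#' Comma-separated, UTF-8, header row, missing values written as empty
#' fields. `read_panel_long(write_panel_long(ds))` round-trips exactly.
#'
#' @param panel a canonical panel tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel_long <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an imputation stack
#'
#' A stack is a long CSV with an extra `imputation` column holding replicate
#' indices 1..M (contiguous). Every replicate must be complete (no missing
#' values) and all replicates must share the same subjects, timepoints, and
#' attributes.
#'
#' @inheritParams read_panel_long
#' @return A list of M complete panel tibbles, one per replicate, each
#'   carrying its index in the `imputation` column.
#' @export
read_imputation_stack <- function(path, schema = NULL,
                                  cols = c(subject = "subject", time = "time",
                                           attribute = "attribute",
                                           value = "value",
                                           imputation = "imputation")) {
  panel <- read_panel_long(path, schema, cols)
  if (!"imputation" %in% names(panel)) {
    abort_data("imputation stack needs an imputation column")
  }
  split_imputations(panel)
}

#' Split a stacked panel into per-replicate panels
#'
#' @param panel a panel tibble with an `imputation` column.
#' @return A list of complete panel tibbles.
#' @export
split_imputations <- function(panel) {
  idx <- sort(unique(panel$imputation))
  if (!identical(idx, seq_along(idx))) {
    abort_data(paste0("non-contiguous imputation indices: ",
                      paste(idx, collapse = ", ")))
  }
  reps <- lapply(idx, function(m) panel[panel$imputation == m, , drop = FALSE])
  shapes <- lapply(reps, function(r)
    list(s = unique(r$subject), t = sort(unique(r$time)),
         a = unique(r$attribute)))
  for (m in seq_along(reps)) {
    if (anyNA(reps[[m]]$value)) {
      abort_data(paste0("imputation replicate ", m, " contains missing values"))
    }
    if (!identical(shapes[[m]], shapes[[1L]])) {
      abort_data("imputation replicates differ in shape")
    }
  }
  reps
}

#' Summarize panel completeness and degeneracies
#'
#' Reports, without mutating the data: per-attribute missingness fractions,
#' per-timepoint retention (fraction of subjects with at least one observed
#' attribute at that wave), and warnings for attributes with zero
#' group-level variance.
#'
#' @param panel a canonical panel tibble.
#' @return A list of class `warpnet_validation` with tibbles
#'   `attribute_missingness` and `timepoint_retention`, a character vector
#'   `warnings`, and the panel dimensions.
#' @export
validate_panel <- function(panel) {
  dims <- panel_dims(panel)
  by_attr <- dplyr::summarise(
    dplyr::group_by(panel, .data$attribute),
    n = dplyr::n(),
    n_missing = sum(is.na(.data$value)),
    missing_fraction = mean(is.na(.data$value)),
    .groups = "drop"
  )
  by_time <- dplyr::summarise(
    dplyr::group_by(panel, .data$time, .data$subject),
    any_observed = any(!is.na(.data$value)),
    .groups = "drop"
  )
  retention <- dplyr::summarise(
    dplyr::group_by(by_time, .data$time),
    n_retained = sum(.data$any_observed),
    retention = mean(.data$any_observed),
    .groups = "drop"
  )
  sds <- dplyr::summarise(
    dplyr::group_by(panel, .data$attribute),
    sd = stats::sd(.data$value, na.rm = TRUE),
    n_obs = sum(!is.na(.data$value)),
    .groups = "drop"
  )
  flat <- sds$attribute[!is.na(sds$sd) & sds$sd == 0 & sds$n_obs > 1]
  warnings <- if (length(flat) > 0) {
    paste0("zero group-level variance: ", flat)
  } else {
    character()
  }
  structure(
    list(
      n_subjects = length(dims$subjects),
      n_timepoints = length(dims$timepoints),
      n_attributes = length(dims$attributes),
      attribute_missingness = by_attr,
      timepoint_retention = retention,
      warnings = warnings
    ),
    class = "warpnet_validation"
  )
}

#' @export
print.warpnet_validation <- function(x, ...) {
  cat(sprintf("Panel: %d subjects x %d timepoints x %d attributes\n",
              x$n_subjects, x$n_timepoints, x$n_attributes))
  cat("Per-timepoint retention:\n")
  print(x$timepoint_retention)
  cat("Per-attribute missingness:\n")
  print(x$attribute_missingness)
  if (length(x$warnings) > 0) {
    cat("Warnings:\n")
    for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}
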