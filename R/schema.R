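#' Construct an attribute schema
#'
#' The schema declares every attribute (network node) the analysis may see:
#' a short identifier, a display label, and a valence flag stating whether a
#' higher raw score means a worse outcome. Attributes with
#' `higher_is_worse = FALSE` (e.g., well-being, social support) are
#' reverse-coded before any distance is computed so that higher always means
#' worse. `group_hint` is cosmetic (plot coloring only) and never enters the
#' analysis.
#'
#' @param name character vector of unique, non-empty attribute identifiers.
#' @param label display labels; defaults to `name`.
#' @param higher_is_worse logical valence flags, recycled if length 1.
#' @param group_hint optional character grouping used only for plot colors.
#'
#' @return A tibble of class `warpnet_schema` with columns `name`, `label`,
#'   `higher_is_worse`, `group_hint`.
#' @export
#' @examples
#' attribute_schema(c("depression", "wellbeing"),
#'                  higher_is_worse = c(TRUE, FALSE))
attribute_schema <- function(name, label = name, higher_is_worse = TRUE,
                             group_hint = NA_character_) {
  name <- as.character(name)
  if (length(name) == 0L || anyNA(name) || any(!nzchar(name))) {
    abort_data("schema attribute names must be non-empty")
  }
  if (anyDuplicated(name)) {
    abort_data(paste0("duplicate attribute name(s) in schema: ",
                      paste(unique(name[duplicated(name)]), collapse = ", ")))
  }
  out <- tibble::tibble(
    name = name,
    label = rep_len(as.character(label), length(name)),
    higher_is_worse = rep_len(as.logical(higher_is_worse), length(name)),
    group_hint = rep_len(as.character(group_hint), length(name))
  )
  if (anyNA(out$higher_is_worse)) {
    abort_data("higher_is_worse must be TRUE/FALSE for every attribute")
  }
  class(out) <- c("warpnet_schema", class(out))
  out
}

#' Default 12-attribute eating-disorder schema
#'
#' The attribute set of the Featback-style design: eating-disorder
#' psychopathology, binge eating, vomiting, laxative use, anxiety,
#' depression, BMI, social support, self-efficacy, well-being, health-related
#' quality of life, and self-rated health. BMI, social support,
#' self-efficacy, well-being, quality of life, and self-rated health are
#' marked `higher_is_worse = FALSE` (higher raw scores are better) and are
#' therefore reverse-coded by the pipeline. Whether self-rated health (a
#' 0-100 "best imaginable health" scale) should be reverse-coded is a schema
#' setting, not hard-coded: edit the returned tibble to change it.
#'
#' @return A `warpnet_schema` tibble with 12 rows.
#' @export
default_schema <- function() {
  attribute_schema(
    name = c("bmi", "social_support", "self_efficacy", "edeq_global",
             "binge_eating", "vomiting", "laxative_use", "anxiety",
             "depression", "wellbeing", "hrqol", "self_rated_health"),
    label = c("BMI", "Social support", "Self-efficacy", "ED psychopathology",
              "Binge eating", "Vomiting", "Laxative use", "Anxiety",
              "Depression", "Well-being", "HR quality of life",
              "Self-rated health"),
    higher_is_worse = c(FALSE, FALSE, FALSE, TRUE,
                        TRUE, TRUE, TRUE, TRUE,
                        TRUE, FALSE, FALSE, FALSE)
  )
}

#' Read an attribute schema from YAML, JSON, or CSV
#'
#' YAML/JSON files hold a list of records with fields `name`, optional
#' `label`, `higher_is_worse`, optional `group_hint`; CSV files need the same
#' columns.
#'
#' @param path file path; format inferred from the extension
#'   (`.yaml`/`.yml`, `.json`, `.csv`).
#' @return A `warpnet_schema` tibble.
#' @export
read_schema <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    csv  = utils::read.csv(path, stringsAsFactors = FALSE),
    abort_config(paste0("unsupported schema format: .", ext))
  )
  if (!is.data.frame(rec)) {
    rec <- dplyr::bind_rows(lapply(rec, tibble::as_tibble))
  }
  if (!all(c("name", "higher_is_worse") %in% names(rec))) {
    abort_config("schema needs at least 'name' and 'higher_is_worse' fields")
  }
  attribute_schema(
    name = rec$name,
    label = if ("label" %in% names(rec)) rec$label else rec$name,
    higher_is_worse = rec$higher_is_worse,
    group_hint = if ("group_hint" %in% names(rec)) rec$group_hint else NA_character_
  )
}

#' Write an attribute schema to YAML
#'
#' @param schema a `warpnet_schema` tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  recs <- purrr::pmap(schema, function(name, label, higher_is_worse, group_hint) {
    r <- list(name = name, label = label, higher_is_worse = higher_is_worse)
    if (!is.na(group_hint)) r$group_hint <- group_hint
    r
  })
  yaml::write_yaml(recs, path)
  invisible(path)
}

check_schema <- function(schema) {
  if (!inherits(schema, "warpnet_schema")) {
    schema <- attribute_schema(schema$name, schema$label,
                               schema$higher_is_worse, schema$group_hint)
  }
  schema
}
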