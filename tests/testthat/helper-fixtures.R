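# In-code fixtures shared across test files.

# tiny two-attribute schema
tiny_schema <- function() {
  attribute_schema(c("depression", "wellbeing"),
                   higher_is_worse = c(TRUE, FALSE))
}

# small complete panel: 2 subjects x 3 timepoints x 2 attributes
tiny_panel <- function() {
  grid <- expand.grid(subject = c("s1", "s2"), time = 0:2,
                      attribute = c("depression", "wellbeing"),
                      stringsAsFactors = FALSE)
  grid$value <- seq(0.5, by = 0.25, length.out = nrow(grid))
  as_panel(grid, tiny_schema())
}

# panel built from explicit per-subject series matrices:
# series[[subject]] is a T x K matrix with attribute columns
panel_from_series <- function(series, attrs = NULL) {
  rows <- lapply(names(series), function(s) {
    m <- series[[s]]
    if (is.null(attrs)) attrs <- colnames(m)
    data.frame(
      subject = s,
      time = rep(0:(nrow(m) - 1), times = ncol(m)),
      attribute = rep(attrs, each = nrow(m)),
      value = as.vector(m)
    )
  })
  as_panel(do.call(rbind, rows))
}

# random series pair admissible for the undirected band-1 pattern
random_pair <- function(min_len = 4, max_len = 8) {
  n <- sample(min_len:max_len, 1)
  m <- max(min_len, min(max_len, n + sample(-1:1, 1)))
  list(x = rnorm(n), y = rnorm(m))
}

expect_panel_equal <- function(a, b) {
  expect_equal(as.data.frame(a), as.data.frame(b))
}
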