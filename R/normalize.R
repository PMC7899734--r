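#' Percent-normalize indegree within one interval
#'
#' Divides each AOI's indegree by the interval's indegree total, giving the
#' share of all received attention shifts attributed to that AOI; shares sum
#' to 1. Percent normalization is meaningful for indegree only (closeness and
#' betweenness totals have no such interpretation), so other measures are
#' rejected rather than silently computed.
#'
#' @param measures Measure tibble rows from a single interval, with columns
#'   `interval`, `aoi`, `indegree`.
#' @return The input with an added `indegree_pct` column.
#' @export
percent_normalize_indegree <- function(measures) {
  check_one_interval(measures)
  if (!"indegree" %in% names(measures)) {
    cli::cli_abort("Percent normalization applies to indegree only; no {.val indegree} column found.")
  }
  total <- sum(measures$indegree)
  if (total == 0) {
    cli::cli_warn("All indegrees are zero in this interval; percent shares set to 0.")
    return(mutate(measures, indegree_pct = 0))
  }
  mutate(measures, indegree_pct = .data$indegree / total)
}

#' Distance-normalize a measure within one interval
#'
#' Rescales a measure to `(value - min) / (max - min)` over the interval's
#' AOIs: the most important AOI maps to 1 and the least to 0, making values
#' comparable across intervals and observers. Defined for all three
#' importance measures. When every AOI ties (max = min) all values map to 0,
#' keeping the "distance from the maximum" reading without dividing by zero.
#'
#' @param measures Measure tibble rows from a single interval.
#' @param measure Name of the measure column (`"indegree"`, `"closeness"`, or
#'   `"betweenness"`).
#' @return The input with an added `<measure>_dist` column.
#' @export
distance_normalize <- function(measures, measure) {
  if (nrow(measures) == 0) cli::cli_abort("Cannot normalize an empty record set.")
  check_one_interval(measures)
  if (!measure %in% names(measures)) {
    cli::cli_abort("No column {.val {measure}} in the measure table.")
  }
  v <- measures[[measure]]
  rng <- range(v)
  if (rng[1] == rng[2]) {
    cli::cli_warn("All {measure} values tie in this interval; distance-normalized values set to 0.")
    norm <- rep(0, length(v))
  } else {
    norm <- (v - rng[1]) / (rng[2] - rng[1])
  }
  measures[[paste0(measure, "_dist")]] <- norm
  measures
}

check_one_interval <- function(measures) {
  if (length(unique(measures$interval)) > 1) {
    cli::cli_abort("Records span several intervals; normalize one interval at a time.")
  }
  invisible(measures)
}

#' Normalize all measures across every interval
#'
#' Applies percent normalization (indegree) and distance normalization (all
#' three measures) interval by interval, returning a long tibble ready for
#' the dot-plot and bar-plot renderers.
#'
#' @param measures Full measure table from [measure_table()].
#' @return A long tibble with columns `interval`, `aoi`, `measure`, `value`,
#'   `percent_norm` (`NA` except for indegree), `distance_norm`.
#' @export
normalize_measures <- function(measures) {
  parts <- map(split(measures, measures$interval), function(df) {
    df <- percent_normalize_indegree(df)
    for (m in c("indegree", "closeness", "betweenness")) {
      df <- distance_normalize(df, m)
    }
    long <- tidyr::pivot_longer(
      df, cols = c("indegree", "closeness", "betweenness"),
      names_to = "measure", values_to = "value"
    )
    long |>
      mutate(
        percent_norm = ifelse(.data$measure == "indegree", .data$indegree_pct, NA_real_),
        distance_norm = dplyr::case_when(
          measure == "indegree" ~ indegree_dist,
          measure == "closeness" ~ closeness_dist,
          TRUE ~ betweenness_dist
        )
      ) |>
      select("interval", "aoi", "measure", "value", "percent_norm", "distance_norm")
  })
  bind_rows(parts) |> arrange(.data$interval)
}
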