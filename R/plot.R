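#' Visual encoding options for dynamic-network figures
#'
#' Node area is proportional to the number of fixations received, node fill
#' follows a sequential yellow-to-red scale over total dwell duration (red =
#' long dwell), and edge width is proportional to the transition count.
#'
#' @param node_size_scale Multiplier from fixation count to node area units.
#' @param edge_width_scale Multiplier from transition count to line width.
#' @param min_node_size Floor on the rendered node size so rarely fixated
#'   states stay visible.
#' @param low,high Colors bounding the dwell scale.
#' @param color_bounds `"global"` (default) scales dwell color over all
#'   intervals of the figure so panels are comparable; `"interval"` rescales
#'   within each panel.
#' @return A list of class `dnet_encoding`.
#' @export
dnet_encoding <- function(node_size_scale = 1, edge_width_scale = 1,
                          min_node_size = 0.5, low = "#FFEDA0", high = "#BD0026",
                          color_bounds = c("global", "interval")) {
  stopifnot(node_size_scale > 0, edge_width_scale > 0, min_node_size > 0)
  structure(list(node_size_scale = node_size_scale,
                 edge_width_scale = edge_width_scale,
                 min_node_size = min_node_size,
                 low = low, high = high,
                 color_bounds = match.arg(color_bounds)),
            class = "dnet_encoding")
}

dnet_node_table <- function(dnet, layout, enc) {
  nodes <- bind_rows(map(dnet$networks, function(net) {
    tibble(interval = net$window$index %||% NA_integer_,
           aoi = net$states,
           n_fixations = unname(net$fix_counts[net$states]),
           dwell_ms = unname(net$dwell_ms[net$states]))
  }))
  grid <- tidyr::expand_grid(
    interval = map_int(dnet$networks, function(n) as.integer(n$window$index)),
    aoi = dnet$universe
  )
  nodes <- left_join(grid, nodes, by = c("interval", "aoi")) |>
    mutate(present = !is.na(.data$n_fixations),
           n_fixations = ifelse(.data$present, .data$n_fixations, 0),
           dwell_ms = ifelse(.data$present, .data$dwell_ms, 0)) |>
    left_join(layout, by = "aoi")
  ramp <- scales::colour_ramp(c(enc$low, enc$high))
  nodes <- if (enc$color_bounds == "global") {
    mutate(nodes, dwell_unit = scales::rescale(.data$dwell_ms, from = range(.data$dwell_ms)))
  } else {
    nodes |> group_by(.data$interval) |>
      mutate(dwell_unit = scales::rescale(.data$dwell_ms, from = range(.data$dwell_ms))) |>
      ungroup()
  }
  nodes |>
    mutate(dwell_unit = ifelse(is.nan(.data$dwell_unit), 0, .data$dwell_unit),
           size = pmax(enc$min_node_size, enc$node_size_scale * .data$n_fixations),
           color = ramp(.data$dwell_unit))
}

dnet_edge_table <- function(dnet, layout, enc) {
  edges <- bind_rows(map(dnet$networks, tidy))
  if (nrow(edges) == 0) {
    return(tibble(interval = integer(), from = character(), to = character(),
                  count = numeric(), x = numeric(), y = numeric(),
                  xend = numeric(), yend = numeric(), width = numeric()))
  }
  edges |>
    left_join(layout, by = c(from = "aoi")) |>
    dplyr::rename(x = "col", y = "row") |>
    left_join(layout, by = c(to = "aoi")) |>
    dplyr::rename(xend = "col", yend = "row") |>
    mutate(width = enc$edge_width_scale * .data$count)
}

#' Dynamic-network small-multiples figure
#'
#' Renders one node-link panel per time interval, nodes at identical grid
#' positions in every panel (mental-map preservation), directed edges with
#' arrowheads, node size/color and edge width following the visual encoding.
#' States absent from an interval are drawn ghosted with their position
#' reserved. Alongside the ggplot, plain node/edge attribute tables (position,
#' size, color, width) are returned so tests and downstream tools never have
#' to parse image bytes.
#'
#' @param dnet A `gaze_dnet`.
#' @param encoding A [dnet_encoding()].
#' @param file Optional output path (`.pdf`, `.png`, ... by extension).
#' @param width,height Device size in inches when `file` is given.
#' @return An object of class `dnet_plot`: list with `plot` (ggplot), `nodes`,
#'   `edges`, `layout`.
#' @export
plot_dnet <- function(dnet, encoding = dnet_encoding(), file = NULL,
                      width = 8, height = 6) {
  stopifnot(inherits(dnet, "gaze_dnet"))
  layout <- grid_positions(dnet$universe)
  nodes <- dnet_node_table(dnet, layout, encoding)
  edges <- dnet_edge_table(dnet, layout, encoding)
  p <- ggplot() +
    geom_curve(
      data = edges,
      aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
          linewidth = .data$width),
      curvature = 0.15, color = "grey40",
      arrow = arrow(length = unit(0.12, "inches"), type = "closed")
    ) +
    geom_point(
      data = nodes,
      aes(x = .data$col, y = .data$row, size = .data$size),
      color = nodes$color, alpha = ifelse(nodes$present, 1, 0.15)
    ) +
    geom_text(data = nodes, aes(x = .data$col, y = .data$row, label = .data$aoi),
              vjust = -1.6, size = 3) +
    ggplot2::scale_linewidth_continuous(range = c(0.3, 2.5)) +
    scale_size_area(max_size = 12) +
    facet_wrap(~interval, labeller = ggplot2::label_both) +
    ggplot2::expand_limits(
      x = c(-0.5, max(layout$col) + 0.5),
      y = c(-0.5, max(layout$row) + 0.7)
    ) +
    theme_minimal() +
    theme(axis.title = element_blank(), axis.text = element_blank(),
          panel.grid = element_blank(), legend.position = "none")
  maybe_save(p, file, width, height)
  structure(list(plot = p, nodes = nodes, edges = edges, layout = layout),
            class = "dnet_plot")
}

#' @export
print.dnet_plot <- function(x, ...) { print(x$plot); invisible(x) }

#' @export
#' @method autoplot gaze_dnet
autoplot.gaze_dnet <- function(object, ...) plot_dnet(object, ...)$plot

#' Dot plot of percent-normalized indegree over time
#'
#' Rows are AOI states in layout order, columns are time intervals; dot area
#' is proportional to the AOI's share of received attention in that interval,
#' and a zero share draws no dot. Shows at a glance how attention to each
#' target waxes and wanes.
#'
#' @param normalized Long tibble from [normalize_measures()] (indegree rows
#'   with a `percent_norm` column are used; passing a table without them is an
#'   error).
#' @param file Optional output path.
#' @param width,height Device size in inches.
#' @return An object of class `gaze_dotplot`: list with `plot` and `points`
#'   (the attribute table, including zero-share rows with `area = 0`).
#' @export
plot_indegree_dots <- function(normalized, file = NULL, width = 6, height = 4) {
  if (!all(c("measure", "percent_norm") %in% names(normalized)) ||
      !any(normalized$measure == "indegree")) {
    cli::cli_abort("Need percent-normalized indegree records (see {.fn normalize_measures}).")
  }
  pts <- normalized |>
    filter(.data$measure == "indegree") |>
    mutate(area = .data$percent_norm)
  layout_order <- order_states(unique(pts$aoi))
  pts <- mutate(pts, aoi = factor(.data$aoi, levels = rev(layout_order)))
  p <- ggplot(filter(pts, .data$area > 0),
              aes(x = .data$interval, y = .data$aoi, size = .data$area)) +
    geom_point(color = "#2B6CB0") +
    scale_size_area(max_size = 10, name = "indegree share") +
    labs(x = "time interval", y = "AOI state") +
    theme_minimal()
  maybe_save(p, file, width, height)
  structure(list(plot = p, points = as_tibble(pts)), class = "gaze_dotplot")
}

#' @export
print.gaze_dotplot <- function(x, ...) { print(x$plot); invisible(x) }

#' Grouped bar plot of distance-normalized measures
#'
#' Compares relative AOI importance within one interval. In
#' `mode = "by_participant"` the bars of each AOI group are participants (one
#' measure, `participant` column required; only AOI states common to all
#' participants are drawn so comparisons are like-for-like). In
#' `mode = "by_measure"` the bars are the three measures for one participant.
#' The vertical axis is fixed to `[0, 1]`, the range of distance-normalized
#' values.
#'
#' @param records Long tibble from [normalize_measures()] restricted to one
#'   interval (mixed intervals are an error), with `distance_norm` values;
#'   for `by_participant` also a `participant` column.
#' @param mode Grouping mode, see above.
#' @param file Optional output path.
#' @param width,height Device size in inches.
#' @return An object of class `gaze_barplot`: list with `plot` and `bars`.
#' @export
plot_measure_bars <- function(records, mode = c("by_measure", "by_participant"),
                              file = NULL, width = 6, height = 4) {
  mode <- match.arg(mode)
  check_one_interval(records)
  if (!"distance_norm" %in% names(records)) {
    cli::cli_abort("Need distance-normalized records (see {.fn normalize_measures}).")
  }
  if (mode == "by_participant") {
    if (!"participant" %in% names(records)) {
      cli::cli_abort("{.val by_participant} mode needs a {.val participant} column.")
    }
    if (length(unique(records$measure)) > 1) {
      cli::cli_abort("{.val by_participant} mode compares one measure at a time.")
    }
    common <- Reduce(intersect, split(records$aoi, records$participant))
    bars <- records |> filter(.data$aoi %in% common) |>
      mutate(group = .data$participant)
  } else {
    bars <- mutate(records, group = .data$measure)
  }
  bars <- mutate(bars, aoi = factor(.data$aoi, levels = order_states(unique(.data$aoi))))
  p <- ggplot(bars, aes(x = .data$aoi, y = .data$distance_norm, fill = .data$group)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    ylim(0, 1) +
    labs(x = "AOI state", y = "distance-normalized value", fill = NULL) +
    theme_minimal()
  maybe_save(p, file, width, height)
  structure(list(plot = p, bars = as_tibble(bars)), class = "gaze_barplot")
}

#' @export
print.gaze_barplot <- function(x, ...) { print(x$plot); invisible(x) }

maybe_save <- function(p, file, width, height) {
  if (is.null(file)) return(invisible(NULL))
  dir <- dirname(file)
  if (!dir.exists(dir)) cli::cli_abort("Output directory {.path {dir}} does not exist.")
  ggsave(file, plot = p, width = width, height = height)
  invisible(file)
}
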