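#' Read a fixation file
#'
#' Expects delimited text with header `onset_s,duration_ms,x_px,y_px`: one row
#' per detected fixation (onset in seconds from scenario start, duration in
#' milliseconds, display coordinates in pixels). Rows shorter than the
#' fixation duration threshold are dropped and the count reported; rows are
#' returned sorted by onset.
#'
#' @param path Path to the fixation file.
#' @param threshold_ms Minimum fixation duration in milliseconds (default 100,
#'   the usual detection threshold for this kind of display).
#' @return A tibble with columns `onset_s`, `duration_ms`, `x_px`, `y_px`.
#' @export
read_fixations <- function(path, threshold_ms = 100) {
  df <- read_numeric_table(path, c("onset_s", "duration_ms", "x_px", "y_px"))
  if (nrow(df) == 0) {
    cli::cli_warn("Fixation file {.path {path}} has no data rows.")
    return(df)
  }
  n_short <- sum(df$duration_ms < threshold_ms)
  if (n_short > 0) {
    cli::cli_inform("Dropped {n_short} fixation{?s} shorter than {threshold_ms} ms.")
  }
  df |>
    filter(.data$duration_ms >= threshold_ms) |>
    arrange(.data$onset_s)
}

#' Read a target trajectory file
#'
#' Expects delimited text with header
#' `time_s,label,icon_x,icon_y,block_x,block_y,block_w,block_h`: one row per
#' target per timestamp, giving the aircraft icon position and the data-block
#' rectangle (anchor = lower-left corner, plus width and height). A target is
#' considered present between its first and last sample; outside that span it
#' has no AOI region.
#'
#' @param path Path to the trajectory file.
#' @return A tibble grouped-ready by `label`, time-sorted within label.
#' @export
read_target_tracks <- function(path, check = TRUE) {
  df <- read_numeric_table(
    path,
    c("time_s", "icon_x", "icon_y", "block_x", "block_y", "block_w", "block_h"),
    character_cols = "label"
  )
  if (check) {
    dup <- df |> dplyr::count(.data$label, .data$time_s) |> filter(.data$n > 1)
    if (nrow(dup) > 0) {
      cli::cli_abort("Duplicate (label, time) rows in {.path {path}}, e.g. {dup$label[1]} at t={dup$time_s[1]}.")
    }
    if (any(df$block_w < 0 | df$block_h < 0)) {
      cli::cli_abort("Negative data-block geometry in {.path {path}}.")
    }
  }
  df |> arrange(.data$label, .data$time_s)
}

read_numeric_table <- function(path, numeric_cols, character_cols = character()) {
  if (!file.exists(path)) cli::cli_abort("File {.path {path}} does not exist.")
  df <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  )
  missing <- setdiff(c(numeric_cols, character_cols), names(df))
  if (length(missing) > 0) {
    cli::cli_abort("File {.path {path}} is missing column{?s} {.val {missing}}.")
  }
  df <- df[, c(intersect(names(df), c(numeric_cols, character_cols)))]
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      cli::cli_abort("Non-numeric value {.val {df[[col]][bad[1]]}} in column {.val {col}}, row {bad[1]} of {.path {path}}.")
    }
    df[[col]] <- parsed
  }
  as_tibble(df)
}

#' Write fixation and trajectory files
#'
#' Inverse of [read_fixations()] and [read_target_tracks()]; the synthetic
#' scenario generator uses these so simulated data round-trips through the
#' same readers real data would use.
#'
#' @param fixations,tracks Tibbles in the reader column layouts.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_fixations <- function(fixations, path) {
  readr::write_csv(fixations[, c("onset_s", "duration_ms", "x_px", "y_px")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_fixations
#' @export
write_target_tracks <- function(tracks, path) {
  cols <- c("time_s", "label", "icon_x", "icon_y", "block_x", "block_y",
            "block_w", "block_h")
  readr::write_csv(tracks[, cols], path, progress = FALSE)
  invisible(path)
}

# Interpolate every target's geometry at the given times.
# Returns a tibble (times x labels) with NA coordinates where a label is not
# present (outside its first..last sample span).
interp_tracks_at <- function(tracks, times) {
  by_label <- split(tracks, tracks$label)
  rows <- imap(by_label, function(tr, lab) {
    coords <- c("icon_x", "icon_y", "block_x", "block_y", "block_w", "block_h")
    vals <- map(coords, function(cc) {
      if (nrow(tr) == 1) {
        ifelse(times >= tr$time_s[1] & times <= tr$time_s[1], tr[[cc]][1], NA_real_)
      } else {
        approx(tr$time_s, tr[[cc]], xout = times, rule = 1, ties = "ordered")$y
      }
    })
    names(vals) <- coords
    tibble(time_s = times, label = lab, !!!vals)
  })
  bind_rows(rows)
}

# Axis-aligned bounding box over the icon point and the data-block rectangle,
# inflated by margin_px on all sides.
bbox_from_geometry <- function(g, margin_px) {
  tibble(
    label = g$label,
    xmin = pmin(g$icon_x, g$block_x) - margin_px,
    xmax = pmax(g$icon_x, g$block_x + g$block_w) + margin_px,
    ymin = pmin(g$icon_y, g$block_y) - margin_px,
    ymax = pmax(g$icon_y, g$block_y + g$block_h) + margin_px
  )
}

#' Dynamic AOI regions at a time point
#'
#' For every target present at time `t`, builds its AOI region: the
#' axis-aligned bounding box covering the aircraft icon and its data block
#' (geometry linearly interpolated between trajectory samples), inflated by
#' `margin_px` on all sides to absorb eye-tracker accuracy error. See
#' [visual_margin_px()] for converting a visual-angle margin to pixels.
#'
#' @param tracks Trajectory tibble from [read_target_tracks()].
#' @param t Time in seconds.
#' @param margin_px Non-negative inflation margin, pixels.
#' @return A tibble with columns `label`, `xmin`, `xmax`, `ymin`, `ymax`.
#' @export
aoi_regions_at <- function(tracks, t, margin_px = 0) {
  stopifnot(is.numeric(margin_px), margin_px >= 0, length(t) == 1)
  if (t < min(tracks$time_s) || t > max(tracks$time_s)) {
    cli::cli_warn("Time {t} s is outside the scenario span; no AOI regions.")
    return(tibble(label = character(), xmin = numeric(), xmax = numeric(),
                  ymin = numeric(), ymax = numeric()))
  }
  g <- interp_tracks_at(tracks, t) |> filter(!is.na(.data$icon_x))
  bbox_from_geometry(g, margin_px) |> arrange(.data$label)
}

#' Resolve a fixation against AOI regions
#'
#' `hit_test()` returns the AOI state for one display point: all labels whose
#' region contains it (an overlap state like `"(A;B)"` when inside an
#' intersection), or `NA` when it falls in no region. `resolve_aoi()` is the
#' vectorized version for a whole fixation stream, aligning each fixation with
#' the target geometry at its onset time.
#'
#' @param x,y Display coordinates in pixels.
#' @param regions Region tibble from [aoi_regions_at()].
#' @return `hit_test()`: a canonical state string or `NA_character_`.
#' @export
hit_test <- function(x, y, regions) {
  if (nrow(regions) == 0) return(NA_character_)
  inside <- x >= regions$xmin & x <= regions$xmax &
            y >= regions$ymin & y <= regions$ymax
  if (!any(inside)) return(NA_character_)
  aoi_state(regions$label[inside])
}

#' @rdname hit_test
#' @param fixations Fixation tibble (`onset_s`, `duration_ms`, `x_px`, `y_px`).
#' @param tracks Trajectory tibble.
#' @param margin_px AOI inflation margin, pixels.
#' @return `resolve_aoi()`: the fixation tibble with an added `aoi` column
#'   (canonical state or `NA` for off-AOI fixations).
#' @export
resolve_aoi <- function(fixations, tracks, margin_px = 0) {
  stopifnot(margin_px >= 0)
  if (nrow(fixations) == 0) return(mutate(fixations, aoi = character()))
  g <- interp_tracks_at(tracks, fixations$onset_s)
  boxes <- bbox_from_geometry(g, margin_px)
  n_fix <- nrow(fixations)
  labels <- unique(g$label)
  # one column per label, rows aligned with fixations
  hit_members <- vector("list", n_fix)
  for (lab in labels) {
    b <- boxes[g$label == lab, ]
    inside <- !is.na(b$xmin) &
      fixations$x_px >= b$xmin & fixations$x_px <= b$xmax &
      fixations$y_px >= b$ymin & fixations$y_px <= b$ymax
    idx <- which(inside)
    for (i in idx) hit_members[[i]] <- c(hit_members[[i]], lab)
  }
  aoi <- map_chr(hit_members, function(m) if (is.null(m)) NA_character_ else aoi_state(m))
  mutate(fixations, aoi = aoi)
}

#' Build the raw AOI fixation sequence for one time window
#'
#' Fixations with onset in `[window$start, window$end)` are resolved to AOI
#' states in time order; off-AOI fixations are dropped from the sequence (the
#' count is reported). Per-state fixation counts and dwell totals are attached
#' to the returned sequence for downstream visual encodings.
#'
#' @inheritParams resolve_aoi
#' @param window A list or one-row tibble with `start`, `end`, `index`.
#' @return A raw [aoi_seq] with `fix_counts` and `dwell_ms` payloads.
#' @export
build_raw_sequence <- function(fixations, tracks, window, margin_px = 0) {
  w <- normalize_window(window)
  stopifnot(!is.na(w$start), !is.na(w$end), w$start < w$end)
  fx <- fixations |>
    filter(.data$onset_s >= w$start, .data$onset_s < w$end) |>
    arrange(.data$onset_s)
  if (nrow(fx) == 0) {
    cli::cli_warn("No fixations in window [{w$start}, {w$end}).")
    return(aoi_seq(character(), window = w, fix_counts = numeric(), dwell_ms = numeric()))
  }
  fx <- resolve_aoi(fx, tracks, margin_px)
  n_off <- sum(is.na(fx$aoi))
  if (n_off > 0) {
    cli::cli_inform("Window {w$index %||% '?'}: ignored {n_off} off-AOI fixation{?s}.")
  }
  fx <- filter(fx, !is.na(.data$aoi))
  counts <- tapply(rep(1, nrow(fx)), fx$aoi, sum, default = 0)
  dwell <- tapply(fx$duration_ms, fx$aoi, sum, default = 0)
  aoi_seq(fx$aoi, window = w, collapsed = FALSE,
          fix_counts = counts[order_states(names(counts))],
          dwell_ms = dwell[order_states(names(dwell))])
}
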