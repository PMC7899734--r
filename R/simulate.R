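#' Specify a synthetic enroute-like target scenario
#'
#' Describes a radar-display scenario for the trajectory simulator: labeled
#' targets (aircraft icon + data block) that enter and leave a square display,
#' move continuously, and can be forced to overlap in time windows. Defaults
#' emulate a busy enroute sector: a 2048x2048 px display, 20 minutes, 39
#' targets labeled `A`-`Z` then `a`-`m`, around 20 present at any moment.
#'
#' @param display_px Display width/height in pixels.
#' @param duration_s Scenario length in seconds.
#' @param n_targets Number of targets (max 52; labels `A`-`Z` then `a`-`z`).
#' @param avg_on_screen Average number of targets present per frame; sets each
#'   target's presence span.
#' @param block_offset Data-block anchor offset from the icon, pixels (x, y).
#' @param block_size Data-block width and height, pixels.
#' @param speed_px_s Range of target speeds, pixels per second.
#' @param overlap_episodes Optional tibble with columns `a`, `b`, `start`,
#'   `end`: during `[start, end]` target `b` is steered next to target `a` so
#'   their AOI boxes intersect (entered and left via a short ramp).
#' @param sample_every_s Trajectory sampling period, seconds (display update
#'   rate).
#' @param seed Integer seed; the simulator is deterministic given the spec.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(display_px = c(2048, 2048), duration_s = 1200,
                          n_targets = 39, avg_on_screen = 20,
                          block_offset = c(15, 15), block_size = c(110, 50),
                          speed_px_s = c(5, 40), overlap_episodes = NULL,
                          sample_every_s = 1, seed = 1) {
  stopifnot(n_targets >= 1, n_targets <= 52, duration_s > 0,
            avg_on_screen > 0, avg_on_screen <= n_targets)
  if (!is.null(overlap_episodes)) {
    stopifnot(all(c("a", "b", "start", "end") %in% names(overlap_episodes)))
  }
  structure(
    list(display_px = display_px, duration_s = duration_s,
         n_targets = n_targets, avg_on_screen = avg_on_screen,
         block_offset = block_offset, block_size = block_size,
         speed_px_s = speed_px_s, overlap_episodes = overlap_episodes,
         sample_every_s = sample_every_s, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

target_labels <- function(n) c(LETTERS, letters)[seq_len(n)]

# Fold an unbounded linear path into [lo, hi] (billiard reflection), keeping
# motion piecewise linear at constant speed.
fold_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y <= span, y, 2 * span - y)
}

#' Simulate target trajectories
#'
#' Each target gets a presence span (length set by `avg_on_screen /
#' n_targets`, jittered), a random start position, and a constant-velocity
#' straight path reflected at the display edges, sampled on a regular grid.
#' The data block travels at a fixed offset from the icon. Overlap episodes
#' steer the second target of a pair alongside the first so their AOI boxes
#' verifiably intersect during the span; a pair not co-present throughout its
#' episode is an error.
#'
#' @param spec A [scenario_spec()].
#' @return A trajectory tibble in the [read_target_tracks()] layout.
#' @export
simulate_targets <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, simulate_targets_impl(spec))
}

simulate_targets_impl <- function(spec) {
  labs <- target_labels(spec$n_targets)
  pad <- 80  # keep icons away from the display border
  w <- spec$display_px[1]; h <- spec$display_px[2]
  base_len <- spec$duration_s * spec$avg_on_screen / spec$n_targets
  per_target <- map(labs, function(lab) {
    len <- min(spec$duration_s, base_len * runif(1, 0.7, 1.3))
    entry <- runif(1, 0, spec$duration_s - len)
    times <- seq(ceiling(entry), floor(entry + len), by = spec$sample_every_s)
    speed <- runif(1, spec$speed_px_s[1], spec$speed_px_s[2])
    angle <- runif(1, 0, 2 * pi)
    x0 <- runif(1, pad, w - pad); y0 <- runif(1, pad, h - pad)
    tibble(
      time_s = times, label = lab,
      icon_x = fold_into(x0 + speed * cos(angle) * (times - times[1]), pad, w - pad),
      icon_y = fold_into(y0 + speed * sin(angle) * (times - times[1]), pad, h - pad)
    )
  })
  tracks <- bind_rows(per_target)
  if (!is.null(spec$overlap_episodes)) {
    tracks <- apply_overlap_episodes(tracks, spec)
  }
  tracks |>
    mutate(block_x = .data$icon_x + spec$block_offset[1],
           block_y = .data$icon_y + spec$block_offset[2],
           block_w = spec$block_size[1], block_h = spec$block_size[2]) |>
    arrange(.data$label, .data$time_s)
}

apply_overlap_episodes <- function(tracks, spec) {
  ramp <- 5  # seconds to blend in/out of the forced-overlap position
  for (i in seq_len(nrow(spec$overlap_episodes))) {
    ep <- spec$overlap_episodes[i, ]
    ta <- filter(tracks, .data$label == ep$a)
    tb_idx <- which(tracks$label == ep$b)
    tb <- tracks[tb_idx, ]
    if (nrow(ta) == 0 || nrow(tb) == 0 ||
        min(ta$time_s) > ep$start || max(ta$time_s) < ep$end ||
        min(tb$time_s) > ep$start || max(tb$time_s) < ep$end) {
      cli::cli_abort(
        "Overlap episode {ep$a}/{ep$b} in [{ep$start}, {ep$end}] is infeasible: targets not co-present."
      )
    }
    ax <- approx(ta$time_s, ta$icon_x, xout = tb$time_s, rule = 2)$y
    ay <- approx(ta$time_s, ta$icon_y, xout = tb$time_s, rule = 2)$y
    wgt <- pmax(0, pmin(1, pmin((tb$time_s - (ep$start - ramp)) / ramp,
                                ((ep$end + ramp) - tb$time_s) / ramp)))
    tracks$icon_x[tb_idx] <- (1 - wgt) * tb$icon_x + wgt * (ax + 10)
    tracks$icon_y[tb_idx] <- (1 - wgt) * tb$icon_y + wgt * (ay - 10)
  }
  tracks
}

#' Specify a Markov scanpath model
#'
#' A first-order Markov chain over planned AOI targets drives the simulated
#' scanpath: rows of `transition` are conditional next-target distributions
#' (must sum to 1). Dwell durations are log-normal, truncated below at the
#' fixation-detection threshold; fixations land at the center of the planned
#' target's AOI box, plus optional Gaussian jitter; with probability
#' `off_aoi_rate` a stray fixation is inserted at a uniform display location
#' (the chain does not advance on strays).
#'
#' @param transition Square named row-stochastic matrix over target labels.
#' @param dwell_meanlog,dwell_sdlog Log-normal dwell parameters, log-ms
#'   (defaults: median 300 ms, sigma 0.5).
#' @param min_duration_ms Truncation threshold, milliseconds.
#' @param jitter_px SD of isotropic Gaussian placement jitter, pixels.
#' @param off_aoi_rate Probability of a stray off-target fixation, in `[0,1]`.
#' @param saccade_gap_ms Inter-fixation gap, milliseconds.
#' @param seed Integer seed.
#' @return A list of class `scanpath_model`.
#' @export
scanpath_model <- function(transition, dwell_meanlog = log(300),
                           dwell_sdlog = 0.5, min_duration_ms = 100,
                           jitter_px = 0, off_aoi_rate = 0,
                           saccade_gap_ms = 30, seed = 1) {
  stopifnot(is.matrix(transition), nrow(transition) == ncol(transition),
            !is.null(rownames(transition)),
            identical(rownames(transition), colnames(transition)),
            off_aoi_rate >= 0, off_aoi_rate <= 1)
  if (any(abs(rowSums(transition) - 1) > 1e-9)) {
    cli::cli_abort("Each transition-matrix row must sum to 1 (tolerance 1e-9).")
  }
  structure(
    list(transition = transition, dwell_meanlog = dwell_meanlog,
         dwell_sdlog = dwell_sdlog, min_duration_ms = min_duration_ms,
         jitter_px = jitter_px, off_aoi_rate = off_aoi_rate,
         saccade_gap_ms = saccade_gap_ms, seed = as.integer(seed)),
    class = "scanpath_model"
  )
}

#' Simulate a Markov-governed scanpath over moving targets
#'
#' Emits `n_fixations` fixations following the scanpath model: at each step
#' the planned target is drawn from the Markov chain; if it is not on screen
#' at emission time the step resamples among the model targets currently
#' present (renormalized row, occurrences reported). Deterministic given the
#' model seed.
#'
#' @param tracks Trajectory tibble ([simulate_targets()] or file).
#' @param model A [scanpath_model()].
#' @param n_fixations Number of fixations to emit.
#' @param start_s Onset of the first fixation (default: scenario start).
#' @return A fixation tibble (`onset_s`, `duration_ms`, `x_px`, `y_px`) with
#'   an extra `planned` column naming the intended target (`NA` for strays).
#' @export
simulate_scanpath <- function(tracks, model, n_fixations = 1000, start_s = NULL) {
  stopifnot(inherits(model, "scanpath_model"), n_fixations >= 1)
  with_seed(model$seed, simulate_scanpath_impl(tracks, model, n_fixations, start_s))
}

simulate_scanpath_impl <- function(tracks, model, n_fixations, start_s) {
  labs <- rownames(model$transition)
  missing <- setdiff(labs, unique(tracks$label))
  if (length(missing) > 0) {
    cli::cli_abort("Model target{?s} {.val {missing}} not in the trajectory data.")
  }
  span <- map(split(tracks, tracks$label)[labs],
              function(tr) range(tr$time_s))
  interp <- map(split(tracks, tracks$label)[labs], function(tr) {
    list(icon_x = stats::approxfun(tr$time_s, tr$icon_x, rule = 2),
         icon_y = stats::approxfun(tr$time_s, tr$icon_y, rule = 2),
         block_x = stats::approxfun(tr$time_s, tr$block_x, rule = 2),
         block_y = stats::approxfun(tr$time_s, tr$block_y, rule = 2),
         block_w = tr$block_w[1], block_h = tr$block_h[1])
  })
  present_at <- function(t) labs[map_lgl(span, function(r) t >= r[1] & t <= r[2])]
  center_of <- function(lab, t) {
    f <- interp[[lab]]
    ix <- f$icon_x(t); iy <- f$icon_y(t)
    bx <- f$block_x(t); by <- f$block_y(t)
    c((min(ix, bx) + max(ix, bx + f$block_w)) / 2,
      (min(iy, by) + max(iy, by + f$block_h)) / 2)
  }
  draw_dwell <- function() {
    d <- rlnorm(1, model$dwell_meanlog, model$dwell_sdlog)
    while (d < model$min_duration_ms) d <- rlnorm(1, model$dwell_meanlog, model$dwell_sdlog)
    d
  }
  t <- start_s %||% min(tracks$time_s)
  onset <- duration <- x <- y <- numeric(n_fixations)
  planned <- character(n_fixations)
  current <- NA_character_
  n_resampled <- 0
  i <- 1
  while (i <= n_fixations) {
    pres <- present_at(t)
    if (length(pres) == 0) {
      cli::cli_abort("No model target on screen at t = {round(t, 1)} s.")
    }
    stray <- model$off_aoi_rate > 0 && runif(1) < model$off_aoi_rate
    if (stray) {
      lab <- NA_character_
      pos <- c(runif(1, 0, max(tracks$icon_x) + 100),
               runif(1, 0, max(tracks$icon_y) + 100))
    } else {
      lab <- if (is.na(current)) {
        sample(pres, 1)
      } else {
        sample(labs, 1, prob = model$transition[current, ])
      }
      if (!lab %in% pres) {
        n_resampled <- n_resampled + 1
        probs <- if (is.na(current)) rep(1, length(pres)) else model$transition[current, pres]
        if (sum(probs) == 0) probs <- rep(1, length(pres))
        lab <- pres[sample.int(length(pres), 1, prob = probs)]
      }
      pos <- center_of(lab, t)
      if (model$jitter_px > 0) pos <- pos + rnorm(2, 0, model$jitter_px)
      current <- lab
    }
    d <- draw_dwell()
    onset[i] <- t; duration[i] <- d; x[i] <- pos[1]; y[i] <- pos[2]
    planned[i] <- lab
    t <- t + (d + model$saccade_gap_ms) / 1000
    i <- i + 1
  }
  if (n_resampled > 0) {
    cli::cli_inform("Resampled {n_resampled} planned target{?s} that had left the display.")
  }
  tibble(onset_s = onset, duration_ms = duration, x_px = x, y_px = y,
         planned = planned)
}
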