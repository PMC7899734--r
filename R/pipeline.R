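#' Convert a visual-angle margin to pixels
#'
#' AOI boxes are inflated by a small visual-angle margin to absorb
#' eye-tracker accuracy error. The conversion uses the viewing geometry:
#' `margin_px = tan(margin_deg) * viewing_distance_cm * pixel_pitch`.
#' Defaults describe a 2048-px, 19.83-inch radar display viewed from 60 cm
#' (the middle of a typical 50-70 cm range) with a 0.75 degree margin, the
#' midpoint of the usual 0.5-1.0 degree tracker accuracy band.
#'
#' @param margin_deg Margin in degrees of visual angle.
#' @param viewing_distance_cm Eye-to-display distance, cm.
#' @param pixel_pitch_px_cm Display resolution, pixels per cm.
#' @return Margin in pixels.
#' @examples
#' visual_margin_px()  # ~32 px
#' @export
visual_margin_px <- function(margin_deg = 0.75, viewing_distance_cm = 60,
                             pixel_pitch_px_cm = 2048 / (19.83 * 2.54)) {
  stopifnot(margin_deg >= 0, viewing_distance_cm > 0, pixel_pitch_px_cm > 0)
  tan(margin_deg * pi / 180) * viewing_distance_cm * pixel_pitch_px_cm
}

#' Configuration for a full analysis run
#'
#' Collects every knob of the pipeline: input paths, interval specification
#' (equal count or explicit cuts), viewing geometry for the AOI margin,
#' fixation threshold, visual encoding, output directory, and seed.
#'
#' @param fixations_path,tracks_path Input files ([read_fixations()] /
#'   [read_target_tracks()] layouts).
#' @param intervals Number of equal intervals, or use `cuts`.
#' @param cuts Explicit interior cut points, seconds.
#' @param margin_deg,viewing_distance_cm,pixel_pitch_px_cm See
#'   [visual_margin_px()].
#' @param fixation_threshold_ms Minimum fixation duration, ms.
#' @param encoding A [dnet_encoding()].
#' @param out_dir Output directory (created if missing).
#' @param participant Participant label for the measure files.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fixations_path = NULL, tracks_path = NULL,
                       intervals = 4, cuts = NULL, margin_deg = 0.75,
                       viewing_distance_cm = 60,
                       pixel_pitch_px_cm = 2048 / (19.83 * 2.54),
                       fixation_threshold_ms = 100,
                       encoding = dnet_encoding(), out_dir = tempdir(),
                       participant = "P1", seed = 1) {
  stopifnot(fixation_threshold_ms > 0, viewing_distance_cm > 0,
            pixel_pitch_px_cm > 0, margin_deg >= 0)
  structure(
    list(fixations_path = fixations_path, tracks_path = tracks_path,
         intervals = intervals, cuts = cuts, margin_deg = margin_deg,
         viewing_distance_cm = viewing_distance_cm,
         pixel_pitch_px_cm = pixel_pitch_px_cm,
         fixation_threshold_ms = fixation_threshold_ms,
         encoding = encoding, out_dir = out_dir,
         participant = participant, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the full scanpath-to-dynamic-network pipeline
#'
#' Reads fixations and target trajectories, partitions the timeline, builds
#' per-interval AOI sequences and transition networks, computes and
#' normalizes the importance measures, and writes all artifacts to the output
#' directory: `sequences.tsv`, `matrix_<t>.tsv` per interval, `measures.csv`,
#' `measures_normalized.csv`, node/edge attribute tables, the three figures
#' (`dnet.pdf`, `dotplot.pdf`, `barplot.pdf`), and a `manifest.json`
#' recording versions, seed, and parameters.
#'
#' @param config A [run_config()].
#' @return Invisibly, a bundle list: `dnet`, `measures`, `normalized`,
#'   `windows`, `paths` (named vector of written files).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fixations <- read_fixations(config$fixations_path,
                              threshold_ms = config$fixation_threshold_ms)
  tracks <- read_target_tracks(config$tracks_path)
  windows <- partition_time(min(tracks$time_s), max(tracks$time_s),
                            k = config$intervals, cuts = config$cuts)
  margin_px <- visual_margin_px(config$margin_deg, config$viewing_distance_cm,
                                config$pixel_pitch_px_cm)
  seqs <- map(seq_len(nrow(windows)), function(i) {
    build_raw_sequence(fixations, tracks, windows[i, ], margin_px) |>
      collapse_sequence()
  })
  finish_run(map(seqs, interval_network), seqs, windows, config)
}

#' Run the pipeline from an AOI sequence file
#'
#' Starts the analysis at the sequence stage, for published or hand-built
#' collapsed AOI fixation sequences (one `index<TAB>sequence` line per
#' interval, see [read_sequence_file()]). Downstream behavior — matrices,
#' measures, normalization, figures, manifest — is identical to
#' [run_pipeline()]. Fixation counts per state default to occurrence counts
#' in the collapsed sequence, the only information a sequence file carries.
#'
#' @param path Sequence file path.
#' @param config A [run_config()].
#' @return Invisibly, the same bundle as [run_pipeline()].
#' @export
run_from_sequences <- function(path, config = run_config()) {
  seqs <- read_sequence_file(path)
  if (length(seqs) == 0) cli::cli_abort("No sequences in {.path {path}}.")
  windows <- tibble(index = map_int(seqs, function(s) s$window$index),
                    start = NA_real_, end = NA_real_)
  finish_run(map(seqs, interval_network), seqs, windows, config)
}

finish_run <- function(networks, seqs, windows, config) {
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  dnet <- assemble_dnet(networks)
  paths <- c(sequences = file.path(out, "sequences.tsv"))
  write_sequence_file(seqs, paths[["sequences"]])
  for (net in dnet$networks) {
    p <- file.path(out, sprintf("matrix_%d.tsv", net$window$index))
    write_transition_matrix(net$counts, p)
    paths[[sprintf("matrix_%d", net$window$index)]] <- p
  }
  measures <- measure_table(dnet)
  normalized <- normalize_measures(measures)
  paths[["measures"]] <- file.path(out, "measures.csv")
  write_measures(measures, paths[["measures"]], participant = config$participant)
  paths[["normalized"]] <- file.path(out, "measures_normalized.csv")
  write_measures(normalized, paths[["normalized"]], participant = config$participant)

  dp <- plot_dnet(dnet, encoding = config$encoding,
                  file = file.path(out, "dnet.pdf"))
  paths[["dnet_figure"]] <- file.path(out, "dnet.pdf")
  paths[["node_attributes"]] <- file.path(out, "dnet_nodes.tsv")
  readr::write_tsv(dp$nodes, paths[["node_attributes"]], progress = FALSE)
  paths[["edge_attributes"]] <- file.path(out, "dnet_edges.tsv")
  readr::write_tsv(dp$edges, paths[["edge_attributes"]], progress = FALSE)

  dot <- plot_indegree_dots(normalized, file = file.path(out, "dotplot.pdf"))
  paths[["dotplot"]] <- file.path(out, "dotplot.pdf")
  last_interval <- max(normalized$interval)
  bars <- plot_measure_bars(filter(normalized, .data$interval == last_interval),
                            mode = "by_measure",
                            file = file.path(out, "barplot.pdf"))
  paths[["barplot"]] <- file.path(out, "barplot.pdf")

  manifest <- list(
    package = "gazenet",
    package_version = as.character(packageVersion("gazenet")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    participant = config$participant,
    margin_deg = config$margin_deg,
    viewing_distance_cm = config$viewing_distance_cm,
    pixel_pitch_px_cm = config$pixel_pitch_px_cm,
    fixation_threshold_ms = config$fixation_threshold_ms,
    n_intervals = dnet$n_intervals,
    universe = dnet$universe
  )
  paths[["manifest"]] <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dnet = dnet, measures = measures, normalized = normalized,
                 windows = windows, paths = paths,
                 figures = list(dnet = dp, dotplot = dot, barplot = bars)))
}
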