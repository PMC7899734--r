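#' Build an AOI transition matrix from a collapsed sequence
#'
#' Counts adjacent ordered state pairs in a collapsed AOI fixation sequence:
#' `counts[i, j]` is the number of direct attention shifts from state `i` to
#' state `j` within the interval. The diagonal is structurally zero (a
#' collapsed sequence has no self-transitions) and the grand total equals the
#' sequence length minus one. States are ordered canonically (singles before
#' overlaps, see [order_states()]).
#'
#' @param seq A collapsed [aoi_seq]; raw input is an error to prevent silently
#'   counting self-transitions.
#' @return A square integer matrix of class `transition_matrix` with state
#'   dimnames.
#' @examples
#' tm <- build_transition_matrix(parse_sequence("AABCC", collapsed = FALSE) |>
#'   collapse_sequence())
#' @export
build_transition_matrix <- function(seq) {
  stopifnot(inherits(seq, "aoi_seq"))
  if (!seq$collapsed) {
    cli::cli_abort("Input sequence must be collapsed; call {.fn collapse_sequence} first.")
  }
  states <- order_states(seq$states)
  m <- length(states)
  counts <- matrix(0L, m, m, dimnames = list(from = states, to = states))
  s <- seq$states
  if (length(s) > 1) {
    from <- s[-length(s)]
    to <- s[-1]
    for (i in seq_along(from)) {
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
    }
  }
  structure(counts, class = c("transition_matrix", class(counts)))
}

#' Write or read a transition matrix as delimited text
#'
#' Tab-separated with a header row and leading column of state labels (rows =
#' origin state, columns = destination state). Output is deterministic:
#' identical matrices yield byte-identical files.
#'
#' @param tm A `transition_matrix` (or plain square matrix with dimnames).
#' @param path File path.
#' @export
write_transition_matrix <- function(tm, path) {
  states <- colnames(tm)
  lines <- c(
    paste(c("from", states), collapse = "\t"),
    map_chr(seq_along(states), function(i) {
      paste(c(states[i], format(tm[i, ], trim = TRUE, scientific = FALSE)),
            collapse = "\t")
    })
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[1], "\t")[[1]][-1]
  m <- length(header)
  counts <- matrix(0L, m, m, dimnames = list(from = header, to = header))
  for (i in seq_len(m)) {
    parts <- strsplit(lines[i + 1], "\t")[[1]]
    counts[parts[1], ] <- as.integer(parts[-1])
  }
  structure(counts, class = c("transition_matrix", class(counts)))
}

#' Per-interval transition network
#'
#' Wraps a transition matrix together with its time window and the per-state
#' visual-encoding payloads: raw (pre-collapse) fixation counts and total
#' dwell durations. The vertex set is exactly the matrix's state set — only
#' states actually fixated in the interval appear.
#'
#' @param tm A `transition_matrix`.
#' @param fix_counts,dwell_ms Named numeric vectors keyed by state; keys must
#'   be matrix states. Missing states default to the state's occurrence count
#'   in the collapsed sequence (for `fix_counts`) or 0 (for `dwell_ms`).
#' @param window Time window (list or one-row tibble with `start`, `end`,
#'   `index`).
#' @return An object of class `interval_network`.
#' @export
build_interval_network <- function(tm, fix_counts = NULL, dwell_ms = NULL,
                                   window = NULL) {
  states <- colnames(tm) %||% character()
  check_payload <- function(p, what) {
    if (is.null(p)) return(setNames(numeric(length(states)), states))
    extra <- setdiff(names(p), states)
    if (length(extra) > 0) {
      cli::cli_abort("{what} payload has key{?s} {.val {extra}} not in the vertex set.")
    }
    out <- setNames(numeric(length(states)), states)
    out[names(p)] <- as.numeric(p)
    out
  }
  structure(
    list(window = normalize_window(window),
         states = states,
         counts = unclass(tm),
         fix_counts = check_payload(fix_counts, "Fixation-count"),
         dwell_ms = check_payload(dwell_ms, "Dwell")),
    class = "interval_network"
  )
}

#' @rdname build_interval_network
#' @param seq An [aoi_seq] (raw or collapsed); raw sequences are collapsed
#'   before counting, and their fixation/dwell payloads carried over.
#' @export
interval_network <- function(seq) {
  stopifnot(inherits(seq, "aoi_seq"))
  collapsed <- if (seq$collapsed) seq else collapse_sequence(seq)
  tm <- build_transition_matrix(collapsed)
  fc <- seq$fix_counts
  if (is.null(fc) && length(collapsed$states) > 0) {
    fc <- tapply(rep(1, length(collapsed$states)), collapsed$states, sum, default = 0)
  }
  build_interval_network(tm, fix_counts = fc, dwell_ms = seq$dwell_ms,
                         window = seq$window)
}

#' @export
print.interval_network <- function(x, ...) {
  idx <- x$window$index %||% NA
  cat("<interval_network t=", idx, "> ", length(x$states), " states, ",
      sum(x$counts), " transitions\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy interval_network
tidy.interval_network <- function(x, ...) {
  edges <- which(x$counts > 0, arr.ind = TRUE)
  tibble(
    interval = x$window$index %||% NA_integer_,
    from = x$states[edges[, 1]],
    to = x$states[edges[, 2]],
    count = x$counts[edges]
  ) |> arrange(match(.data$from, x$states), match(.data$to, x$states))
}

#' @export
#' @method glance interval_network
glance.interval_network <- function(x, ...) {
  tibble(interval = x$window$index %||% NA_integer_,
         n_states = length(x$states),
         n_edges = sum(x$counts > 0),
         n_transitions = sum(x$counts),
         total_dwell_ms = sum(x$dwell_ms))
}

#' Assemble a dynamic network from per-interval networks
#'
#' A dynamic network is the time-ordered sequence of per-interval transition
#' networks sharing one global state universe (the union of interval vertex
#' sets; targets never fixated are absent by construction). Interval indices
#' must be unique and windows in time order.
#'
#' @param networks List of `interval_network` objects.
#' @return An object of class `gaze_dnet` with fields `networks`, `universe`,
#'   `n_intervals`.
#' @export
assemble_dnet <- function(networks) {
  stopifnot(length(networks) > 0,
            all(map_chr(networks, function(n) class(n)[1]) == "interval_network"))
  idx <- map_int(networks, function(n) as.integer(n$window$index %||% NA_integer_))
  if (anyNA(idx)) cli::cli_abort("Every interval network needs a window index.")
  if (anyDuplicated(idx)) cli::cli_abort("Duplicate interval window index.")
  networks <- networks[order(idx)]
  universe <- order_states(unlist(map(networks, function(n) n$states)))
  structure(list(networks = networks, universe = universe,
                 n_intervals = length(networks)),
            class = "gaze_dnet")
}

#' @export
print.gaze_dnet <- function(x, ...) {
  cat("<gaze_dnet> ", x$n_intervals, " intervals, universe of ",
      length(x$universe), " AOI states: ",
      paste(x$universe, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy gaze_dnet
tidy.gaze_dnet <- function(x, ...) {
  bind_rows(map(x$networks, tidy))
}

#' @export
#' @method glance gaze_dnet
glance.gaze_dnet <- function(x, ...) {
  tibble(n_intervals = x$n_intervals,
         n_states = length(x$universe),
         n_transitions = sum(map_dbl(x$networks, function(n) sum(n$counts))))
}

#' Build a dynamic network straight from gaze and trajectory data
#'
#' Convenience pipeline: for each time window, builds the raw AOI fixation
#' sequence ([build_raw_sequence()]), collapses it, counts transitions, and
#' assembles the per-interval networks into one dynamic network.
#'
#' @inheritParams resolve_aoi
#' @param windows Window tibble from [partition_time()].
#' @return A `gaze_dnet`.
#' @export
build_dnet <- function(fixations, tracks, windows, margin_px = 0) {
  seqs <- map(seq_len(nrow(windows)), function(i) {
    build_raw_sequence(fixations, tracks, windows[i, ], margin_px)
  })
  assemble_dnet(map(seqs, interval_network))
}

#' @rdname build_dnet
#' @param seqs List of [aoi_seq] objects (e.g. from [read_sequence_file()]).
#' @export
dnet_from_sequences <- function(seqs) {
  assemble_dnet(map(seqs, interval_network))
}
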