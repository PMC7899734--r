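#' AOI fixation sequences
#'
#' An `aoi_seq` is the time-ordered list of AOI states fixated within one time
#' interval. A *raw* sequence has one state per hit fixation; a *collapsed*
#' sequence merges maximal runs of identical states (`AABCC` becomes `ABC`),
#' which is the form transition matrices are built from. Per-state fixation
#' counts and dwell totals (from the raw fixations) travel with the object.
#'
#' @param states Character vector of canonical AOI states, in time order.
#' @param window Optional time window: a list or one-row data frame with
#'   `start`, `end` (seconds) and `index` (1-based interval number).
#' @param collapsed Logical; `TRUE` if adjacent repeats have been merged.
#' @param fix_counts,dwell_ms Optional named numeric vectors keyed by state:
#'   raw fixation counts and summed fixation durations (milliseconds).
#' @return An object of class `aoi_seq`.
#' @export
aoi_seq <- function(states = character(), window = NULL, collapsed = FALSE,
                    fix_counts = NULL, dwell_ms = NULL) {
  states <- as.character(states)
  if (collapsed && length(states) > 1 &&
      any(states[-1] == states[-length(states)])) {
    cli::cli_abort("A collapsed sequence cannot contain adjacent repeats.")
  }
  window <- normalize_window(window)
  structure(
    list(states = states, window = window, collapsed = collapsed,
         fix_counts = fix_counts, dwell_ms = dwell_ms),
    class = "aoi_seq"
  )
}

normalize_window <- function(window) {
  if (is.null(window)) return(NULL)
  if (is.data.frame(window)) window <- as.list(window[1, , drop = FALSE])
  list(start = window$start %||% NA_real_, end = window$end %||% NA_real_,
       index = window$index %||% NA_integer_)
}

#' @export
length.aoi_seq <- function(x) length(x$states)

#' @export
format.aoi_seq <- function(x, ...) format_sequence(x)

#' @export
print.aoi_seq <- function(x, ...) {
  kind <- if (x$collapsed) "collapsed" else "raw"
  idx <- if (!is.null(x$window)) paste0(" [interval ", x$window$index, "]") else ""
  cat("<aoi_seq ", kind, idx, "> ", format_sequence(x), "\n", sep = "")
  invisible(x)
}

#' Collapse adjacent repeats in an AOI fixation sequence
#'
#' Replaces each maximal run of identical states by a single occurrence, the
#' standard preprocessing before counting transitions (self-transitions carry
#' no information about shifts of attention). Idempotent; fixation-count and
#' dwell payloads are untouched since they are per-state totals.
#'
#' @param seq An [aoi_seq].
#' @return The collapsed [aoi_seq].
#' @examples
#' format_sequence(collapse_sequence(parse_sequence("AABCC")))  # "ABC"
#' @export
collapse_sequence <- function(seq) {
  stopifnot(inherits(seq, "aoi_seq"))
  s <- seq$states
  if (length(s) > 1) s <- s[c(TRUE, s[-1] != s[-length(s)])]
  aoi_seq(s, window = seq$window, collapsed = TRUE,
          fix_counts = seq$fix_counts, dwell_ms = seq$dwell_ms)
}

#' Parse and format the AOI sequence text notation
#'
#' Sequences are written as a string of single-letter states with overlap
#' states parenthesized and semicolon-separated, e.g. `"C(D;G)C"`. Whitespace
#' inside groups is tolerated on input; output is always canonical (members
#' sorted, no spaces). `parse_sequence()` and `format_sequence()` round-trip.
#'
#' @param text Sequence string.
#' @param window,collapsed Passed to [aoi_seq()].
#' @return `parse_sequence()` returns an [aoi_seq]; `format_sequence()` a string.
#' @examples
#' format_sequence(parse_sequence("(G;D)"))  # "(D;G)"
#' @export
parse_sequence <- function(text, window = NULL, collapsed = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  states <- character()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1
    } else if (ch == "(") {
      close <- NA_integer_
      j <- i + 1
      while (j <= length(chars)) {
        if (chars[j] == "(") {
          cli::cli_abort("Nested '(' at position {j} in sequence text.")
        }
        if (chars[j] == ")") { close <- j; break }
        j <- j + 1
      }
      if (is.na(close)) {
        cli::cli_abort("Unbalanced '(' at position {i} in sequence text.")
      }
      members <- str_trim(str_split(paste(chars[(i + 1):(close - 1)], collapse = ""), ";")[[1]])
      if (any(members == "") || length(members) == 0) {
        cli::cli_abort("Empty member in group starting at position {i}.")
      }
      if (!all(is_single_letter(members))) {
        cli::cli_abort("Group starting at position {i} has a non-letter member.")
      }
      states <- c(states, aoi_state(members))
      i <- close + 1
    } else if (ch == ")") {
      cli::cli_abort("Unbalanced ')' at position {i} in sequence text.")
    } else if (is_single_letter(ch)) {
      states <- c(states, ch)
      i <- i + 1
    } else {
      cli::cli_abort("Unexpected character {.val {ch}} at position {i}.")
    }
  }
  aoi_seq(states, window = window, collapsed = collapsed)
}

#' @rdname parse_sequence
#' @param seq An [aoi_seq].
#' @export
format_sequence <- function(seq) {
  stopifnot(inherits(seq, "aoi_seq"))
  paste(seq$states, collapse = "")
}

#' Partition an experiment timeline into analysis intervals
#'
#' Splits `[start, end)` into contiguous half-open windows, either `k` equal
#' widths or at explicit interior cut points. Interval membership throughout
#' the package is by fixation onset, `start <= onset < end`, so windows
#' partition the timeline without double counting.
#'
#' @param start,end Scenario start and end, seconds; `start < end`.
#' @param k Number of equal intervals (ignored when `cuts` given).
#' @param cuts Strictly increasing interior cut points in `(start, end)`.
#' @return A tibble with columns `index`, `start`, `end`, one row per window.
#' @examples
#' partition_time(0, 1200, k = 4)
#' partition_time(0, 100, cuts = 40)
#' @export
partition_time <- function(start, end, k = NULL, cuts = NULL) {
  stopifnot(is.numeric(start), is.numeric(end), start < end)
  if (!is.null(cuts)) {
    cuts <- as.numeric(cuts)
    if (any(diff(cuts) <= 0) || any(cuts <= start) || any(cuts >= end)) {
      cli::cli_abort("Cuts must be strictly increasing and inside ({start}, {end}).")
    }
    edges <- c(start, cuts, end)
  } else {
    k <- as.integer(k %||% 1L)
    if (k < 1) cli::cli_abort("`k` must be at least 1.")
    edges <- seq(start, end, length.out = k + 1)
  }
  tibble(index = seq_len(length(edges) - 1),
         start = edges[-length(edges)], end = edges[-1])
}

#' Read and write sequence files
#'
#' One interval per line, `index<TAB>sequence`, in the text notation of
#' [parse_sequence()]. Sequences read this way are assumed collapsed.
#'
#' @param path File path.
#' @return `read_sequence_file()` returns a list of collapsed [aoi_seq]
#'   objects ordered by interval index.
#' @export
read_sequence_file <- function(path) {
  if (!file.exists(path)) cli::cli_abort("File {.path {path}} does not exist.")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(str_trim(lines))]
  if (length(lines) == 0) {
    cli::cli_warn("Sequence file {.path {path}} is empty.")
    return(list())
  }
  seqs <- imap(lines, function(line, i) {
    parts <- strsplit(line, "\t")[[1]]
    if (length(parts) != 2) {
      cli::cli_abort("Line {i} of {.path {path}} is not `index<TAB>sequence`.")
    }
    idx <- suppressWarnings(as.integer(parts[1]))
    if (is.na(idx)) cli::cli_abort("Line {i}: interval index {.val {parts[1]}} is not an integer.")
    seq <- tryCatch(parse_sequence(parts[2]),
      error = function(e) {
        cli::cli_abort("Line {i} of {.path {path}}: {conditionMessage(e)}")
      })
    collapse_sequence(aoi_seq(seq$states, window = list(index = idx), collapsed = FALSE))
  })
  seqs[order(map_int(seqs, function(s) s$window$index))]
}

#' @rdname read_sequence_file
#' @param seqs List of [aoi_seq] objects.
#' @export
write_sequence_file <- function(seqs, path) {
  lines <- map_chr(seqs, function(s) {
    paste0(s$window$index %||% NA_integer_, "\t", format_sequence(s))
  })
  writeLines(lines, path)
  invisible(path)
}
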