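# Shared fixtures, all built in code.

demo_seq_path <- function() {
  system.file("extdata", "demo_sequences.tsv", package = "gazenet")
}

demo_dnet <- function() {
  dnet_from_sequences(read_sequence_file(demo_seq_path()))
}

# An interval network straight from a named count matrix.
make_net <- function(counts, index = 1L) {
  states <- colnames(counts)
  tm <- structure(counts, dimnames = list(from = states, to = states),
                  class = c("transition_matrix", class(counts)))
  build_interval_network(tm, window = list(index = index))
}

# The worked four-state network (states A, B, C, E).
worked_net <- function() demo_dnet()$networks[[1]]

# Random weighted digraph on m vertices, integer weights 0..wmax.
rand_counts <- function(m, wmax = 5) {
  counts <- matrix(sample(0:wmax, m * m, replace = TRUE), m, m)
  diag(counts) <- 0
  labels <- LETTERS[seq_len(m)]
  dimnames(counts) <- list(from = labels, to = labels)
  counts
}

# Random collapsed AOI sequence over a random alphabet (may include one
# overlap state); adjacent repeats are avoided by construction.
rand_collapsed_states <- function(len, alphabet) {
  s <- character(len)
  s[1] <- sample(alphabet, 1)
  for (i in seq_len(len - 1) + 1) {
    s[i] <- sample(setdiff(alphabet, s[i - 1]), 1)
  }
  s
}

# Stationary targets laid out far apart, present over [0, t_end].
static_tracks <- function(labels, t_end = 1000, spacing = 400) {
  n <- length(labels)
  centers_x <- spacing * (seq_len(n) - 1) + 200
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    tibble::tibble(
      time_s = c(0, t_end), label = labels[i],
      icon_x = centers_x[i], icon_y = 500,
      block_x = centers_x[i] + 15, block_y = 515,
      block_w = 80, block_h = 40
    )
  }))
}

# A fixation row shorthand.
fx <- function(onset_s, duration_ms, x, y) {
  tibble::tibble(onset_s = onset_s, duration_ms = duration_ms,
                 x_px = x, y_px = y)
}
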