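#' Mental-map-preserving grid layout
#'
#' Places states on a rectangular grid, filling from the bottom-left corner
#' rightward and then upward, in the canonical display order of
#' [order_states()]. The column count is `ceiling(sqrt(n))`, the smallest
#' width giving a near-square rectangle. Because the layout depends only on
#' the state set, a state occupies the same cell in every interval panel of a
#' dynamic-network figure — the mental map is preserved.
#'
#' @param ordered Character vector of states, already ordered (e.g. by
#'   [order_states()]); an unordered set is accepted and ordered first.
#' @return A tibble with columns `aoi`, `row` (0 = bottom), `col` (0 = left),
#'   with attribute `n_col`.
#' @examples
#' grid_positions(order_states(c("A", "B", "C", "E", "F", "(D;G)")))
#' @export
grid_positions <- function(ordered) {
  ordered <- order_states(ordered)
  n <- length(ordered)
  if (n == 0) {
    out <- tibble(aoi = character(), row = integer(), col = integer())
    attr(out, "n_col") <- 0L
    return(out)
  }
  n_col <- ceiling(sqrt(n))
  i <- seq_len(n) - 1L
  out <- tibble(aoi = ordered,
                row = as.integer(i %/% n_col),
                col = as.integer(i %% n_col))
  attr(out, "n_col") <- as.integer(n_col)
  out
}
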