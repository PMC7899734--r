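#' AOI states and their canonical text form
#'
#' An AOI state is either a single target label (e.g. `"A"`) or a set of
#' labels fixated simultaneously because their regions overlap, written
#' `"(A;B)"`. States are represented throughout the package as canonical
#' character strings: members sorted with uppercase labels before lowercase
#' (alphabetical within each block), single members written bare, multi-member
#' sets parenthesized and semicolon-separated without spaces.
#'
#' @param members Character vector of target labels (each a single letter).
#' @return `aoi_state()` returns the canonical string form of one state.
#' @examples
#' aoi_state(c("G", "D"))   # "(D;G)"
#' aoi_state("A")           # "A"
#' @export
aoi_state <- function(members) {
  members <- unique(as.character(members))
  if (length(members) == 0 || any(is.na(members)) || any(members == "")) {
    cli::cli_abort("An AOI state needs at least one non-empty member label.")
  }
  members <- sort_labels(members)
  if (length(members) == 1) members else paste0("(", paste(members, collapse = ";"), ")")
}

#' @rdname aoi_state
#' @param state Canonical state string.
#' @return `state_members()` returns the member labels of one state.
#' @export
state_members <- function(state) {
  if (startsWith(state, "(")) {
    inner <- substr(state, 2, nchar(state) - 1)
    str_trim(str_split(inner, ";")[[1]])
  } else {
    state
  }
}

# ASCII collation: uppercase A-Z sorts before lowercase a-z.
sort_labels <- function(x) sort(x, method = "radix")

#' Order AOI states for layout and matrix axes
#'
#' Single-target states come first (uppercase A-Z then lowercase a-z,
#' alphabetical within each block), followed by overlap states ordered by
#' member count and then lexicographically by canonical form, so `(A;B)`
#' precedes `(A;B;C)`. This one ordering is used for transition-matrix axes,
#' measure tables, and grid layouts alike.
#'
#' @param states Character vector of canonical AOI states (duplicates dropped).
#' @return Character vector of unique states in canonical display order.
#' @examples
#' order_states(c("b", "A", "(A;B)", "a", "B"))
#' @export
order_states <- function(states) {
  states <- unique(as.character(states))
  if (length(states) == 0) return(character())
  n_members <- map_int(states, function(s) length(state_members(s)))
  singles <- sort_labels(states[n_members == 1])
  overlaps <- states[n_members > 1]
  overlaps <- overlaps[order(n_members[n_members > 1], overlaps, method = "radix")]
  c(singles, overlaps)
}

is_single_letter <- function(x) nchar(x) == 1 & grepl("^[A-Za-z]$", x)
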