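#' Edge distance from a transition count
#'
#' Distance between AOIs is the reciprocal of the number of fixation
#' transitions along the edge: frequently traversed pairs are "close" in the
#' observer's scanning strategy. A zero count means no edge, i.e. infinite
#' distance.
#'
#' @param weight Non-negative integer transition count (vectorized).
#' @return `1/weight`, with `Inf` for zero weights.
#' @examples
#' edge_distance(c(3, 1, 0))  # 1/3, 1, Inf
#' @export
edge_distance <- function(weight) {
  if (any(weight < 0)) cli::cli_abort("Transition counts cannot be negative.")
  ifelse(weight > 0, 1 / weight, Inf)
}

# Relative tolerance for comparing floating-point path lengths (sums of unit
# fractions); used everywhere a path-length tie must be recognized.
path_eq <- function(a, b, tol = 1e-9) {
  abs(a - b) <= tol * pmax(1, abs(a), abs(b))
}

# Dijkstra over the inverse-weight distance matrix from one source.
# Returns the vector of minimum distances; O(m^2), fine for AOI-scale graphs.
dijkstra_from <- function(D, s) {
  m <- nrow(D)
  dist <- rep(Inf, m)
  dist[s] <- 0
  done <- rep(FALSE, m)
  for (step in seq_len(m)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    relax <- !done & is.finite(D[u, ])
    nd <- dist[u] + D[u, ]
    upd <- relax & nd < dist
    dist[upd] <- nd[upd]
  }
  dist
}

# Count shortest paths from source s to every vertex by accumulating over
# "tight" edges (u,v) with d[u] + D[u,v] == d[v], processing vertices in
# nondecreasing distance order. With strictly positive distances every
# shortest walk is simple, so this counts simple shortest paths.
count_paths_from <- function(D, s, dist) {
  m <- nrow(D)
  sigma <- rep(0, m)
  sigma[s] <- 1
  ord <- order(dist)
  for (v in ord) {
    if (v == s || !is.finite(dist[v])) next
    pred <- which(is.finite(D[, v]) & path_eq(dist + D[, v], dist[v]) &
                    dist < dist[v])
    sigma[v] <- sum(sigma[pred])
  }
  sigma
}

# All-sources distance and shortest-path-count matrices for a network,
# dist[s, t] and sigma[s, t]. The workhorse behind closeness, betweenness,
# and path counting.
sp_tables <- function(net) {
  D <- edge_distance(net$counts)
  diag(D) <- Inf   # no self edges; d*_jj is 0 by definition, handled by callers
  m <- length(net$states)
  dist <- matrix(Inf, m, m)
  sigma <- matrix(0, m, m)
  for (s in seq_len(m)) {
    dist[s, ] <- dijkstra_from(D, s)
    sigma[s, ] <- count_paths_from(D, s, dist[s, ])
  }
  list(dist = dist, sigma = sigma)
}

state_index <- function(net, state, arg = "state") {
  i <- match(state, net$states)
  if (is.na(i)) cli::cli_abort("{.val {state}} is not a vertex of this network.")
  i
}

#' Shortest scanning distances from one AOI
#'
#' Minimum summed inverse-transition-count distance from `source` to every
#' vertex of the interval network, over all directed paths; `Inf` when a
#' vertex is unreachable, 0 to the source itself.
#'
#' @param net An `interval_network`.
#' @param source Canonical AOI state string.
#' @return A tibble with columns `aoi`, `distance`.
#' @export
shortest_distances <- function(net, source) {
  s <- state_index(net, source, "source")
  dist <- sp_tables(net)$dist[s, ]
  dist[s] <- 0
  tibble(aoi = net$states, distance = dist)
}

#' Count shortest paths between two AOIs
#'
#' Number of distinct directed paths from `k` to `l` whose length ties the
#' minimum (relative tolerance 1e-9), and, for each possible intermediate
#' vertex `j`, how many of them pass through `j`. These are the ingredients
#' of the betweenness measure.
#'
#' @param net An `interval_network`.
#' @param k,l Distinct canonical AOI states.
#' @return A list with `n_paths` (0 when unreachable) and `through`, a tibble
#'   (`aoi`, `n_paths`) over intermediates.
#' @export
count_shortest_paths <- function(net, k, l) {
  ki <- state_index(net, k)
  li <- state_index(net, l)
  if (ki == li) cli::cli_abort("`k` and `l` must be distinct AOI states.")
  tabs <- sp_tables(net)
  n_kl <- if (is.finite(tabs$dist[ki, li])) tabs$sigma[ki, li] else 0
  inter <- setdiff(seq_along(net$states), c(ki, li))
  through <- map_dbl(inter, function(j) {
    if (n_kl == 0) return(0)
    if (is.finite(tabs$dist[ki, j]) && is.finite(tabs$dist[j, li]) &&
        path_eq(tabs$dist[ki, j] + tabs$dist[j, li], tabs$dist[ki, li])) {
      tabs$sigma[ki, j] * tabs$sigma[j, li]
    } else 0
  })
  list(n_paths = n_kl,
       through = tibble(aoi = net$states[inter], n_paths = through))
}

#' Time-resolved AOI importance measures
#'
#' For one interval network: `aoi_indegree()` is the column sum of the
#' transition matrix (direct attention received); `aoi_outdegree()` the row
#' sum; `aoi_closeness()` sums reciprocal shortest distances to all other
#' vertices (global accessibility in the scanning strategy; unreachable
#' vertices contribute 0); `aoi_betweenness()` sums, over ordered pairs of
#' other vertices, the fraction of shortest paths passing through the AOI
#' (bridging role in attention flow).
#'
#' @param net An `interval_network`.
#' @param j Canonical AOI state.
#' @return A single number.
#' @export
aoi_indegree <- function(net, j) {
  unname(colSums(net$counts)[state_index(net, j)])
}

#' @rdname aoi_indegree
#' @export
aoi_outdegree <- function(net, j) {
  unname(rowSums(net$counts)[state_index(net, j)])
}

#' @rdname aoi_indegree
#' @export
aoi_closeness <- function(net, j) {
  ji <- state_index(net, j)
  d <- sp_tables(net)$dist[ji, -ji]
  sum(ifelse(is.finite(d), 1 / d, 0))
}

#' @rdname aoi_indegree
#' @export
aoi_betweenness <- function(net, j) {
  ji <- state_index(net, j)
  betweenness_all(net)[ji]
}

# Betweenness of every vertex at once via the pair-rational form
# sum_{k != l != j} sigma_k(j) * sigma_j(l) / sigma_k(l) over tight triples.
betweenness_all <- function(net) {
  m <- length(net$states)
  if (m < 3) return(rep(0, m))
  tabs <- sp_tables(net)
  out <- rep(0, m)
  for (k in seq_len(m)) for (l in seq_len(m)) {
    if (k == l || !is.finite(tabs$dist[k, l]) || tabs$sigma[k, l] == 0) next
    for (j in seq_len(m)) {
      if (j == k || j == l) next
      if (is.finite(tabs$dist[k, j]) && is.finite(tabs$dist[j, l]) &&
          path_eq(tabs$dist[k, j] + tabs$dist[j, l], tabs$dist[k, l])) {
        out[j] <- out[j] + tabs$sigma[k, j] * tabs$sigma[j, l] / tabs$sigma[k, l]
      }
    }
  }
  out
}

#' Importance measures for every interval of a dynamic network
#'
#' One row per (interval, AOI state of that interval): raw fixation count and
#' dwell total plus indegree, outdegree, closeness, and betweenness. Measures
#' are computed on each interval's own vertex set (states actually fixated in
#' that interval), in deterministic order.
#'
#' @param dnet A `gaze_dnet`.
#' @return A tibble with columns `interval`, `aoi`, `n_fixations`, `dwell_ms`,
#'   `indegree`, `outdegree`, `closeness`, `betweenness`.
#' @export
measure_table <- function(dnet) {
  stopifnot(inherits(dnet, "gaze_dnet"))
  bind_rows(map(dnet$networks, function(net) {
    m <- length(net$states)
    if (m == 0) return(NULL)
    btw <- betweenness_all(net)
    tabs <- sp_tables(net)
    clo <- map_dbl(seq_len(m), function(ji) {
      d <- tabs$dist[ji, -ji]
      sum(ifelse(is.finite(d), 1 / d, 0))
    })
    tibble(
      interval = net$window$index %||% NA_integer_,
      aoi = net$states,
      n_fixations = unname(net$fix_counts[net$states]),
      dwell_ms = unname(net$dwell_ms[net$states]),
      indegree = unname(colSums(net$counts)),
      outdegree = unname(rowSums(net$counts)),
      closeness = clo,
      betweenness = btw
    )
  }))
}

#' Write a measure table as delimited text
#'
#' Tidy CSV with one row per (participant, interval, AOI); extra columns
#' beyond the core measure set (e.g. normalized values) are written as-is.
#'
#' @param measures Tibble from [measure_table()] or [normalize_measures()].
#' @param path Output path.
#' @param participant Participant identifier recycled over rows.
#' @export
write_measures <- function(measures, path, participant = "P1") {
  out <- dplyr::bind_cols(tibble(participant = participant), measures)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
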