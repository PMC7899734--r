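# Independent oracle: exhaustive enumeration of all simple directed paths.
# Used to verify the Dijkstra-based distances and shortest-path counts; kept
# deliberately naive (depth-first over every simple path, no pruning).

oracle_eq <- function(a, b, tol = 1e-9) {
  is.finite(a) & is.finite(b) & abs(a - b) <= tol * pmax(1, abs(a), abs(b))
}

# From source k over distance matrix D (Inf = no edge), returns
#   dist: minimum path length to every vertex (Inf unreachable, 0 at k)
#   n_paths: number of minimum-length simple paths
#   through: matrix through[l, j] = number of those k->l paths with j interior
oracle_paths <- function(D, k) {
  m <- nrow(D)
  dmin <- rep(Inf, m)
  cnt <- rep(0, m)
  thr <- matrix(0, m, m)
  visited <- rep(FALSE, m)
  visited[k] <- TRUE
  rec <- function(v, len, interior) {
    # interior = vertices strictly between k and v on the current path
    for (u in which(is.finite(D[v, ]))) {
      if (visited[u]) next
      nl <- len + D[v, u]
      new_int <- if (v == k) integer(0) else c(interior, v)
      if (nl < dmin[u] && !oracle_eq(nl, dmin[u])) {
        dmin[u] <<- nl
        cnt[u] <<- 1
        thr[u, ] <<- 0
        thr[u, new_int] <<- 1
      } else if (oracle_eq(nl, dmin[u])) {
        cnt[u] <<- cnt[u] + 1
        thr[u, new_int] <<- thr[u, new_int] + 1
      }
      visited[u] <<- TRUE
      rec(u, nl, new_int)
      visited[u] <<- FALSE
    }
  }
  rec(k, 0, integer(0))
  dmin[k] <- 0
  list(dist = dmin, n_paths = cnt, through = thr)
}

# Oracle closeness/betweenness assembled straight from the enumerated paths.
oracle_measures <- function(counts) {
  m <- nrow(counts)
  D <- ifelse(counts > 0, 1 / counts, Inf)
  diag(D) <- Inf
  per_source <- lapply(seq_len(m), function(k) oracle_paths(D, k))
  closeness <- vapply(seq_len(m), function(j) {
    d <- per_source[[j]]$dist[-j]
    sum(ifelse(is.finite(d), 1 / d, 0))
  }, numeric(1))
  betweenness <- rep(0, m)
  for (k in seq_len(m)) for (l in seq_len(m)) {
    if (k == l) next
    o <- per_source[[k]]
    if (o$n_paths[l] == 0) next
    for (j in seq_len(m)) {
      if (j == k || j == l) next
      betweenness[j] <- betweenness[j] + o$through[l, j] / o$n_paths[l]
    }
  }
  list(closeness = closeness, betweenness = betweenness)
}
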