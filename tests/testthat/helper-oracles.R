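# Independent brute-force oracle for information distances: exhaustive
# enumeration of all simple paths (hop distances are nonnegative, so some
# shortest path is simple). Deliberately naive and separate from the
# package's Dijkstra-based implementation.
brute_force_id <- function(g, sources) {
  p <- suppressWarnings(transition_matrix(g))
  ihd <- hop_distances(p)
  n <- nrow(ihd)
  labels <- rownames(ihd)
  best <- matrix(Inf, length(sources), n, dimnames = list(sources, labels))
  dfs <- function(si, current, cost, visited) {
    row <- match(sources[si], labels)
    if (cost < best[si, current]) best[si, current] <<- cost
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && is.finite(ihd[current, nxt])) {
        visited[nxt] <- TRUE
        dfs(si, nxt, cost + ihd[current, nxt], visited)
        visited[nxt] <- FALSE
      }
    }
  }
  for (si in seq_along(sources)) {
    start <- match(sources[si], labels)
    visited <- rep(FALSE, n)
    visited[start] <- TRUE
    dfs(si, start, 0, visited)
  }
  best
}

# reference NDCG written directly from the defining sum, independent of ndcg()
reference_ndcg <- function(ranking, relevant) {
  dcg <- 0
  for (p in seq_along(ranking)) {
    if (ranking[p] %in% relevant) dcg <- dcg + 1 / log2(p + 1)
  }
  idcg <- 0
  for (p in seq_len(min(length(relevant), length(ranking)))) {
    idcg <- idcg + 1 / log2(p + 1)
  }
  dcg / idcg
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
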