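# small graphs built in code, shared across test files

make_graph <- function(edges, labels = NULL, directed = FALSE) {
  # edges: data.frame/matrix-like list of c(src, dst, w) triples
  src <- vapply(edges, `[[`, "", 1)
  dst <- vapply(edges, `[[`, "", 2)
  w <- as.numeric(vapply(edges, `[[`, "", 3))
  if (is.null(labels)) labels <- sort(unique(c(src, dst)))
  m <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (k in seq_along(w)) {
    m[src[k], dst[k]] <- w[k]
    if (!directed) m[dst[k], src[k]] <- w[k]
  }
  weighted_graph(m, directed = directed)
}

complete_graph <- function(n, weight = 1) {
  labels <- sprintf("k%02d", seq_len(n))
  m <- matrix(weight, n, n, dimnames = list(labels, labels))
  diag(m) <- 0
  weighted_graph(m)
}

chain_graph <- function(labels, weight = 1) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) m[i, i + 1] <- m[i + 1, i] <- weight
  weighted_graph(m)
}

two_triangles <- function() {
  make_graph(list(c("A", "B", 1), c("B", "C", 1), c("A", "C", 1),
                  c("D", "E", 1), c("E", "F", 1), c("D", "F", 1)))
}

# random small weighted graph, possibly disconnected / directed-asymmetric
random_small_graph <- function(n, p_edge = 0.5, directed = FALSE) {
  labels <- sprintf("r%02d", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (directed || i < j) {
        if (stats::runif(1) < p_edge) {
          w <- stats::runif(1, 0.2, 3)
          m[i, j] <- w
          if (!directed) m[j, i] <- w
        }
      }
    }
  }
  weighted_graph(m, directed = directed)
}
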