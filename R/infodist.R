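#' Random-walk transition matrix of a weighted graph
#'
#' Row-normalizes the weight matrix: `p[i, j] = w[i, j] / degree(i)`, the
#' probability of moving from `i` to `j` in one step of a weighted random
#' walk. Rows of zero-degree (isolated) nodes are left all zero and the
#' affected labels are reported with a warning.
#'
#' Row normalization makes the transitions asymmetric in general even for an
#' undirected input graph; all downstream distances are computed on this
#' directed transition structure.
#'
#' @param g a [weighted_graph()] with at least 2 nodes
#' @return object of class `transition_matrix`: list with `probs` (row
#'   stochastic matrix), `labels`, and `isolated` (labels of zero-degree nodes)
#' @export
transition_matrix <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  if (graph_order(g) < 2) stop("graph must have at least 2 nodes")
  deg <- rowSums(g$weights)
  isolated <- g$labels[deg == 0]
  if (length(isolated)) {
    warning("isolated node(s) with zero degree: ",
            paste(isolated, collapse = ", "))
  }
  p <- g$weights / ifelse(deg > 0, deg, 1)
  structure(list(probs = p, labels = g$labels, isolated = isolated),
            class = "transition_matrix")
}

#' Information hop distances
#'
#' The self-information, in bits, of each one-step transition:
#' `ihd[i, j] = -log2(p[i, j])` where `p[i, j] > 0`, and `+Inf` where the
#' transition is impossible (absent edge). A deterministic transition
#' (`p = 1`) costs 0 bits; `p = 1/2` costs 1 bit.
#'
#' @param p a `transition_matrix` (or a row-stochastic numeric matrix)
#' @return matrix of hop distances in bits, `+Inf` off the support
#' @export
hop_distances <- function(p) {
  probs <- if (inherits(p, "transition_matrix")) p$probs else as.matrix(p)
  if (any(probs < 0) || any(probs > 1)) stop("transition probabilities must lie in [0, 1]")
  ihd <- -log2(probs)            # p = 0 -> Inf, exactly the absent-edge case
  ihd[probs == 0] <- Inf
  ihd
}

#' Information distances from a set of source nodes
#'
#' The information distance `id(i, j)` is the minimum, over all directed
#' paths from `i` to `j`, of the summed hop distances along the path — a
#' shortest path in information space, in bits. `id(i, i) = 0`; unreachable
#' targets get `+Inf`. Computed with multi-source Dijkstra on the finite
#' entries of the hop-distance matrix.
#'
#' @param ihd hop-distance matrix from [hop_distances()] (dimnames = labels)
#' @param sources nonempty character vector of source labels
#' @return `length(sources) x n` matrix of distances in bits
#' @export
information_distances <- function(ihd, sources) {
  ihd <- as.matrix(ihd)
  labels <- rownames(ihd)
  if (is.null(labels)) stop("hop-distance matrix must carry node labels as dimnames")
  if (length(sources) == 0) stop("source set is empty")
  missing <- setdiff(sources, labels)
  if (length(missing)) stop("unknown source label(s): ", paste(missing, collapse = ", "))
  idx <- which(is.finite(ihd), arr.ind = TRUE)
  ig <- igraph::make_empty_graph(n = length(labels), directed = TRUE)
  igraph::V(ig)$name <- labels
  if (nrow(idx)) {
    ig <- igraph::add_edges(ig, rbind(idx[, 1], idx[, 2]),
                            weight = ihd[idx])
  }
  d <- igraph::distances(ig, v = match(sources, labels), to = igraph::V(ig),
                         mode = "out", weights = igraph::E(ig)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- list(sources, labels)
  d
}

#' Equal-length encoding threshold
#'
#' Under a null model of purely random connectivity the optimal code names
#' any of the `n` nodes with exactly `log2(n)` bits; information distances at
#' or above this cost indicate connections no better than random.
#'
#' @param n_nodes integer >= 2
#' @return threshold in bits, `log2(n_nodes)`
#' @export
equal_length_threshold <- function(n_nodes) {
  if (length(n_nodes) != 1 || is.na(n_nodes) || n_nodes < 2) {
    stop("n_nodes must be a single integer >= 2")
  }
  log2(n_nodes)
}

#' Thresholded information distances
#'
#' Caps all information distances at the equal-length encoding threshold:
#' `idt = min(id, T)` elementwise. Infinite distances (unreachable targets)
#' become exactly `T`; a value equal to `T` means "not significantly
#' connected under the null model".
#'
#' @param id matrix (or vector) of information distances in bits
#' @param threshold positive threshold `T` in bits
#' @return capped distances, same shape as `id`
#' @export
thresholded_distances <- function(id, threshold) {
  if (length(threshold) != 1 || !is.finite(threshold) || threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  pmin(id, threshold)
}

#' Compute the full thresholded-distance bundle for a query set
#'
#' Composes [transition_matrix()], [hop_distances()],
#' [information_distances()], [equal_length_threshold()] and
#' [thresholded_distances()] for a set of source nodes: the complete
#' source-to-all distance structure the recommender consumes.
#'
#' @param g a [weighted_graph()] with at least 2 nodes
#' @param sources nonempty character vector of source labels
#' @return object of class `distance_bundle`: list with `sources`, `labels`,
#'   `id` (raw distances, `+Inf` allowed), `threshold` (= `log2(|V|)`), and
#'   `idt` (capped distances, all in `[0, threshold]`)
#' @export
distance_bundle <- function(g, sources) {
  stopifnot(inherits(g, "weighted_graph"))
  check_nodes(g, sources, what = "source")
  p <- suppressWarnings(transition_matrix(g))
  ihd <- hop_distances(p)
  id <- information_distances(ihd, sources)
  threshold <- equal_length_threshold(graph_order(g))
  structure(list(sources = sources, labels = g$labels, id = id,
                 threshold = threshold,
                 idt = thresholded_distances(id, threshold)),
            class = "distance_bundle")
}

#' @export
print.distance_bundle <- function(x, ...) {
  cat(sprintf("<distance_bundle> %d source(s) x %d nodes, T = %.4f bits\n",
              length(x$sources), length(x$labels), x$threshold))
  invisible(x)
}

#' Export thresholded distances as CSV
#'
#' Sources as rows, all nodes as columns, labels preserved, values in bits
#' with 6 decimal places.
#'
#' @param bundle a `distance_bundle`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_idt_csv <- function(bundle, path) {
  stopifnot(inherits(bundle, "distance_bundle"))
  m <- format(round(bundle$idt, 6), trim = TRUE, nsmall = 6, scientific = FALSE)
  df <- data.frame(source = bundle$sources, m, check.names = FALSE)
  colnames(df) <- c("source", bundle$labels)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
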