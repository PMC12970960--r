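#' Construct a weighted graph
#'
#' The basic container used throughout the package: an ordered set of unique
#' node labels together with a dense nonnegative weight matrix `w[i, j]`
#' (weight of the edge from node `i` to node `j`; absent edges are exactly 0).
#' Self-loops are permitted and contribute to a node's degree like any other
#' edge, although the synthetic generators never emit them.
#'
#' @param weights numeric square matrix of nonnegative edge weights. Row and
#'   column names, when present, must agree and become the node labels;
#'   otherwise labels `"v1"..."vn"` are assigned.
#' @param directed logical; if `FALSE` (default) the matrix must be symmetric.
#' @param labels optional character vector of node labels overriding dimnames.
#' @return an object of class `weighted_graph` with fields `labels`,
#'   `weights` (with dimnames set to the labels) and `directed`.
#' @examples
#' w <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' g <- weighted_graph(w)
#' node_degree(g)
#' @export
weighted_graph <- function(weights, directed = FALSE, labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("weight matrix must be square, got ", nrow(weights), "x", ncol(weights))
  }
  if (!is.numeric(weights)) stop("weights must be numeric")
  if (anyNA(weights)) stop("weights must not contain NA")
  if (any(weights < 0)) stop("negative edge weight not allowed")
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- colnames(weights)
    if (is.null(labels)) labels <- paste0("v", seq_len(nrow(weights)))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(weights)) {
    stop("number of labels does not match matrix dimension")
  }
  if (anyDuplicated(labels)) stop("duplicate node labels")
  if (!directed && !isTRUE(all.equal(weights, t(weights),
                                     check.attributes = FALSE,
                                     tolerance = 1e-8))) {
    stop("weights must be symmetric for an undirected graph")
  }
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights, directed = directed),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  n_edges <- sum(x$weights > 0)
  if (!x$directed) n_edges <- (n_edges + sum(diag(x$weights) > 0)) / 2
  cat(sprintf("<weighted_graph> %d nodes, %d %s edges\n",
              length(x$labels), n_edges,
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

#' Number of nodes of a weighted graph
#' @param g a `weighted_graph`
#' @return integer node count
#' @export
graph_order <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  length(g$labels)
}

sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a weighted graph from a file
#'
#' Two dialects are supported. An *edge list* is a tab-separated file with
#' columns source, target, weight (no header unless `header = TRUE`); for
#' undirected input each listed edge populates both directions and unlisted
#' pairs get weight 0. An *adjacency* file is a CSV whose first row and first
#' column both carry the node labels. With `format = "auto"` the dialect is
#' chosen by extension: `.csv` is adjacency, anything else edge list.
#'
#' Node order is the header order for adjacency input and the lexicographic
#' label order for edge lists, so matrix indexing is reproducible.
#'
#' @param path file path
#' @param format one of `"auto"`, `"edgelist"`, `"adjacency"`
#' @param directed logical, default `FALSE`
#' @param header logical; whether an edge-list file carries a header row
#' @return a [weighted_graph()]
#' @export
read_graph <- function(path, format = c("auto", "edgelist", "adjacency"),
                       directed = FALSE, header = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "adjacency" else "edgelist"
  }
  if (format == "adjacency") {
    m <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(m)
    if (nrow(m) != ncol(m)) stop("adjacency matrix is not square")
    if (!identical(rownames(m), colnames(m))) {
      stop("adjacency row labels do not match column labels")
    }
    weighted_graph(m, directed = directed)
  } else {
    df <- utils::read.table(path, sep = "\t", header = header,
                            stringsAsFactors = FALSE, comment.char = "#",
                            quote = "")
    if (ncol(df) < 3) stop("edge list needs three columns: source, target, weight")
    src <- as.character(df[[1]]); dst <- as.character(df[[2]])
    w <- as.numeric(df[[3]])
    if (anyNA(w)) stop("non-numeric edge weight in edge list")
    if (any(w < 0)) stop("negative edge weight not allowed")
    labels <- sort(unique(c(src, dst)))
    m <- matrix(0, length(labels), length(labels),
                dimnames = list(labels, labels))
    for (k in seq_along(w)) {
      m[src[k], dst[k]] <- w[k]
      if (!directed) m[dst[k], src[k]] <- w[k]
    }
    weighted_graph(m, directed = directed)
  }
}

#' Write a weighted graph to a file
#'
#' Mirrors [read_graph()]: edge lists are written as tab-separated
#' source/target/weight triples (each undirected edge once, `i <= j` order);
#' adjacency output is a full labelled CSV. Weights are serialized with 6
#' decimal places.
#'
#' @param g a `weighted_graph`
#' @param path output path
#' @param format `"auto"` (by extension), `"edgelist"`, or `"adjacency"`
#' @return `path`, invisibly
#' @export
write_graph <- function(g, path, format = c("auto", "edgelist", "adjacency")) {
  stopifnot(inherits(g, "weighted_graph"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "adjacency" else "edgelist"
  }
  if (format == "adjacency") {
    m <- format(g$weights, trim = TRUE, nsmall = 6, scientific = FALSE)
    df <- data.frame(node = g$labels, m, check.names = FALSE)
    colnames(df) <- c("", g$labels)
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(g$weights > 0, arr.ind = TRUE)
    if (!g$directed) idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
    ord <- order(idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
    lines <- sprintf("%s\t%s\t%.6f",
                     g$labels[idx[, 1]], g$labels[idx[, 2]],
                     g$weights[idx])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Weighted node degree (strength)
#'
#' The degree of node `i` is the sum of its outgoing edge weights,
#' `sum_k w[i, k]` — the row sum of the weight matrix.
#'
#' @param g a `weighted_graph`
#' @param nodes node labels; default all
#' @return named numeric vector of degrees
#' @export
node_degree <- function(g, nodes = NULL) {
  stopifnot(inherits(g, "weighted_graph"))
  if (is.null(nodes)) nodes <- g$labels
  check_nodes(g, nodes)
  rowSums(g$weights)[nodes]
}

check_nodes <- function(g, nodes, what = "node") {
  missing <- setdiff(nodes, g$labels)
  if (length(missing)) {
    stop("unknown ", what, " label(s): ", paste(missing, collapse = ", "))
  }
  invisible(nodes)
}

#' Read a seed set from a text file
#'
#' One node label per line; blank lines and `#` comments are ignored.
#'
#' @param path file path
#' @param graph optional `weighted_graph` to validate membership against
#' @return character vector of node labels
#' @export
read_seeds <- function(path, graph = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  seeds <- lines[nzchar(lines)]
  if (anyDuplicated(seeds)) seeds <- unique(seeds)
  if (!is.null(graph)) validate_seeds(graph, seeds)
  seeds
}

#' Validate a seed set against its host graph
#'
#' A valid seed set is a nonempty strict subset of the graph's nodes
#' (extension of the full node set is undefined).
#'
#' @param g a `weighted_graph`
#' @param seeds character vector of node labels
#' @param strict if `TRUE` (default) require a strict subset of V
#' @return `seeds`, invisibly
#' @export
validate_seeds <- function(g, seeds, strict = TRUE) {
  stopifnot(inherits(g, "weighted_graph"))
  if (length(seeds) == 0) stop("seed set is empty")
  if (anyDuplicated(seeds)) stop("duplicate seed labels")
  check_nodes(g, seeds, what = "seed")
  if (strict && length(seeds) >= length(g$labels)) {
    stop("seed set must be a strict subset of the graph's nodes")
  }
  invisible(seeds)
}

#' Does a seed node have a neighbor outside the seed set?
#'
#' @param g a `weighted_graph`
#' @param seeds character vector of seed labels (must contain `node`)
#' @param node a single seed label
#' @return `TRUE` iff some `j` outside the seed set has `w[node, j] > 0`
#' @export
neighbors_outside <- function(g, seeds, node) {
  stopifnot(inherits(g, "weighted_graph"))
  validate_seeds(g, seeds, strict = FALSE)
  if (!node %in% seeds) stop("node '", node, "' is not in the seed set")
  outside <- setdiff(g$labels, seeds)
  if (!length(outside)) return(FALSE)
  any(g$weights[node, outside] > 0)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$weights,
                                      mode = if (g$directed) "directed" else "undirected",
                                      weighted = TRUE, diag = TRUE)
}
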