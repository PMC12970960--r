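#' Center of a seed subgraph (radial key points)
#'
#' The eccentricity of a seed node `i` is its worst-case thresholded
#' information distance to any other seed, `max_{j in S} idt(i, j)`.
#' The center is the node — or set of nodes, ties are kept — attaining the
#' minimal eccentricity. Distances are computed on the full graph (paths may
#' leave the seed set), from a bundle whose sources cover the seeds.
#'
#' @param bundle a [distance_bundle()] whose sources include every seed
#' @param seeds character vector of seed labels
#' @return character vector of center labels (sorted)
#' @export
subgraph_center <- function(bundle, seeds) {
  stopifnot(inherits(bundle, "distance_bundle"))
  if (length(seeds) == 0) stop("seed set is empty")
  missing <- setdiff(seeds, bundle$sources)
  if (length(missing)) {
    stop("bundle is missing seed source(s): ", paste(missing, collapse = ", "))
  }
  if (length(seeds) == 1) return(seeds)
  ecc <- apply(bundle$idt[seeds, seeds, drop = FALSE], 1, max)
  sort(names(ecc)[ecc <= min(ecc) + 1e-12])
}

#' Inner boundary of a seed subgraph (boundary key points)
#'
#' The seed nodes having at least one neighbor outside the seed set. May be
#' empty when the seeds form a union of whole connected components, in which
#' case no extension is possible along edges.
#'
#' @param g a [weighted_graph()]
#' @param seeds character vector of seed labels
#' @return character vector of boundary labels (sorted, possibly empty)
#' @export
inner_boundary <- function(g, seeds) {
  stopifnot(inherits(g, "weighted_graph"))
  validate_seeds(g, seeds, strict = FALSE)
  outside <- setdiff(g$labels, seeds)
  if (!length(outside)) return(character(0))
  has_out <- rowSums(g$weights[seeds, outside, drop = FALSE] > 0) > 0
  sort(seeds[has_out])
}

#' Rank candidate nodes for seed-set extension
#'
#' The guilt-by-association recommender. Key points of the seed subgraph are
#' chosen by `metric`: the subgraph center for `"radial"`, the inner boundary
#' for `"boundary"` (the default — the boundary is the natural demarcation
#' for growing the subgraph). Every node outside the seed set is scored by
#' its minimum thresholded information distance from any key point and the
#' candidates are ranked ascending (ties broken by label), so the strongest
#' associations come first.
#'
#' The cutoff needs no user parameter: candidates whose score reaches the
#' equal-length encoding threshold `T = log2(|V|)` encode no better than the
#' null model of random connectivity and fall at or after `cutoff_index`
#' (strict inequality: a score exactly `T` is excluded).
#'
#' @param g a [weighted_graph()] with at least 2 nodes
#' @param seeds nonempty strict subset of the node labels
#' @param metric `"boundary"` (default) or `"radial"`
#' @return object of class `ranked_extension`: list with `candidates`
#'   (labels, best first), `scores` (bits, nondecreasing), `cutoff_index`
#'   (number of candidates strictly below threshold), `key_points`, `metric`,
#'   and `threshold`
#' @export
extend <- function(g, seeds, metric = c("boundary", "radial")) {
  stopifnot(inherits(g, "weighted_graph"))
  metric <- match.arg(metric)
  validate_seeds(g, seeds)
  bundle <- distance_bundle(g, seeds)
  key_points <- if (metric == "radial") {
    subgraph_center(bundle, seeds)
  } else {
    b <- inner_boundary(g, seeds)
    if (!length(b)) stop("seed set has no outside neighbors; no extension possible")
    b
  }
  candidates <- setdiff(g$labels, seeds)
  sc <- apply(bundle$idt[key_points, candidates, drop = FALSE], 2, min)
  ord <- order(sc, names(sc))
  sc <- sc[ord]
  structure(list(candidates = names(sc),
                 scores = unname(sc),
                 cutoff_index = sum(sc < bundle$threshold - 1e-12),
                 key_points = key_points,
                 metric = metric,
                 threshold = bundle$threshold),
            class = "ranked_extension")
}

#' @export
print.ranked_extension <- function(x, ...) {
  cat(sprintf("<ranked_extension> metric=%s, %d candidates, %d below T=%.4f bits\n",
              x$metric, length(x$candidates), x$cutoff_index, x$threshold))
  n <- min(10L, length(x$candidates))
  if (n) {
    for (i in seq_len(n)) {
      cat(sprintf("  %3d. %s  %.4f%s\n", i, x$candidates[i], x$scores[i],
                  if (i <= x$cutoff_index) "" else "  (at threshold)"))
    }
    if (length(x$candidates) > n) cat("  ...\n")
  }
  invisible(x)
}

#' Turn a ranked extension into a data frame
#' @param x a `ranked_extension`
#' @param ... unused
#' @return data.frame with columns rank, node, score_bits, below_threshold
#' @export
as.data.frame.ranked_extension <- function(x, ...) {
  data.frame(rank = seq_along(x$candidates),
             node = x$candidates,
             score_bits = x$scores,
             below_threshold = seq_along(x$candidates) <= x$cutoff_index,
             stringsAsFactors = FALSE)
}

#' Conductance of a node set
#'
#' `Phi(S) = Cut(S, S') / min(Vol(S), Vol(S'))` where `Cut` is the total
#' weight of edges crossing from `S` to its complement and `Vol(A)` is the
#' total edge weight leaving `A`. Low conductance means the set is well
#' isolated — the regime where guilt-by-association extension is justified.
#'
#' @param g a [weighted_graph()] with positive total weight
#' @param seeds nonempty strict subset of node labels
#' @return object of class `conductance_result`: list with `phi`,
#'   `cut_weight`, `vol_s`, `vol_complement`
#' @export
conductance <- function(g, seeds) {
  stopifnot(inherits(g, "weighted_graph"))
  validate_seeds(g, seeds)
  if (sum(g$weights) <= 0) stop("graph has zero total weight")
  comp <- setdiff(g$labels, seeds)
  cut_weight <- sum(g$weights[seeds, comp, drop = FALSE])
  vol_s <- sum(g$weights[seeds, , drop = FALSE])
  vol_c <- sum(g$weights[comp, , drop = FALSE])
  denom <- min(vol_s, vol_c)
  phi <- if (denom > 0) cut_weight / denom else 0
  structure(list(phi = phi, cut_weight = cut_weight,
                 vol_s = vol_s, vol_complement = vol_c),
            class = "conductance_result")
}

#' @export
print.conductance_result <- function(x, ...) {
  cat(sprintf("phi = %.6f (cut = %.6f, vol_s = %.6f, vol_complement = %.6f)\n",
              x$phi, x$cut_weight, x$vol_s, x$vol_complement))
  invisible(x)
}
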