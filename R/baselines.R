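# Shared power-iteration core for both propagation baselines.
# v <- alpha * (P'v + dangling_mass * e_S) + (1 - alpha) * e_S
# where e_S is uniform over the seeds and alpha is the walk-continuation
# probability. Mass at dangling (zero out-degree) nodes is redistributed to
# the seed vector so probability is conserved at every iteration.
propagate <- function(g, seeds, alpha, tol, max_iter) {
  stopifnot(inherits(g, "weighted_graph"))
  validate_seeds(g, seeds, strict = FALSE)
  if (alpha < 0 || alpha >= 1) stop("walk-continuation probability must lie in [0, 1)")
  n <- graph_order(g)
  p <- suppressWarnings(transition_matrix(g))
  pt <- t(p$probs)
  dangling <- g$labels %in% p$isolated
  e <- numeric(n); names(e) <- g$labels
  e[seeds] <- 1 / length(seeds)
  v <- e
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    v_new <- alpha * (drop(pt %*% v) + sum(v[dangling]) * e) + (1 - alpha) * e
    delta <- sum(abs(v_new - v))
    v <- v_new
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(scores = v, restart_prob = 1 - alpha, seeds = seeds,
                 iterations_used = it, converged = converged),
            class = "propagation_scores")
}

#' @export
print.propagation_scores <- function(x, ...) {
  cat(sprintf("<propagation_scores> restart = %.3f, %d iterations, converged = %s\n",
              x$restart_prob, x$iterations_used, x$converged))
  invisible(x)
}

#' Random walk with restart scores
#'
#' Stationary distribution of a walker that at each step either follows a
#' weighted random-walk transition (probability `1 - restart_prob`) or
#' restarts uniformly at a seed node (probability `restart_prob`). Solved by
#' power iteration of `v <- (1 - r) P'v + r e_S` to an L1 change below
#' `tol`; dangling-node mass is returned to the seed vector so the scores
#' always sum to 1. Frequently visited nodes score highly, reflecting their
#' proximity to the seeds.
#'
#' @param g a [weighted_graph()]
#' @param seeds nonempty character vector of seed labels
#' @param restart_prob restart probability in (0, 1); default 0.15
#' @param tol L1 convergence tolerance, default 1e-10
#' @param max_iter iteration cap, default 10000
#' @return object of class `propagation_scores`: list with `scores` (named,
#'   nonnegative, summing to 1), `restart_prob`, `seeds`, `iterations_used`,
#'   `converged`
#' @export
rwr_scores <- function(g, seeds, restart_prob = 0.15, tol = 1e-10,
                       max_iter = 10000L) {
  if (restart_prob <= 0 || restart_prob >= 1) stop("restart_prob must lie in (0, 1)")
  res <- propagate(g, seeds, alpha = 1 - restart_prob, tol = tol,
                   max_iter = max_iter)
  if (!res$converged) {
    warning("random walk with restart did not converge in ", max_iter,
            " iterations")
  }
  res
}

#' Personalized PageRank scores
#'
#' PageRank with the teleport vector uniform over the seed set: with
#' probability `damping` the walker follows a transition, otherwise it
#' teleports to a seed. Dangling-node mass is redistributed to the teleport
#' vector (standard convention). Equivalent to [rwr_scores()] with
#' `restart_prob = 1 - damping`.
#'
#' @param g a [weighted_graph()]
#' @param seeds nonempty character vector of seed labels
#' @param damping continuation probability in \[0, 1); default 0.85
#' @param tol L1 convergence tolerance, default 1e-10
#' @param max_iter iteration cap, default 10000
#' @return a `propagation_scores` object (see [rwr_scores()])
#' @export
ppr_scores <- function(g, seeds, damping = 0.85, tol = 1e-10,
                       max_iter = 10000L) {
  res <- propagate(g, seeds, alpha = damping, tol = tol, max_iter = max_iter)
  if (!res$converged) {
    warning("personalized PageRank did not converge in ", max_iter,
            " iterations")
  }
  res
}

#' Rank non-seed nodes by propagation score
#'
#' Seed nodes are excluded; the rest are sorted by descending score with
#' ties broken by label order, producing a deterministic full ranking
#' comparable with the information-distance recommender.
#'
#' @param scores a `propagation_scores` object
#' @param exclude node labels to drop (defaults to the scoring seed set)
#' @return character vector of node labels, best first
#' @export
rank_by_scores <- function(scores, exclude = scores$seeds) {
  stopifnot(inherits(scores, "propagation_scores"))
  s <- scores$scores[!names(scores$scores) %in% exclude]
  names(s)[order(-s, names(s))]
}
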