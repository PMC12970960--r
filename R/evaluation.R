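#' Normalized discounted cumulative gain (binary relevance)
#'
#' `DCG = sum_p rel_p / log2(p + 1)` over 1-based positions `p` of the
#' ranking, with `rel_p = 1` when the item at position `p` is relevant;
#' `IDCG` is the DCG of the ideal ranking placing all relevant items first.
#' The returned `DCG / IDCG` lies in `[0, 1]` and equals 1 exactly when all
#' relevant items occupy the top ranks.
#'
#' @param ranking ordered character vector of candidate labels, best first
#' @param relevant nonempty character vector of relevant labels
#' @return NDCG in `[0, 1]`
#' @export
ndcg <- function(ranking, relevant) {
  if (length(relevant) == 0) stop("relevant set is empty")
  pos <- seq_along(ranking)
  rel <- ranking %in% relevant
  dcg <- sum(1 / log2(pos[rel] + 1))
  ideal_n <- min(length(relevant), length(ranking))
  idcg <- sum(1 / log2(seq_len(ideal_n) + 1))
  dcg / idcg
}

# run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

rank_with_method <- function(g, train, method, restart_prob) {
  switch(method,
    "idgba-boundary" = extend(g, train, metric = "boundary"),
    "idgba-radial"   = extend(g, train, metric = "radial"),
    "rwr" = rank_by_scores(rwr_scores(g, train, restart_prob = restart_prob)),
    "ppr" = rank_by_scores(ppr_scores(g, train, damping = 1 - restart_prob)),
    stop("unknown method: ", method)
  )
}

#' Repeated hold-out evaluation of extension methods
#'
#' For each of `n_splits` random splits, a `train_fraction` sample of the
#' cluster serves as the seed set and each method produces a full ranking of
#' the remaining nodes; NDCG is computed with the held-out members as the
#' relevant set. The information-distance methods are scored on their full
#' ranking (the automatic cutoff is recorded separately as precision/recall
#' of the below-threshold set, not used to truncate), so NDCG is comparable
#' with baselines lacking a cutoff. The cluster's conductance is always
#' reported.
#'
#' @param g a [weighted_graph()]
#' @param cluster character vector of cluster member labels (>= 5, strict
#'   subset of V)
#' @param methods subset of `"idgba-boundary"`, `"idgba-radial"`, `"rwr"`,
#'   `"ppr"`; may be empty
#' @param n_splits number of random splits, default 10
#' @param train_fraction fraction of the cluster used as seeds, default 0.8;
#'   train size is `round(train_fraction * |cluster|)`
#' @param rng_seed integer seed controlling the splits
#' @param restart_prob restart probability passed to the rwr/ppr baselines
#' @return object of class `evaluation_report`: list with `ndcg` (matrix
#'   splits x methods), `conductance`, `splits` (list of train/test label
#'   sets), `cutoff` (per idgba method, splits x precision/recall), and the
#'   call parameters
#' @export
run_splits <- function(g, cluster, methods = c("idgba-boundary", "rwr", "ppr"),
                       n_splits = 10L, train_fraction = 0.8, rng_seed = 0L,
                       restart_prob = 0.15) {
  stopifnot(inherits(g, "weighted_graph"))
  validate_seeds(g, cluster)
  if (length(cluster) < 5) stop("cluster must have at least 5 members")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  n_train <- round(train_fraction * length(cluster))
  if (n_train < 1 || n_train >= length(cluster)) {
    stop("cluster too small for a nonempty train and test set at this fraction")
  }
  splits <- with_seed(rng_seed, lapply(seq_len(n_splits), function(s) {
    train <- sort(sample(cluster, n_train))
    list(train = train, test = setdiff(cluster, train))
  }))
  scores <- matrix(NA_real_, n_splits, length(methods),
                   dimnames = list(NULL, methods))
  cutoff <- list()
  for (m in methods) {
    if (startsWith(m, "idgba")) {
      cutoff[[m]] <- matrix(NA_real_, n_splits, 2,
                            dimnames = list(NULL, c("precision", "recall")))
    }
  }
  for (s in seq_len(n_splits)) {
    for (m in methods) {
      res <- rank_with_method(g, splits[[s]]$train, m, restart_prob)
      if (inherits(res, "ranked_extension")) {
        ranking <- res$candidates
        accepted <- res$candidates[seq_len(res$cutoff_index)]
        hit <- length(intersect(accepted, splits[[s]]$test))
        cutoff[[m]][s, ] <- c(
          precision = if (length(accepted)) hit / length(accepted) else NA_real_,
          recall = hit / length(splits[[s]]$test))
      } else {
        ranking <- res
      }
      scores[s, m] <- ndcg(ranking, splits[[s]]$test)
    }
  }
  structure(list(ndcg = scores,
                 conductance = conductance(g, cluster),
                 splits = splits,
                 cutoff = cutoff,
                 methods = methods,
                 n_splits = n_splits,
                 train_fraction = train_fraction,
                 rng_seed = rng_seed,
                 restart_prob = restart_prob),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d splits, cluster conductance = %.4f\n",
              x$n_splits, x$conductance$phi))
  if (length(x$methods)) {
    for (m in x$methods) {
      cat(sprintf("  %-16s mean NDCG = %.4f\n", m, mean(x$ndcg[, m])))
    }
  }
  invisible(x)
}

#' Summarize an evaluation report
#'
#' Per-method mean NDCG, sample standard deviation and a t-based 95%
#' confidence interval (t with n-1 degrees of freedom — split counts are
#' small), plus paired per-split comparisons between every method pair with
#' a paired t-test p-value (NA when the per-split differences are constant).
#'
#' @param report an `evaluation_report` with at least 2 splits
#' @param conf_level confidence level, default 0.95
#' @return list with `per_method` and `pairwise` data frames
#' @export
summarize_evaluation <- function(report, conf_level = 0.95) {
  stopifnot(inherits(report, "evaluation_report"))
  if (report$n_splits < 2) stop("need at least 2 splits to summarize")
  m <- report$ndcg
  n <- nrow(m)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  per_method <- data.frame(
    method = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  per_method$ci_lo <- per_method$mean - tq * per_method$sd / sqrt(n)
  per_method$ci_hi <- per_method$mean + tq * per_method$sd / sqrt(n)
  pairs <- if (ncol(m) >= 2) utils::combn(colnames(m), 2, simplify = FALSE) else list()
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    d <- m[, pr[1]] - m[, pr[2]]
    pval <- if (stats::sd(d) > 0) stats::t.test(d)$p.value else NA_real_
    data.frame(method_a = pr[1], method_b = pr[2],
               mean_difference = mean(d), p_value = pval,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairwise)) {
    pairwise <- data.frame(method_a = character(0), method_b = character(0),
                           mean_difference = numeric(0), p_value = numeric(0))
  }
  list(per_method = per_method, pairwise = pairwise)
}

#' @export
summary.evaluation_report <- function(object, ...) summarize_evaluation(object, ...)
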