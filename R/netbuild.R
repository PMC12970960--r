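#' Construct a case/control expression matrix
#'
#' Genes as rows, samples as columns, with a case/control condition label
#' per sample. Both conditions must be present.
#'
#' @param values numeric matrix genes x samples with unique dimnames
#' @param condition character/factor per sample, values `"case"`/`"control"`
#' @return object of class `expression_matrix`: list with `values` and
#'   `condition` (factor, aligned with the sample columns)
#' @export
expression_matrix <- function(values, condition) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene labels")
  if (anyDuplicated(colnames(values))) stop("duplicate sample labels")
  condition <- as.character(condition)
  if (length(condition) != ncol(values)) {
    stop("condition must have one entry per sample")
  }
  if (!all(condition %in% c("case", "control"))) {
    stop("condition values must be 'case' or 'control'")
  }
  if (length(unique(condition)) < 2) stop("both conditions must be present")
  structure(list(values = values,
                 condition = factor(condition, levels = c("case", "control"))),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d case / %d control)\n",
              nrow(x$values), ncol(x$values),
              sum(x$condition == "case"), sum(x$condition == "control")))
  invisible(x)
}

#' Read an expression matrix and its sample annotation
#'
#' The expression file is CSV or TSV (by extension) with genes as rows
#' (first column) and samples as columns (header). The annotation is a
#' two-column CSV `sample,condition` with condition `case` or `control`.
#'
#' @param values_path expression file path
#' @param annot_path sample annotation CSV path
#' @return an [expression_matrix()]
#' @export
read_expression <- function(values_path, annot_path) {
  if (!file.exists(values_path)) stop("file not found: ", values_path)
  if (!file.exists(annot_path)) stop("file not found: ", annot_path)
  vals <- utils::read.table(values_path, sep = sep_for(values_path),
                            header = TRUE, row.names = 1, check.names = FALSE)
  annot <- utils::read.csv(annot_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "condition") %in% colnames(annot))) {
    stop("annotation needs columns 'sample' and 'condition'")
  }
  cond <- annot$condition[match(colnames(vals), annot$sample)]
  if (anyNA(cond)) stop("annotation missing for sample(s): ",
                        paste(colnames(vals)[is.na(cond)], collapse = ", "))
  expression_matrix(as.matrix(vals), cond)
}

#' Z-score normalize an expression matrix
#'
#' Centers and scales every gene to mean 0 and unit variance across all
#' samples. Genes with zero variance cannot be standardized and are dropped
#' with a warning.
#'
#' @param x an [expression_matrix()] with at least 2 samples
#' @return a normalized `expression_matrix`
#' @export
normalize_expression <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  if (ncol(x$values) < 2) stop("need at least 2 samples to normalize")
  sds <- apply(x$values, 1, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant gene(s): ",
            paste(utils::head(rownames(x$values)[constant], 5), collapse = ", "))
  }
  v <- x$values[!constant, , drop = FALSE]
  v <- (v - rowMeans(v)) / apply(v, 1, stats::sd)
  expression_matrix(v, as.character(x$condition))
}

#' Keep the most variable genes
#'
#' Ranks genes by variance across all samples on the values as given
#' (variance filtering is meaningful on raw values; after z-scoring every
#' gene has unit variance) and keeps the top `n`, ties at the boundary
#' resolved in favor of the lexicographically smaller label.
#'
#' @param x an [expression_matrix()]
#' @param n number of genes to keep, at most the number of genes
#' @return an `expression_matrix` restricted to the selected genes (original
#'   row order preserved)
#' @export
select_top_variable <- function(x, n) {
  stopifnot(inherits(x, "expression_matrix"))
  if (n > nrow(x$values)) stop("n exceeds the number of genes")
  v <- apply(x$values, 1, stats::var)
  keep <- rownames(x$values)[order(-v, rownames(x$values))][seq_len(n)]
  expression_matrix(x$values[rownames(x$values) %in% keep, , drop = FALSE],
                    as.character(x$condition))
}

# invert a covariance matrix; when near-singular (p >= n or condition number
# beyond `cond_max`) a common heavy ridge `lambda` is required from the caller
prec_of <- function(s, lambda = 0) {
  if (lambda > 0) s <- s + lambda * diag(nrow(s))
  solve(s)
}

cov_condition_bad <- function(s, cond_max = 1e12) {
  r <- rcond(s)
  !is.finite(r) || r < 1 / cond_max
}

#' Differential co-expression graph from case/control expression
#'
#' Estimates gene-gene precision (inverse covariance) matrices for the
#' control samples and for all samples pooled, and takes their difference:
#' off-diagonal precision entries encode conditional dependence, so the
#' difference highlights gene pairs whose dependence structure changes in
#' cases. The difference is symmetrized, its absolute value taken (the
#' magnitude of differential conditional dependence — an adjacency matrix
#' must be nonnegative), and the diagonal zeroed.
#'
#' Well-conditioned covariances are inverted directly. When either
#' covariance is near-singular (condition number beyond `cond_max`, which is
#' unavoidable whenever genes outnumber samples) both are given the same
#' heavy ridge `lambda = ridge_scale * max spectral norm`: in this
#' shrinkage-dominated regime the regularized precision difference is a
#' stable, smoothly weighted transform of the covariance difference rather
#' than an explosive inverse of a rank-deficient estimate.
#'
#' @param x an [expression_matrix()] with at least 3 samples per condition
#' @param ridge_scale ridge multiple of the larger spectral norm used in the
#'   near-singular regime, default 2
#' @param cond_max condition-number limit beyond which the ridge is applied,
#'   default 1e12
#' @return an undirected [weighted_graph()] on the genes with zero diagonal
#' @export
differential_precision_graph <- function(x, ridge_scale = 2, cond_max = 1e12) {
  stopifnot(inherits(x, "expression_matrix"))
  n_case <- sum(x$condition == "case")
  n_ctrl <- sum(x$condition == "control")
  if (n_case < 3 || n_ctrl < 3) stop("need at least 3 samples per condition")
  s_ctrl <- stats::cov(t(x$values[, x$condition == "control", drop = FALSE]))
  s_all <- stats::cov(t(x$values))
  lambda <- 0
  if (cov_condition_bad(s_ctrl, cond_max) || cov_condition_bad(s_all, cond_max)) {
    norm2 <- function(s) eigen(s, symmetric = TRUE, only.values = TRUE)$values[1]
    lambda <- ridge_scale * max(norm2(s_ctrl), norm2(s_all))
  }
  d <- prec_of(s_all, lambda) - prec_of(s_ctrl, lambda)
  d <- (d + t(d)) / 2
  w <- abs(d)
  diag(w) <- 0
  weighted_graph(w, directed = FALSE, labels = rownames(x$values))
}

internal_conductance <- function(w, idx) {
  comp <- setdiff(seq_len(nrow(w)), idx)
  cut <- sum(w[idx, comp, drop = FALSE])
  denom <- min(sum(w[idx, , drop = FALSE]), sum(w[comp, , drop = FALSE]))
  if (denom > 0) cut / denom else 0
}

#' Spectral clustering with minimum-conductance cluster selection
#'
#' Normalized spectral clustering on the graph's weights as an affinity
#' matrix: the k eigenvectors of the symmetric normalized Laplacian with the
#' smallest eigenvalues are row-normalized and partitioned with k-means.
#' Every cluster's conductance is computed and the minimum-conductance
#' cluster — the most tightly isolated gene community — is returned as the
#' recommended starting module for extension.
#'
#' @param g a [weighted_graph()]
#' @param k number of clusters, `2 <= k < |V|`; 40 suits genome-scale
#'   co-expression graphs where modules should match pathway size
#' @param rng_seed seed for the k-means stage (fixing it makes the
#'   clustering deterministic)
#' @param nstart k-means restarts, default 10
#' @return object of class `cluster_assignment`: list with `assignment`
#'   (named integer per gene in 1..k), `k`, `conductance` (per cluster),
#'   `selected_cluster` (index) and `selected` (labels of the
#'   minimum-conductance cluster)
#' @export
spectral_cluster_select <- function(g, k, rng_seed = 0L, nstart = 10L) {
  stopifnot(inherits(g, "weighted_graph"))
  n <- graph_order(g)
  if (k < 2 || k >= n) stop("k must satisfy 2 <= k < |V|")
  w <- g$weights
  deg <- rowSums(w)
  dinv <- 1 / sqrt(pmax(deg, 1e-300))
  lap <- diag(n) - dinv * sweep(w, 2, dinv, "*")
  ev <- eigen(lap, symmetric = TRUE)
  u <- ev$vectors[, n - seq_len(k) + 1, drop = FALSE]
  u <- u / pmax(sqrt(rowSums(u^2)), 1e-12)
  km <- with_seed(rng_seed, stats::kmeans(u, centers = k, nstart = nstart))
  assignment <- stats::setNames(km$cluster, g$labels)
  phis <- vapply(seq_len(k), function(cl) {
    idx <- which(assignment == cl)
    if (length(idx) == n) return(NA_real_)
    internal_conductance(w, idx)
  }, numeric(1))
  sel <- which.min(phis)
  structure(list(assignment = assignment, k = k, conductance = phis,
                 selected_cluster = sel,
                 selected = sort(g$labels[assignment == sel])),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d; selected cluster %d (%d genes, phi = %.4f)\n",
              x$k, x$selected_cluster, length(x$selected),
              x$conductance[x$selected_cluster]))
  invisible(x)
}

#' Disease-disease graph from gene association scores
#'
#' Each disease is a vector of per-gene association scores in `[0, 1]`. The
#' edge weight between two diseases is the Pearson correlation (or cosine
#' similarity) of their score vectors restricted to genes where at least one
#' of the two has a nonzero score, clipped below at 0. The densely connected
#' result is then pruned: only the top `prune_fraction` of positive-weight
#' edges (by weight, boundary ties all kept) survive.
#'
#' @param scores numeric matrix genes x diseases with entries in `[0, 1]`
#' @param prune_fraction fraction of positive edges to keep, in (0, 1];
#'   default 0.05
#' @param method `"pearson"` (default) or `"cosine"`
#' @return an undirected [weighted_graph()] over the diseases
#' @export
disease_graph <- function(scores, prune_fraction = 0.05,
                          method = c("pearson", "cosine")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) stop("score matrix needs disease column names")
  if (ncol(scores) < 2) stop("need at least 2 diseases")
  if (any(scores < 0) || any(scores > 1)) stop("scores must lie in [0, 1]")
  if (prune_fraction <= 0 || prune_fraction > 1) {
    stop("prune_fraction must lie in (0, 1]")
  }
  zero <- colSums(scores) == 0
  if (any(zero)) {
    warning("excluding disease(s) with all-zero scores: ",
            paste(colnames(scores)[zero], collapse = ", "))
    scores <- scores[, !zero, drop = FALSE]
    if (ncol(scores) < 2) stop("fewer than 2 diseases with nonzero scores")
  }
  diseases <- colnames(scores)
  nd <- length(diseases)
  w <- matrix(0, nd, nd, dimnames = list(diseases, diseases))
  for (i in seq_len(nd - 1)) {
    for (j in (i + 1):nd) {
      support <- scores[, i] > 0 | scores[, j] > 0
      a <- scores[support, i]; b <- scores[support, j]
      val <- if (method == "pearson") {
        if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
      } else {
        sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
      }
      w[i, j] <- w[j, i] <- max(val, 0)
    }
  }
  if (prune_fraction < 1) {
    upper <- w[upper.tri(w)]
    pos <- upper[upper > 0]
    if (length(pos)) {
      n_keep <- ceiling(prune_fraction * length(pos))
      cutoff <- sort(pos, decreasing = TRUE)[n_keep]
      w[w < cutoff] <- 0
    }
  }
  weighted_graph(w, directed = FALSE)
}
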