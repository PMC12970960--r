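#' Random graph with one planted dense cluster
#'
#' Emulates the structure the recommender assumes: a module that is well
#' isolated from the rest of the graph. The first `cluster_size` nodes form
#' the planted cluster; within-cluster pairs receive an edge with
#' probability `p_in`, all other pairs with probability `p_out`, and edge
#' weights are drawn uniformly from `[weight_low, weight_high]` (non-unit
#' weights keep row normalization nontrivial, so asymmetric transitions are
#' exercised). No self-loops are emitted.
#'
#' When `connect = TRUE` (default) a minimal random spanning structure at
#' weight `weight_low` joins any disconnected components, so every node is
#' reachable; disable it to exercise the unreachable-node (distance = T)
#' code paths.
#'
#' @param n_nodes total nodes, default 300
#' @param cluster_size planted cluster size (< n_nodes), default 30
#' @param p_in within-cluster edge probability, default 0.3
#' @param p_out background edge probability (< p_in), default 0.01
#' @param weight_low,weight_high uniform weight range, defaults 0.5 and 1.5
#' @param rng_seed integer seed; generation is bit-reproducible
#' @param connect repair connectivity, default TRUE
#' @return list with `graph` (a [weighted_graph()]) and `members` (labels of
#'   the planted cluster)
#' @export
planted_cluster_graph <- function(n_nodes = 300L, cluster_size = 30L,
                                  p_in = 0.3, p_out = 0.01,
                                  weight_low = 0.5, weight_high = 1.5,
                                  rng_seed = 0L, connect = TRUE) {
  if (cluster_size >= n_nodes) stop("cluster_size must be smaller than n_nodes")
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  if (weight_low <= 0 || weight_high < weight_low) {
    stop("need 0 < weight_low <= weight_high")
  }
  labels <- sprintf("n%0*d", nchar(as.character(n_nodes)), seq_len(n_nodes))
  members <- labels[seq_len(cluster_size)]
  with_seed(rng_seed, {
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    in_cluster <- pairs[, 1] <= cluster_size & pairs[, 2] <= cluster_size
    prob <- ifelse(in_cluster, p_in, p_out)
    present <- stats::runif(nrow(pairs)) < prob
    w <- matrix(0, n_nodes, n_nodes, dimnames = list(labels, labels))
    if (any(present)) {
      wts <- stats::runif(sum(present), weight_low, weight_high)
      sel <- pairs[present, , drop = FALSE]
      w[sel] <- wts
      w[sel[, c(2, 1), drop = FALSE]] <- wts
    }
    if (connect) {
      comps <- igraph::components(
        igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected"))
      if (comps$no > 1) {
        anchor_comp <- which.max(comps$csize)
        pick <- function(idx) idx[sample.int(length(idx), 1)]
        anchor_nodes <- which(comps$membership == anchor_comp)
        for (cmp in setdiff(seq_len(comps$no), anchor_comp)) {
          a <- pick(which(comps$membership == cmp))
          b <- pick(anchor_nodes)
          w[a, b] <- w[b, a] <- weight_low
        }
      }
    }
    list(graph = weighted_graph(w, directed = FALSE), members = members)
  })
}

#' Case/control expression matrix with a planted co-regulated module
#'
#' Emulates a gene module co-regulated only in disease: control samples are
#' i.i.d. standard normal for every gene; in case samples the first
#' `module_genes` genes share a per-sample latent factor mixed as
#' `sqrt(module_corr) * factor + sqrt(1 - module_corr) * noise`, which gives
#' pairwise within-module correlation close to `module_corr` (attenuated
#' slightly by the measurement noise added to every entry). The defaults —
#' a 40-gene module among 500 genes with correlation 0.8, 100 case and 100
#' control samples — describe a strong, desk-scale differential module.
#'
#' @param n_genes total genes, default 500
#' @param n_case,n_control sample counts (each >= 3), defaults 100
#' @param module_genes module size (<= n_genes), default 40
#' @param module_corr target within-module case correlation in (0, 1),
#'   default 0.8
#' @param noise_sd s.d. of i.i.d. measurement noise added to every entry,
#'   default 0.1
#' @param rng_seed integer seed; generation is bit-reproducible
#' @return list with `expr` (an [expression_matrix()], case samples first)
#'   and `module` (labels of the planted module genes)
#' @export
planted_expression <- function(n_genes = 500L, n_case = 100L, n_control = 100L,
                               module_genes = 40L, module_corr = 0.8,
                               noise_sd = 0.1, rng_seed = 0L) {
  if (module_genes > n_genes) stop("module_genes must not exceed n_genes")
  if (n_case < 3 || n_control < 3) stop("need at least 3 samples per condition")
  if (module_corr <= 0 || module_corr >= 1) stop("module_corr must lie in (0, 1)")
  genes <- sprintf("g%0*d", nchar(as.character(n_genes)), seq_len(n_genes))
  samples <- c(sprintf("case_%03d", seq_len(n_case)),
               sprintf("ctrl_%03d", seq_len(n_control)))
  module <- genes[seq_len(module_genes)]
  with_seed(rng_seed, {
    case <- matrix(stats::rnorm(n_genes * n_case), n_genes, n_case)
    latent <- stats::rnorm(n_case)
    case[seq_len(module_genes), ] <-
      sqrt(module_corr) * matrix(latent, module_genes, n_case, byrow = TRUE) +
      sqrt(1 - module_corr) * case[seq_len(module_genes), ]
    ctrl <- matrix(stats::rnorm(n_genes * n_control), n_genes, n_control)
    vals <- cbind(case, ctrl) +
      matrix(stats::rnorm(n_genes * (n_case + n_control), sd = noise_sd),
             n_genes, n_case + n_control)
    dimnames(vals) <- list(genes, samples)
    list(expr = expression_matrix(vals, rep(c("case", "control"),
                                            c(n_case, n_control))),
         module = module)
  })
}
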