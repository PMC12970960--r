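make_expr <- function(values, cond) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  expression_matrix(values, cond)
}

test_that("z-score normalization standardizes genes and drops constants", {
  v <- rbind(c(1, 2, 3), c(5, 5, 5), c(0, 10, 20))
  x <- make_expr(v, c("case", "case", "control"))
  expect_warning(nx <- normalize_expression(x), "constant")
  expect_equal(nrow(nx$values), 2)
  expect_equal(unname(rowMeans(nx$values)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(nx$values, 1, sd)), c(1, 1), tolerance = 1e-12)
  # idempotence on standardized input
  nx2 <- normalize_expression(nx)
  expect_equal(nx2$values, nx$values, tolerance = 1e-9)
})

test_that("top-variable selection ranks by variance with label tie-breaks", {
  v <- rbind(a = c(0, 1, 2), b = c(0, 2, 4), c = c(0, 3, 6))
  x <- make_expr(v, c("case", "control", "control"))
  expect_equal(rownames(select_top_variable(x, 3)$values), c("a", "b", "c"))
  expect_equal(rownames(select_top_variable(x, 2)$values), c("b", "c"))
  expect_error(select_top_variable(x, 4), "exceeds")
  # exact tie at the boundary: lexicographically smaller label wins
  v2 <- rbind(zz = c(0, 1), aa = c(0, 1), mm = c(0, 2))
  x2 <- make_expr(v2, c("case", "control"))
  expect_equal(sort(rownames(select_top_variable(x2, 2)$values)),
               c("aa", "mm"))
})

test_that("differential precision graph is a valid symmetric graph", {
  res <- planted_expression(n_genes = 40, n_case = 60, n_control = 60,
                            module_genes = 8, rng_seed = 1)
  g <- differential_precision_graph(normalize_expression(res$expr))
  expect_s3_class(g, "weighted_graph")
  expect_true(isSymmetric(g$weights))
  expect_true(all(g$weights >= 0))
  expect_equal(unname(diag(g$weights)), rep(0, 40))
  expect_error(differential_precision_graph(
    make_expr(matrix(rnorm(20), 4, 5),
              c("case", "case", "control", "control", "control"))),
    "3 samples per condition")
})

test_that("null data gives near-zero weights and planted pairs rank high", {
  # no differential structure: the weight scale shrinks toward zero as the
  # sample count grows (simulation oracle for the estimator's consistency)
  set.seed(4)
  med <- vapply(c(100, 1600), function(n) {
    v <- matrix(rnorm(30 * n), 30, n)
    x <- make_expr(v, rep(c("case", "control"), each = n / 2))
    g0 <- differential_precision_graph(normalize_expression(x))
    median(g0$weights[upper.tri(g0$weights)])
  }, numeric(1))
  expect_lt(med[2], med[1] / 4)
  expect_lt(med[2], 0.05)

  # planted differential module in the genes > samples regime (the regime
  # co-expression data lives in): module pairs dominate the heaviest edges
  for (s in 1:3) {
    res <- planted_expression(n_genes = 60, n_case = 25, n_control = 25,
                              module_genes = 10, module_corr = 0.8,
                              rng_seed = s)
    g1 <- differential_precision_graph(normalize_expression(res$expr))
    w <- g1$weights
    ut <- upper.tri(w)
    in_mod_pair <- outer(rownames(w) %in% res$module,
                         colnames(w) %in% res$module, "&")
    expect_gt(mean(w[in_mod_pair & ut]), 2 * mean(w[!in_mod_pair & ut]))
    # of the 20 heaviest edges, far more than the ~3% chance rate are
    # module-module pairs
    top20 <- order(-w[ut])[1:20]
    expect_gte(sum(in_mod_pair[ut][top20]), 8)
  }
})

test_that("spectral clustering recovers disjoint blocks exactly", {
  blocks <- matrix(0, 10, 10,
                   dimnames = list(sprintf("g%02d", 1:10), sprintf("g%02d", 1:10)))
  blocks[1:5, 1:5] <- 1
  blocks[6:10, 6:10] <- 1
  diag(blocks) <- 0
  g <- weighted_graph(blocks)
  cl <- spectral_cluster_select(g, k = 2, rng_seed = 1)
  expect_equal(length(unique(cl$assignment[1:5])), 1)
  expect_equal(length(unique(cl$assignment[6:10])), 1)
  expect_false(cl$assignment[1] == cl$assignment[6])
  expect_equal(unname(cl$conductance), c(0, 0))
  # determinism under a fixed seed
  cl2 <- spectral_cluster_select(g, k = 2, rng_seed = 1)
  expect_identical(cl$assignment, cl2$assignment)
  # bounds on k
  expect_error(spectral_cluster_select(g, k = 1), "2 <= k")
  cl9 <- spectral_cluster_select(g, k = 9, rng_seed = 1)
  expect_equal(length(cl9$assignment), 10)
  expect_true(all(table(cl9$assignment) >= 1))
})

test_that("the expression pipeline recovers the planted module", {
  res <- planted_expression(n_genes = 200, n_case = 80, n_control = 80,
                            module_genes = 25, module_corr = 0.8, rng_seed = 7)
  x <- select_top_variable(res$expr, 200)
  x <- normalize_expression(x)
  g <- differential_precision_graph(x)
  cl <- spectral_cluster_select(g, k = 5, rng_seed = 7)
  expect_gte(jaccard(cl$selected, res$module), 0.8)
})

test_that("disease graphs correlate score vectors and prune to the top edges", {
  scores <- cbind(d1 = c(0.9, 0.8, 0.1, 0, 0),
                  d2 = c(0.9, 0.8, 0.1, 0, 0),
                  d3 = c(0, 0, 0.2, 0.9, 0.7))
  rownames(scores) <- sprintf("g%d", 1:5)
  g <- disease_graph(scores, prune_fraction = 1)
  expect_equal(g$weights["d1", "d2"], 1)
  expect_true(all(g$weights >= 0))  # anticorrelated pairs clipped to zero

  # pruning keeps ceil(fraction * positive edges)
  set.seed(6)
  big <- matrix(runif(20 * 10), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("d%02d", 1:10)))
  gp <- disease_graph(big, prune_fraction = 0.1)
  gfull <- disease_graph(big, prune_fraction = 1)
  n_pos <- sum(gfull$weights[upper.tri(gfull$weights)] > 0)
  n_kept <- sum(gp$weights[upper.tri(gp$weights)] > 0)
  expect_equal(n_kept, ceiling(0.1 * n_pos))
  # kept edges are the heaviest ones
  kept <- gp$weights[upper.tri(gp$weights)]
  expect_true(min(kept[kept > 0]) >=
                max(gfull$weights[upper.tri(gfull$weights)][kept == 0]))

  # all-zero diseases are excluded with a warning
  z <- cbind(scores, dz = c(0, 0, 0, 0, 0))
  expect_warning(gz <- disease_graph(z, prune_fraction = 1), "all-zero")
  expect_false("dz" %in% gz$labels)
})

test_that("expression files round-trip through read_expression", {
  res <- planted_expression(n_genes = 12, n_case = 4, n_control = 4,
                            module_genes = 3, rng_seed = 3)
  vp <- withr::local_tempfile(fileext = ".csv")
  ap <- withr::local_tempfile(fileext = ".csv")
  vals <- res$expr$values
  utils::write.csv(data.frame(gene = rownames(vals), vals, check.names = FALSE),
                   vp, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(sample = colnames(vals),
                              condition = as.character(res$expr$condition)),
                   ap, row.names = FALSE, quote = FALSE)
  x <- read_expression(vp, ap)
  expect_equal(x$values, vals, tolerance = 1e-12)
  expect_equal(as.character(x$condition), as.character(res$expr$condition))
})
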