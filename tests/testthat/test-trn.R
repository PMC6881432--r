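toy_regulon <- function(n = 60, seed = 1, slope = 5, noise = 0.1,
                        n_tfs = 20) {
  set.seed(seed)
  tfs <- matrix(rnorm(n * n_tfs), n, n_tfs,
                dimnames = list(NULL, paste0("tf", seq_len(n_tfs))))
  target <- slope * tfs[, 1] + rnorm(n, sd = noise)
  x <- cbind(tfs, target = target, noise1 = rnorm(n), noise2 = rnorm(n))
  x
}

test_that("gaussian MI is a monotone map of correlation and caps at identity", {
  set.seed(1)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  x[, "b"] <- x[, "a"]                     # y = x exactly
  mi <- mi_matrix(x, "gaussian", mi_max = 10)
  expect_equal(mi["a", "b"], 10)
  expect_true(all(diag(mi) == 0))
  s <- score_mi_clr(x, c("a", "c"))
  expect_true(is.na(s["a", "a"]))
  expect_equal(colnames(s)[which.max(s["a", ])], "b")
})

test_that("binned MI estimator detects dependence on small matrices", {
  set.seed(2)
  u <- rnorm(200)
  x <- cbind(a = u, b = u + rnorm(200, sd = 0.2), c = rnorm(200))
  mi <- mi_matrix(x, "binned", n_bins = 8)
  expect_gt(mi["a", "b"], mi["a", "c"])
  expect_equal(mi, t(mi))
})

test_that("CLR scores of independent genes are centered near zero", {
  set.seed(3)
  accs <- replicate(3, {
    x <- matrix(rnorm(40 * 30), 40, 30,
                dimnames = list(NULL, paste0("g", 1:30)))
    s <- score_mi_clr(x, paste0("g", 1:5))
    mean(s, na.rm = TRUE)
  })
  expect_lt(mean(accs), 0.8)  # CLR is non-negative; null mean stays small
})

test_that("DPI removes exactly the weakest edge of a toy triangle", {
  mi <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  mi["A", "B"] <- mi["B", "A"] <- 0.9
  mi["B", "C"] <- mi["C", "B"] <- 0.8
  mi["A", "C"] <- mi["C", "A"] <- 0.3
  pruned <- dpi_prune(mi, 0)
  expect_equal(pruned["A", "C"], 0)
  expect_equal(pruned["A", "B"], 0.9)
  expect_equal(pruned["B", "C"], 0.8)
})

test_that("ARACNE output is a subset of MI and never drops a triangle's top edge", {
  set.seed(4)
  x <- matrix(rnorm(25 * 12), 25, 12,
              dimnames = list(NULL, paste0("g", 1:12)))
  mi <- mi_matrix(x)
  pruned <- dpi_prune(unclass(mi), 0)
  expect_true(all(pruned[pruned > 0] == mi[pruned > 0]))
  expect_true(all((pruned > 0) <= (unclass(mi) > 0)))
  # every removed edge is dominated by some third gene
  p <- ncol(mi)
  removed <- which(pruned == 0 & unclass(mi) > 0 & upper.tri(mi),
                   arr.ind = TRUE)
  expect_gt(nrow(removed), 0)
  for (e in seq_len(nrow(removed))) {
    i <- removed[e, 1]; j <- removed[e, 2]
    dom <- pmin(mi[i, ], mi[j, ])[-c(i, j)]
    expect_gt(max(dom), mi[i, j])
  }
  # the globally strongest edge can never be dominated, hence never removed
  top <- which(unclass(mi) == max(mi), arr.ind = TRUE)[1, ]
  expect_gt(pruned[top[1], top[2]], 0)
})

test_that("tree importance finds a planted linear regulator, deterministically", {
  x <- toy_regulon(seed = 5)
  s <- score_tree_importance(x, paste0("tf", 1:20), n_trees = 100, seed = 7)
  expect_equal(rownames(s)[which.max(s[, "target"])], "tf1")
  s2 <- score_tree_importance(x, paste0("tf", 1:20), n_trees = 100,
                              seed = 7)
  expect_identical(s, s2)
  expect_gt(max(s[, "target"], na.rm = TRUE),
            max(s[, "noise1"], na.rm = TRUE))
  expect_error(score_tree_importance(x, "absent"), "no TFs")
})

test_that("shrinkage partial correlation demotes mediated edges", {
  set.seed(6)
  n <- 500
  x1 <- rnorm(n)
  y <- 0.9 * x1 + rnorm(n, sd = 0.4)
  z <- 0.9 * y + rnorm(n, sd = 0.4)
  x <- cbind(X = x1, Y = y, Z = z, N = rnorm(n))
  s <- score_partial_correlation(x, c("X", "Y", "Z"))
  expect_lt(s["X", "Z"], abs(cor(x1, z)))
  expect_gt(s["X", "Y"], s["X", "Z"])
  expect_gt(s["Y", "Z"], s["X", "Z"])
  expect_lt(s["X", "N"], 0.1)
  # near-zero shrinkage at large n: agree with the analytic inverse
  om <- solve(cor(x))
  pc_xy <- -om["X", "Y"] / sqrt(om["X", "X"] * om["Y", "Y"])
  expect_lt(abs(s["X", "Y"] - abs(pc_xy)), 0.02)
})

test_that("BIC selects the planted number of clusters", {
  set.seed(7)
  centers <- matrix(rnorm(5 * 4, sd = 12), 5, 4)
  g <- centers[rep(1:5, each = 30), ] + matrix(rnorm(150 * 4), 150, 4)
  rownames(g) <- paste0("g", 1:150)
  cl <- kmeans_bic(t(g), k_range = c(3, 8), nstart = 10, seed = 8)
  expect_equal(cl$K, 5)
  expect_equal(length(cl$assignments), 150)
  cl3 <- kmeans_bic(t(g), k_range = c(3, 3), nstart = 5, seed = 8)
  expect_equal(cl3$K, 3)
  expect_error(kmeans_bic(t(g), k_range = c(3, 200)), "k_range")
})

test_that("BIC reduces to the bare penalty when clusters fit exactly", {
  set.seed(9)
  centers <- matrix(c(0, 0, 10, 10, -10, 5, 0, 20, 7, -3), 5, 2)
  g <- centers[rep(1:5, each = 10), ] + matrix(rnorm(100, sd = 1e-6), 50, 2)
  rownames(g) <- paste0("g", 1:50)
  cl <- kmeans_bic(t(g), k_range = c(3, 5), nstart = 10, seed = 9)
  expect_equal(cl$K, 5)
  # at K = 5 residuals vanish, leaving only the log(N) * M * K penalty
  expect_equal(unname(cl$bic_curve[["5"]]), log(50) * 2 * 5,
               tolerance = 1e-6)
})

test_that("module scores follow TF-centroid correlation", {
  set.seed(10)
  n <- 24
  c1 <- rnorm(n); c2 <- rnorm(n)
  x <- cbind(tfA = c1,
             m1 = c1 + rnorm(n, sd = 0.05), m2 = c1 + rnorm(n, sd = 0.05),
             m3 = c2 + rnorm(n, sd = 0.05), m4 = c2 + rnorm(n, sd = 0.05))
  cl <- kmeans_bic(x[, -1], k_range = c(3, 3), nstart = 10, seed = 1)
  s <- score_modules(x, "tfA", k_range = c(3, 3), nstart = 10, seed = 1)
  expect_gt(min(s["tfA", c("m1", "m2")]), 0.9)
  expect_lt(max(s["tfA", c("m3", "m4")], na.rm = TRUE),
            min(s["tfA", c("m1", "m2")]))
})

test_that("ensemble aggregation respects identical inputs and filters promiscuous targets", {
  set.seed(11)
  tfs <- paste0("tf", 1:10)
  genes <- c(tfs, paste0("g", 1:30))
  m <- matrix(runif(10 * 40), 10, 40, dimnames = list(tfs, genes))
  for (tf in tfs) m[tf, tf] <- NA
  same <- ensemble_network(list(m, m, m), top_k_per_method = 100,
                           top_k_final = 100)
  v <- as.vector(m); names(v) <- paste(rep(tfs, times = 40),
                                       rep(genes, each = 10))
  v <- v[!is.na(v)]
  expected <- names(sort(v, decreasing = TRUE))[1:100]
  expect_equal(paste(same$tf, same$target), expected)

  # method relabeling cannot change the aggregate
  m2 <- matrix(runif(10 * 40), 10, 40, dimnames = list(tfs, genes))
  for (tf in tfs) m2[tf, tf] <- NA
  e12 <- ensemble_network(list(m, m2), top_k_per_method = 50,
                          top_k_final = 50)
  e21 <- ensemble_network(list(m2, m), top_k_per_method = 50,
                          top_k_final = 50)
  expect_equal(paste(e12$tf, e12$target), paste(e21$tf, e21$target))

  # a target hit by every TF is filtered and the list refilled
  hub <- m; hub[, "g1"] <- 2               # top score from all 10 TFs
  net <- ensemble_network(list(hub, hub), top_k_per_method = 200,
                          top_k_final = 60, promiscuity_fraction = 1)
  expect_false("g1" %in% net$target)
  expect_equal(attr(net, "filtered_targets"), "g1")
  expect_equal(nrow(net), 60)
})

test_that("per-TF networks give every TF its quota of targets", {
  set.seed(12)
  tfs <- paste0("tf", 1:5)
  genes <- c(tfs, paste0("g", 1:20))
  m <- matrix(runif(5 * 25), 5, 25, dimnames = list(tfs, genes))
  for (tf in tfs) m[tf, tf] <- NA
  net <- per_tf_network(list(m), top_m = 7)
  expect_equal(as.integer(table(net$tf)), rep(7L, 5))
  one <- net[net$tf == "tf1", ]
  expect_equal(one$target,
               names(sort(m["tf1", ], decreasing = TRUE))[1:7])
  expect_equal(as.integer(table(per_tf_network(list(m), top_m = 100)$tf)),
               rep(24L, 5))               # capped at n_genes - 1
})

test_that("ensemble recovers a planted network better than the median method", {
  st <- simulate_studies(simulation_config(n_genes = 400, n_tfs = 15,
                                           targets_per_tf = 10,
                                           confounder_effect = 1,
                                           tf_effect = 1.5, seed = 13))
  xs <- lapply(st$datasets, function(ds) log_quantile_center(rpkm(ds)))
  pooled <- do.call(rbind, xs)
  tfs <- st$tf_ids
  mats <- list(score_mi_clr(pooled, tfs),
               score_aracne(pooled, tfs),
               score_partial_correlation(pooled, tfs),
               score_tree_importance(pooled, tfs, n_trees = 50, seed = 2))
  truth <- paste(st$truth_edges$tf, st$truth_edges$target)
  dn <- dimnames(mats[[1]])
  tfv <- rep(dn[[1]], times = length(dn[[2]]))
  tgv <- rep(dn[[2]], each = length(dn[[1]]))
  keep <- tfv != tgv
  labs <- paste(tfv, tgv)[keep] %in% truth
  aucs <- vapply(mats, function(m)
    auroc(as.vector(unclass(m))[keep], labs), numeric(1))
  ranks <- vapply(mats, function(m) {
    v <- as.vector(unclass(m))[keep]; v[is.na(v)] <- -Inf
    r <- numeric(length(v)); ord <- order(-v); r[ord] <- seq_along(ord); r
  }, numeric(sum(keep)))
  ens_auc <- auroc(-apply(ranks, 1, median), labs)
  expect_gte(ens_auc, 0.70)
  expect_gte(ens_auc, median(aucs))
})
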