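test_that("hypergeometric tail matches exact enumeration", {
  expect_equal(hypergeom_p(4, 5, 5, 20), 76 / 15504)
  expect_equal(hypergeom_p(0, 5, 5, 20), 1)
  expect_equal(hypergeom_p(5, 5, 5, 5), 1)
  set.seed(1)
  for (i in 1:40) {
    N <- sample(5:25, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_p(k, n, K, N), oracle_hyper_p(k, n, K, N),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_p(6, 5, 10, 20), "inconsistent")
  expect_error(hypergeom_p(2, 5, 10, 8), "inconsistent")
})

toy_network <- function() {
  tfs <- paste0("tf", 1:4)
  genes <- paste0("g", 1:96)
  edges <- rbind(
    data.frame(tf = "tf1", target = genes[1:10]),    # all core
    data.frame(tf = "tf2", target = genes[11:30]),   # no core
    data.frame(tf = "tf3", target = c(genes[1:2], genes[31:38])),  # 2 core
    data.frame(tf = "tf4", target = c(genes[1:5], genes[41:55])))  # 5 of 20
  list(edges = edges, core = genes[1:10],
       universe = c(tfs, genes))
}

test_that("PhaseCoreTF detection applies the tail test, the >=3 filter and BH", {
  tn <- toy_network()
  res <- phasecore_tf(tn$edges, tn$core, universe = tn$universe)
  r1 <- res[res$tf == "tf1", ]
  # all 10 targets in a 10-gene core: the most extreme possible overlap
  expect_equal(r1$pval, 1 / choose(100, 10), tolerance = 1e-12)
  expect_true(r1$is_phasecore_tf)
  r3 <- res[res$tf == "tf3", ]
  expect_false(r3$kept)                       # only 2 core targets
  expect_true(is.na(r3$qval))
  expect_false(r3$is_phasecore_tf)
  kept <- res[res$kept, ]
  expect_equal(kept$qval, bh_adjust(kept$pval))
  expect_error(phasecore_tf(tn$edges, character(0)), "empty")
})

test_that("PhaseCoreTF recovery on a planted overlap is near perfect", {
  set.seed(2)
  genes <- paste0("g", 1:500)
  core <- genes[1:50]
  edges <- do.call(rbind, lapply(1:20, function(i) {
    tf <- paste0("tf", i)
    tgt <- if (i <= 10) c(sample(core, 8), sample(genes[51:500], 12))
           else sample(genes[51:500], 20)
    data.frame(tf = tf, target = tgt)
  }))
  res <- phasecore_tf(edges, core,
                      universe = c(paste0("tf", 1:20), genes))
  hits <- res$is_phasecore_tf[match(paste0("tf", 1:10), res$tf)]
  expect_gte(mean(hits), 0.9)
  others <- res$is_phasecore_tf[match(paste0("tf", 11:20), res$tf)]
  expect_lte(sum(others, na.rm = TRUE), 1)
})

test_that("functional enrichment switches between chi-squared and Fisher", {
  universe <- paste0("g", 1:200)
  lst <- universe[1:40]
  sets <- list(balanced = universe[c(1:20, 41:60)],   # expected cells >= 5
               tiny = universe[c(1:4, 195:200)],      # expected < 5
               two = universe[c(1, 2, 100:120)])
  res <- functional_enrichment(lst, sets, universe = universe)
  expect_equal(res$method[res$set == "balanced"], "chisq")
  expect_equal(res$method[res$set == "tiny"], "fisher")
  expect_false(res$kept[res$set == "two"])            # overlap 2 dropped
  # Fisher p agrees with direct exact test on the same table
  k <- 4; K <- 10; nl <- 40; N <- 200
  tab <- matrix(c(k, nl - k, K - k, N - nl - K + k), 2, 2)
  expect_equal(res$pval[res$set == "tiny"],
               stats::fisher.test(tab)$p.value)
  # no association: p = 1
  res0 <- functional_enrichment(universe[1:20],
                                list(s = universe[c(1:10, 21:30)]),
                                universe = universe[1:40])
  expect_equal(res0$pval, 1)
  expect_error(functional_enrichment(character(0), sets), "empty")
})

test_that("the chi-squared/Fisher switch depends only on expected counts", {
  set.seed(3)
  universe <- paste0("g", 1:150)
  for (i in 1:10) {
    lst <- sample(universe, sample(10:60, 1))
    set <- list(s = sample(universe, sample(5:60, 1)))
    res <- functional_enrichment(lst, set, universe = universe)
    k <- res$k; nl <- res$n; K <- res$K; N <- res$N
    tab <- matrix(c(k, nl - k, K - k, N - nl - K + k), 2, 2)
    expected <- outer(rowSums(tab), colSums(tab)) / N
    expect_equal(res$method, if (any(expected < 5)) "fisher" else "chisq")
  }
})

test_that("BH adjustment is the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(4)
  p <- runif(20)
  q <- bh_adjust(p)
  # literal step-up with monotonicity enforcement
  o <- order(p)
  stepup <- rev(cummin(rev(p[o] * 20 / seq_len(20))))
  expect_equal(q[o], pmin(1, stepup))
  expect_true(all(q >= p))
  # rejections form a prefix of the sorted p-values
  rej <- q[o] < 0.25
  expect_true(all(diff(rej) <= 0))
})

test_that("multi-set intersection permutation p agrees with the exact pairwise tail", {
  set.seed(5)
  universe <- 500
  a <- paste0("g", 1:60)
  b <- paste0("g", c(1:25, 301:335))
  res <- multiset_intersection_p(list(A = a, B = b), universe,
                                 n_perm = 4000, seed = 6)
  exact <- res$exact_p[1]
  mc_se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(res$pval[1] - exact), 3 * mc_se + 1 / 4000)

  ident <- multiset_intersection_p(list(A = a, B = a, C = a), universe,
                                   n_perm = 500, seed = 7)
  expect_true(all(ident$pval <= 1 / 500 + 1e-9))

  disj <- multiset_intersection_p(
    list(A = paste0("g", 1:5), B = paste0("g", 6:10)), 10000,
    n_perm = 500, seed = 8)
  expect_gt(disj$pval[1], 0.9)            # observed overlap is 0
  expect_error(multiset_intersection_p(list(a = paste0("g", 1:30)), 20),
               "at least 2")
  expect_error(multiset_intersection_p(list(a = paste0("g", 1:30),
                                            b = paste0("g", 1:5)), 20),
               "larger")
})

test_that("GMT collections round-trip through disk", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(back$sets, sets)
  expect_setequal(back$universe, c("g1", "g2", "g3", "g4"))
})
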