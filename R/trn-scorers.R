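#' Pairwise mutual information matrix
#'
#' Gaussian estimator: \code{MI = -1/2 log(1 - rho^2)} from the Pearson
#' correlation (capped at \code{mi_max} for |rho| -> 1). Binned estimator:
#' empirical MI over fixed equal-width bins (intended for small matrices).
#'
#' @param x samples-by-genes numeric matrix.
#' @param estimator \code{"gaussian"} or \code{"binned"}.
#' @param n_bins bins per gene for the binned estimator.
#' @param mi_max cap for the Gaussian estimator at perfect correlation.
#' @return symmetric genes-by-genes MI matrix, zero diagonal. Constant genes
#'   get zero MI and are flagged in attribute \code{"flagged"}.
#' @export
mi_matrix <- function(x, estimator = c("gaussian", "binned"), n_bins = 10,
                      mi_max = 10) {
  estimator <- match.arg(estimator)
  x <- as.matrix(x)
  flagged <- colnames(x)[apply(x, 2, stats::sd) == 0]
  if (estimator == "gaussian") {
    cc <- suppressWarnings(stats::cor(x))
    cc[!is.finite(cc)] <- 0
    mi <- -0.5 * log(pmax(1 - cc^2, .Machine$double.eps))
    mi[mi > mi_max] <- mi_max
  } else {
    disc <- apply(x, 2, function(v) {
      if (stats::sd(v) == 0) return(rep(1L, length(v)))
      br <- seq(min(v), max(v), length.out = n_bins + 1)
      findInterval(v, br, rightmost.closed = TRUE, all.inside = TRUE)
    })
    p <- ncol(x)
    mi <- matrix(0, p, p)
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      tab <- table(disc[, i], disc[, j]) / nrow(x)
      pi_ <- rowSums(tab); pj <- colSums(tab)
      nz <- tab > 0
      mi[i, j] <- mi[j, i] <-
        sum(tab[nz] * log(tab[nz] / outer(pi_, pj)[nz]))
    }
  }
  diag(mi) <- 0
  dimnames(mi) <- list(colnames(x), colnames(x))
  structure(mi, flagged = flagged)
}

#' Data-processing-inequality pruning of a mutual-information matrix
#'
#' Removes edge (i,j) whenever a third gene k exists with
#' \code{min(MI_ik, MI_jk) > MI_ij + eps}: in every triangle, only the
#' weakest edge can be removed, never the strongest.
#'
#' @param mi symmetric non-negative MI matrix.
#' @param eps DPI tolerance (default 0).
#' @return pruned matrix (removed edges set to 0).
#' @export
dpi_prune <- function(mi, eps = 0) {
  mi <- as.matrix(mi)
  if (nrow(mi) != ncol(mi)) stop("MI matrix must be square")
  out <- dpi_prune_cpp(mi, eps)
  dimnames(out) <- dimnames(mi)
  out
}

# subset a genes-by-genes score matrix to TF rows and mask self-edges
tf_rows <- function(score, tf_list) {
  tf_list <- intersect(tf_list, rownames(score))
  if (!length(tf_list)) stop("no TFs found among the genes")
  out <- score[tf_list, , drop = FALSE]
  for (tf in tf_list) out[tf, tf] <- NA
  class(out) <- c("score_matrix", class(out))
  out
}

#' CLR network scores
#'
#' Context-likelihood-of-relatedness: each MI value is standardized against
#' the MI background distribution of both genes,
#' \code{z_ij = sqrt(max(0, z_i(j))^2 + max(0, z_j(i))^2)}.
#'
#' @inheritParams mi_matrix
#' @param tf_list character vector of TF gene ids (must be columns of x).
#' @return TF-by-gene \code{score_matrix}, self-edges NA, attribute
#'   \code{"method"} = "clr".
#' @export
score_mi_clr <- function(x, tf_list, estimator = "gaussian", n_bins = 10) {
  mi <- mi_matrix(x, estimator, n_bins)
  mu <- rowMeans(mi)
  sdv <- apply(mi, 1, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (mi - mu) / sdv              # z_i(j) by row
  zp <- pmax(z, 0)
  clr <- sqrt(zp^2 + t(zp)^2)
  out <- tf_rows(clr, tf_list)
  attr(out, "method") <- "clr"
  out
}

#' ARACNE network scores
#'
#' Mutual information pruned by the data-processing inequality: the weakest
#' edge of every triangle is removed when it is below the triangle's other
#' two edges by more than \code{dpi_eps}.
#'
#' @inheritParams score_mi_clr
#' @param dpi_eps DPI tolerance (default 0).
#' @return TF-by-gene \code{score_matrix} of pruned MI values.
#' @export
score_aracne <- function(x, tf_list, dpi_eps = 0, estimator = "gaussian",
                         n_bins = 10) {
  mi <- mi_matrix(x, estimator, n_bins)
  pruned <- dpi_prune_cpp(unclass(mi), dpi_eps)
  dimnames(pruned) <- dimnames(mi)
  out <- tf_rows(pruned, tf_list)
  attr(out, "method") <- "aracne"
  out
}

#' Topological-overlap network scores
#'
#' TOM between every TF and gene from the signed soft-threshold adjacency
#' (see \code{\link{tom_matrix}}). With several datasets, each dataset's
#' TF-target pairs are ranked separately and merged by Borda median; the
#' returned score is then the negated median rank (higher = stronger).
#'
#' @param x samples-by-genes matrix, or a list of such matrices (one per
#'   dataset, same genes).
#' @param tf_list TF gene ids.
#' @param beta soft-threshold power(s); recycled over datasets.
#' @return TF-by-gene \code{score_matrix}.
#' @export
score_tom <- function(x, tf_list, beta = 6) {
  xs <- if (is.list(x) && !is.data.frame(x)) x else list(x)
  beta <- rep_len(beta, length(xs))
  mats <- lapply(seq_along(xs), function(i)
    tf_rows(tom_matrix(t(xs[[i]]), beta[i])$tom, tf_list))
  out <- if (length(mats) == 1) mats[[1]] else borda_merge_scores(mats)
  attr(out, "method") <- "tom"
  out
}

# Borda-median merge of several TF-by-gene score matrices: rank pairs within
# each matrix (descending score, deterministic tie-break), take the median
# rank, return negated median ranks as scores
borda_merge_scores <- function(mats) {
  template <- mats[[1]]
  ranks <- vapply(mats, function(m) {
    v <- as.vector(m)
    r <- rep(NA_real_, length(v))
    ok <- !is.na(v)
    ord <- order(-v[ok], which(ok))
    tmp <- r[ok]
    tmp[ord] <- seq_along(ord)
    r[ok] <- tmp
    r
  }, numeric(length(template)))
  med <- apply(ranks, 1, stats::median)
  out <- matrix(-med, nrow(template), ncol(template),
                dimnames = dimnames(template))
  class(out) <- c("score_matrix", class(out))
  out
}

#' Tree-ensemble importance network scores
#'
#' For every target gene, a random-forest regression of the target's profile
#' on all TF profiles (the target itself excluded when it is a TF); the score
#' of pair (TF, target) is the TF's impurity importance. Deterministic under
#' the seed.
#'
#' @param x samples-by-genes matrix (>= 10 samples).
#' @param tf_list TF gene ids.
#' @param n_trees trees per forest (default 100).
#' @param seed RNG seed.
#' @return TF-by-gene \code{score_matrix}.
#' @export
score_tree_importance <- function(x, tf_list, n_trees = 100, seed = 1) {
  x <- as.matrix(x)
  tf_list <- intersect(tf_list, colnames(x))
  if (!length(tf_list)) stop("no TFs found among the genes")
  genes <- colnames(x)
  out <- matrix(NA_real_, length(tf_list), length(genes),
                dimnames = list(tf_list, genes))
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    preds <- setdiff(tf_list, g)
    if (!length(preds)) next
    df <- data.frame(y = x[, g], x[, preds, drop = FALSE],
                     check.names = FALSE)
    fit <- ranger::ranger(
      dependent.variable.name = "y", data = df, num.trees = n_trees,
      importance = "impurity", mtry = max(1, floor(sqrt(length(preds)))),
      seed = seed + gi, num.threads = 1, verbose = FALSE)
    imp <- ranger::importance(fit)
    out[names(imp), g] <- imp
  }
  class(out) <- c("score_matrix", class(out))
  attr(out, "method") <- "trees"
  out
}

#' Shrinkage partial-correlation network scores
#'
#' Schafer-Strimmer shrinkage of the correlation matrix toward the identity
#' with the analytic shrinkage intensity, inverted to partial correlations;
#' the score is |partial correlation|. Normal-approximation p-values
#' (Fisher z) with BH adjustment are attached as attributes \code{"pval"}
#' and \code{"qval"}.
#'
#' @param x samples-by-genes matrix.
#' @param tf_list TF gene ids.
#' @param shrink override the analytic shrinkage intensity (NULL = analytic).
#' @return TF-by-gene \code{score_matrix}.
#' @export
score_partial_correlation <- function(x, tf_list, shrink = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  z <- scale(x)
  z[!is.finite(z)] <- 0
  r <- crossprod(z) / (n - 1)
  diag(r) <- 1
  if (is.null(shrink)) {
    # analytic intensity: sum of estimated variances of r_ij over sum r_ij^2
    w2 <- crossprod(z^2)                      # sum_k z_ki^2 z_kj^2
    wbar <- r * (n - 1) / n
    var_r <- n / (n - 1)^3 * (w2 - n * wbar^2)
    off <- upper.tri(r)
    shrink <- sum(var_r[off]) / sum(r[off]^2)
    shrink <- min(1, max(0, shrink))
  }
  rs <- (1 - shrink) * r
  diag(rs) <- 1
  om <- solve(rs)
  d <- 1 / sqrt(diag(om))
  pc <- -om * outer(d, d)
  diag(pc) <- 1
  dimnames(pc) <- list(colnames(x), colnames(x))
  zstat <- atanh(pmin(pmax(pc, -1 + 1e-12), 1 - 1e-12)) *
    sqrt(max(n - 3, 1))
  pv <- 2 * stats::pnorm(-abs(zstat))
  out <- tf_rows(abs(pc), tf_list)
  attr(out, "method") <- "pcor"
  attr(out, "shrinkage") <- shrink
  attr(out, "pval") <- pv[rownames(out), , drop = FALSE]
  qv <- pv
  qv[] <- stats::p.adjust(pv, method = "BH")
  attr(out, "qval") <- qv[rownames(out), , drop = FALSE]
  out
}

#' K-means clustering with BIC model selection
#'
#' Genes are clustered over the sample dimensions for integer K in
#' \code{k_range}; K* minimizes
#' \code{BIC(K) = sum((x - centroid)/sigma_eps)^2 + log(N) * M * K}, where
#' \code{sigma_eps^2} is the mean intra-cluster variance evaluated at K = 3
#' (the residual term is squared; any BIC requires it).
#'
#' @param x samples-by-genes matrix; genes are the clustering units.
#' @param k_range integer vector \code{c(min, max)} of cluster counts
#'   (default c(3, 15); the full-scale analysis used up to 100).
#' @param nstart random restarts per K.
#' @param iter_max K-means iteration cap.
#' @param seed RNG seed.
#' @return a \code{module_clustering}: list with \code{K}, \code{assignments}
#'   (per gene), \code{centroids} (K x samples), \code{sigma_eps},
#'   \code{bic_curve}.
#' @export
kmeans_bic <- function(x, k_range = c(3, 15), nstart = 10, iter_max = 50,
                       seed = 1) {
  g <- t(as.matrix(x))                       # genes x samples
  n_genes <- nrow(g); m <- ncol(g)
  ks <- seq(max(3, k_range[1]), k_range[length(k_range)])
  if (min(ks) < 2 || max(ks) > n_genes - 1)
    stop("k_range outside [2, N-1]")
  set.seed(seed)
  km3 <- stats::kmeans(g, centers = 3, nstart = nstart,
                       iter.max = iter_max)
  sigma2 <- km3$tot.withinss / (n_genes * m)
  fits <- lapply(ks, function(k) {
    if (k == 3) return(km3)
    stats::kmeans(g, centers = k, nstart = nstart, iter.max = iter_max)
  })
  bic <- vapply(seq_along(ks), function(i)
    fits[[i]]$tot.withinss / sigma2 + log(n_genes) * m * ks[i],
    numeric(1))
  best <- which.min(bic)
  structure(list(K = ks[best],
                 assignments = stats::setNames(fits[[best]]$cluster,
                                               rownames(g)),
                 centroids = fits[[best]]$centers,
                 sigma_eps = sqrt(sigma2),
                 bic_curve = stats::setNames(bic, ks)),
            class = "module_clustering")
}

#' Module-based network scores
#'
#' Every gene inherits, for each TF, the absolute correlation between the TF
#' profile and the centroid of the gene's cluster — a module-level surrogate
#' for regulator-to-module scoring. With several datasets the per-dataset
#' pair rankings are merged by Borda median.
#'
#' @param x samples-by-genes matrix, or list of such matrices.
#' @param tf_list TF gene ids.
#' @param clustering optional precomputed \code{\link{kmeans_bic}} result
#'   (single-matrix case only).
#' @param ... passed to \code{\link{kmeans_bic}}.
#' @return TF-by-gene \code{score_matrix}.
#' @export
score_modules <- function(x, tf_list, clustering = NULL, ...) {
  xs <- if (is.list(x) && !is.data.frame(x)) x else list(x)
  mats <- lapply(seq_along(xs), function(i) {
    xi <- as.matrix(xs[[i]])
    cl <- if (length(xs) == 1 && !is.null(clustering)) clustering
          else kmeans_bic(xi, ...)
    tfs <- intersect(tf_list, colnames(xi))
    if (!length(tfs)) stop("no TFs found among the genes")
    cen <- cl$centroids                      # K x samples
    tf_cor <- abs(suppressWarnings(stats::cor(xi[, tfs, drop = FALSE],
                                              t(cen))))
    tf_cor[!is.finite(tf_cor)] <- 0          # TF x K
    sc <- tf_cor[, cl$assignments[colnames(xi)], drop = FALSE]
    colnames(sc) <- colnames(xi)
    tf_rows(sc, tfs)
  })
  out <- if (length(mats) == 1) mats[[1]] else borda_merge_scores(mats)
  attr(out, "method") <- "modules"
  out
}
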