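#' Confounder design: replicate groups whose internal variation is confounding
#'
#' For the development and tissue designs, all samples of the same phase are
#' treated as biological replicates, so within-phase variation (stages,
#' tissues) is penalized. For the time-course design, samples of the two
#' tissues at the same time point under the same treatment form a replicate
#' group, and the final converged time point is removed before grouping.
#'
#' @param metadata sample metadata data.frame; needs \code{phase}, and for
#'   time-course data \code{treatment} and \code{time} columns.
#' @param dataset_kind \code{"development"}, \code{"tissue"} or
#'   \code{"timecourse"}.
#' @param drop_final_time for time-course input, drop the last time point
#'   before grouping (default TRUE).
#' @return an object of class \code{confounder_design}: list with
#'   \code{groups} (factor over kept samples), \code{keep} (logical index
#'   into the original samples) and \code{dataset_kind}.
#' @export
build_confounder_design <- function(metadata,
                                    dataset_kind = c("development", "tissue",
                                                     "timecourse"),
                                    drop_final_time = TRUE) {
  dataset_kind <- tryCatch(match.arg(dataset_kind),
                           error = function(e) stop("unknown dataset_kind: ",
                                                    dataset_kind[1]))
  metadata <- as.data.frame(metadata)
  keep <- rep(TRUE, nrow(metadata))
  if (dataset_kind %in% c("development", "tissue")) {
    groups <- factor(map_phase_labels(metadata$phase))
  } else {
    if (is.null(metadata$time) || is.null(metadata$treatment))
      stop("time-course metadata needs 'time' and 'treatment' columns")
    if (drop_final_time) keep <- metadata$time < max(metadata$time)
    md <- metadata[keep, , drop = FALSE]
    groups <- factor(paste(md$treatment, md$time, sep = "_"))
  }
  structure(list(groups = groups, keep = keep, dataset_kind = dataset_kind),
            class = "confounder_design")
}

# Within-group centering operator applied to the rows of x: for each replicate
# group subtract the group mean profile. Singleton groups contribute zero.
within_group_center <- function(x, groups) {
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      mu <- colMeans(x[idx, , drop = FALSE])
      x[idx, ] <- sweep(x[idx, , drop = FALSE], 2, mu)
    } else {
      x[idx, ] <- 0
    }
  }
  x
}

#' Confounding-adjusted PCA
#'
#' Finds unit loading vectors v maximizing \code{v'X'Xv - lambda * v'X'CX v},
#' where C is the within-replicate-group centering operator: the penalty is
#' the summed squared within-group scatter of the sample scores, so at large
#' lambda the leading component ignores variation that replicates share
#' (stage, tissue, time point) and is free to capture the phase difference.
#' Solved as the leading eigenvectors of the symmetric matrix
#' \code{X'X - lambda * (CX)'(CX)}; when genes far outnumber samples the
#' eigenproblem is solved in sample space.
#'
#' @param x samples-by-genes matrix from \code{\link{log_quantile_center}}.
#' @param design a \code{confounder_design} over the rows of \code{x} (its
#'   \code{keep} index is applied to \code{x} first). NULL means no penalty.
#' @param lambda penalty weight, >= 0.
#' @param n_components number of components (default 2).
#' @param phase optional per-sample phase labels ("G"/"S", aligned with the
#'   rows of \code{x} before \code{keep}); used to fix the sign convention so
#'   that the mean PC1 score of gregarious samples is positive.
#' @return an \code{acpca_model}: list with \code{loadings} (genes x
#'   components, orthonormal), \code{scores}, \code{lambda}, \code{sign_map}
#'   (c(G = "+", S = "-") under the gregarious-positive convention),
#'   \code{penalty} (within-group score scatter of PC1),
#'   \code{variance_explained}, \code{gene_ids}.
#' @export
fit_acpca <- function(x, design = NULL, lambda = 0, n_components = 2,
                      phase = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  x <- as.matrix(x)
  if (!is.null(design)) {
    if (!is.null(phase)) phase <- phase[design$keep]
    x <- x[design$keep, , drop = FALSE]
  }
  # gene columns are re-centered so dropping samples (converged time point)
  # cannot leave an offset that leaks into the leading component
  x <- scale(x, center = TRUE, scale = FALSE)
  attr(x, "scaled:center") <- NULL
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("need at least 2 samples")
  n_components <- min(n_components, n - 1, p)
  cx <- if (is.null(design)) matrix(0, n, p)
        else within_group_center(x, design$groups)

  if (p <= n) {
    a <- crossprod(x) - lambda * crossprod(cx)
    es <- eigen(a, symmetric = TRUE)
    v <- es$vectors[, seq_len(n_components), drop = FALSE]
    evals <- es$values[seq_len(n_components)]
  } else {
    # sample-space solve: eigenvectors of the p x p matrix X'BX
    # (B = I - lambda*C) lie in the row space of X, so with X = U D V'
    # they are v = V a where a solves the small symmetric problem
    # (D U' B U D) a = mu a; the returned loadings stay exactly orthonormal
    sv <- svd(x)
    r <- sum(sv$d > sv$d[1] * 1e-12)
    u <- sv$u[, seq_len(r), drop = FALSE]
    d <- sv$d[seq_len(r)]
    bu <- u - lambda * (if (is.null(design)) 0 else
                        within_group_center(u, design$groups))
    m_small <- diag(d, r) %*% crossprod(u, bu) %*% diag(d, r)
    m_small <- (m_small + t(m_small)) / 2
    es <- eigen(m_small, symmetric = TRUE)
    n_components <- min(n_components, r)
    v <- sv$v[, seq_len(r), drop = FALSE] %*%
      es$vectors[, seq_len(n_components), drop = FALSE]
    evals <- es$values[seq_len(n_components)]
  }
  scores <- x %*% v
  colnames(v) <- colnames(scores) <- paste0("PC", seq_len(n_components))
  if (!is.null(colnames(x))) rownames(v) <- colnames(x)

  sign_map <- c(G = "+", S = "-")
  if (!is.null(phase)) {
    gm <- mean(scores[phase == "G", 1])
    sm <- mean(scores[phase == "S", 1])
    if (is.finite(gm) && is.finite(sm) && gm < sm) {
      v <- -v
      scores <- -scores
    }
  }
  pen <- if (is.null(design)) rep(0, n_components)
         else colSums((cx %*% v)^2)
  tot <- sum(x^2)
  structure(list(loadings = v, scores = scores, lambda = lambda,
                 sign_map = sign_map, penalty = pen,
                 eigenvalues = evals,
                 variance_explained = colSums(scores^2) / tot,
                 gene_ids = colnames(x)),
            class = "acpca_model")
}

#' @export
print.acpca_model <- function(x, ...) {
  cat(sprintf("acpca_model: %d genes, %d components, lambda = %g\n",
              nrow(x$loadings), ncol(x$loadings), x$lambda))
  cat(sprintf("  variance explained: %s\n",
              paste(sprintf("%.3g", x$variance_explained), collapse = ", ")))
  invisible(x)
}

#' Tune the AC-PCA penalty weight
#'
#' Fits the leading component along an ascending grid of lambda values and
#' returns the smallest one whose within-group score scatter has dropped to
#' at most \code{tol} of its unpenalized value. If no grid value qualifies
#' the grid maximum is returned with \code{converged = FALSE}.
#'
#' @inheritParams fit_acpca
#' @param grid ascending numeric vector of candidate lambda values.
#' @param tol penalty-ratio tolerance (default 0.05).
#' @return list with \code{lambda}, \code{converged}, and the per-grid-point
#'   \code{ratio} of penalty(v(lambda)) to penalty(v(0)).
#' @export
tune_lambda <- function(x, design, grid = lambda_grid(), tol = 0.05) {
  if (!length(grid)) stop("empty lambda grid")
  if (is.unsorted(grid)) stop("lambda grid must be ascending")
  m0 <- fit_acpca(x, design, lambda = 0, n_components = 1)
  base <- m0$penalty[1]
  # penalty already negligible next to the component variance: nothing to tune
  if (base <= tol * sum(m0$scores[, 1]^2))
    return(list(lambda = grid[1], converged = TRUE,
                ratio = rep(0, length(grid))))
  ratio <- vapply(grid, function(l)
    fit_acpca(x, design, lambda = l, n_components = 1)$penalty[1] / base,
    numeric(1))
  ok <- which(ratio <= tol)
  if (length(ok))
    list(lambda = grid[ok[1]], converged = TRUE, ratio = ratio)
  else {
    warning("no grid lambda reached the penalty tolerance; using grid max")
    list(lambda = grid[length(grid)], converged = FALSE, ratio = ratio)
  }
}

#' Default lambda grid: 20 log-spaced points in [0.1, 100]
#' @param n number of grid points.
#' @param from,to grid range.
#' @return numeric vector.
#' @export
lambda_grid <- function(n = 20, from = 0.1, to = 100) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Predict phase for new samples by projection sign
#'
#' Projects preprocessed profiles onto the model's PC1 loadings; a positive
#' score is called the phase the sign convention maps to "+" (gregarious), a
#' negative score the other phase, and an exactly zero score is left
#' \code{"unassigned"}.
#'
#' @param model an \code{acpca_model}.
#' @param x_new samples-by-genes matrix preprocessed like the training data
#'   (log2(x+1), quantile normalization, gene centering). Columns are matched
#'   to the model's gene set by name when both are named.
#' @param true_phase optional "G"/"S" labels to score accuracy against.
#' @return data.frame with \code{score}, \code{call}, and (when labels are
#'   given) \code{correct}; accuracy attached as attribute \code{"accuracy"}.
#' @export
predict_phase <- function(model, x_new, true_phase = NULL) {
  x_new <- as.matrix(x_new)
  v <- model$loadings[, 1]
  if (!is.null(colnames(x_new)) && !is.null(model$gene_ids)) {
    shared <- intersect(model$gene_ids, colnames(x_new))
    if (!length(shared)) stop("no overlap between model and new gene sets")
    x_new <- x_new[, shared, drop = FALSE]
    v <- v[match(shared, model$gene_ids)]
  } else if (ncol(x_new) != length(v)) {
    stop("no overlap between model and new gene sets")
  }
  score <- as.numeric(x_new %*% v)
  pos <- names(model$sign_map)[model$sign_map == "+"]
  neg <- names(model$sign_map)[model$sign_map == "-"]
  call <- ifelse(score > 0, pos, ifelse(score < 0, neg, "unassigned"))
  out <- data.frame(score = score, call = call,
                    stringsAsFactors = FALSE)
  if (!is.null(rownames(x_new))) rownames(out) <- rownames(x_new)
  if (!is.null(true_phase)) {
    out$correct <- out$call == map_phase_labels(true_phase)
    attr(out, "accuracy") <- mean(out$correct)
  }
  out
}
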