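#' Rank genes by their PC1 loading in one dataset
#'
#' Under the gregarious-positive sign convention, ranking by decreasing
#' loading puts gregarious-biased genes at the top; \code{direction = "S"}
#' ranks by increasing loading instead.
#'
#' @param model an \code{acpca_model}.
#' @param direction which phase is ranked at the top ("G" or "S").
#' @return a \code{ranked_gene_list}: data.frame with \code{gene_id},
#'   \code{score} (PC1 loading) and \code{rank}; direction kept as attribute.
#' @export
rank_genes <- function(model, direction = c("G", "S")) {
  direction <- match.arg(direction)
  sc <- model$loadings[, 1]
  ord <- if (direction == "G") order(-sc, model$gene_ids)
         else order(sc, model$gene_ids)
  out <- data.frame(gene_id = model$gene_ids[ord], score = sc[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "direction") <- direction
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Borda aggregation with the median method
#'
#' Each gene's Borda score is the median of its ranks across the input lists;
#' the output is ordered by ascending score, with ties broken by mean rank and
#' then lexicographically by gene id. Lists are first restricted to their
#' common gene universe.
#'
#' @param lists a list of two or more ranked gene lists (data.frames with a
#'   \code{gene_id} column ordered best-first, or plain character vectors).
#' @return a \code{ranked_gene_list} with columns \code{gene_id},
#'   \code{score} (median rank), \code{mean_rank}, \code{rank}.
#' @export
borda_median <- function(lists) {
  if (length(lists) < 2) stop("borda_median needs at least 2 lists")
  ids <- lapply(lists, function(l) if (is.character(l)) l else l$gene_id)
  universe <- Reduce(intersect, ids)
  if (!length(universe)) stop("input lists have disjoint gene universes")
  ranks <- vapply(ids, function(v) {
    v <- v[v %in% universe]
    match(universe, v)
  }, integer(length(universe)))
  med <- apply(ranks, 1, stats::median)
  mn <- rowMeans(ranks)
  ord <- order(med, mn, universe)
  out <- data.frame(gene_id = universe[ord], score = med[ord],
                    mean_rank = mn[ord], rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Merge the two directional Borda lists by alternation
#'
#' Walks the gregarious-top and solitary-top Borda lists from the top,
#' alternately emitting the next not-yet-emitted gene from each, starting with
#' the gregarious list. Each emitted gene is tagged with the phase direction
#' of the pass that contributed it.
#'
#' @param borda_g Borda result with gregarious-biased genes ranked at the top.
#' @param borda_s Borda result with solitary-biased genes ranked at the top.
#' @return a \code{ranked_gene_list} with columns \code{gene_id},
#'   \code{direction} ("G"/"S"), \code{rank}.
#' @export
directional_merge <- function(borda_g, borda_s) {
  g <- if (is.character(borda_g)) borda_g else borda_g$gene_id
  s <- if (is.character(borda_s)) borda_s else borda_s$gene_id
  if (!setequal(g, s)) stop("the two Borda passes cover different universes")
  n <- length(g)
  merged <- character(n)
  dir <- character(n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  ig <- 1L; is_ <- 1L
  for (k in seq_len(n)) {
    from_g <- k %% 2L == 1L
    if (from_g) {
      while (ig <= n && !is.null(seen[[g[ig]]])) ig <- ig + 1L
      merged[k] <- g[ig]; dir[k] <- "G"
    } else {
      while (is_ <= n && !is.null(seen[[s[is_]]])) is_ <- is_ + 1L
      merged[k] <- s[is_]; dir[k] <- "S"
    }
    seen[[merged[k]]] <- TRUE
  }
  out <- data.frame(gene_id = merged, direction = dir, rank = seq_len(n),
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_gene_list", "data.frame")
  out
}

#' Directional Borda list from several fitted AC-PCA models
#'
#' Runs Borda median aggregation twice over the per-dataset PC1 rankings —
#' once with gregarious-biased genes on top, once with solitary-biased genes
#' on top — and merges the two lists by alternation.
#'
#' @param models list of \code{acpca_model} objects (one per dataset).
#' @return a \code{ranked_gene_list} with per-gene \code{direction}.
#' @export
directional_borda <- function(models) {
  g <- borda_median(lapply(models, rank_genes, direction = "G"))
  s <- borda_median(lapply(models, rank_genes, direction = "S"))
  directional_merge(g, s)
}

#' Select the core gene set from a ranked list
#'
#' @param ranked a \code{ranked_gene_list} (or character vector, best first).
#' @param fraction top fraction to keep, in (0,1); default 0.10.
#' @param universe_size number of genes the fraction refers to; defaults to
#'   the list length.
#' @return character vector of core gene ids.
#' @export
select_core <- function(ranked, fraction = 0.10, universe_size = NULL) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0,1)")
  ids <- if (is.character(ranked)) ranked else ranked$gene_id
  if (is.null(universe_size)) universe_size <- length(ids)
  ids[seq_len(floor(fraction * universe_size))]
}

#' Binned cross-validation of phase prediction
#'
#' Splits the top \code{n_top} genes of a ranked list into consecutive bins of
#' \code{bin_size} genes and, for each bin, refits AC-PCA restricted to the
#' bin's genes and measures phase-prediction accuracy, either by
#' leave-one-sample-out within each dataset (\code{mode = "loo"}) or by
#' training on one dataset and predicting the others (\code{mode = "cdv"}).
#'
#' @param datasets named list of \code{expression_dataset} objects (RPKM).
#' @param ranked a \code{ranked_gene_list} covering at least \code{n_top} genes.
#' @param bin_size genes per bin (e.g. 1000, 500, 100).
#' @param n_top number of top genes considered (default
#'   \code{floor(length/bin_size) * bin_size}).
#' @param mode \code{"loo"} or \code{"cdv"}.
#' @param kinds named character vector giving each dataset's design kind for
#'   \code{\link{build_confounder_design}}; defaults to names in
#'   \code{c("development","tissue","timecourse")} matched by dataset name.
#' @param lambda penalty weight used for every refit (default 10).
#' @return data.frame with \code{bin}, \code{first_rank}, \code{last_rank},
#'   \code{accuracy} (pooled over datasets and samples), and one accuracy
#'   column per dataset.
#' @export
binned_validation <- function(datasets, ranked, bin_size, n_top = NULL,
                              mode = c("loo", "cdv"), kinds = NULL,
                              lambda = 10) {
  mode <- match.arg(mode)
  ids <- if (is.character(ranked)) ranked else ranked$gene_id
  if (is.null(n_top)) n_top <- floor(length(ids) / bin_size) * bin_size
  if (n_top > length(ids)) stop("ranked list shorter than n_top")
  if (bin_size < 2) stop("bins need at least 2 genes")
  n_bins <- n_top %/% bin_size
  if (is.null(kinds)) {
    kinds <- names(datasets)
    names(kinds) <- names(datasets)
  }
  prep <- lapply(names(datasets), function(nm) {
    ds <- datasets[[nm]]
    list(x = log_quantile_center(ds),
         design = build_confounder_design(ds$samples, kinds[[nm]]),
         phase = map_phase_labels(ds$samples$phase))
  })
  names(prep) <- names(datasets)

  res <- lapply(seq_len(n_bins), function(b) {
    genes <- ids[((b - 1) * bin_size + 1):(b * bin_size)]
    per_ds <- vapply(names(prep), function(nm) {
      pr <- prep[[nm]]
      keep_genes <- intersect(genes, colnames(pr$x))
      if (length(keep_genes) < 2) stop("a bin has fewer than 2 genes")
      xb <- pr$x[, keep_genes, drop = FALSE]
      if (mode == "loo") {
        acc_loo(xb, pr$design, pr$phase, lambda)
      } else {
        acc_cdv(nm, prep, genes, lambda)
      }
    }, numeric(2))
    cbind(data.frame(bin = b, first_rank = (b - 1) * bin_size + 1,
                     last_rank = b * bin_size,
                     accuracy = sum(per_ds[1, ] * per_ds[2, ]) /
                       sum(per_ds[2, ])),
          as.data.frame(as.list(per_ds[1, ])))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# leave-one-sample-out accuracy on one preprocessed dataset; returns
# c(accuracy, n_predictions)
acc_loo <- function(x, design, phase, lambda) {
  keep <- design$keep
  xk <- x[keep, , drop = FALSE]
  ph <- phase[keep]
  grp <- design$groups
  correct <- vapply(seq_len(nrow(xk)), function(i) {
    di <- structure(list(groups = droplevels(grp[-i]),
                         keep = rep(TRUE, nrow(xk) - 1)),
                    class = "confounder_design")
    m <- fit_acpca(xk[-i, , drop = FALSE], di, lambda = lambda,
                   n_components = 1, phase = ph[-i])
    pred <- predict_phase(m, xk[i, , drop = FALSE], ph[i])
    pred$correct[1]
  }, logical(1))
  c(mean(correct), length(correct))
}

# train on dataset `nm`, predict the samples of all others; returns
# c(accuracy, n_predictions)
acc_cdv <- function(nm, prep, genes, lambda) {
  pr <- prep[[nm]]
  keep_genes <- intersect(genes, colnames(pr$x))
  m <- fit_acpca(pr$x[, keep_genes, drop = FALSE], pr$design,
                 lambda = lambda, n_components = 1, phase = pr$phase)
  hits <- 0; tot <- 0
  for (other in setdiff(names(prep), nm)) {
    po <- prep[[other]]
    pred <- predict_phase(m, po$x, po$phase)
    hits <- hits + sum(pred$correct)
    tot <- tot + nrow(pred)
  }
  c(hits / tot, tot)
}
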