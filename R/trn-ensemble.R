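#' Ensemble TF-target network by Borda aggregation of method rankings
#'
#' Each scorer's TF-target pairs are ranked by decreasing score and truncated
#' to \code{top_k_per_method}; pairs missing from a method's truncated list
#' get rank \code{top_k_per_method + 1}. Pairs are aggregated by Borda median
#' (ties by mean rank, then pair id), truncated to \code{top_k_final}, and
#' promiscuous targets — those regulated by at least
#' \code{promiscuity_fraction} of all TFs present in the network — are
#' removed, with the list refilled once from the aggregate ranking.
#'
#' @param score_matrices list of two or more TF-by-gene \code{score_matrix}
#'   objects over the same TF/gene universe (self-edges NA).
#' @param top_k_per_method truncation per method (default 100000).
#' @param top_k_final edges kept in the network (default 100000).
#' @param promiscuity_fraction in-degree fraction, of the network's TFs, at
#'   which a target is considered promiscuous (default 1 = regulated by
#'   every TF).
#' @return an \code{ensemble_network}: data.frame with \code{tf},
#'   \code{target}, \code{aggregate_rank}, \code{median_rank} and one rank
#'   column per method; node metadata in attribute \code{"nodes"}, removed
#'   promiscuous targets in attribute \code{"filtered_targets"}.
#' @export
ensemble_network <- function(score_matrices, top_k_per_method = 100000,
                             top_k_final = 100000,
                             promiscuity_fraction = 1.0) {
  if (length(score_matrices) < 2)
    stop("ensemble needs at least 2 score matrices")
  dn <- dimnames(score_matrices[[1]])
  for (m in score_matrices)
    if (!identical(dimnames(m), dn))
      stop("score matrices have inconsistent TF/gene universes")
  tfs <- dn[[1]]; genes <- dn[[2]]
  pair_tf <- rep(tfs, times = length(genes))        # column-major layout
  pair_tg <- rep(genes, each = length(tfs))
  keep <- pair_tf != pair_tg
  pair_tf <- pair_tf[keep]; pair_tg <- pair_tg[keep]

  ranks <- vapply(score_matrices, function(m) {
    v <- as.vector(unclass(m))[keep]
    v[is.na(v)] <- -Inf
    r <- numeric(length(v))
    ord <- order(-v, pair_tf, pair_tg)
    r[ord] <- seq_along(ord)
    r[r > top_k_per_method] <- top_k_per_method + 1
    r
  }, numeric(sum(keep)))
  mnames <- vapply(seq_along(score_matrices), function(i) {
    nm <- attr(score_matrices[[i]], "method")
    if (is.null(nm)) paste0("method", i) else nm
  }, character(1))
  colnames(ranks) <- make.unique(mnames)

  med <- apply(ranks, 1, stats::median)
  mn <- rowMeans(ranks)
  ord <- order(med, mn, pair_tf, pair_tg)

  take <- function(ord_idx, exclude_targets = character(0)) {
    if (length(exclude_targets))
      ord_idx <- ord_idx[!(pair_tg[ord_idx] %in% exclude_targets)]
    utils::head(ord_idx, top_k_final)
  }
  sel <- take(ord)
  n_tf_net <- length(unique(pair_tf[sel]))
  indeg <- table(pair_tg[sel])
  bad <- names(indeg)[indeg >= promiscuity_fraction * n_tf_net]
  if (length(bad)) sel <- take(ord, exclude_targets = bad)

  edges <- data.frame(tf = pair_tf[sel], target = pair_tg[sel],
                      aggregate_rank = seq_along(sel),
                      median_rank = med[sel],
                      ranks[sel, , drop = FALSE],
                      stringsAsFactors = FALSE)
  nodes <- data.frame(node = unique(c(edges$tf, edges$target)),
                      stringsAsFactors = FALSE)
  nodes$is_tf <- nodes$node %in% tfs
  attr(edges, "nodes") <- nodes
  attr(edges, "filtered_targets") <- bad
  attr(edges, "methods") <- colnames(ranks)
  class(edges) <- c("ensemble_network", "data.frame")
  edges
}

#' Per-TF ensemble network
#'
#' Aggregates each TF's own pair ranking across methods independently (Borda
#' median over the ranks of that TF's candidate targets) and keeps the TF's
#' top \code{top_m} targets, so low-ranking TFs still get a comparable
#' target set.
#'
#' @inheritParams ensemble_network
#' @param top_m targets kept per TF (default 1700).
#' @return an \code{ensemble_network} data.frame (tf, target, tf_rank,
#'   median_rank).
#' @export
per_tf_network <- function(score_matrices, top_m = 1700) {
  if (!is.list(score_matrices)) score_matrices <- list(score_matrices)
  dn <- dimnames(score_matrices[[1]])
  for (m in score_matrices)
    if (!identical(dimnames(m), dn))
      stop("score matrices have inconsistent TF/gene universes")
  tfs <- dn[[1]]; genes <- dn[[2]]
  out <- lapply(tfs, function(tf) {
    ranks <- vapply(score_matrices, function(m) {
      v <- unclass(m)[tf, ]
      r <- rep(NA_real_, length(v))
      ok <- !is.na(v)
      ord <- order(-v[ok], genes[ok])
      tmp <- r[ok]; tmp[ord] <- seq_along(ord); r[ok] <- tmp
      r
    }, numeric(length(genes)))
    med <- apply(ranks, 1, stats::median)
    ok <- !is.na(med)
    ord <- order(med[ok], genes[ok])
    sel <- which(ok)[ord][seq_len(min(top_m, sum(ok)))]
    data.frame(tf = tf, target = genes[sel], tf_rank = seq_along(sel),
               median_rank = med[sel], stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, out)
  rownames(edges) <- NULL
  class(edges) <- c("ensemble_network", "data.frame")
  edges
}

#' Area under the ROC curve for edge recovery
#'
#' Rank-statistic AUROC of a score vector against binary truth labels.
#'
#' @param scores numeric scores (higher = more likely positive); NAs dropped
#'   together with their labels.
#' @param labels logical/0-1 truth.
#' @return AUC in [0,1].
#' @export
auroc <- function(scores, labels) {
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write an ensemble network edge list as TSV
#'
#' @param network an \code{ensemble_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(as.data.frame(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
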