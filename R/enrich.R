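#' Hypergeometric upper-tail enrichment p-value
#'
#' P(X >= k) for X hypergeometric: k of n drawn genes fall in a category of
#' size K inside a universe of N genes. Exact tail mass via the stable
#' distribution functions.
#'
#' @param k overlap count.
#' @param n draws (e.g. a TF's target-set size).
#' @param K category size (e.g. the core-set size).
#' @param N universe size.
#' @return upper-tail p-value (vectorized).
#' @export
hypergeom_p <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0) || any(k > n) || any(n > N) ||
      any(K > N) || any(k > K))
    stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' PhaseCoreTF detection: TFs whose targets are enriched in the core set
#'
#' For every TF in the network, tests whether its target set is
#' over-represented among the core genes with a hypergeometric upper tail
#' (k = core targets, n = targets, K = core genes in the universe, N =
#' network gene universe). TFs with fewer than \code{min_enriched} core
#' targets are dropped before BH adjustment; a PhaseCoreTF is a kept TF with
#' adjusted p below \code{alpha}.
#'
#' @param network an \code{ensemble_network} (or any data.frame with
#'   \code{tf}, \code{target} columns).
#' @param core_genes character vector of core gene ids.
#' @param min_enriched minimum core targets to keep a TF (default 3).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param universe gene universe; defaults to the network's nodes.
#' @return an \code{enrichment_result} data.frame: \code{tf}, \code{k},
#'   \code{n}, \code{K}, \code{N}, \code{pval}, \code{kept}, \code{reason},
#'   \code{qval}, \code{is_phasecore_tf}.
#' @export
phasecore_tf <- function(network, core_genes, min_enriched = 3,
                         alpha = 0.05, universe = NULL) {
  if (!length(core_genes)) stop("empty core gene set")
  edges <- as.data.frame(network)
  if (is.null(universe)) universe <- unique(c(edges$tf, edges$target))
  core <- intersect(core_genes, universe)
  N <- length(universe); K <- length(core)
  tgt <- split(edges$target, edges$tf)
  out <- data.frame(tf = names(tgt),
                    k = vapply(tgt, function(t) length(intersect(t, core)),
                               integer(1)),
                    n = lengths(tgt), K = K, N = N,
                    stringsAsFactors = FALSE)
  out$pval <- hypergeom_p(out$k, out$n, out$K, out$N)
  out$kept <- out$k >= min_enriched
  out$reason <- ifelse(out$kept, "", sprintf("fewer than %d core targets",
                                             min_enriched))
  out$qval <- NA_real_
  out$qval[out$kept] <- stats::p.adjust(out$pval[out$kept], method = "BH")
  out$is_phasecore_tf <- !is.na(out$qval) & out$qval < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Functional-class enrichment of a gene list
#'
#' Per gene set, a 2x2 contingency test of list membership against set
#' membership over the annotation universe: chi-squared without continuity
#' correction, switching to the two-sided Fisher exact test whenever any
#' expected cell is below 5. Sets overlapping the list in fewer than
#' \code{min_overlap} genes are dropped before BH adjustment.
#'
#' @param gene_list character vector of genes (subset of the universe).
#' @param collection named list of gene sets, or a \code{gene_set_collection}
#'   from \code{\link{read_gmt}}.
#' @param universe background gene universe; defaults to the union of the
#'   collection's sets and the list.
#' @param min_overlap minimum overlap to keep a set (default 3).
#' @param alpha BH significance threshold recorded in \code{significant}.
#' @return an \code{enrichment_result} data.frame: \code{set}, \code{k},
#'   \code{n}, \code{K}, \code{N}, \code{method} ("chisq"/"fisher"),
#'   \code{pval}, \code{kept}, \code{reason}, \code{qval},
#'   \code{significant}.
#' @export
functional_enrichment <- function(gene_list, collection, universe = NULL,
                                  min_overlap = 3, alpha = 0.05) {
  if (!length(gene_list)) stop("empty gene list")
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  if (is.null(universe)) {
    universe <- if (inherits(collection, "gene_set_collection") &&
                    !is.null(collection$universe)) collection$universe
                else unique(c(unlist(sets), gene_list))
  }
  gene_list <- intersect(gene_list, universe)
  N <- length(universe); nl <- length(gene_list)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(gene_list, set))
    tab <- matrix(c(k, nl - k, K - k, N - nl - K + k), 2, 2)
    expected <- outer(rowSums(tab), colSums(tab)) / N
    if (any(expected < 5)) {
      p <- stats::fisher.test(tab)$p.value
      method <- "fisher"
    } else {
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      method <- "chisq"
    }
    data.frame(set = nm, k = k, n = nl, K = K, N = N, method = method,
               pval = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$kept <- out$k >= min_overlap
  out$reason <- ifelse(out$kept, "",
                       sprintf("overlap below %d", min_overlap))
  out$qval <- NA_real_
  out$qval[out$kept] <- stats::p.adjust(out$pval[out$kept], method = "BH")
  out$significant <- !is.na(out$qval) & out$qval < alpha
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' \code{stats::p.adjust}).
#'
#' @param pvals numeric p-values.
#' @return adjusted q-values, same length.
#' @export
bh_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Permutation test for multi-set intersections
#'
#' For every combination of two or more of the supplied sets, compares the
#' observed intersection size with intersections of uniformly drawn random
#' sets of the same sizes from the universe; p is the add-one-smoothed
#' fraction of permutations reaching at least the observed overlap. For
#' pairwise combinations the exact hypergeometric upper tail is also
#' reported.
#'
#' @param sets named list of >= 2 character vectors (each within the
#'   universe size).
#' @param universe_size size of the background universe.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return data.frame with \code{pattern}, \code{degree}, \code{observed},
#'   \code{expected} (mean permuted overlap), \code{pval}, \code{exact_p}
#'   (pairwise only).
#' @export
multiset_intersection_p <- function(sets, universe_size, n_perm = 10000,
                                    seed = 1) {
  if (length(sets) < 2) stop("need at least 2 sets")
  sizes <- lengths(sets)
  if (any(sizes > universe_size)) stop("a set is larger than the universe")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  set.seed(seed)
  m <- length(sets)
  combos <- unlist(lapply(2:m, function(d)
    utils::combn(m, d, simplify = FALSE)), recursive = FALSE)
  observed <- vapply(combos, function(cb)
    length(Reduce(intersect, sets[cb])), integer(1))
  hits <- numeric(length(combos))
  tot <- numeric(length(combos))
  for (r in seq_len(n_perm)) {
    rnd <- lapply(sizes, function(s) sample.int(universe_size, s))
    ov <- vapply(seq_along(combos), function(ci) {
      cb <- combos[[ci]]
      cnt <- tabulate(unlist(rnd[cb]), nbins = universe_size)
      sum(cnt == length(cb))
    }, numeric(1))
    hits <- hits + (ov >= observed)
    tot <- tot + ov
  }
  out <- data.frame(
    pattern = vapply(combos, function(cb)
      paste(names(sets)[cb], collapse = "&"), character(1)),
    degree = lengths(combos),
    observed = observed,
    expected = tot / n_perm,
    pval = (hits + 1) / (n_perm + 1),
    exact_p = NA_real_, stringsAsFactors = FALSE)
  for (ci in seq_along(combos)) {
    cb <- combos[[ci]]
    if (length(cb) == 2)
      out$exact_p[ci] <- hypergeom_p(observed[ci], sizes[cb[1]],
                                     sizes[cb[2]], universe_size)
  }
  out
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @param universe optional explicit background universe; defaults to the
#'   union of all sets.
#' @return a \code{gene_set_collection}: list with \code{sets} (named list)
#'   and \code{universe}.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (is.null(universe)) universe <- unique(unlist(sets))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection a \code{gene_set_collection} or named list of sets.
#' @export
write_gmt <- function(collection, path) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
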