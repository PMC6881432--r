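#' RPKM from raw counts
#'
#' Reads per kilobase of transcript per million mapped reads:
#' \code{count / (length/1000) / (library_size/1e6)}.
#'
#' @param counts genes-by-samples non-negative integer matrix, or an
#'   \code{expression_dataset} of kind \code{"counts"}.
#' @param gene_lengths gene lengths in nucleotides (one per gene). Taken from
#'   the dataset when \code{counts} is an \code{expression_dataset}.
#' @param library_sizes per-sample totals; defaults to column sums.
#' @return an \code{expression_dataset} of kind \code{"rpkm"} (when given a
#'   dataset) or the RPKM matrix (when given a bare matrix).
#' @export
rpkm <- function(counts, gene_lengths = NULL, library_sizes = NULL) {
  is_ds <- inherits(counts, "expression_dataset")
  m <- if (is_ds) counts$values else as.matrix(counts)
  if (is_ds && is.null(gene_lengths)) gene_lengths <- counts$gene_lengths
  if (is.null(gene_lengths)) stop("gene_lengths required for RPKM")
  if (is.null(library_sizes)) library_sizes <- colSums(m)
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  out <- m / (gene_lengths / 1000) / rep(library_sizes / 1e6,
                                         each = nrow(m))
  if (!is_ds) return(out)
  expression_dataset(out, counts$samples, kind = "rpkm",
                     gene_ids = counts$gene_ids,
                     gene_lengths = gene_lengths)
}

#' TMM per-sample scaling factors
#'
#' Trimmed mean of M-values normalization factors: for each sample, the
#' weighted trimmed mean of per-gene log2 expression ratios (M-values) against
#' a reference sample, after trimming the most extreme 30\% of M-values and
#' 5\% of A-values; factors are renormalized to geometric mean 1. The
#' reference sample is the one whose upper quartile of scaled counts is
#' closest to the mean upper quartile. Computation is delegated to edgeR.
#'
#' @param counts genes-by-samples count matrix or an \code{expression_dataset}.
#' @param ref_column optional index of the reference sample; default lets the
#'   upper-quartile rule choose.
#' @param trim_m fraction of M-values trimmed from each tail (default 0.30).
#' @param trim_a fraction of A-values trimmed from each tail (default 0.05).
#' @return named numeric vector of per-sample factors (geometric mean 1).
#'   Effective library sizes are \code{colSums(counts) * factors}.
#' @export
tmm_factors <- function(counts, ref_column = NULL, trim_m = 0.30,
                        trim_a = 0.05) {
  m <- if (inherits(counts, "expression_dataset")) counts$values
       else as.matrix(counts)
  if (any(m < 0)) stop("counts must be non-negative")
  tot <- colSums(m)
  if (any(tot == 0)) {
    bad <- colnames(m)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop("sample(s) with all-zero counts: ", paste(bad, collapse = ", "))
  }
  f <- edgeR::calcNormFactors(m, method = "TMM",
                              refColumn = ref_column,
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(as.numeric(f), colnames(m))
}

#' Quantile normalization reference-based transform for AC-PCA and TRN input
#'
#' Applies the preprocessing the ranking and network stages assume:
#' \code{log2(x + 1)} on RPKM values, quantile normalization across samples
#' (each sample's sorted values are replaced by the mean of sorted columns;
#' ties receive the mean of the reference values at their tied ranks), then
#' mean-centering of every gene. The result is returned with rows as samples
#' and columns as genes, the orientation the AC-PCA fit expects.
#'
#' @param dataset an \code{expression_dataset} of kind \code{"rpkm"} (a bare
#'   genes-by-samples matrix is also accepted and treated as RPKM).
#' @param log2_transform apply \code{log2(x+1)} first (default TRUE).
#' @return samples-by-genes numeric matrix, quantile-normalized and gene-centered.
#' @export
log_quantile_center <- function(dataset, log2_transform = TRUE) {
  m <- if (inherits(dataset, "expression_dataset")) {
    if (dataset$kind != "rpkm")
      stop("log_quantile_center expects an RPKM-flagged dataset")
    dataset$values
  } else as.matrix(dataset)
  if (ncol(m) < 2) stop("quantile normalization needs at least 2 samples")
  if (log2_transform) m <- log2(m + 1)
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  x <- t(qn)                       # samples x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  attr(x, "scaled:center") <- NULL
  x
}
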