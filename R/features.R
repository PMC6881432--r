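#' Tissue/sample specificity index tau
#'
#' \deqn{\tau_i = \frac{\sum_{j=1}^n \left(1 - \log_2(S_{ij}+1)/\log_2(S_{i,max}+1)\right)}{n-1}}
#' 0 for uniform expression, 1 for expression confined to a single sample.
#'
#' @param x numeric vector of RPKM values over n >= 2 samples, or a
#'   genes-by-samples matrix (tau computed per row).
#' @return numeric tau in [0,1]; NA for an all-zero row.
#' @export
tau <- function(x) {
  if (is.matrix(x)) return(apply(x, 1, tau))
  if (length(x) < 2) stop("tau needs at least 2 samples")
  if (any(x < 0)) stop("RPKM values must be non-negative")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - log2(x + 1) / log2(mx + 1)) / (length(x) - 1)
}

#' CpG observed/expected ratio
#'
#' \code{\%CG / (\%C x \%G)} with \code{\%CG = #CG / (L - 1)}; base fractions
#' use only A/C/G/T characters and CG dinucleotides spanning a non-ACGT
#' character are not counted. Case-insensitive.
#'
#' @param sequence a single nucleotide string, a character vector of them, or
#'   a \code{Biostrings::DNAStringSet}.
#' @return numeric ratio(s); NA when the sequence has no C or no G.
#' @export
cpg_oe <- function(sequence) {
  if (inherits(sequence, "XStringSet")) sequence <- as.character(sequence)
  if (length(sequence) > 1) return(vapply(sequence, cpg_oe, numeric(1)))
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  if (L < 2) stop("CpG o/e undefined for sequences shorter than 2")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  acgt <- chars %in% c("A", "C", "G", "T")
  n_c <- sum(chars == "C")
  n_g <- sum(chars == "G")
  if (n_c == 0 || n_g == 0) return(NA_real_)
  valid_total <- sum(acgt)
  cg <- sum(chars[-L] == "C" & chars[-1] == "G")
  pcg <- cg / (L - 1)
  (pcg) / ((n_c / valid_total) * (n_g / valid_total))
}

#' Gene-body methylation level
#'
#' Mean per-CG-site methylation level for every gene with at least
#' \code{min_sites} CG sites; genes below the threshold are dropped.
#'
#' @param table data.frame with columns \code{gene_id} and \code{beta}
#'   (per-site methylation level in [0,1]); or a named list of per-gene
#'   numeric vectors.
#' @param min_sites minimum CG sites required (default 19, i.e. genes with
#'   fewer than 19 sites are filtered out).
#' @return named numeric vector of per-gene mean methylation.
#' @export
methylation_gene_level <- function(table, min_sites = 19) {
  if (is.data.frame(table)) {
    sites <- split(table$beta, table$gene_id)
  } else sites <- table
  if (!length(sites)) return(stats::setNames(numeric(0), character(0)))
  bad <- vapply(sites, function(b) any(b < 0 | b > 1), logical(1))
  if (any(bad)) stop("methylation levels must be in [0,1]")
  keep <- vapply(sites, length, integer(1)) >= min_sites
  vapply(sites[keep], mean, numeric(1))
}

#' Signed soft-threshold adjacency and topological overlap
#'
#' Adjacency \code{a_ij = ((1 + cor(i,j))/2)^beta};
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 - a_ij)}
#' with connectivities \code{k} the adjacency row sums (diagonal excluded).
#'
#' @param expr genes-by-samples numeric matrix (>= 3 samples).
#' @param beta soft-threshold power, >= 1.
#' @return list with \code{adjacency}, \code{tom} (both genes x genes, unit
#'   diagonal) and \code{connectivity} (per-gene TOM sum, diagonal excluded).
#'   Genes with zero variance get zero correlations and are flagged in
#'   attribute \code{"flagged"}.
#' @export
tom_matrix <- function(expr, beta = 6) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("TOM needs at least 3 samples")
  if (beta < 1) stop("beta must be >= 1")
  sds <- apply(expr, 1, stats::sd)
  flagged <- rownames(expr)[sds == 0]
  cc <- suppressWarnings(stats::cor(t(expr)))
  cc[!is.finite(cc)] <- 0
  a <- ((1 + cc) / 2)^beta
  diag(a) <- 1
  k <- rowSums(a) - 1
  # sum_u a_iu a_uj over u != i,j: (a %*% a) includes u = i and u = j, each
  # contributing a_ij (unit diagonal), hence the -2a correction
  num <- a %*% a - 2 * a
  tom <- (num + a) / (outer(k, k, pmin) + 1 - a)
  diag(tom) <- 1
  conn <- rowSums(tom) - 1
  structure(list(adjacency = a, tom = tom, connectivity = conn),
            flagged = flagged)
}

#' Per-gene TOM connectivity
#'
#' @inheritParams tom_matrix
#' @return named numeric vector: each gene's summed topological overlap with
#'   all other genes.
#' @export
tom_connectivity <- function(expr, beta = 6) {
  tom_matrix(expr, beta)$connectivity
}

#' Audic-Claverie test for differential expression without replicates
#'
#' Under the null of equal relative expression, the second library's count
#' given the first follows
#' \deqn{p(y|x) = (N_2/N_1)^y \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},}
#' a negative binomial with size \code{x+1} and success probability
#' \code{N1/(N1+N2)}; tails are evaluated through that identity in stable
#' log space. The two-sided p is twice the smaller tail, capped at 1.
#'
#' @param x,y observed counts in the two libraries (non-negative integers,
#'   vectorized).
#' @param n1,n2 library sizes (> 0).
#' @return two-sided p-value(s).
#' @export
audic_claverie_p <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be positive")
  prob <- n1 / (n1 + n2)
  lo <- stats::pnbinom(y, size = x + 1, prob = prob)          # P(Y <= y | x)
  hi <- stats::pnbinom(y - 1, size = x + 1, prob = prob,
                       lower.tail = FALSE)                    # P(Y >= y | x)
  pmin(1, 2 * pmin(lo, hi))
}

#' Detect phase-related genes (PRGs) in a no-replicate design
#'
#' For every confounder level with one gregarious and one solitary sample,
#' genes are tested with the Audic-Claverie statistic (BH-adjusted within the
#' comparison) and required to change at least \code{fc}-fold on the
#' library-size-normalized scale. A gene is a PRG if it is significant in at
#' least one comparison (\code{rule = "any"}), in more than half
#' (\code{"majority"}), or in all (\code{"all"}).
#'
#' @param dataset an \code{expression_dataset} of kind \code{"counts"} with
#'   one G and one S sample per confounder level.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param fc minimum fold change on normalized counts (default 2).
#' @param rule how many matched comparisons must be significant.
#' @return character vector of PRG gene ids; the per-comparison significance
#'   matrix is attached as attribute \code{"calls"}.
#' @export
detect_prgs <- function(dataset, alpha = 0.05, fc = 2,
                        rule = c("any", "majority", "all")) {
  rule <- match.arg(rule)
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$kind != "counts") stop("detect_prgs expects raw counts")
  meta <- dataset$samples
  lev <- unique(meta$confounder_level)
  calls <- sapply(lev, function(l) {
    gi <- which(meta$confounder_level == l & meta$phase == "G")
    si <- which(meta$confounder_level == l & meta$phase == "S")
    if (length(gi) != 1 || length(si) != 1)
      stop("confounder level '", l, "' is not a matched G/S pair")
    xg <- dataset$values[, gi]
    xs <- dataset$values[, si]
    n1 <- sum(xg); n2 <- sum(xs)
    p <- audic_claverie_p(xg, xs, n1, n2)
    q <- stats::p.adjust(p, method = "BH")
    rg <- (xg / n1) / (xs / n2)
    ratio <- ifelse(xg == 0 & xs == 0, 1, rg)
    ratio[xs == 0 & xg > 0] <- Inf
    q < alpha & pmax(ratio, 1 / ratio) >= fc
  })
  rownames(calls) <- dataset$gene_ids
  need <- switch(rule, any = 1, majority = floor(ncol(calls) / 2) + 1,
                 all = ncol(calls))
  prgs <- dataset$gene_ids[rowSums(calls) >= need]
  attr(prgs, "calls") <- calls
  prgs
}

#' Summarize gene features along Borda rank bins
#'
#' Splits the top \code{n_top} genes of a ranked list into consecutive bins
#' and summarizes every feature per bin (mean and median for numeric
#' features, fraction TRUE for logical flags), plus the Spearman correlation
#' of the per-bin means with the bin index.
#'
#' @param ranked a \code{ranked_gene_list} (or character vector, best first).
#' @param features data.frame of per-gene features with a \code{gene_id}
#'   column (missing values allowed, kept as NA).
#' @param bin_size genes per bin (default 1700).
#' @param n_top total genes binned (default 15300); must be divisible by
#'   \code{bin_size}.
#' @return list with \code{bins} (per-bin summary data.frame) and
#'   \code{trend} (named Spearman rho of bin means vs bin index).
#' @export
bin_feature_trends <- function(ranked, features, bin_size = 1700,
                               n_top = 15300) {
  if (n_top %% bin_size != 0) stop("n_top must be divisible by bin_size")
  ids <- if (is.character(ranked)) ranked else ranked$gene_id
  if (length(ids) < n_top) stop("ranked list shorter than n_top")
  ids <- ids[seq_len(n_top)]
  n_bins <- n_top %/% bin_size
  bin_of <- rep(seq_len(n_bins), each = bin_size)
  ft <- features[match(ids, features$gene_id), , drop = FALSE]
  num_cols <- names(ft)[vapply(ft, is.numeric, logical(1))]
  flag_cols <- names(ft)[vapply(ft, is.logical, logical(1))]
  rows <- lapply(seq_len(n_bins), function(b) {
    sub <- ft[bin_of == b, , drop = FALSE]
    row <- data.frame(bin = b)
    for (cn in num_cols) {
      row[[paste0(cn, "_mean")]] <- mean(sub[[cn]], na.rm = TRUE)
      row[[paste0(cn, "_median")]] <- stats::median(sub[[cn]], na.rm = TRUE)
    }
    for (cn in flag_cols)
      row[[paste0(cn, "_fraction")]] <- mean(sub[[cn]], na.rm = TRUE)
    row
  })
  bins <- do.call(rbind, rows)
  trend_cols <- c(paste0(num_cols, "_mean"), paste0(flag_cols, "_fraction"))
  trend <- vapply(trend_cols, function(cn) {
    v <- bins[[cn]]
    if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0) return(0)
    suppressWarnings(stats::cor(bins$bin, v, method = "spearman",
                                use = "complete.obs"))
  }, numeric(1))
  list(bins = bins, trend = trend)
}
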