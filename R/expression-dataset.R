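#' Expression dataset container
#'
#' Bundles a genes-by-samples expression matrix (raw counts or RPKM) with the
#' per-sample metadata the phase analysis needs: the phase label (\code{"G"}
#' gregarious / \code{"S"} solitary), the confounder level (developmental
#' stage, tissue, or treatment-by-time-point group) and a dataset identifier.
#'
#' @param values numeric matrix, genes in rows, samples in columns,
#'   non-negative. Row names are taken as gene ids if \code{gene_ids} is NULL.
#' @param samples data.frame with one row per column of \code{values};
#'   must contain columns \code{sample_id}, \code{phase} and
#'   \code{confounder_level}; a \code{dataset} column is added if missing.
#' @param kind \code{"counts"} or \code{"rpkm"}.
#' @param gene_ids character vector of unique gene identifiers.
#' @param gene_lengths optional numeric vector of gene lengths in nucleotides
#'   (required to derive RPKM from counts).
#'
#' @return An object of class \code{expression_dataset}: a list with elements
#'   \code{values}, \code{kind}, \code{gene_ids}, \code{samples},
#'   \code{gene_lengths}.
#' @export
expression_dataset <- function(values, samples, kind = c("counts", "rpkm"),
                               gene_ids = NULL, gene_lengths = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(gene_ids)) gene_ids <- rownames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (anyDuplicated(gene_ids)) stop("gene ids must be unique")
  if (length(gene_ids) != nrow(values)) stop("gene_ids length != nrow(values)")
  if (any(values < 0)) stop("expression values must be non-negative")
  samples <- as.data.frame(samples)
  if (nrow(samples) != ncol(values)) stop("samples rows != ncol(values)")
  req <- c("sample_id", "phase", "confounder_level")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  samples$phase <- map_phase_labels(samples$phase)
  if (!all(samples$phase %in% c("G", "S")))
    stop("phase labels must be 'G'/'S' (or 'CS'/'IG')")
  if (is.null(samples$dataset)) samples$dataset <- "dataset1"
  rownames(values) <- gene_ids
  colnames(values) <- samples$sample_id
  if (!is.null(gene_lengths)) {
    if (length(gene_lengths) != length(gene_ids))
      stop("gene_lengths length != number of genes")
    if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
    gene_lengths <- stats::setNames(as.numeric(gene_lengths), gene_ids)
  }
  structure(list(values = values, kind = kind, gene_ids = gene_ids,
                 samples = samples, gene_lengths = gene_lengths),
            class = "expression_dataset")
}

#' Map time-course treatment labels onto the two phases
#'
#' Crowding of solitary locusts (CS) is labelled with its phase of origin
#' \code{"S"}, isolation of gregarious locusts (IG) with \code{"G"}.
#'
#' @param x character vector of labels in \{G, S, CS, IG\}.
#' @return character vector of "G"/"S".
#' @keywords internal
map_phase_labels <- function(x) {
  x <- as.character(x)
  x[x == "CS"] <- "S"
  x[x == "IG"] <- "G"
  x
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset (%s): %d genes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  cat(sprintf("  phases: %s\n",
              paste(sprintf("%s=%d", names(table(x$samples$phase)),
                            table(x$samples$phase)), collapse = ", ")))
  cat(sprintf("  datasets: %s\n",
              paste(unique(x$samples$dataset), collapse = ", ")))
  invisible(x)
}

#' Subset an expression dataset by genes and/or samples
#'
#' @param dataset an \code{expression_dataset}.
#' @param genes character vector of gene ids, or NULL to keep all.
#' @param sample_idx integer/logical index over samples, or NULL to keep all.
#' @return an \code{expression_dataset}.
#' @export
subset_dataset <- function(dataset, genes = NULL, sample_idx = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  gl <- dataset$gene_lengths
  if (!is.null(genes)) {
    missing_genes <- setdiff(genes, dataset$gene_ids)
    if (length(missing_genes))
      stop("genes not in dataset: ", paste(utils::head(missing_genes, 5),
                                           collapse = ", "))
    v <- v[genes, , drop = FALSE]
    if (!is.null(gl)) gl <- gl[genes]
  }
  s <- dataset$samples
  if (!is.null(sample_idx)) {
    v <- v[, sample_idx, drop = FALSE]
    s <- s[sample_idx, , drop = FALSE]
  }
  expression_dataset(v, s, kind = dataset$kind, gene_ids = rownames(v),
                     gene_lengths = gl)
}

#' Write / read the expression TSV dialect
#'
#' Genes as rows (first column \code{gene_id}), samples as columns. The sample
#' metadata travels in a companion TSV with columns \code{sample_id},
#' \code{phase}, \code{dataset}, \code{confounder_level}.
#'
#' @param dataset an \code{expression_dataset}.
#' @param path output TSV path for the matrix.
#' @param meta_path optional output TSV path for the sample metadata.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(dataset, path, meta_path = NULL) {
  df <- data.frame(gene_id = dataset$gene_ids, dataset$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(dataset$samples, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param kind matrix kind flag for the object being read.
#' @export
read_expression_tsv <- function(path, meta_path, kind = "counts") {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- utils::read.delim(meta_path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  meta <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
  expression_dataset(m, meta, kind = kind, gene_ids = df$gene_id)
}
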