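#' Gene-by-sample count container
#'
#' Bundles an integer count matrix with per-gene exonic lengths and per-sample
#' metadata, the central object of the sequencing arm. Metadata must describe
#' every sample: cell type (e.g. ESC, MEF, MYO), condition (`donor` or `NT`),
#' timepoint, replicate and recipient-female id.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids); all values >= 0.
#' @param gene_length numeric vector of summed exon lengths in bp, one per
#'   gene, all > 0. Named vectors are matched to rownames.
#' @param samples data.frame with one row per sample and at least the columns
#'   `sample_id`, `cell_type`, `condition`, `timepoint`, `replicate`,
#'   `female_id`.
#' @return An object of class `gv_counts`: a list with elements `counts`,
#'   `gene_length` and `samples`.
#' @export
gv_counts <- function(counts, gene_length, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(gene_length))) gene_length <- gene_length[rownames(counts)]
  gene_length <- as.numeric(gene_length)
  if (length(gene_length) != nrow(counts))
    stop("gene_length must have one entry per gene")
  if (any(!is.finite(gene_length)) || any(gene_length <= 0))
    stop("gene lengths must be positive")
  samples <- as.data.frame(samples)
  req <- c("sample_id", "cell_type", "condition", "timepoint",
           "replicate", "female_id")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(samples[req])) stop("sample metadata must be complete")
  if (!setequal(samples$sample_id, colnames(counts)) ||
      anyDuplicated(samples$sample_id))
    stop("samples$sample_id must match count matrix columns")
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts,
                 gene_length = stats::setNames(gene_length, rownames(counts)),
                 samples = samples),
            class = "gv_counts")
}

#' @export
print.gv_counts <- function(x, ...) {
  cat(sprintf("gv_counts: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("cell types:", paste(unique(x$samples$cell_type), collapse = ", "), "\n")
  cat("conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a count table and its sample metadata as TSV
#'
#' The count table is genes x samples with a header row of sample ids and a
#' leading `gene_id` column carrying gene ids, plus a `length_bp` column with
#' summed exon lengths. Metadata is a plain TSV with the columns documented in
#' [gv_counts()].
#'
#' @param x a `gv_counts` object.
#' @param counts_file,metadata_file output (or input) paths.
#' @return `write_counts_tsv` returns the paths invisibly; `read_counts_tsv`
#'   returns a `gv_counts`.
#' @export
write_counts_tsv <- function(x, counts_file, metadata_file) {
  stopifnot(inherits(x, "gv_counts"))
  df <- data.frame(gene_id = rownames(x$counts),
                   length_bp = x$gene_length,
                   x$counts, check.names = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$samples, metadata_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts = counts_file, metadata = metadata_file))
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(counts_file, metadata_file) {
  df <- utils::read.delim(counts_file, check.names = FALSE)
  samples <- utils::read.delim(metadata_file)
  m <- as.matrix(df[, setdiff(names(df), c("gene_id", "length_bp")),
                    drop = FALSE])
  rownames(m) <- df$gene_id
  gv_counts(m, stats::setNames(df$length_bp, df$gene_id), samples)
}
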