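#' Transcripts-per-million normalisation
#'
#' Converts raw counts to TPM: per sample, each gene's count is divided by its
#' exonic length, and the resulting rates are scaled to sum to one million.
#' TPM is the scale on which all downstream thresholds (inducibility,
#' fold-change classification, resistance) operate.
#'
#' @param x a [gv_counts()] object.
#' @return An object of class `gv_tpm`: list with `tpm` (genes x samples
#'   matrix whose columns each sum to 1e6) and `samples` (metadata copied from
#'   the input).
#' @examples
#' cnt <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' meta <- data.frame(sample_id = "s1", cell_type = "MEF", condition = "NT",
#'                    timepoint = "24h", replicate = 1, female_id = "F1")
#' x <- gv_counts(cnt, c(g1 = 1000, g2 = 2000), meta)
#' compute_tpm(x)$tpm  # 2:1 rate ratio -> 666666.67 / 333333.33
#' @export
compute_tpm <- function(x) {
  stopifnot(inherits(x, "gv_counts"))
  rate <- x$counts / x$gene_length
  tot <- colSums(rate)
  if (any(tot <= 0)) stop("sample with zero total count rate: ",
                          paste(colnames(x$counts)[tot <= 0], collapse = ", "))
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  structure(list(tpm = tpm, samples = x$samples), class = "gv_tpm")
}

#' @export
print.gv_tpm <- function(x, ...) {
  cat(sprintf("gv_tpm: %d genes x %d samples\n", nrow(x$tpm), ncol(x$tpm)))
  invisible(x)
}

# replicate-mean TPM for one (cell_type, condition), optionally one timepoint
.mean_tpm <- function(expr, cell_type, condition, timepoint = NULL) {
  s <- expr$samples
  sel <- s$cell_type == cell_type & s$condition == condition
  if (!is.null(timepoint)) sel <- sel & s$timepoint %in% timepoint
  if (!any(sel))
    stop(sprintf("no %s samples for cell type %s", condition, cell_type))
  rowMeans(expr$tpm[, s$sample_id[sel], drop = FALSE])
}
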