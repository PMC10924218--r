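#' Thresholds for response classification and resistance calling
#'
#' Central container for every cutoff of the sequencing arm, so that a single
#' pseudocount and a single set of fold-change boundaries are used everywhere.
#'
#' @param tpm_inducible mean NT TPM at or above which a gene counts as
#'   oocyte-inducible (default 1).
#' @param tpm_expressed mean donor TPM at or above which a gene counts as
#'   expressed in the donor (default 1); below it, an induced gene is
#'   `activated` rather than `enhanced`.
#' @param fc_enhance minimum pseudocounted NT/donor fold change for
#'   `enhanced` (default 2).
#' @param fc_repress minimum pseudocounted donor/NT fold change for
#'   `repressed` (default 2).
#' @param fc_resist minimum cross-cell-type NT fold change for resistance
#'   (default 4).
#' @param pseudocount added to TPM before every ratio or log (default 1,
#'   matching the TPM+1 display scale).
#' @param aggregate how replicates are combined before thresholding:
#'   `"mean"` (default) or `"median"`.
#' @return A list of class `gv_classification_config`.
#' @export
classification_config <- function(tpm_inducible = 1, tpm_expressed = 1,
                                  fc_enhance = 2, fc_repress = 2,
                                  fc_resist = 4, pseudocount = 1,
                                  aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  vals <- c(tpm_inducible = tpm_inducible, tpm_expressed = tpm_expressed,
            fc_enhance = fc_enhance, fc_repress = fc_repress,
            fc_resist = fc_resist, pseudocount = pseudocount)
  if (any(vals <= 0)) stop("all thresholds must be > 0")
  if (fc_resist < 1) stop("fc_resist must be >= 1")
  structure(c(as.list(vals), list(aggregate = aggregate)),
            class = "gv_classification_config")
}

.aggregate_tpm <- function(expr, cell_type, condition, cfg,
                           timepoint = NULL) {
  s <- expr$samples
  sel <- s$cell_type == cell_type & s$condition == condition
  if (!is.null(timepoint)) sel <- sel & s$timepoint %in% timepoint
  if (!any(sel))
    stop(sprintf("no %s samples for cell type %s", condition, cell_type))
  m <- expr$tpm[, s$sample_id[sel], drop = FALSE]
  if (cfg$aggregate == "median") apply(m, 1, stats::median) else rowMeans(m)
}

# definitional response rule on aggregated donor / NT TPM vectors;
# precedence: activated, else enhanced, else repressed, else unchanged
.response_class <- function(donor, nt, cfg) {
  pc <- cfg$pseudocount
  fc_up <- (nt + pc) / (donor + pc)
  cls <- rep("unchanged", length(donor))
  cls[1 / fc_up >= cfg$fc_repress] <- "repressed"
  cls[donor >= cfg$tpm_expressed & fc_up >= cfg$fc_enhance] <- "enhanced"
  cls[donor < cfg$tpm_expressed & nt >= cfg$tpm_inducible] <- "activated"
  cls
}

#' Classify per-gene transcriptional responses to nuclear transfer
#'
#' Compares replicate-aggregated donor and NT TPM for one cell type and
#' assigns each gene exactly one class: `activated` (silent in the donor,
#' induced by the oocyte), `enhanced` (expressed in the donor and increased at
#' least `fc_enhance`-fold), `repressed` (decreased at least
#' `fc_repress`-fold) or `unchanged`. Precedence is activated, else enhanced,
#' else repressed. All ratios use the configured pseudocount.
#'
#' @param expr a [compute_tpm()] result.
#' @param cfg a [classification_config()].
#' @param cell_type cell type label to classify.
#' @param timepoint optional NT timepoint filter (default: all NT samples of
#'   the cell type are pooled).
#' @return A data.frame of class `gv_response_table` with columns `gene_id`,
#'   `cell_type`, `class`, `inducible`, `donor_tpm`, `nt_tpm`, `fc`
#'   (pseudocounted NT/donor ratio). The attribute `summary` holds
#'   per-class counts and percentages.
#' @export
classify_response <- function(expr, cfg = classification_config(),
                              cell_type, timepoint = NULL) {
  stopifnot(inherits(expr, "gv_tpm"),
            inherits(cfg, "gv_classification_config"))
  donor <- .aggregate_tpm(expr, cell_type, "donor", cfg)
  nt <- .aggregate_tpm(expr, cell_type, "NT", cfg, timepoint)
  cls <- .response_class(donor, nt, cfg)
  pc <- cfg$pseudocount
  out <- data.frame(gene_id = rownames(expr$tpm),
                    cell_type = cell_type,
                    class = cls,
                    inducible = nt >= cfg$tpm_inducible,
                    donor_tpm = donor, nt_tpm = nt,
                    fc = (nt + pc) / (donor + pc),
                    row.names = NULL)
  tab <- table(factor(cls, levels = c("activated", "enhanced",
                                      "repressed", "unchanged")))
  attr(out, "summary") <- data.frame(class = names(tab),
                                     n = as.integer(tab),
                                     percent = 100 * as.integer(tab) /
                                       length(cls))
  class(out) <- c("gv_response_table", "data.frame")
  out
}

#' Call oocyte-inducible genes and their cross-cell-type overlap
#'
#' A gene is oocyte-inducible in a cell type when its replicate-aggregated
#' nascent (NT) TPM reaches `tpm_inducible`. Returns the per-cell-type sets
#' together with all Venn-region counts, the union and the full intersection,
#' for the three-set overlap display.
#'
#' @inheritParams classify_response
#' @param cell_types cell types to evaluate (default: all with NT samples).
#' @return A list of class `gv_inducible`: `sets` (named list of gene-id
#'   vectors), `sizes`, `union_size`, `intersection_size` and `venn` (named
#'   region counts, names like `"ESC&MYO"` for genes exclusive to a region).
#' @export
call_inducible <- function(expr, cfg = classification_config(),
                           cell_types = NULL) {
  stopifnot(inherits(expr, "gv_tpm"))
  s <- expr$samples
  if (is.null(cell_types))
    cell_types <- unique(s$cell_type[s$condition == "NT"])
  sets <- lapply(cell_types, function(ct) {
    nt <- .aggregate_tpm(expr, ct, "NT", cfg)
    rownames(expr$tpm)[nt >= cfg$tpm_inducible]
  })
  names(sets) <- cell_types
  member <- vapply(sets, function(g) rownames(expr$tpm) %in% g,
                   logical(nrow(expr$tpm)))
  key <- apply(member, 1, function(r)
    paste(cell_types[r], collapse = "&"))
  key <- key[key != ""]
  venn <- table(key)
  structure(list(sets = sets,
                 sizes = vapply(sets, length, integer(1)),
                 union_size = sum(rowSums(member) > 0),
                 intersection_size = sum(rowSums(member) == length(sets)),
                 venn = stats::setNames(as.integer(venn), names(venn))),
            class = "gv_inducible")
}

#' Identify reprogramming-resistant genes
#'
#' A gene is resistant in a focal cell type when (a) it is oocyte-inducible in
#' at least one other cell type, (b) its NT expression in the focal cell type
#' is at least `fc_resist`-fold below the other cell types' NT expression
#' (pseudocounted), and (c) it is not classified `repressed` in the focal cell
#' type — genes the oocyte itself downregulates are excluded. The comparator
#' is the mean over the other cell types' replicate-aggregated NT TPM
#' (`mode = "mean"`); `mode = "pairwise"` is a strict variant requiring the
#' fold change against every other inducible cell type.
#'
#' @inheritParams classify_response
#' @param responses named list of [classify_response()] tables, one per cell
#'   type (computed if omitted).
#' @param cell_types cell types to evaluate; at least two required.
#' @param mode `"mean"` (default) or `"pairwise"`.
#' @return A list of class `gv_resistant`: `sets` (named list of gene-id
#'   vectors per focal cell type), `sizes`, and `detail` (long data.frame with
#'   the comparator and fold change per gene and focal cell type).
#' @export
find_resistant <- function(expr, cfg = classification_config(),
                           cell_types = NULL, responses = NULL,
                           mode = c("mean", "pairwise")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "gv_tpm"))
  s <- expr$samples
  if (is.null(cell_types))
    cell_types <- unique(s$cell_type[s$condition == "NT"])
  if (length(cell_types) < 2)
    stop("resistance needs at least two cell types")
  if (is.null(responses)) {
    responses <- lapply(cell_types, function(ct)
      classify_response(expr, cfg, ct))
    names(responses) <- cell_types
  }
  nt <- vapply(cell_types, function(ct) .aggregate_tpm(expr, ct, "NT", cfg),
               numeric(nrow(expr$tpm)))
  nt <- matrix(nt, nrow = nrow(expr$tpm),
               dimnames = list(rownames(expr$tpm), cell_types))
  pc <- cfg$pseudocount
  inducible <- nt >= cfg$tpm_inducible
  detail <- list()
  sets <- list()
  for (ct in cell_types) {
    others <- setdiff(cell_types, ct)
    ind_other <- rowSums(inducible[, others, drop = FALSE]) > 0
    if (mode == "mean") {
      comp <- rowMeans(nt[, others, drop = FALSE])
      fc <- (comp + pc) / (nt[, ct] + pc)
      pass_fc <- fc >= cfg$fc_resist
    } else {
      fcs <- (nt[, others, drop = FALSE] + pc) / (nt[, ct] + pc)
      # against every other cell type in which the gene is inducible
      pass <- fcs >= cfg$fc_resist | !inducible[, others, drop = FALSE]
      pass_fc <- rowSums(!pass) == 0
      fc <- apply(fcs, 1, min)
      comp <- rowMeans(nt[, others, drop = FALSE])
    }
    not_repressed <- responses[[ct]]$class != "repressed"
    res <- ind_other & pass_fc & not_repressed
    sets[[ct]] <- rownames(expr$tpm)[res]
    detail[[ct]] <- data.frame(gene_id = rownames(expr$tpm),
                               cell_type = ct, resistant = res,
                               nt_tpm = nt[, ct], other_nt_tpm = comp,
                               fc = fc, row.names = NULL)
  }
  structure(list(sets = sets,
                 sizes = vapply(sets, length, integer(1)),
                 detail = do.call(rbind, detail)),
            class = "gv_resistant")
}

#' Pearson correlation between replicate-mean expression profiles
#'
#' Computes Pearson's r on log2(TPM + pseudocount) between the replicate-mean
#' profiles of two (cell type, condition) groups, the statistic used to
#' compare donor against NT and NT against NT transcriptomes.
#'
#' @inheritParams classify_response
#' @param pairs data.frame with columns `cell_type_1`, `condition_1`,
#'   `cell_type_2`, `condition_2` (optionally `timepoint_1`, `timepoint_2`).
#' @return The input data.frame with an added numeric column `r`.
#' @export
correlate_samples <- function(expr, pairs, cfg = classification_config()) {
  stopifnot(inherits(expr, "gv_tpm"))
  pc <- cfg$pseudocount
  pairs$r <- vapply(seq_len(nrow(pairs)), function(i) {
    tp1 <- if ("timepoint_1" %in% names(pairs)) pairs$timepoint_1[i]
    tp2 <- if ("timepoint_2" %in% names(pairs)) pairs$timepoint_2[i]
    x <- log2(.aggregate_tpm(expr, pairs$cell_type_1[i], pairs$condition_1[i],
                             cfg, tp1) + pc)
    y <- log2(.aggregate_tpm(expr, pairs$cell_type_2[i], pairs$condition_2[i],
                             cfg, tp2) + pc)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance in a correlation input")
    stats::cor(x, y)
  }, numeric(1))
  pairs
}

#' Top expressed genes of one (cell type, condition)
#'
#' Genes ranked by replicate-aggregated TPM, descending; ties broken by
#' lexicographic gene id. Used e.g. to list the most actively induced genes
#' of a cell type after nuclear transfer.
#'
#' @inheritParams classify_response
#' @param condition `"NT"` or `"donor"`.
#' @param n number of genes to return (default 1500).
#' @return Character vector of `n` gene ids, most expressed first.
#' @export
top_expressed <- function(expr, cell_type, condition = "NT", n = 1500,
                          cfg = classification_config()) {
  stopifnot(inherits(expr, "gv_tpm"))
  if (n > nrow(expr$tpm)) stop("n exceeds the number of genes")
  v <- .aggregate_tpm(expr, cell_type, condition, cfg)
  ids <- rownames(expr$tpm)
  ord <- order(-v, ids, method = "radix")
  ids[ord][seq_len(n)]
}

#' Average-linkage correlation clustering for heatmap ordering
#'
#' Agglomerative clustering with average linkage on the correlation distance
#' 1 - Pearson r over log2(TPM + pseudocount), applied to samples and (for a
#' given gene subset) to genes, yielding the leaf orders used to lay out
#' expression heatmaps.
#'
#' @inheritParams classify_response
#' @param genes optional character vector restricting the gene universe.
#' @return List of class `gv_cluster_order`: `sample_order`, `gene_order`
#'   (character vectors of leaf labels) and the two `hclust` trees.
#' @export
cluster_order <- function(expr, genes = NULL,
                          cfg = classification_config()) {
  stopifnot(inherits(expr, "gv_tpm"))
  m <- log2(expr$tpm + cfg$pseudocount)
  if (!is.null(genes)) m <- m[genes, , drop = FALSE]
  if (ncol(m) < 2) stop("clustering needs at least two samples")
  if (any(apply(m, 2, stats::sd) == 0) || any(apply(m, 1, stats::sd) == 0))
    stop("constant row or column: correlation distance undefined")
  hs <- stats::hclust(stats::as.dist(1 - stats::cor(m)), method = "average")
  hg <- stats::hclust(stats::as.dist(1 - stats::cor(t(m))), method = "average")
  structure(list(sample_order = colnames(m)[hs$order],
                 gene_order = rownames(m)[hg$order],
                 sample_tree = hs, gene_tree = hg),
            class = "gv_cluster_order")
}
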