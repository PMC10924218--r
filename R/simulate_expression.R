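#' Configuration for the nascent-transcriptome simulator
#'
#' Defines the study conditions the sequencing-arm generator emulates: three
#' donor cell types whose nuclei converge to a shared oocyte-induced
#' expression state after nuclear transfer, with configurable proportions of
#' activated / enhanced / repressed / unchanged genes and a per-cell-type
#' fraction of inducible genes forced to resist induction.
#'
#' Expression levels are drawn in relative log2 units and self-calibrated so
#' each simulated profile's TPM total is one million: the `mean` entries of
#' `donor_mean_log2` and `induced_mean_log2` set locations relative to each
#' other, the `sd` entries the spread.
#'
#' @param n_genes number of genes (>= 1).
#' @param cell_types donor cell type labels.
#' @param class_proportions named fractions for `activated`, `enhanced`,
#'   `repressed`, `unchanged`; must sum to 1.
#' @param resistant_fraction named per-cell-type fraction of
#'   induced-elsewhere genes forced resistant in that cell type.
#' @param class_correlation probability that a cell type adopts the gene's
#'   shared response class rather than an independent draw; couples which
#'   genes the oocyte induces across donor cell types (marginal class
#'   proportions are unaffected). 0 = independent responses, 1 = identical
#'   response programs.
#' @param donor_mean_log2 `c(mean, sd)` of the per-gene log2 donor baseline.
#' @param celltype_sd_log2 sd of the per-cell-type deviation added to the
#'   donor baseline, so donor profiles differ between cell types.
#' @param induced_mean_log2 `c(mean, sd)` of the log2 shared induced target.
#' @param nb_dispersion negative-binomial dispersion of counts (0 = Poisson).
#' @param library_size expected reads per sample.
#' @param n_replicates replicates (recipient females) per condition.
#' @param gene_length_range bp bounds for simulated exonic lengths.
#' @param seed RNG seed.
#' @return A list of class `gv_expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 5000,
                            cell_types = c("ESC", "MEF", "MYO"),
                            class_proportions = c(activated = 0.16,
                                                  enhanced = 0.10,
                                                  repressed = 0.14,
                                                  unchanged = 0.60),
                            resistant_fraction = c(ESC = 0.04, MEF = 0.03,
                                                   MYO = 0.10),
                            class_correlation = 0.7,
                            donor_mean_log2 = c(mean = 3, sd = 2),
                            celltype_sd_log2 = 0.6,
                            induced_mean_log2 = c(mean = 3.5, sd = 1.5),
                            nb_dispersion = 0.1,
                            library_size = 1e6,
                            n_replicates = 3,
                            gene_length_range = c(500, 5000),
                            seed = 1) {
  cls <- c("activated", "enhanced", "repressed", "unchanged")
  if (!setequal(names(class_proportions), cls))
    stop("class_proportions must be named ", paste(cls, collapse = ", "))
  class_proportions <- class_proportions[cls]
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(class_proportions < 0) || any(class_proportions > 1))
    stop("class_proportions must lie in [0, 1]")
  if (!all(cell_types %in% names(resistant_fraction)))
    stop("resistant_fraction must name every cell type")
  resistant_fraction <- resistant_fraction[cell_types]
  if (any(resistant_fraction < 0) || any(resistant_fraction > 1))
    stop("resistant_fraction must lie in [0, 1]")
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (class_correlation < 0 || class_correlation > 1)
    stop("class_correlation must lie in [0, 1]")
  structure(list(n_genes = as.integer(n_genes), cell_types = cell_types,
                 class_proportions = class_proportions,
                 resistant_fraction = resistant_fraction,
                 class_correlation = class_correlation,
                 donor_mean_log2 = donor_mean_log2,
                 celltype_sd_log2 = celltype_sd_log2,
                 induced_mean_log2 = induced_mean_log2,
                 nb_dispersion = nb_dispersion,
                 library_size = library_size,
                 n_replicates = as.integer(n_replicates),
                 gene_length_range = gene_length_range,
                 seed = as.integer(seed)),
            class = "gv_expr_sim_config")
}

#' Simulate nascent-transcriptome counts with known response classes
#'
#' Draws, per gene, a shared oocyte-induced target TPM and, per cell type, a
#' donor TPM constructed so the sampled response class (activation,
#' enhancement, repression, unchanged) is realized exactly on the noise-free
#' expected TPM values under the default [classification_config()] rules.
#' NT samples reflect only post-transfer transcription (the BrUTP-labelled
#' nascent pool), never carried-over donor RNA; 48 h samples are new
#' negative-binomial draws from the same per-gene means as 24 h. Counts are
#' negative binomial around the TPM-implied expected count given gene length
#' and library size.
#'
#' Forced-resistant genes are chosen among genes unchanged in the focal cell
#' type but induced elsewhere: their donor level in the focal cell type is
#' lowered, the shared target raised to a detectable margin, and their NT
#' expression set equal to their donor level (no induction). Truth labels
#' (`class`, `resistant`) come from applying the definitional rules to the
#' noise-free expected TPM, so recovery tests measure sampling noise only;
#' by construction the definitional class equals the sampled class.
#'
#' @param config an [expr_sim_config()].
#' @return List with `counts` (a [gv_counts()]; per cell type:
#'   `n_replicates` donor samples at 0h and NT samples at 24h and 48h) and
#'   `truth`, a list with `genes` (gene_id, length_bp, induced_target_tpm),
#'   `assignments` (long data.frame: gene_id, cell_type, class,
#'   forced_resistant, resistant, donor_tpm, nt_tpm) and the config.
#' @export
simulate_expression <- function(config = expr_sim_config()) {
  stopifnot(inherits(config, "gv_expr_sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  cts <- config$cell_types
  ids <- sprintf("gene%05d", seq_len(n))
  len <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                n, replace = TRUE)

  # sampled class per gene per cell type: a shared per-gene response program
  # adopted with probability class_correlation, otherwise an independent
  # draw — the mixture leaves marginal class proportions untouched
  shared_cls <- sample(names(config$class_proportions), n, replace = TRUE,
                       prob = config$class_proportions)
  cls <- matrix(sample(names(config$class_proportions), n * length(cts),
                       replace = TRUE, prob = config$class_proportions),
                n, length(cts), dimnames = list(ids, cts))
  adopt <- matrix(stats::runif(n * length(cts)) < config$class_correlation,
                  n, length(cts))
  cls[adopt] <- shared_cls[row(cls)[adopt]]
  induced <- cls == "activated" | cls == "enhanced"
  any_enh <- rowSums(cls == "enhanced") > 0

  # all random draws up front; the calibration loop below reuses them
  t_raw <- 2^stats::rnorm(n, config$induced_mean_log2["mean"],
                          config$induced_mean_log2["sd"])
  base <- stats::rnorm(n, config$donor_mean_log2["mean"],
                       config$donor_mean_log2["sd"])
  d_raw <- vapply(cts, function(ct)
    2^(base + stats::rnorm(n, 0, config$celltype_sd_log2)), numeric(n))
  u_act <- matrix(stats::runif(n * length(cts), 0, 0.5), n)
  fc_enh <- matrix(2^stats::runif(n * length(cts), 1.4, 3), n)
  fc_rep <- matrix(2^stats::runif(n * length(cts), 1.2, 3), n)

  # self-calibration: scale the raw draws so that donor and NT profiles each
  # total ~1e6 TPM while every class constraint is met in final TPM units.
  # Constrained masses are small, so the fixed point converges in few steps.
  build <- function(s_d, s_nt) {
    t_fin <- pmax(t_raw / s_nt, 1.5)
    t_fin[any_enh] <- pmax(t_fin[any_enh], 4)
    donor <- nt <- matrix(0, n, length(cts), dimnames = list(ids, cts))
    for (j in seq_along(cts)) {
      d <- d_raw[, j] / s_d
      k <- cls[, j]
      i <- k == "activated"
      d[i] <- u_act[i, j]
      nt[i, j] <- t_fin[i]
      i <- k == "enhanced"
      d[i] <- pmax((t_fin[i] + 1) / fc_enh[i, j] - 1, 1)
      nt[i, j] <- t_fin[i]
      i <- k == "repressed"
      d[i] <- pmax(d[i], 1.5)
      nt[i, j] <- pmax((d[i] + 1) / fc_rep[i, j] - 1, 0)
      i <- k == "unchanged"
      nt[i, j] <- d[i]
      donor[, j] <- d
    }
    list(target = t_fin, donor = donor, nt = nt)
  }
  s_d <- s_nt <- sum(d_raw) / length(cts) / 1e6
  for (it in 1:6) {
    p <- build(s_d, s_nt)
    s_d <- s_d * mean(colSums(p$donor)) / 1e6
    s_nt <- s_nt * mean(colSums(p$nt)) / 1e6
  }
  p <- build(s_d, s_nt)
  target <- p$target; donor <- p$donor; nt <- p$nt

  # force resistance: genes unchanged in the focal cell type, induced
  # elsewhere; no class changes, so realized class frequencies are untouched
  forced <- matrix(FALSE, n, length(cts), dimnames = list(ids, cts))
  for (j in seq_along(cts)) {
    frac <- config$resistant_fraction[[j]]
    if (frac <= 0) next
    elsewhere <- rowSums(induced[, -j, drop = FALSE]) > 0
    pool <- which(cls[, j] == "unchanged" & elsewhere)
    n_force <- round(frac * sum(elsewhere))
    if (n_force > length(pool))
      stop("too few eligible genes to force the requested resistant fraction")
    sel <- sample(pool, n_force)
    forced[sel, j] <- TRUE
    donor[sel, j] <- stats::runif(length(sel), 0, 0.5)
    nt[sel, j] <- donor[sel, j]             # no induction in the focal type
    target[sel] <- pmax(target[sel], 16)    # detectable margin elsewhere
    for (o in seq_along(cts)[-j]) {
      i <- sel[induced[sel, o]]
      nt[i, o] <- target[i]
    }
  }

  # definitional truth on the noise-free expected TPM
  cfg0 <- classification_config()
  true_class <- vapply(cts, function(ct)
    .response_class(donor[, ct], nt[, ct], cfg0), character(n))
  dimnames(true_class) <- list(ids, cts)
  inducible <- nt >= cfg0$tpm_inducible
  resistant <- matrix(FALSE, n, length(cts), dimnames = list(ids, cts))
  for (j in seq_along(cts)) {
    comp <- rowMeans(nt[, -j, drop = FALSE])
    resistant[, j] <- rowSums(inducible[, -j, drop = FALSE]) > 0 &
      (comp + cfg0$pseudocount) / (nt[, j] + cfg0$pseudocount) >=
        cfg0$fc_resist &
      true_class[, j] != "repressed"
  }

  # counts: NB around TPM-implied expected counts given length and library
  draw <- function(tpm_profile) {
    w <- tpm_profile * len
    mu <- config$library_size * w / sum(w)
    if (config$nb_dispersion == 0) stats::rpois(n, mu)
    else stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
  }
  reps <- seq_len(config$n_replicates)
  meta <- list(); cols <- list()
  for (ct in cts) {
    for (r in reps) {
      sid <- sprintf("%s_donor_0h_r%d", ct, r)
      cols[[sid]] <- draw(donor[, ct])
      meta[[sid]] <- data.frame(sample_id = sid, cell_type = ct,
                                condition = "donor", timepoint = "0h",
                                replicate = r,
                                female_id = sprintf("F%d", r))
    }
    for (tp in c("24h", "48h")) for (r in reps) {
      sid <- sprintf("%s_NT_%s_r%d", ct, tp, r)
      cols[[sid]] <- draw(nt[, ct])
      meta[[sid]] <- data.frame(sample_id = sid, cell_type = ct,
                                condition = "NT", timepoint = tp,
                                replicate = r,
                                female_id = sprintf("F%d", r))
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  counts <- gv_counts(m, stats::setNames(len, ids), do.call(rbind, meta))

  assignments <- do.call(rbind, lapply(seq_along(cts), function(j)
    data.frame(gene_id = ids, cell_type = cts[j], class = true_class[, j],
               sampled_class = cls[, j],
               forced_resistant = forced[, j], resistant = resistant[, j],
               donor_tpm = donor[, j], nt_tpm = nt[, j], row.names = NULL)))
  list(counts = counts,
       truth = list(genes = data.frame(gene_id = ids, length_bp = len,
                                       induced_target_tpm = target,
                                       row.names = NULL),
                    assignments = assignments,
                    config = config))
}
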