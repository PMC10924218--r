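#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates the enabled stages in dependency order — simulate expression
#' counts, expression analysis (TPM, inducible sets, response classes,
#' resistant genes, correlations, clustering), the hybrid-reference
#' demonstration (fixture genomes, k-mer assignment, counting), simulate
#' images, and imaging quantification (segmentation, density classes,
#' HP1-alpha occupancy, area comparison) — writing every output under one
#' directory together with a manifest of seeds, configuration and file
#' checksums. Reruns with an identical configuration produce byte-identical
#' outputs.
#'
#' The configuration is a plain named list (or a YAML file with the same
#' structure): `stages` (logical flags `simulate_expression`,
#' `expression_analysis`, `hybrid_demo`, `simulate_images`,
#' `imaging_analysis`), optional argument lists `expr_sim`, `img_sim`,
#' `classification`, `watershed`, `fixture` passed to the respective
#' constructors, optional `counts_file`/`metadata_file` for pre-computed
#' counts, `seed`, and `output_dir`. A top-level `seed` overrides the
#' generator seeds (expression: seed; images: seed + 1; fixture: seed + 2).
#'
#' @param config named list or path to a YAML config file.
#' @param output_dir overrides `config$output_dir`.
#' @return The manifest (list), invisibly written as `manifest.json`:
#'   package version, seeds, stage flags, and per-file md5 checksums.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- utils::modifyList(
    list(simulate_expression = TRUE, expression_analysis = TRUE,
         hybrid_demo = FALSE, simulate_images = TRUE,
         imaging_analysis = TRUE),
    config$stages %||% list())
  out <- output_dir %||% config$output_dir
  if (is.null(out)) stop("config must give an output_dir")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out, 2) != 0) stop("output_dir is not writable")
  seed <- config$seed %||% 1
  files <- character(0)
  add <- function(...) files <<- c(files, ...)
  wjson <- function(x, name) {
    p <- file.path(out, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add(p)
  }
  wtsv <- function(df, name) {
    p <- file.path(out, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    add(p)
  }

  counts <- NULL
  if (isTRUE(stages$simulate_expression)) {
    ecfg <- do.call(expr_sim_config,
                    utils::modifyList(config$expr_sim %||% list(),
                                      list(seed = seed)))
    sim <- simulate_expression(ecfg)
    counts <- sim$counts
    write_counts_tsv(counts, file.path(out, "counts.tsv"),
                     file.path(out, "sample_metadata.tsv"))
    add(file.path(out, "counts.tsv"), file.path(out, "sample_metadata.tsv"))
    wtsv(sim$truth$assignments, "truth_assignments.tsv")
  } else if (!is.null(config$counts_file)) {
    counts <- read_counts_tsv(config$counts_file, config$metadata_file)
  }

  if (isTRUE(stages$expression_analysis)) {
    if (is.null(counts))
      stop("expression_analysis enabled but no count table available: ",
           "enable simulate_expression or give counts_file/metadata_file")
    ccfg <- do.call(classification_config, config$classification %||% list())
    expr <- compute_tpm(counts)
    tdf <- data.frame(gene_id = rownames(expr$tpm), expr$tpm,
                      check.names = FALSE)
    wtsv(tdf, "tpm.tsv")
    cts <- unique(expr$samples$cell_type[expr$samples$condition == "NT"])
    ind <- call_inducible(expr, ccfg, cts)
    wjson(list(sizes = as.list(ind$sizes), union = ind$union_size,
               intersection = ind$intersection_size,
               venn = as.list(ind$venn)), "inducible_venn.json")
    responses <- lapply(cts, function(ct) classify_response(expr, ccfg, ct))
    names(responses) <- cts
    wtsv(do.call(rbind, lapply(responses, as.data.frame)),
         "response_table.tsv")
    wtsv(do.call(rbind, lapply(cts, function(ct)
      cbind(cell_type = ct, attr(responses[[ct]], "summary")))),
      "response_summary.tsv")
    if (length(cts) >= 2) {
      res <- find_resistant(expr, ccfg, cts, responses)
      wtsv(res$detail[res$detail$resistant, ], "resistant_genes.tsv")
    }
    prs <- expand.grid(cell_type_1 = cts, cell_type_2 = cts,
                       stringsAsFactors = FALSE)
    prs <- prs[prs$cell_type_1 < prs$cell_type_2, ]
    prs$condition_1 <- "NT"; prs$condition_2 <- "NT"
    donor_nt <- data.frame(cell_type_1 = cts, condition_1 = "donor",
                           cell_type_2 = cts, condition_2 = "NT")
    wjson(apply(correlate_samples(expr, rbind(prs, donor_nt), ccfg), 1,
                as.list), "correlations.json")
    ord <- cluster_order(expr, cfg = ccfg)
    wjson(list(sample_order = ord$sample_order,
               gene_order = ord$gene_order), "cluster_order.json")
  }

  if (isTRUE(stages$hybrid_demo)) {
    fcfg <- config$fixture %||% list()
    fcfg$dir <- file.path(out, "fixture")
    fcfg$seed <- seed + 2
    fx <- do.call(write_fixture_genome, fcfg)
    add(fx$fasta, fx$gtf, fx$fastq)
    ref <- build_hybrid_reference(fx$fasta[1], fx$fasta[2],
                                  fx$gtf[1], fx$gtf[2])
    asn <- assign_reads(fx$fastq, ref)
    cm <- count_by_gene(asn, ref)
    write_counts_tsv(cm, file.path(out, "hybrid_counts.tsv"),
                     file.path(out, "hybrid_metadata.tsv"))
    add(file.path(out, "hybrid_counts.tsv"),
        file.path(out, "hybrid_metadata.tsv"))
    wjson(as.list(attr(cm, "species_totals")[1, ]), "hybrid_totals.json")
  }

  imgs <- NULL
  if (isTRUE(stages$simulate_images)) {
    icfg <- do.call(img_sim_config,
                    utils::modifyList(config$img_sim %||% list(),
                                      list(seed = seed + 1)))
    imgs <- simulate_images(icfg, n_images = config$n_images %||% 1,
                            paired = TRUE)
    for (set in c("baseline", "dispersed"))
      for (i in seq_along(imgs[[set]])) {
        p <- file.path(out, sprintf("image_%s_%02d.tif", set, i))
        write_image_tiff(imgs[[set]][[i]], p)
        add(p)
      }
  }

  if (isTRUE(stages$imaging_analysis)) {
    if (is.null(imgs))
      stop("imaging_analysis enabled but simulate_images is not")
    wcfg <- do.call(watershed_params, config$watershed %||% list())
    seg_rows <- list(); occ_rows <- list(); th_list <- list()
    areas <- list(baseline = numeric(0), dispersed = numeric(0))
    for (set in c("baseline", "dispersed")) {
      for (i in seq_along(imgs[[set]])) {
        img <- imgs[[set]][[i]]
        thr <- huang_threshold(img$dna)
        part <- iterative_otsu(img$dna)
        areas[[set]] <- c(areas[[set]],
                          measure_chromatin_area(part))
        th_list[[sprintf("%s_%02d", set, i)]] <-
          list(huang = thr, otsu = as.list(part$thresholds))
        occ <- hp1a_occupancy(part, img$hp1)
        occ_rows[[length(occ_rows) + 1]] <-
          cbind(set = set, image = i, as.data.frame(occ))
        if (set == "baseline") {
          seg <- recursive_watershed(img$dna >= thr, wcfg)
          lab <- segments_to_labels(seg)
          p <- file.path(out, sprintf("labels_%02d.tif", i))
          tiff::writeTIFF(lab / 65535, p, bits.per.sample = 16L,
                          compression = "none")
          add(p)
          seg_rows[[length(seg_rows) + 1]] <- do.call(rbind, lapply(
            seg$segments, function(s)
              data.frame(image = i, label = s$label, area_px = s$area,
                         depth = s$depth)))
        }
      }
    }
    wtsv(do.call(rbind, seg_rows), "segments.tsv")
    wtsv(do.call(rbind, occ_rows), "occupancy.tsv")
    wjson(th_list, "thresholds.json")
    cmp <- compare_chromatin_areas(areas$baseline, areas$dispersed)
    wjson(unclass(cmp), "area_comparison.json")
  }

  manifest <- list(
    package = "gvreprog",
    version = as.character(utils::packageVersion("gvreprog")),
    seed = seed,
    stages = stages,
    files = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
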