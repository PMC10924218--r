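#' Write a synthetic two-species genome fixture with truth-labelled reads
#'
#' Generates two toy genomes of random sequence (so that, at typical k-mer
#' lengths, virtually no k-mer is shared by chance), places non-overlapping
#' two-exon genes on each, and samples error-free single-end reads from
#' within single exons. Read names encode the true species and gene
#' (`species|gene|rNNNN`), so assignment and counting can be scored exactly.
#' Optionally a shared segment is copied from genome A into genome B to
#' create genuinely ambiguous sequence.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed; identical seeds give byte-identical files.
#' @param n_genes_per_species genes per species.
#' @param chrom_length bp per chromosome (two chromosomes per species);
#'   must be large enough to place the requested genes.
#' @param shared_segment_length bp copied from A chr1 into B chr1 (0 = fully
#'   disjoint genomes); genes are never placed over the shared segment.
#' @param n_reads total reads sampled (uniformly over species and genes).
#' @param read_length bp per read (default 50, single-end).
#' @param species labels used in file names and read names.
#' @return Invisibly, a list with `fasta` (2 paths), `gtf` (2 paths),
#'   `fastq`, and `truth` (data.frame: read_id, species, gene_id).
#' @export
write_fixture_genome <- function(dir, seed = 1, n_genes_per_species = 8,
                                 chrom_length = 20000,
                                 shared_segment_length = 0,
                                 n_reads = 500, read_length = 50,
                                 species = c("speciesA", "speciesB")) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  genomes <- list()
  for (sp in species)
    genomes[[sp]] <- c(chr1 = rand_dna(chrom_length),
                       chr2 = rand_dna(chrom_length))
  shared_end <- 0
  if (shared_segment_length > 0) {
    if (shared_segment_length > chrom_length)
      stop("shared segment longer than the chromosome")
    seg <- substr(genomes[[species[1]]]["chr1"], 1, shared_segment_length)
    g2 <- genomes[[species[2]]]["chr1"]
    genomes[[species[2]]]["chr1"] <-
      paste0(seg, substr(g2, shared_segment_length + 1, chrom_length))
    shared_end <- shared_segment_length
  }

  # two-exon genes laid out left to right, alternating chromosomes
  exon_rows <- list(); truth_genes <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    pos <- c(chr1 = if (si == 2) shared_end + 50 else 1, chr2 = 1)
    for (gi in seq_len(n_genes_per_species)) {
      chrom <- if (gi %% 2 == 1) "chr1" else "chr2"
      e1 <- sample(150:300, 1); e2 <- sample(150:300, 1)
      intron <- sample(100:200, 1); gap <- sample(200:400, 1)
      start <- pos[chrom] + gap
      end <- start + e1 + intron + e2 - 1
      if (end > chrom_length)
        stop("chrom_length too small to place ", n_genes_per_species,
             " genes per species")
      gene_id <- sprintf("%s_g%02d", sp, gi)
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        species = sp, chrom = chrom, gene_id = gene_id,
        strand = if (gi %% 3 == 0) "-" else "+",
        start = c(start, start + e1 + intron),
        end = c(start + e1 - 1, end))
      pos[chrom] <- end
    }
  }
  exons <- do.call(rbind, exon_rows)

  fasta <- file.path(dir, paste0(species, "_genome.fa"))
  gtf <- file.path(dir, paste0(species, "_genes.gtf"))
  for (si in seq_along(species)) {
    ss <- Biostrings::DNAStringSet(genomes[[species[si]]])
    Biostrings::writeXStringSet(ss, fasta[si], width = 70)
    e <- exons[exons$species == species[si], ]
    gr <- GenomicRanges::GRanges(e$chrom,
                                 IRanges::IRanges(e$start, e$end),
                                 strand = e$strand)
    gr$type <- "exon"
    gr$source <- "gvreprog_fixture"
    gr$gene_id <- e$gene_id
    gr$transcript_id <- paste0(e$gene_id, ".t1")
    rtracklayer::export(gr, gtf[si], format = "gtf")
  }

  # reads sampled fully inside single exons, forward strand of the genome
  pick <- exons[sample(nrow(exons), n_reads, replace = TRUE), ]
  ok <- pick$end - pick$start + 1 >= read_length
  if (!all(ok)) pick <- pick[ok, ]
  starts <- pick$start +
    floor(stats::runif(nrow(pick)) * (pick$end - pick$start + 2 - read_length))
  seqs <- vapply(seq_len(nrow(pick)), function(i)
    substr(genomes[[pick$species[i]]][pick$chrom[i]],
           starts[i], starts[i] + read_length - 1), character(1))
  ids <- sprintf("%s|%s|r%04d", pick$species, pick$gene_id,
                 seq_len(nrow(pick)))
  reads <- Biostrings::DNAStringSet(seqs)
  names(reads) <- ids
  fastq <- file.path(dir, "reads.fastq")
  Biostrings::writeXStringSet(
    reads, fastq, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", read_length))[
      rep(1, length(reads))])
  invisible(list(fasta = fasta, gtf = gtf, fastq = fastq,
                 truth = data.frame(read_id = ids, species = pick$species,
                                    gene_id = pick$gene_id,
                                    row.names = NULL)))
}

#' Parse fixture read names back to their true origin
#'
#' @param read_id character vector of `species|gene|rNNNN` names.
#' @return data.frame with columns `read_id`, `species`, `gene_id`.
#' @export
parse_fixture_read_names <- function(read_id) {
  parts <- strsplit(read_id, "|", fixed = TRUE)
  if (any(lengths(parts) != 3)) stop("malformed fixture read name")
  data.frame(read_id = read_id,
             species = vapply(parts, `[`, "", 1),
             gene_id = vapply(parts, `[`, "", 2), row.names = NULL)
}
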