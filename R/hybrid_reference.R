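#' Build a two-species hybrid reference
#'
#' Concatenates two genomes into one reference, renaming the second species'
#' chromosomes with a disambiguating prefix (by default `xla_`, so `chr1`
#' becomes `xla_chr1`), and merges the two annotations with a species tag per
#' gene. Species-of-origin of a read can then be decided by which side of the
#' hybrid its sequence matches.
#'
#' @param fasta_a,fasta_b genome FASTA paths (species A kept first, species B
#'   prefixed).
#' @param gtf_a,gtf_b annotation GTF paths; exon records with a `gene_id`
#'   attribute are used; coordinates are 1-based inclusive throughout.
#' @param prefix chromosome-name prefix applied to species B.
#' @param species length-2 character, labels for the two species.
#' @return An object of class `gv_hybrid_reference`: list with `seqs`
#'   (a `DNAStringSet`, species A chromosomes then prefixed species B),
#'   `genes` (data.frame: gene_id, species, chrom, strand, exon_bp) and
#'   `exons` (a `GRanges` on hybrid chromosome names with `gene_id` and
#'   `species` metadata columns).
#' @export
build_hybrid_reference <- function(fasta_a, fasta_b, gtf_a, gtf_b,
                                   prefix = "xla_",
                                   species = c("speciesA", "speciesB")) {
  sa <- Biostrings::readDNAStringSet(fasta_a)
  sb <- Biostrings::readDNAStringSet(fasta_b)
  if (length(sa) == 0 || length(sb) == 0) stop("empty genome FASTA")
  names(sa) <- sub("\\s.*$", "", names(sa))
  names(sb) <- paste0(prefix, sub("\\s.*$", "", names(sb)))
  if (any(names(sb) %in% names(sa)) ||
      anyDuplicated(c(names(sa), names(sb))))
    stop("chromosome name collision after prefixing")
  seqs <- c(sa, sb)

  read_exons <- function(gtf, sp, rename = identity) {
    gr <- rtracklayer::import(gtf, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0) stop("no exon records in ", gtf)
    GenomicRanges::GRanges(
      seqnames = rename(as.character(GenomicRanges::seqnames(gr))),
      ranges = IRanges::ranges(gr),
      strand = GenomicRanges::strand(gr),
      gene_id = gr$gene_id, species = sp)
  }
  exons <- suppressWarnings(
    c(read_exons(gtf_a, species[1]),
      read_exons(gtf_b, species[2], function(x) paste0(prefix, x))))

  chrom_of <- as.character(GenomicRanges::seqnames(exons))
  if (!all(chrom_of %in% names(seqs)))
    stop("gene annotation references missing chromosome: ",
         paste(unique(setdiff(chrom_of, names(seqs))), collapse = ", "))
  clen <- Biostrings::width(seqs)[match(chrom_of, names(seqs))]
  if (any(GenomicRanges::start(exons) < 1) ||
      any(GenomicRanges::end(exons) > clen))
    stop("exon interval outside chromosome bounds")

  per_gene <- S4Vectors::split(exons, exons$gene_id)
  exon_bp <- vapply(per_gene, function(g)
    sum(IRanges::width(IRanges::reduce(IRanges::ranges(g)))), numeric(1))
  if (any(exon_bp <= 0)) stop("gene with zero exonic length")
  first <- !duplicated(exons$gene_id)
  genes <- data.frame(gene_id = exons$gene_id[first],
                      species = exons$species[first],
                      chrom = chrom_of[first],
                      strand = as.character(GenomicRanges::strand(exons))[first],
                      exon_bp = as.numeric(exon_bp[exons$gene_id[first]]),
                      row.names = NULL)
  if (anyDuplicated(genes$gene_id))
    stop("gene_id shared between species: annotate uniquely per species")
  structure(list(seqs = seqs, genes = genes, exons = exons,
                 species = species, prefix = prefix),
            class = "gv_hybrid_reference")
}

#' @export
print.gv_hybrid_reference <- function(x, ...) {
  cat(sprintf("gv_hybrid_reference: %d chromosomes (%s bp), %d genes\n",
              length(x$seqs), format(sum(Biostrings::width(x$seqs)),
                                     big.mark = ","), nrow(x$genes)))
  cat(sprintf("species: %s (%d genes), %s (%d genes, chromosome prefix '%s')\n",
              x$species[1], sum(x$genes$species == x$species[1]),
              x$species[2], sum(x$genes$species == x$species[2]), x$prefix))
  invisible(x)
}

# k-mer sets of a DNAStringSet (forward strand), as a character vector
.genome_kmers <- function(seqs, k) {
  unlist(lapply(as.character(seqs), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
}

# k-mer -> gene_id map over exonic sequence; k-mers seen in >1 gene map to NA
.exon_kmer_map <- function(ref, sp, k) {
  ex <- ref$exons[ref$exons$species == sp]
  km <- character(0); gene <- character(0)
  for (i in seq_along(ex)) {
    s <- as.character(Biostrings::subseq(
      ref$seqs[[as.character(GenomicRanges::seqnames(ex[i]))]],
      GenomicRanges::start(ex[i]), GenomicRanges::end(ex[i])))
    n <- nchar(s)
    if (n < k) next
    kk <- substring(s, 1:(n - k + 1), k:n)
    km <- c(km, kk); gene <- c(gene, rep(ex$gene_id[i], length(kk)))
  }
  # a k-mer is gene-unique if all its occurrences carry the same gene_id
  tab <- tapply(gene, km, function(g) if (length(unique(g)) == 1) g[1]
                else NA_character_)
  stats::setNames(as.character(tab), names(tab))
}

#' Assign reads to species and gene by unique k-mer content
#'
#' A desk-scale surrogate for alignment to the hybrid genome: each read's
#' k-mers (both strands) are looked up in the two species' k-mer sets. Reads
#' whose k-mers hit exactly one species are labelled with it; k-mer hits in
#' both species make the read `ambiguous`; no hits anywhere, `unassigned`.
#' A species-labelled read additionally receives a `gene_id` when all k-mers
#' of one of its strands fall inside a single gene's exons (union counting
#' semantics: exonic k-mers shared between genes disqualify).
#'
#' @param fastq path to a single-end FASTQ file.
#' @param ref a [build_hybrid_reference()] result.
#' @param k k-mer length (default 25); must not exceed the read length.
#' @return A data.frame of class `gv_read_assignment` with columns
#'   `read_id`, `label` (species A label, species B label, `ambiguous` or
#'   `unassigned`) and `gene_id` (NA unless uniquely exonic).
#' @export
assign_reads <- function(fastq, ref, k = 25) {
  stopifnot(inherits(ref, "gv_hybrid_reference"))
  if (k < 1) stop("k must be >= 1")
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  if (length(reads) == 0) stop("empty FASTQ")
  if (k > min(Biostrings::width(reads)))
    stop("k exceeds the shortest read length")
  is_b <- startsWith(names(ref$seqs), ref$prefix)
  kmA <- unique(.genome_kmers(ref$seqs[!is_b], k))
  kmB <- unique(.genome_kmers(ref$seqs[is_b], k))
  if (length(kmA) == 0 && length(kmB) == 0) stop("empty reference index")
  mapA <- .exon_kmer_map(ref, ref$species[1], k)
  mapB <- .exon_kmer_map(ref, ref$species[2], k)

  read_kmers <- function(ss) {
    ch <- as.character(ss)
    lapply(ch, function(s) {
      n <- nchar(s)
      substring(s, 1:(n - k + 1), k:n)
    })
  }
  fwd <- read_kmers(reads)
  rev <- read_kmers(Biostrings::reverseComplement(reads))
  idx <- rep(seq_along(reads), lengths(fwd))
  all_f <- unlist(fwd, use.names = FALSE)
  all_r <- unlist(rev, use.names = FALSE)

  fA <- all_f %in% kmA; fB <- all_f %in% kmB
  rA <- all_r %in% kmA; rB <- all_r %in% kmB
  hitA <- as.logical(tapply(fA | rA, idx, any))
  hitB <- as.logical(tapply(fB | rB, idx, any))
  label <- ifelse(hitA & hitB, "ambiguous",
           ifelse(hitA, ref$species[1],
           ifelse(hitB, ref$species[2], "unassigned")))

  gene_id <- rep(NA_character_, length(reads))
  ia <- which(label == ref$species[1])
  if (length(ia))
    gene_id[ia] <- vapply(ia, function(i)
      .read_gene(fwd[[i]], rev[[i]], mapA), character(1))
  ib <- which(label == ref$species[2])
  if (length(ib))
    gene_id[ib] <- vapply(ib, function(i)
      .read_gene(fwd[[i]], rev[[i]], mapB), character(1))

  out <- data.frame(read_id = sub("\\s.*$", "", names(reads)),
                    label = label, gene_id = gene_id, row.names = NULL)
  attr(out, "species") <- ref$species
  class(out) <- c("gv_read_assignment", "data.frame")
  out
}

# gene for one species-labelled read: a strand qualifies when every k-mer is
# exonic and gene-unique for the same single gene
.read_gene <- function(kf, kr, map) {
  for (kk in list(kf, kr)) {
    if (!all(kk %in% names(map))) next
    g <- map[kk]
    if (!anyNA(g) && length(unique(g)) == 1) return(unname(g[1]))
  }
  NA_character_
}

#' Count uniquely assigned reads per gene
#'
#' Tabulates [assign_reads()] results into a gene-by-sample count matrix over
#' the hybrid annotation. Ambiguous and unassigned reads are excluded from
#' gene counts but tallied, and per-sample species totals are reported, so
#' that species A + species B + ambiguous + unassigned equals the read total.
#'
#' @param assignments a `gv_read_assignment` or a named list of them (one per
#'   sample).
#' @param ref the [build_hybrid_reference()] used for assignment.
#' @param samples optional metadata data.frame (see [gv_counts()]); defaults
#'   to minimal placeholder metadata named by sample.
#' @return A [gv_counts()] whose genes are the hybrid annotation's genes, with
#'   attribute `species_totals`: data.frame per sample of species A, species
#'   B, ambiguous, unassigned and total read tallies.
#' @export
count_by_gene <- function(assignments, ref, samples = NULL) {
  stopifnot(inherits(ref, "gv_hybrid_reference"))
  if (inherits(assignments, "gv_read_assignment"))
    assignments <- list(sample1 = assignments)
  if (is.null(names(assignments)) || anyDuplicated(names(assignments)))
    stop("assignments must be a uniquely named list, one entry per sample")
  if (!is.null(samples) &&
      !setequal(samples$sample_id, names(assignments)))
    stop("sample metadata does not match assignment names")
  gid <- ref$genes$gene_id
  m <- vapply(assignments, function(a) {
    counted <- a$gene_id[a$label %in% ref$species & !is.na(a$gene_id)]
    as.integer(table(factor(counted, levels = gid)))
  }, integer(length(gid)))
  m <- matrix(m, nrow = length(gid),
              dimnames = list(gid, names(assignments)))
  totals <- do.call(rbind, lapply(names(assignments), function(s) {
    a <- assignments[[s]]
    data.frame(sample_id = s,
               species_a = sum(a$label == ref$species[1]),
               species_b = sum(a$label == ref$species[2]),
               ambiguous = sum(a$label == "ambiguous"),
               unassigned = sum(a$label == "unassigned"),
               total = nrow(a))
  }))
  if (is.null(samples))
    samples <- data.frame(sample_id = names(assignments),
                          cell_type = "unknown", condition = "NT",
                          timepoint = "24h",
                          replicate = seq_along(assignments),
                          female_id = "F1")
  out <- gv_counts(m, stats::setNames(ref$genes$exon_bp, gid), samples)
  attr(out, "species_totals") <- totals
  out
}
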