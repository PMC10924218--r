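fixture <- local({
  d <- file.path(tempdir(), "gv_fixture")
  write_fixture_genome(d, seed = 3, n_genes_per_species = 6, n_reads = 300)
})

test_that("fixture files are deterministic and reads round-trip", {
  d2 <- file.path(tempdir(), "gv_fixture2")
  fx2 <- write_fixture_genome(d2, seed = 3, n_genes_per_species = 6,
                              n_reads = 300)
  expect_identical(unname(tools::md5sum(c(fixture$fasta, fixture$gtf,
                                          fixture$fastq))),
                   unname(tools::md5sum(c(fx2$fasta, fx2$gtf, fx2$fastq))))
  parsed <- parse_fixture_read_names(fixture$truth$read_id)
  expect_identical(parsed$species, fixture$truth$species)
  expect_identical(parsed$gene_id, fixture$truth$gene_id)
})

test_that("disjoint genomes give species-unique read sequences", {
  reads <- Biostrings::readDNAStringSet(fixture$fastq, format = "fastq")
  ga <- Biostrings::readDNAStringSet(fixture$fasta[1])
  gb <- Biostrings::readDNAStringSet(fixture$fasta[2])
  hits <- function(genome, r) sum(Biostrings::vcountPattern(r, genome)) > 0
  set.seed(1)
  for (i in sample(length(reads), 25)) {
    in_a <- hits(ga, reads[[i]])
    in_b <- hits(gb, reads[[i]])
    expect_true(xor(in_a, in_b))
  }
})

test_that("hybrid reference prefixes species B and preserves lengths", {
  ref <- build_hybrid_reference(fixture$fasta[1], fixture$fasta[2],
                                fixture$gtf[1], fixture$gtf[2])
  expect_identical(names(ref$seqs),
                   c("chr1", "chr2", "xla_chr1", "xla_chr2"))
  la <- sum(Biostrings::width(Biostrings::readDNAStringSet(fixture$fasta[1])))
  lb <- sum(Biostrings::width(Biostrings::readDNAStringSet(fixture$fasta[2])))
  expect_equal(sum(Biostrings::width(ref$seqs)), la + lb)
  expect_setequal(unique(ref$genes$species), c("speciesA", "speciesB"))
  expect_true(all(ref$genes$exon_bp > 0))
})

test_that("a pre-existing prefixed name collides", {
  d <- tempfile()
  dir.create(d)
  # species A already carries an xla_-prefixed chromosome name
  writeLines(c(">xla_chr1", strrep("ACGT", 100)),
             file.path(d, "a.fa"))
  file.copy(fixture$fasta[2], file.path(d, "b.fa"))
  expect_error(build_hybrid_reference(file.path(d, "a.fa"),
                                      file.path(d, "b.fa"),
                                      fixture$gtf[1], fixture$gtf[2]),
               "collision")
})

test_that("GTF round trip preserves exon intervals exactly", {
  gr <- rtracklayer::import(fixture$gtf[1], format = "gtf")
  tmp <- tempfile(fileext = ".gtf")
  rtracklayer::export(gr, tmp, format = "gtf")
  gr2 <- rtracklayer::import(tmp, format = "gtf")
  expect_equal(GenomicRanges::start(gr), GenomicRanges::start(gr2))
  expect_equal(GenomicRanges::end(gr), GenomicRanges::end(gr2))
})

test_that("k-mer assignment recovers species and gene from fixture reads", {
  ref <- build_hybrid_reference(fixture$fasta[1], fixture$fasta[2],
                                fixture$gtf[1], fixture$gtf[2])
  asn <- assign_reads(fixture$fastq, ref, k = 25)
  truth <- parse_fixture_read_names(asn$read_id)
  expect_gte(mean(asn$label == truth$species), 0.99)
  expect_gte(mean(!is.na(asn$gene_id) & asn$gene_id == truth$gene_id), 0.99)
  # conservation identity
  tab <- table(factor(asn$label, levels = c("speciesA", "speciesB",
                                            "ambiguous", "unassigned")))
  expect_equal(sum(tab), nrow(asn))
})

test_that("shared-segment reads are ambiguous, foreign reads unassigned", {
  d <- file.path(tempdir(), "gv_fixture_shared")
  fx <- write_fixture_genome(d, seed = 5, n_genes_per_species = 4,
                             shared_segment_length = 400, n_reads = 50)
  ref <- build_hybrid_reference(fx$fasta[1], fx$fasta[2],
                                fx$gtf[1], fx$gtf[2])
  ga <- Biostrings::readDNAStringSet(fx$fasta[1])
  shared_read <- Biostrings::DNAStringSet(
    Biostrings::subseq(ga[["chr1"]], 10, 59))
  names(shared_read) <- "shared"
  # a read not present in either genome
  set.seed(99)
  random_read <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = ""))
  names(random_read) <- "foreign"
  fq <- tempfile(fileext = ".fastq")
  Biostrings::writeXStringSet(c(shared_read, random_read), fq,
                              format = "fastq",
                              qualities = Biostrings::BStringSet(
                                rep(strrep("I", 50), 2)))
  asn <- assign_reads(fq, ref, k = 25)
  expect_identical(asn$label, c("ambiguous", "unassigned"))
  expect_true(all(is.na(asn$gene_id)))
})

test_that("counting excludes ambiguous reads and matches truth tallies", {
  ref <- build_hybrid_reference(fixture$fasta[1], fixture$fasta[2],
                                fixture$gtf[1], fixture$gtf[2])
  asn <- assign_reads(fixture$fastq, ref, k = 25)
  cm <- count_by_gene(asn, ref)
  truth <- parse_fixture_read_names(asn$read_id)
  expected <- table(factor(truth$gene_id, levels = rownames(cm$counts)))
  expect_equal(unname(cm$counts[, 1]), as.integer(expected))
  st <- attr(cm, "species_totals")
  expect_equal(st$species_a + st$species_b + st$ambiguous + st$unassigned,
               st$total)
  # all-ambiguous input gives a zero matrix with a nonzero tally
  asn2 <- asn
  asn2$label <- "ambiguous"; asn2$gene_id <- NA_character_
  cm2 <- count_by_gene(asn2, ref)
  expect_true(all(cm2$counts == 0))
  expect_equal(attr(cm2, "species_totals")$ambiguous, nrow(asn2))
})

test_that("assignment input validation", {
  ref <- build_hybrid_reference(fixture$fasta[1], fixture$fasta[2],
                                fixture$gtf[1], fixture$gtf[2])
  expect_error(assign_reads(fixture$fastq, ref, k = 0), "k must be")
  expect_error(assign_reads(fixture$fastq, ref, k = 100), "read length")
})
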