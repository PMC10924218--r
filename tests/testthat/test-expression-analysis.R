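meta1 <- function(ids, ct = "MEF", cond = "NT") {
  data.frame(sample_id = ids, cell_type = ct, condition = cond,
             timepoint = "24h", replicate = seq_along(ids), female_id = "F1")
}

test_that("TPM normalization follows the definitional formula", {
  # single gene: the whole budget
  x <- gv_counts(matrix(7, 1, 1, dimnames = list("g1", "s1")),
                 c(g1 = 500), meta1("s1"))
  expect_equal(compute_tpm(x)$tpm[1, 1], 1e6)
  # 2:1 rate ratio from lengths 1000 / 2000 at equal counts
  x2 <- gv_counts(matrix(c(10, 10), 2, 1,
                         dimnames = list(c("g1", "g2"), "s1")),
                  c(g1 = 1000, g2 = 2000), meta1("s1"))
  expect_equal(unname(compute_tpm(x2)$tpm[, 1]),
               c(2e6 / 3, 1e6 / 3), tolerance = 1e-12)
  # random matrix equals the independent oracle; columns sum to 1e6
  set.seed(42)
  m <- matrix(rpois(200, 30), 50, 4,
              dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:4)))
  len <- sample(200:2000, 50)
  x3 <- gv_counts(m, setNames(len, rownames(m)), meta1(paste0("s", 1:4)))
  tpm <- compute_tpm(x3)$tpm
  expect_equal(tpm, oracle_tpm(m, len))
  expect_equal(unname(colSums(tpm)), rep(1e6, 4))
})

test_that("an all-zero sample is an error", {
  m <- matrix(c(5, 0), 1, 2, dimnames = list("g1", c("a", "b")))
  x <- gv_counts(m, c(g1 = 100), meta1(c("a", "b")))
  expect_error(compute_tpm(x), "zero total")
})

test_that("inducibility thresholds the replicate-mean NT expression", {
  tpm <- matrix(c(0.2, 0.4, 0.3,
                  2.0, 1.5, 2.5), 2, 3, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("s", 1:3)))
  expr <- make_tpm(tpm, "ESC", "NT")
  ind <- call_inducible(expr, classification_config(), "ESC")
  expect_identical(ind$sets$ESC, "g2")   # g1 mean 0.3 < 1
})

test_that("Venn regions agree with brute-force set enumeration", {
  sim <- simulate_expression(expr_sim_config(n_genes = 800, seed = 1))
  expr <- compute_tpm(sim$counts)
  ind <- call_inducible(expr)
  ora <- oracle_venn(ind$sets)
  expect_mapequal(as.list(ind$venn), as.list(ora))
  expect_equal(ind$union_size, length(unique(unlist(ind$sets))))
  expect_equal(ind$intersection_size,
               length(Reduce(intersect, ind$sets)))
})

test_that("all genes inducible everywhere collapses the Venn to the union", {
  tpm <- matrix(5, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  tpm <- tpm + matrix(runif(24), 4)   # avoid zero variance edge elsewhere
  expr <- make_tpm(tpm, rep(c("ESC", "MEF", "MYO"), each = 2), "NT")
  ind <- call_inducible(expr)
  expect_equal(ind$intersection_size, 4)
  expect_equal(ind$union_size, 4)
  expect_equal(unname(ind$venn["ESC&MEF&MYO"]), 4L)
})

test_that("response classes follow the definitional rules and partition", {
  tpm <- cbind(donor = c(0, 10, 40, 7), nt = c(50, 80, 9, 7))
  rownames(tpm) <- paste0("g", 1:4)
  expr <- make_tpm(tpm, "MEF", c("donor", "NT"))
  rt <- classify_response(expr, classification_config(), "MEF")
  expect_identical(rt$class, c("activated", "enhanced", "repressed",
                               "unchanged"))
  expect_true(all(table(rt$gene_id) == 1))   # exactly one class per gene
  s <- attr(rt, "summary")
  expect_equal(sum(s$percent), 100)
})

test_that("resistance rule, exclusion and monotonicity", {
  # inducible in ESC+MEF, silent in MYO, not repressed there -> resistant
  tpm <- cbind(esc_d = c(1, 5), esc_n = c(100, 5),
               mef_d = c(1, 5), mef_n = c(120, 5),
               myo_d = c(4, 5), myo_n = c(5, 5))
  rownames(tpm) <- c("g1", "g2")
  expr <- make_tpm(tpm, rep(c("ESC", "MEF", "MYO"), each = 2),
                   rep(c("donor", "NT"), 3))
  res <- find_resistant(expr)
  expect_identical(res$sets$MYO, "g1")       # (111)/(6) >= 4
  # a gene equal across all NT samples is resistant nowhere
  expect_false("g2" %in% unlist(res$sets))
  # repressed-in-focal genes are excluded even at large fold change
  tpm2 <- cbind(esc_d = 1, esc_n = 100, mef_d = 1, mef_n = 120,
                myo_d = 40, myo_n = 5)
  rownames(tpm2) <- "g1"
  expr2 <- make_tpm(tpm2, rep(c("ESC", "MEF", "MYO"), each = 2),
                    rep(c("donor", "NT"), 3))
  expect_length(find_resistant(expr2)$sets$MYO, 0)
  # raising fc_resist never grows a resistant set
  sim <- simulate_expression(expr_sim_config(n_genes = 600, seed = 9))
  expr3 <- compute_tpm(sim$counts)
  r4 <- find_resistant(expr3, classification_config(fc_resist = 4))
  r8 <- find_resistant(expr3, classification_config(fc_resist = 8))
  for (ct in names(r4$sets))
    expect_true(all(r8$sets[[ct]] %in% r4$sets[[ct]]))
  # and raising tpm_inducible never grows an inducible set
  i1 <- call_inducible(expr3, classification_config(tpm_inducible = 1))
  i5 <- call_inducible(expr3, classification_config(tpm_inducible = 5))
  for (ct in names(i1$sets))
    expect_true(all(i5$sets[[ct]] %in% i1$sets[[ct]]))
})

test_that("both resistance modes agree with a per-gene brute-force oracle", {
  sim <- simulate_expression(expr_sim_config(n_genes = 300, seed = 10))
  expr <- compute_tpm(sim$counts)
  cfg <- classification_config()
  cts <- c("ESC", "MEF", "MYO")
  nt <- vapply(cts, function(ct) {
    s <- expr$samples
    rowMeans(expr$tpm[, s$sample_id[s$cell_type == ct & s$condition == "NT"]])
  }, numeric(nrow(expr$tpm)))
  repressed <- vapply(cts, function(ct)
    classify_response(expr, cfg, ct)$class == "repressed",
    logical(nrow(expr$tpm)))
  rm_ <- find_resistant(expr, cfg, mode = "mean")
  rp <- find_resistant(expr, cfg, mode = "pairwise")
  for (ct in cts) {
    others <- setdiff(cts, ct)
    ora_mean <- ora_pair <- logical(nrow(nt))
    for (g in seq_len(nrow(nt))) {
      ind_other <- nt[g, others] >= 1
      if (!any(ind_other) || repressed[g, ct]) next
      ora_mean[g] <- (mean(nt[g, others]) + 1) / (nt[g, ct] + 1) >= 4
      ora_pair[g] <- all((nt[g, others][ind_other] + 1) /
                           (nt[g, ct] + 1) >= 4)
    }
    expect_setequal(rm_$sets[[ct]], rownames(expr$tpm)[ora_mean])
    expect_setequal(rp$sets[[ct]], rownames(expr$tpm)[ora_pair])
  }
})

test_that("sample correlations match the definitional Pearson formula", {
  set.seed(7)
  tpm <- matrix(rexp(100, 1 / 50), 50, 2,
                dimnames = list(sprintf("g%02d", 1:50), c("a", "b")))
  expr <- make_tpm(tpm, c("ESC", "MEF"), "NT")
  pairs <- data.frame(cell_type_1 = c("ESC", "ESC"),
                      condition_1 = "NT",
                      cell_type_2 = c("ESC", "MEF"), condition_2 = "NT")
  r <- correlate_samples(expr, pairs)$r
  expect_equal(r[1], 1)
  x <- log2(tpm[, 1] + 1); y <- log2(tpm[, 2] + 1)
  r_ora <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r[2], r_ora)
  # an exactly reversed profile correlates at -1
  expr2 <- make_tpm(cbind(a = tpm[, 1], b = max(tpm[, 1]) - tpm[, 1] + 1),
                    c("ESC", "MEF"), "NT")
  # build on the log scale directly for exact linearity
  expr2$tpm[, "b"] <- 2^(10 - log2(expr2$tpm[, "a"] + 1)) - 1
  expect_equal(correlate_samples(expr2, pairs[2, ])$r, -1)
})

test_that("top_expressed sorts by mean TPM with lexicographic ties", {
  tpm <- matrix(c(5, 5, 9, 1), 4, 1,
                dimnames = list(c("gB", "gA", "gC", "gD"), "s1"))
  expr <- make_tpm(tpm, "MYO", "NT")
  expect_identical(top_expressed(expr, "MYO", n = 4),
                   c("gC", "gA", "gB", "gD"))
  expect_error(top_expressed(expr, "MYO", n = 5), "exceeds")
  set.seed(12)
  tpm2 <- matrix(rexp(60), 30, 2,
                 dimnames = list(sprintf("g%02d", 1:30), c("a", "b")))
  expr2 <- make_tpm(tpm2, "MYO", "NT")
  ora <- names(sort(rowMeans(tpm2), decreasing = TRUE))[1:10]
  expect_identical(top_expressed(expr2, "MYO", n = 10), ora)
})

test_that("average-linkage ordering merges the most correlated pair first", {
  set.seed(3)
  a <- rexp(40, 1 / 20)
  tpm <- cbind(s1 = a, s2 = a * 1.02 + 0.3, s3 = rev(a) + runif(40))
  rownames(tpm) <- sprintf("g%02d", 1:40)
  expr <- make_tpm(tpm, c("ESC", "ESC", "MYO"), "NT")
  ord <- cluster_order(expr)
  m <- log2(tpm + 1)
  d <- 1 - cor(m)
  first_pair <- oracle_avg_linkage3(d)
  expect_equal(sort(ord$sample_tree$merge[1, ]), sort(-first_pair))
  # the near-identical pair ends up adjacent in the leaf order
  expect_equal(abs(diff(match(c("s1", "s2"), ord$sample_order))), 1)
  expect_error(cluster_order(make_tpm(matrix(1, 3, 2,
                                             dimnames = list(paste0("g", 1:3),
                                                             c("a", "b"))),
                                      "ESC", "NT")),
               "constant")
})

test_that("replicates of one condition cluster into contiguous blocks", {
  sim <- simulate_expression(expr_sim_config(n_genes = 800, seed = 5))
  expr <- compute_tpm(sim$counts)
  ord <- cluster_order(expr)
  s <- expr$samples
  grp <- paste(s$cell_type, s$condition)[match(ord$sample_order,
                                               s$sample_id)]
  # each (cell type, condition) group occupies one contiguous leaf block
  expect_equal(sum(grp[-1] != grp[-length(grp)]) + 1, length(unique(grp)))
})

test_that("TSV round trip preserves the count container", {
  sim <- simulate_expression(expr_sim_config(n_genes = 50, seed = 2))
  fc <- tempfile(fileext = ".tsv"); fm <- tempfile(fileext = ".tsv")
  write_counts_tsv(sim$counts, fc, fm)
  back <- read_counts_tsv(fc, fm)
  expect_equal(back$counts, sim$counts$counts)
  expect_equal(back$gene_length, sim$counts$gene_length)
  expect_equal(back$samples$cell_type, sim$counts$samples$cell_type)
})
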