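# Independent brute-force oracles, written directly from the definitions and
# kept free of the package's vectorized implementations.

# Huang fuzziness: scalar loop over candidate splits and gray levels
oracle_huang <- function(v) {
  lev <- sort(unique(v))
  C <- max(lev) - min(lev)
  best <- Inf; best_t <- NA
  for (i in seq_len(length(lev) - 1)) {
    lo <- v[v <= lev[i]]; hi <- v[v > lev[i]]
    mu0 <- mean(lo); mu1 <- mean(hi)
    S <- 0
    for (g in v) {
      mu <- if (g <= lev[i]) mu0 else mu1
      u <- 1 / (1 + abs(g - mu) / C)
      if (u > 0 && u < 1) S <- S - u * log(u) - (1 - u) * log(1 - u)
    }
    if (S < best) { best <- S; best_t <- (lev[i] + lev[i + 1]) / 2 }
  }
  best_t
}

# Otsu between-class variance: scalar loop over candidate splits
oracle_otsu <- function(v) {
  lev <- sort(unique(v))
  best <- -Inf; best_t <- NA
  for (i in seq_len(length(lev) - 1)) {
    lo <- v[v <= lev[i]]; hi <- v[v > lev[i]]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best) { best <- sb; best_t <- (lev[i] + lev[i + 1]) / 2 }
  }
  best_t
}

# chained restricted-histogram multilevel Otsu via the scalar oracle
oracle_iterative_otsu <- function(v, n_thresholds = 3) {
  th <- numeric(0); sub <- v
  for (i in seq_len(n_thresholds)) {
    t_i <- oracle_otsu(sub)
    th <- c(th, t_i)
    sub <- sub[sub >= t_i]
  }
  th
}

# exhaustive average-linkage merge sequence for three items
oracle_avg_linkage3 <- function(d) {
  # d: 3x3 distance matrix; returns indices of the first merged pair
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  dv <- vapply(pairs, function(p) d[p[1], p[2]], numeric(1))
  pairs[[which.min(dv)]]
}

# definitional TPM from counts and lengths
oracle_tpm <- function(counts, len) {
  out <- counts
  for (j in seq_len(ncol(counts))) {
    r <- counts[, j] / len
    out[, j] <- r / sum(r) * 1e6
  }
  out
}

# brute-force Venn region counts by set enumeration
oracle_venn <- function(sets) {
  universe <- unique(unlist(sets))
  regions <- list()
  for (g in universe) {
    key <- paste(names(sets)[vapply(sets, function(s) g %in% s, logical(1))],
                 collapse = "&")
    regions[[key]] <- c(regions[[key]], g)
  }
  vapply(regions, length, integer(1))
}

# a minimal gv_tpm object for rule-level unit tests
make_tpm <- function(tpm, cell_type, condition, timepoint = "24h") {
  samples <- data.frame(sample_id = colnames(tpm), cell_type = cell_type,
                        condition = condition, timepoint = timepoint,
                        replicate = seq_len(ncol(tpm)), female_id = "F1")
  structure(list(tpm = tpm, samples = samples), class = "gv_tpm")
}

# truth table for one cell type from a simulate_expression result
truth_for <- function(sim, ct) {
  tr <- sim$truth$assignments
  tr[tr$cell_type == ct, ]
}
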