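#' Huang fuzzy threshold
#'
#' Automatic binarization threshold minimizing Huang's measure of fuzziness:
#' for each candidate split of the gray-level histogram, pixels get a fuzzy
#' membership to their class built from the class mean,
#' `u = 1 / (1 + |g - mu_class| / C)` with `C` the gray-level range, and the
#' histogram-weighted Shannon entropy `-u log u - (1-u) log(1-u)` is summed.
#' The returned threshold is the midpoint between the optimal split level and
#' the next occupied level (ties resolved toward the lowest split), so that
#' `image >= threshold` is the foreground.
#'
#' @param image numeric matrix or vector of integer-valued gray levels
#'   (0..65535 range supported; typically 8-bit).
#' @return A single numeric threshold.
#' @export
huang_threshold <- function(image) {
  v <- as.vector(image)
  v <- v[!is.na(v)]
  lev <- sort(unique(v))
  if (length(lev) < 2) stop("constant image: threshold undefined")
  h <- as.numeric(table(factor(v, levels = lev)))
  C <- lev[length(lev)] - lev[1]
  cs <- cumsum(h); cm <- cumsum(h * lev)
  tot <- cs[length(cs)]; totm <- cm[length(cm)]
  ent <- function(u) {
    s <- numeric(length(u))
    i <- u > 0 & u < 1
    s[i] <- -u[i] * log(u[i]) - (1 - u[i]) * log(1 - u[i])
    s
  }
  best <- Inf; best_i <- NA_integer_
  for (i in seq_len(length(lev) - 1)) {
    mu0 <- cm[i] / cs[i]
    mu1 <- (totm - cm[i]) / (tot - cs[i])
    u <- ifelse(seq_along(lev) <= i,
                1 / (1 + abs(lev - mu0) / C),
                1 / (1 + abs(lev - mu1) / C))
    S <- sum(h * ent(u))
    if (S < best) { best <- S; best_i <- i }
  }
  (lev[best_i] + lev[best_i + 1]) / 2
}

# Otsu split on a vector of gray values: maximizes between-class variance
# w0*w1*(mu0-mu1)^2 over all splits; ties toward the lowest; returns the
# midpoint between the optimal split level and the next occupied level.
.otsu_split <- function(v) {
  lev <- sort(unique(v))
  if (length(lev) < 2) stop("fewer than two gray levels: Otsu undefined")
  h <- as.numeric(table(factor(v, levels = lev)))
  cs <- cumsum(h); cm <- cumsum(h * lev)
  tot <- cs[length(cs)]; totm <- cm[length(cm)]
  i <- seq_len(length(lev) - 1)
  w0 <- cs[i] / tot; w1 <- 1 - w0
  mu0 <- cm[i] / cs[i]; mu1 <- (totm - cm[i]) / (tot - cs[i])
  sb <- w0 * w1 * (mu0 - mu1)^2
  best_i <- which.max(sb)   # first maximum: ties resolve to the lowest split
  (lev[best_i] + lev[best_i + 1]) / 2
}

#' Iterative restricted-histogram multi-level Otsu density classification
#'
#' Classifies chromatin into density levels by chaining Otsu thresholds:
#' the first threshold maximizes between-class variance on the full (masked)
#' histogram; each subsequent threshold re-runs Otsu on the histogram
#' restricted to values at or above the previous threshold. With the default
#' three thresholds the first cut separates background from chromatin and the
#' remaining two partition chromatin into loose, middle and dense classes.
#'
#' @param image numeric matrix of gray levels.
#' @param mask optional logical matrix restricting the histogram (the class
#'   map itself is purely threshold-based, per-pixel).
#' @param n_thresholds number of chained thresholds (default 3).
#' @return An object of class `gv_density_partition`: list with `thresholds`
#'   (strictly increasing, named `t_bg`, `t_mid`, `t_dense` when 3) and
#'   `class_map` (integer matrix, 0 = background, 1 = loose, 2 = middle,
#'   3 = dense).
#' @export
iterative_otsu <- function(image, mask = NULL, n_thresholds = 3) {
  v <- as.vector(image)
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(image)))
    v <- v[as.vector(mask) > 0]
  }
  v <- v[!is.na(v)]
  th <- numeric(0)
  sub <- v
  for (i in seq_len(n_thresholds)) {
    if (length(unique(sub)) < 2)
      stop("restricted histogram collapsed to fewer than two levels ",
           "before reaching ", n_thresholds, " thresholds")
    t_i <- .otsu_split(sub)
    th <- c(th, t_i)
    sub <- sub[sub >= t_i]
  }
  if (any(diff(th) <= 0)) stop("thresholds not strictly increasing")
  if (n_thresholds == 3) names(th) <- c("t_bg", "t_mid", "t_dense")
  cm <- matrix(findInterval(image, th), nrow = nrow(image))
  structure(list(thresholds = th, class_map = cm),
            class = "gv_density_partition")
}

#' @export
print.gv_density_partition <- function(x, ...) {
  cat("gv_density_partition; thresholds:",
      paste(sprintf("%s=%.1f", names(x$thresholds), x$thresholds),
            collapse = ", "), "\n")
  tab <- table(factor(x$class_map, levels = 0:length(x$thresholds)))
  lab <- c("background", "loose", "middle", "dense")[1:length(tab)]
  cat(paste(sprintf("%s: %d px", lab, as.integer(tab)), collapse = ", "),
      "\n")
  invisible(x)
}
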