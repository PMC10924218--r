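#' Per-cell chromatin area from a density partition
#'
#' Chromatin area of a cell is the number of non-background density-class
#' pixels inside its segment (or, without a segmentation, in the whole
#' image), times the pixel area.
#'
#' @param partition a [iterative_otsu()] density partition.
#' @param seg optional [recursive_watershed()] segmentation; if supplied, one
#'   area per segment is returned, otherwise a single whole-image total.
#' @param pixel_size px edge length in microns (areas then in square microns;
#'   default 1, i.e. areas in px).
#' @return Numeric vector of chromatin areas.
#' @export
measure_chromatin_area <- function(partition, seg = NULL, pixel_size = 1) {
  stopifnot(inherits(partition, "gv_density_partition"))
  fg <- partition$class_map > 0
  px_area <- pixel_size^2
  if (is.null(seg)) return(sum(fg) * px_area)
  vapply(seg$segments, function(s) sum(fg[s$pixels]) * px_area, numeric(1))
}

#' Compare chromatin areas between two groups
#'
#' Group summary of per-cell (or per-image) chromatin areas before and after
#' nuclear transfer: means, SDs, fold change of means, and an equal-variance
#' two-sample Student's t-test. Two identical zero-variance groups are
#' reported as no difference (t = 0, p = 1).
#'
#' @param areas_0,areas_1 numeric vectors of areas in the two groups (e.g.
#'   0 h and 24 h after transfer).
#' @return List of class `gv_area_comparison`: `mean_0`, `sd_0`, `mean_1`,
#'   `sd_1`, `fold_change` (`mean_1 / mean_0`), `t`, `p_value`, `n`.
#' @export
compare_chromatin_areas <- function(areas_0, areas_1) {
  if (!length(areas_0) || !length(areas_1)) stop("empty group")
  m0 <- mean(areas_0); m1 <- mean(areas_1)
  s0 <- stats::sd(areas_0); s1 <- stats::sd(areas_1)
  n0 <- length(areas_0); n1 <- length(areas_1)
  pooled <- if (n0 + n1 > 2)
    sqrt(((n0 - 1) * s0^2 + (n1 - 1) * s1^2) / (n0 + n1 - 2)) else 0
  if (is.na(pooled) || pooled == 0) {
    tt <- if (isTRUE(all.equal(m0, m1))) 0 else Inf
    p <- if (tt == 0) 1 else 0
  } else {
    tt <- (m1 - m0) / (pooled * sqrt(1 / n0 + 1 / n1))
    p <- 2 * stats::pt(-abs(tt), df = n0 + n1 - 2)
  }
  structure(list(mean_0 = m0, sd_0 = s0, mean_1 = m1, sd_1 = s1,
                 fold_change = m1 / m0, t = tt, p_value = p,
                 n = c(n0, n1)),
            class = "gv_area_comparison")
}

#' @export
print.gv_area_comparison <- function(x, ...) {
  cat(sprintf(
    "chromatin area: %.1f +/- %.1f -> %.1f +/- %.1f (fold change %.2f)\n",
    x$mean_0, x$sd_0, x$mean_1, x$sd_1, x$fold_change))
  cat(sprintf("Student's t = %.2f, p = %.3g (n = %d, %d)\n",
              x$t, x$p_value, x$n[1], x$n[2]))
  invisible(x)
}

#' HP1-alpha occupancy per chromatin density class
#'
#' Fraction of each density class's area occupied by HP1-alpha signal.
#' A pixel is HP1-positive when its HP1-channel intensity reaches the
#' threshold: by default an Otsu threshold computed on the HP1 channel within
#' chromatin (non-background) pixels; a fixed numeric cutoff may be supplied
#' instead.
#'
#' @param partition a [iterative_otsu()] density partition of the DNA channel.
#' @param hp1 HP1-channel matrix, same shape as the class map.
#' @param threshold `"otsu"` (default) or a fixed numeric intensity.
#' @return data.frame of class `gv_occupancy_profile` with one row per class
#'   (`loose`, `middle`, `dense`): `area_px`, `positive_px`, `occupancy`
#'   (NA, flagged in `defined`, for empty classes). The HP1 threshold used is
#'   stored in attribute `hp1_threshold`.
#' @export
hp1a_occupancy <- function(partition, hp1, threshold = "otsu") {
  stopifnot(inherits(partition, "gv_density_partition"))
  cm <- partition$class_map
  if (!all(dim(cm) == dim(hp1)))
    stop("class map and HP1 channel differ in shape")
  chrom <- cm > 0
  thr <- if (identical(threshold, "otsu")) .otsu_split(hp1[chrom])
         else as.numeric(threshold)
  pos <- hp1 >= thr
  out <- do.call(rbind, lapply(1:3, function(k) {
    a <- sum(cm == k)
    p <- sum(pos & cm == k)
    data.frame(class = c("loose", "middle", "dense")[k],
               area_px = a, positive_px = p,
               occupancy = if (a > 0) p / a else NA_real_,
               defined = a > 0)
  }))
  attr(out, "hp1_threshold") <- thr
  class(out) <- c("gv_occupancy_profile", "data.frame")
  out
}
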