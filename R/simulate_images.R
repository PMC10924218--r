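#' Configuration for the two-channel nuclear image simulator
#'
#' Defines the imaging-arm study conditions: fields of ellipse-shaped nuclei
#' (some placed in touching clusters), each with three concentric chromatin
#' density regimes in the DNA-stain channel and density-correlated HP1-alpha
#' positivity in the second channel.
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param n_nuclei total nuclei per image, including clustered ones.
#' @param cluster_spec list with `n_clusters` and `cluster_size`: how many
#'   touching-nuclei clusters and how many nuclei each.
#' @param radius_range px bounds for ellipse semi-axes. The default (14, 18)
#'   keeps single-nucleus areas (~620-1020 px) separated from the smallest
#'   touching pair (~1150 px), so an area gate between them is well defined.
#' @param overlap_spacing cluster center spacing as a fraction of the sum of
#'   the two nuclei's effective radii (< 1 produces touching nuclei).
#' @param density_fractions per-nucleus area fractions of the loose, middle
#'   and dense chromatin classes (innermost = dense); must sum to 1.
#' @param class_intensity_means DNA-channel mean intensity per class,
#'   strictly increasing; background is ~0.
#' @param hp1_occupancy per-class probability that a chromatin pixel is
#'   HP1-alpha positive; non-decreasing from loose to dense.
#' @param hp1_intensity HP1-channel intensity of positive pixels.
#' @param noise_sd additive Gaussian noise sd (both channels); images are
#'   rounded and clamped to 0..255.
#' @param dispersal_factor per-nucleus area scale factor of the paired
#'   post-transfer ("24 h") image set.
#' @param dispersal_hp1_factor multiplier applied to `hp1_occupancy` in the
#'   paired set (heterochromatin loss on dispersal).
#' @param seed RNG seed.
#' @return A list of class `gv_img_sim_config`.
#' @export
img_sim_config <- function(image_shape = c(512, 512), n_nuclei = 20,
                           cluster_spec = list(n_clusters = 3,
                                               cluster_size = 2),
                           radius_range = c(14, 18),
                           overlap_spacing = 0.8,
                           density_fractions = c(loose = 0.5, middle = 0.3,
                                                 dense = 0.2),
                           class_intensity_means = c(loose = 80,
                                                     middle = 150,
                                                     dense = 220),
                           hp1_occupancy = c(loose = 0.2, middle = 0.5,
                                             dense = 0.8),
                           hp1_intensity = 200,
                           noise_sd = 6,
                           dispersal_factor = 2,
                           dispersal_hp1_factor = 0.5,
                           seed = 1) {
  if (any(diff(class_intensity_means) <= 0))
    stop("class_intensity_means must be strictly increasing")
  if (any(diff(hp1_occupancy) < 0))
    stop("hp1_occupancy must be non-decreasing from loose to dense")
  if (any(hp1_occupancy < 0) || any(hp1_occupancy > 1))
    stop("hp1_occupancy must lie in [0, 1]")
  if (abs(sum(density_fractions) - 1) > 1e-9)
    stop("density_fractions must sum to 1")
  n_clustered <- cluster_spec$n_clusters * cluster_spec$cluster_size
  if (n_clustered > n_nuclei)
    stop("cluster_spec requests more nuclei than n_nuclei")
  structure(list(image_shape = as.integer(image_shape),
                 n_nuclei = as.integer(n_nuclei),
                 cluster_spec = cluster_spec,
                 radius_range = radius_range,
                 overlap_spacing = overlap_spacing,
                 density_fractions = density_fractions,
                 class_intensity_means = class_intensity_means,
                 hp1_occupancy = hp1_occupancy,
                 hp1_intensity = hp1_intensity,
                 noise_sd = noise_sd,
                 dispersal_factor = dispersal_factor,
                 dispersal_hp1_factor = dispersal_hp1_factor,
                 seed = as.integer(seed)),
            class = "gv_img_sim_config")
}

# n available pixels nearest the ellipse center in the elliptical metric;
# exact target size, deterministic tie-break by (rho, linear index)
.ellipse_pixels <- function(center, axes, phi, n_px, shape, taken) {
  r_out <- max(axes) * 1.8
  rows <- max(1, floor(center[1] - r_out)):min(shape[1],
                                               ceiling(center[1] + r_out))
  cols <- max(1, floor(center[2] - r_out)):min(shape[2],
                                               ceiling(center[2] + r_out))
  gy <- rep(rows, times = length(cols)) - center[1]
  gx <- rep(cols, each = length(rows)) - center[2]
  u <- gx * cos(phi) + gy * sin(phi)
  w <- -gx * sin(phi) + gy * cos(phi)
  rho <- sqrt((u / axes[1])^2 + (w / axes[2])^2)
  idx <- rep(rows, times = length(cols)) +
    (rep(cols, each = length(rows)) - 1) * shape[1]
  free <- !taken[idx]
  ord <- order(rho[free], idx[free])
  sel <- idx[free][ord]
  if (length(sel) < n_px)
    stop("nucleus does not fit inside the frame: increase margins")
  sel[seq_len(n_px)]
}

# shared per-image geometry: anchors for singles and clusters, per-nucleus
# semi-axes, orientation and offset from its anchor (0 for singles/anchors)
.place_nuclei <- function(config) {
  shape <- config$image_shape
  rr <- config$radius_range
  f <- max(1, config$dispersal_factor)
  margin <- ceiling(rr[2] * sqrt(f) * 1.9) + 2
  if (2 * margin >= min(shape))
    stop("image_shape too small for the configured nuclei")
  sep <- 2 * rr[2] * sqrt(f) * 1.25
  n_cl <- config$cluster_spec$n_clusters
  sz_cl <- config$cluster_spec$cluster_size
  n_single <- config$n_nuclei - n_cl * sz_cl
  centers <- NULL
  far_enough <- function(p, req) {
    is.null(centers) || min(sqrt(colSums((t(centers) - p)^2))) >= req
  }
  draw_center <- function(req) {
    for (try in 1:5000) {
      p <- c(stats::runif(1, margin, shape[1] - margin),
             stats::runif(1, margin, shape[2] - margin))
      if (far_enough(p, req)) return(p)
    }
    stop("could not place nuclei without exceeding the frame")
  }
  nuclei <- list()
  for (ci in seq_len(n_cl)) {
    anchor <- draw_center(sep)
    prev <- anchor
    prev_axes <- stats::runif(2, rr[1], rr[2])
    nuclei[[length(nuclei) + 1]] <- list(anchor = anchor, offset = c(0, 0),
                                         axes = prev_axes,
                                         phi = stats::runif(1, 0, pi),
                                         cluster = ci)
    centers <- rbind(centers, anchor)
    for (m in seq_len(sz_cl - 1)) {
      axes <- stats::runif(2, rr[1], rr[2])
      d <- config$overlap_spacing *
        (sqrt(prod(prev_axes)) + sqrt(prod(axes)))
      placed <- FALSE
      for (try in 1:500) {
        theta <- stats::runif(1, 0, 2 * pi)
        p <- prev + d * c(cos(theta), sin(theta))
        inside <- all(p >= margin) && all(p <= shape - margin)
        own <- sqrt(colSums((t(centers) - p)^2))
        # near its own cluster is intended; everyone else keeps distance
        ok_others <- all(own >= sep |
                           seq_len(nrow(centers)) >
                             (length(nuclei) - m))
        if (inside && ok_others) { placed <- TRUE; break }
      }
      if (!placed) stop("could not place a cluster member inside the frame")
      nuclei[[length(nuclei) + 1]] <- list(anchor = anchor,
                                           offset = p - anchor,
                                           axes = axes,
                                           phi = stats::runif(1, 0, pi),
                                           cluster = ci)
      centers <- rbind(centers, p)
      prev <- p; prev_axes <- axes
    }
  }
  for (si in seq_len(n_single)) {
    p <- draw_center(sep)
    nuclei[[length(nuclei) + 1]] <- list(anchor = p, offset = c(0, 0),
                                         axes = stats::runif(2, rr[1], rr[2]),
                                         phi = stats::runif(1, 0, pi),
                                         cluster = NA_integer_)
    centers <- rbind(centers, p)
  }
  nuclei
}

# render one image from shared geometry at a given area scale
.render_image <- function(config, geom, scale, occupancy) {
  shape <- config$image_shape
  fr <- config$density_fractions
  taken <- matrix(FALSE, shape[1], shape[2])
  class_map <- matrix(0L, shape[1], shape[2])
  dna <- matrix(0, shape[1], shape[2])
  hp1pos <- matrix(FALSE, shape[1], shape[2])
  nuclei <- list()
  for (i in seq_along(geom)) {
    g <- geom[[i]]
    center <- g$anchor + g$offset * scale
    base_area <- round(pi * prod(g$axes))
    n_px <- round(base_area * scale^2)
    idx <- .ellipse_pixels(center, g$axes * scale, g$phi, n_px, shape, taken)
    taken[idx] <- TRUE
    n_dense <- round(n_px * fr["dense"])
    n_mid <- round(n_px * fr["middle"])
    cls <- rep(1L, n_px)   # idx is ordered inside-out: innermost densest
    cls[seq_len(min(n_px, n_dense + n_mid))] <- 2L
    cls[seq_len(min(n_px, n_dense))] <- 3L
    class_map[idx] <- cls
    dna[idx] <- config$class_intensity_means[cls]
    hp1pos[idx] <- stats::runif(n_px) < occupancy[cls]
    nuclei[[i]] <- list(center = center, axes = g$axes * scale, phi = g$phi,
                        cluster = g$cluster, pixels = idx, area = n_px)
  }
  noise <- function(m) {
    if (config$noise_sd > 0)
      m <- m + stats::rnorm(length(m), 0, config$noise_sd)
    matrix(as.integer(pmin(pmax(round(m), 0), 255)), nrow(m))
  }
  hp1 <- matrix(0, shape[1], shape[2])
  hp1[hp1pos] <- config$hp1_intensity
  list(dna = noise(dna), hp1 = noise(hp1),
       truth = list(nuclei = nuclei, class_map = class_map,
                    hp1_pos = hp1pos))
}

#' Simulate two-channel images of nuclei with known density structure
#'
#' Builds, per image, a DNA-stain channel (background ~0; three concentric
#' density regimes per nucleus at the configured mean intensities) and an
#' HP1-alpha channel positive at truth-flagged pixels, with additive
#' Gaussian noise. Nucleus masks are exact-area pixel sets (disjoint;
#' touching within clusters), so truth areas and per-class pixel counts are
#' integers known by construction. With `paired = TRUE` a second,
#' post-transfer image set is rendered from the same nuclei with per-nucleus
#' areas scaled by `dispersal_factor` (exactly, when `dispersal_factor` times
#' the area is an integer) and HP1 occupancy multiplied by
#' `dispersal_hp1_factor` — chromatin dispersal with heterochromatin loss.
#'
#' @param config an [img_sim_config()].
#' @param n_images images per set.
#' @param paired also generate the dispersed ("24 h") set.
#' @return List of class `gv_img_sim` with `baseline` and (if requested)
#'   `dispersed`: each a list of per-image entries holding `dna` and `hp1`
#'   (integer matrices 0..255) and `truth` (`nuclei`: per-nucleus `center`,
#'   `axes`, `phi`, `cluster`, `pixels`, `area`; `class_map`: 0 background,
#'   1 loose, 2 middle, 3 dense; logical `hp1_pos`).
#' @export
simulate_images <- function(config = img_sim_config(), n_images = 1,
                            paired = FALSE) {
  stopifnot(inherits(config, "gv_img_sim_config"))
  set.seed(config$seed)
  geoms <- lapply(seq_len(n_images), function(i) .place_nuclei(config))
  baseline <- lapply(geoms, function(g)
    .render_image(config, g, 1, config$hp1_occupancy))
  out <- list(baseline = baseline, config = config)
  if (paired)
    out$dispersed <- lapply(geoms, function(g)
      .render_image(config, g, sqrt(config$dispersal_factor),
                    config$hp1_occupancy * config$dispersal_hp1_factor))
  structure(out, class = "gv_img_sim")
}

#' Write / read two-channel images as multi-page TIFF
#'
#' Page 1 is the DNA channel, page 2 the HP1-alpha channel; 8-bit grayscale.
#'
#' @param image list with integer matrices `dna` and `hp1` (0..255).
#' @param path TIFF path.
#' @return `write_image_tiff` returns the path invisibly; `read_image_tiff`
#'   a list with `dna` and `hp1` matrices on the 0..255 scale.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(list(image$dna / 255, image$hp1 / 255), path,
                  bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a two-page TIFF (DNA, HP1)")
  list(dna = round(pages[[1]] * 255), hp1 = round(pages[[2]] * 255))
}
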