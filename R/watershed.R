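#' Parameters of the recursive distance-map watershed
#'
#' @param min_area,max_area px area gate for an object to count as one
#'   nucleus. Defaults (300, 1080) bracket the simulator's single-nucleus
#'   areas while keeping the smallest touching pair above the gate; for real
#'   images derive them from the pixel size and a 5-20 micron
#'   nucleus-diameter prior.
#' @param tolerance_start initial h-maxima suppression depth (px) on the
#'   Euclidean distance map; `NULL` (default) uses half the component's
#'   distance-map maximum, so the first pass is conservative.
#' @param tolerance_decay multiplicative tolerance decay per recursion level,
#'   in (0, 1).
#' @param tolerance_floor px; below it an oversized component is reported
#'   unresolved rather than split further.
#' @param max_depth recursion limit.
#' @return A list of class `gv_watershed_params`.
#' @export
watershed_params <- function(min_area = 300, max_area = 1080,
                             tolerance_start = NULL, tolerance_decay = 0.7,
                             tolerance_floor = 1, max_depth = 8) {
  if (min_area <= 0 || max_area <= min_area)
    stop("need 0 < min_area < max_area")
  if (tolerance_decay <= 0 || tolerance_decay >= 1)
    stop("tolerance_decay must lie in (0, 1)")
  if (tolerance_floor <= 0) stop("tolerance_floor must be > 0")
  structure(list(min_area = min_area, max_area = max_area,
                 tolerance_start = tolerance_start,
                 tolerance_decay = tolerance_decay,
                 tolerance_floor = tolerance_floor,
                 max_depth = as.integer(max_depth)),
            class = "gv_watershed_params")
}

#' Recursive distance-map watershed segmentation of nuclei
#'
#' Splits a binary chromatin mask (typically `image >= huang_threshold(image)`)
#' into individual nuclei. Connected components already within the area gate
#' are emitted as-is (extraction depth 0). Each oversized component is
#' watershed-split on its Euclidean distance transform with markers taken as
#' h-maxima at the current tolerance; pieces within the gate are emitted at
#' the current depth, oversized pieces (or components the watershed failed to
#' split) recurse with the tolerance multiplied by `tolerance_decay`. When
#' the tolerance floor or depth limit is reached, oversized remnants are
#' reported as unresolved rather than dropped; components below `min_area`
#' are discarded but tallied. The procedure has no random steps.
#'
#' @param mask logical or 0/1 matrix, foreground = nuclei.
#' @param params a [watershed_params()].
#' @return An object of class `gv_segmentation`: list with `segments` (each:
#'   `label`, `pixels` (linear indices), `area`, `depth`), `unresolved`
#'   (same shape, oversized remnants), `discarded_small` (count and total
#'   area), and `dim` of the mask.
#' @export
recursive_watershed <- function(mask, params = watershed_params()) {
  m <- matrix(as.integer(mask > 0), nrow(mask))
  if (!any(m > 0)) stop("empty mask: nothing to segment")
  segments <- list(); unresolved <- list()
  discarded_n <- 0L; discarded_area <- 0
  emit <- function(px, depth) {
    segments[[length(segments) + 1]] <<-
      list(label = length(segments) + 1L, pixels = px,
           area = length(px), depth = depth)
  }
  process <- function(px, depth, tol) {
    area <- length(px)
    if (area < params$min_area) {
      discarded_n <<- discarded_n + 1L
      discarded_area <<- discarded_area + area
      return(invisible())
    }
    if (area <= params$max_area) return(emit(px, depth))
    # crop to the component bounding box (padded) for the distance map
    rc <- arrayInd(px, dim(m))
    r0 <- min(rc[, 1]) - 1L; c0 <- min(rc[, 2]) - 1L
    h <- max(rc[, 1]) - r0 + 2L; w <- max(rc[, 2]) - c0 + 2L
    sub <- matrix(0L, h, w)
    sub[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- 1L
    dm <- EBImage::distmap(sub)
    if (is.null(tol)) tol <- max(dm) / 2
    if (tol < params$tolerance_floor || depth >= params$max_depth) {
      unresolved[[length(unresolved) + 1]] <<-
        list(label = NA_integer_, pixels = px, area = area, depth = depth)
      return(invisible())
    }
    ws <- EBImage::watershed(dm, tolerance = tol, ext = 1)
    n_obj <- max(ws)
    if (n_obj <= 1) {
      process(px, depth + 1L, tol * params$tolerance_decay)
    } else {
      for (o in seq_len(n_obj)) {
        sel <- which(ws == o)
        rr <- ((sel - 1L) %% h) + 1L + r0
        cc <- ((sel - 1L) %/% h) + 1L + c0
        process(rr + (cc - 1L) * nrow(m), depth + 1L,
                tol * params$tolerance_decay)
      }
    }
    invisible()
  }
  lab <- EBImage::bwlabel(m)
  for (o in seq_len(max(lab)))
    process(which(lab == o), 0L, params$tolerance_start)
  structure(list(segments = segments, unresolved = unresolved,
                 discarded_small = list(n = discarded_n,
                                        area = discarded_area),
                 dim = dim(m)),
            class = "gv_segmentation")
}

#' @export
print.gv_segmentation <- function(x, ...) {
  cat(sprintf("gv_segmentation: %d nuclei (%d unresolved, %d discarded small)\n",
              length(x$segments), length(x$unresolved),
              x$discarded_small$n))
  if (length(x$segments)) {
    a <- vapply(x$segments, `[[`, numeric(1), "area")
    d <- vapply(x$segments, `[[`, numeric(1), "depth")
    cat(sprintf("areas %d-%d px; extraction depth 0-%d\n",
                min(a), max(a), max(d)))
  }
  invisible(x)
}

#' Label image from a segmentation
#'
#' @param seg a [recursive_watershed()] result.
#' @param include_unresolved also label unresolved remnants (after the
#'   regular segments).
#' @return Integer matrix; 0 = background, k = segment `k`.
#' @export
segments_to_labels <- function(seg, include_unresolved = FALSE) {
  lab <- matrix(0L, seg$dim[1], seg$dim[2])
  for (s in seg$segments) lab[s$pixels] <- s$label
  if (include_unresolved) {
    nxt <- length(seg$segments)
    for (u in seg$unresolved) {
      nxt <- nxt + 1L
      lab[u$pixels] <- nxt
    }
  }
  lab
}

#' Match segments to truth nuclei by best Jaccard overlap
#'
#' Greedy one-to-one matching of segmented objects to ground-truth masks in
#' decreasing order of Jaccard index, for scoring segmentation recovery on
#' simulated images.
#'
#' @param seg a [recursive_watershed()] result.
#' @param truth_nuclei `truth$nuclei` from [simulate_images()] (list with
#'   `pixels` per nucleus).
#' @return data.frame with one row per truth nucleus: `nucleus`, `segment`
#'   (NA if unmatched) and `jaccard`.
#' @export
segmentation_jaccard <- function(seg, truth_nuclei) {
  pairs <- expand.grid(nucleus = seq_along(truth_nuclei),
                       segment = seq_along(seg$segments))
  pairs$jaccard <- mapply(function(ni, si) {
    a <- truth_nuclei[[ni]]$pixels; b <- seg$segments[[si]]$pixels
    length(intersect(a, b)) / length(union(a, b))
  }, pairs$nucleus, pairs$segment)
  pairs <- pairs[order(-pairs$jaccard), ]
  out <- data.frame(nucleus = seq_along(truth_nuclei),
                    segment = NA_integer_, jaccard = 0)
  used <- logical(length(seg$segments))
  for (i in seq_len(nrow(pairs))) {
    ni <- pairs$nucleus[i]; si <- pairs$segment[i]
    if (is.na(out$segment[ni]) && !used[si] && pairs$jaccard[i] > 0) {
      out$segment[ni] <- si
      out$jaccard[ni] <- pairs$jaccard[i]
      used[si] <- TRUE
    }
  }
  out
}
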