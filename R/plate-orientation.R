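# Chromosome-plate orientation: segmentation, signed angle against the
# local apico-basal axis, per-cell amplitude, and track categories.

#' Apical (ventricular) surface annotation
#'
#' @param points n x 2 matrix (or data frame) of `(x, y)` positions in um
#'   tracing the local ventricular surface, at least 2 points, forming a
#'   simple (non-self-intersecting) polyline.
#' @return An object of class `"apical_surface"` (the point matrix).
#' @export
apical_surface <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2 || nrow(pts) < 2)
    stop("'points' must be an n x 2 matrix with n >= 2")
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n > 3) {
    for (i in seq_len(n - 3)) {
      for (j in seq(i + 2, n - 1)) {
        if (!is.null(segment_intersection(pts[i, ], pts[i + 1, ],
                                          pts[j, ], pts[j + 1, ], tol = 0)))
          stop("surface polyline must not self-intersect")
      }
    }
  }
  colnames(pts) <- c("x", "y")
  structure(pts, class = "apical_surface")
}

#' Segment the chromosome plate from the DNA channel
#'
#' Thresholds the maximum-intensity projection of the DNA channel and
#' returns the largest connected above-threshold component as the plate
#' mask.
#'
#' @param dna an [image_stack()] with a `"dna"` channel, or a numeric
#'   matrix `[x, y]`.
#' @param threshold_policy `"otsu"` (Otsu's threshold on the projected
#'   intensities), `"half_max"` (half the maximum intensity), or a numeric
#'   absolute threshold.
#' @return Logical matrix `[x, y]` (the plate mask) with the threshold
#'   used in attribute `"threshold"`.
#' @export
segment_chromatin <- function(dna, threshold_policy = "otsu") {
  img <- if (inherits(dna, "image_stack")) max_project(dna, "dna") else dna
  if (!is.matrix(img)) stop("'dna' must be an image_stack or a matrix")
  thr <- if (is.numeric(threshold_policy)) {
    threshold_policy
  } else if (identical(threshold_policy, "half_max")) {
    max(img) / 2
  } else if (identical(threshold_policy, "otsu")) {
    rng <- range(img)
    if (diff(rng) <= 0) stop("no chromatin detected (flat image)")
    EBImage::otsu((img - rng[1]) / diff(rng)) * diff(rng) + rng[1]
  } else stop("unknown threshold policy")
  bin <- img > thr
  if (!any(bin)) stop("no chromatin detected")
  lab <- EBImage::bwlabel(ifelse(bin, 1, 0))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  mask <- lab == which.max(sizes)
  structure(mask, threshold = thr)
}

# local apico-basal direction: the normal (oriented toward +y, i.e. into
# the tissue) of the surface segment nearest to 'point'
local_apicobasal <- function(surface, point) {
  stopifnot(inherits(surface, "apical_surface"))
  pts <- unclass(surface)
  best <- NULL; bestd <- Inf
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    ab <- b - a
    t <- sum((point - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    proj <- a + t * ab
    d <- sum((point - proj)^2)
    if (d < bestd) { bestd <- d; best <- ab }
  }
  nrm <- unit(c(-best[2], best[1]))
  if (nrm[2] < 0) nrm <- -nrm
  nrm
}

#' Signed plate-axis deviation from the local apico-basal axis
#'
#' The plate main axis is the principal axis of the second-order central
#' moments of the mask (on the projected coronal view); the local
#' apico-basal axis is the normal to the nearest apical-surface segment.
#' The returned angle is the signed deviation in degrees, 0 when the plate
#' lies along the apico-basal axis ("vertical"), +/-90 when parallel to
#' the surface, positive when the basal end of the plate axis tilts
#' toward +x (clockwise in the displayed coronal view).
#'
#' @param mask logical plate mask `[x, y]` (from [segment_chromatin()]).
#' @param surface an [apical_surface()].
#' @param spacing pixel size `c(x, y)` in um.
#' @return Signed angle in degrees, in `[-90, 90]`.
#' @export
plate_axis_angle <- function(mask, surface, spacing = c(1, 1)) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  xy <- cbind((idx[, 1] - 0.5) * spacing[1], (idx[, 2] - 0.5) * spacing[2])
  ctr <- colMeans(xy)
  cc <- sweep(xy, 2, ctr)
  covm <- crossprod(cc) / nrow(cc)
  ev <- eigen(covm, symmetric = TRUE)
  if (ev$values[1] <= 0 ||
      (ev$values[1] - ev$values[2]) / ev$values[1] < 1e-9)
    stop("axis undefined (isotropic mask)")
  v <- ev$vectors[, 1]
  nrm <- local_apicobasal(surface, ctr)
  tang <- c(nrm[2], -nrm[1])
  if (sum(v * nrm) < 0) v <- -v
  rad2deg(atan2(sum(v * tang), sum(v * nrm)))
}

# indices of the metaphase..anaphase-onset analysis window
metaphase_window <- function(track) {
  which(track$phase %in% c("metaphase", "anaphase_onset"))
}

#' Maximal amplitude of plate-angle deviations
#'
#' The per-cell statistic: the range (max - min) of the signed deviation
#' angles over the metaphase-to-anaphase-onset window. Prometaphase
#' samples are ignored.
#'
#' @param track a [plate_track()].
#' @return Amplitude in degrees.
#' @export
track_amplitude <- function(track) {
  stopifnot(inherits(track, "plate_track"))
  w <- metaphase_window(track)
  if (length(w) < 2)
    stop("need >= 2 samples from metaphase to anaphase onset")
  a <- track$angles_deg[w]
  max(a) - min(a)
}

#' Angular range bin of a single deviation angle
#'
#' Six colour-coded ranges; edges at 0, +/-15 and +/-30 deg belong to the
#' bin closer to 0 deg (and 0 deg itself to `"green"`).
#'
#' @param angle_deg signed deviation(s), degrees.
#' @return Character vector among `"blue"` (> 30), `"cyan"` (15..30],
#'   `"green"` [0..15], `"yellow"` [-15..0), `"red"` [-30..-15),
#'   `"dark_red"` (< -30).
#' @export
angle_bin <- function(angle_deg) {
  vapply(angle_deg, function(a) {
    if (a > 30) "blue"
    else if (a > 15) "cyan"
    else if (a >= 0) "green"
    else if (a >= -15) "yellow"
    else if (a >= -30) "red"
    else "dark_red"
  }, character(1))
}

#' Categorize a track by the range where most of it remained
#'
#' Each metaphase-window sample is binned with [angle_bin()]; the category
#' is the bin holding the strict majority of samples. When no bin has a
#' strict majority, the tie is broken toward the bin containing the median
#' metaphase angle.
#'
#' @param track a [plate_track()].
#' @return One of the six bin names.
#' @export
classify_track <- function(track) {
  stopifnot(inherits(track, "plate_track"))
  w <- metaphase_window(track)
  if (!length(w)) stop("empty track")
  a <- track$angles_deg[w]
  bins <- angle_bin(a)
  tab <- table(bins)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1 && max(tab) > length(bins) / 2) return(top)
  angle_bin(stats::median(a))
}
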