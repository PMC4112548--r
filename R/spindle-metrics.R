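# Spindle-integrity controls: main spindle region, area, normalized mean
# intensity, normalized per-pixel SD, and soma diameter at the spindle
# plane.

#' Main spindle region from soma shape, poles and foci planes
#'
#' The soma mask clipped to the y-band between the planes through the
#' apical-most and basal-most peri/centromeric foci (inclusive), laterally
#' extended to include a disc of radius `r_pole_um` around each centrosome
#' (intersected with the soma, so the region never leaves the cell). The
#' returned object keeps its defining landmarks (soma, poles, foci
#' planes), which [spindle_area()] uses for sub-pixel area integration.
#'
#' @param soma_mask logical `[x, y]` or `[x, y, z]` mask.
#' @param poles 2 x 2 or 2 x 3 matrix of pole positions (um).
#' @param foci_planes `c(apical, basal)` plane y-coordinates in um, e.g.
#'   `c(partition$apical_bound, partition$basal_bound)`.
#' @param spacing voxel spacing (um), same length as the mask dimension.
#' @param r_pole_um lateral extension radius around each pole, um.
#' @return An object of class `"main_spindle_region"`: `mask` (logical
#'   array, same shape as `soma_mask`), `soma_mask`, `poles`,
#'   `foci_planes`, `r_pole_um`, `spacing`.
#' @export
main_spindle_region <- function(soma_mask, poles, foci_planes,
                                spacing = c(1, 1), r_pole_um = 1.5) {
  d <- dim(soma_mask)
  nd <- length(d)
  if (length(spacing) != nd) stop("spacing/mask dimension mismatch")
  if (foci_planes[1] > foci_planes[2]) stop("foci planes out of order")
  xs <- (seq_len(d[1]) - 0.5) * spacing[1]
  ys <- (seq_len(d[2]) - 0.5) * spacing[2]
  # poles must sit inside the soma
  for (p in seq_len(nrow(poles))) {
    ij <- c(which.min(abs(xs - poles[p, 1])), which.min(abs(ys - poles[p, 2])))
    k <- if (nd == 3L) which.min(abs((seq_len(d[3]) - 0.5) * spacing[3] -
                                       poles[p, 3])) else NULL
    inside <- if (nd == 3L) soma_mask[ij[1], ij[2], k] else
      soma_mask[ij[1], ij[2]]
    if (!inside) stop("pole ", p, " lies outside the soma")
  }
  band2 <- outer(rep(TRUE, d[1]),
                 ys >= foci_planes[1] & ys <= foci_planes[2])
  disc2 <- matrix(FALSE, d[1], d[2])
  X <- matrix(xs, d[1], d[2])
  Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  for (p in seq_len(nrow(poles)))
    disc2 <- disc2 | ((X - poles[p, 1])^2 + (Y - poles[p, 2])^2 <=
                        r_pole_um^2)
  keep2 <- band2 | disc2
  mask <- soma_mask
  if (nd == 2L) {
    mask <- soma_mask & keep2
  } else {
    for (k in seq_len(d[3])) mask[, , k] <- soma_mask[, , k] & keep2
  }
  structure(list(mask = mask, soma_mask = soma_mask,
                 poles = poles[, 1:2, drop = FALSE],
                 foci_planes = as.numeric(foci_planes),
                 r_pole_um = r_pole_um, spacing = spacing),
            class = "main_spindle_region")
}

#' @export
print.main_spindle_region <- function(x, ...) {
  cat("<main_spindle_region> ", sum(x$mask), " voxels between y = ",
      signif(x$foci_planes[1], 4), " and ", signif(x$foci_planes[2], 4),
      " um\n", sep = "")
  invisible(x)
}

# accept either a plain logical mask or a main_spindle_region
region_mask <- function(region) {
  if (inherits(region, "main_spindle_region")) region$mask else region
}

# indices of the two central-most z sections: those straddling the
# intensity-weighted z centroid of the region
central_sections <- function(mask, intensity = NULL) {
  d <- dim(mask)
  if (length(d) == 2L) return(1L)
  wz <- vapply(seq_len(d[3]), function(k) {
    if (is.null(intensity)) sum(mask[, , k]) else
      sum(intensity[, , k] * mask[, , k])
  }, numeric(1))
  if (sum(wz) == 0) return(integer(0))
  zc <- sum(wz * seq_len(d[3])) / sum(wz)
  ks <- unique(c(max(1L, floor(zc)), min(d[3], ceiling(zc))))
  if (length(ks) == 1L) {
    alt <- if (ks < d[3] && (ks == 1L || wz[ks + 1] >= wz[ks - 1])) ks + 1L
    else ks - 1L
    ks <- sort(c(ks, max(1L, alt)))
  }
  unique(ks)
}

# sub-pixel section area of a landmark-carrying region: rows straddling a
# partition plane contribute the fraction of their height inside the band
# (partial-volume weighting), pole-disc pixels count fully
section_area_landmarks <- function(region, soma_sec) {
  d <- dim(soma_sec)
  sp <- region$spacing
  xs <- (seq_len(d[1]) - 0.5) * sp[1]
  ys <- (seq_len(d[2]) - 0.5) * sp[2]
  a <- region$foci_planes[1]; b <- region$foci_planes[2]
  wrow <- pmin(ys + sp[2] / 2, b) - pmax(ys - sp[2] / 2, a)
  wrow <- pmin(pmax(wrow / sp[2], 0), 1)
  W <- matrix(wrow, d[1], d[2], byrow = TRUE)
  X <- matrix(xs, d[1], d[2])
  Y <- matrix(ys, d[1], d[2], byrow = TRUE)
  disc <- matrix(FALSE, d[1], d[2])
  for (p in seq_len(nrow(region$poles)))
    disc <- disc | ((X - region$poles[p, 1])^2 +
                      (Y - region$poles[p, 2])^2 <= region$r_pole_um^2)
  W[disc] <- 1
  sum(W[soma_sec]) * sp[1] * sp[2]
}

#' Area of the main spindle region
#'
#' For a landmark-carrying region (from [main_spindle_region()]) the area
#' is integrated at sub-pixel precision: pixel rows straddling a foci
#' plane contribute the fraction of their height inside the band. A plain
#' logical mask gives voxel count times pixel area. For a 3D region, the
#' mean of the measurements from the two central-most sections (those
#' straddling the region's intensity-weighted z centroid) is returned.
#'
#' @param region a [main_spindle_region()] or a logical mask.
#' @param spacing voxel spacing (um); taken from the region when it
#'   carries one.
#' @param intensity optional intensity array used to weight the z
#'   centroid.
#' @return Area in um^2.
#' @export
spindle_area <- function(region, spacing = c(1, 1), intensity = NULL) {
  if (inherits(region, "main_spindle_region")) {
    spacing <- region$spacing
    soma <- region$soma_mask
    if (length(dim(soma)) == 2L)
      return(section_area_landmarks(region, soma))
    ks <- central_sections(region$mask, intensity)
    if (!length(ks)) return(0)
    return(mean(vapply(ks, function(k)
      section_area_landmarks(region, soma[, , k]), numeric(1))))
  }
  pixel_area <- spacing[1] * spacing[2]
  if (length(dim(region)) == 2L) return(sum(region) * pixel_area)
  ks <- central_sections(region, intensity)
  if (!length(ks)) return(0)
  mean(vapply(ks, function(k) sum(region[, , k]), numeric(1))) * pixel_area
}

#' Mean region intensity normalized to the whole image
#'
#' @param image intensity array.
#' @param region a [main_spindle_region()] or logical mask, same shape.
#' @return `mean(image[region]) / mean(image)`.
#' @export
normalized_mean_intensity <- function(image, region) {
  m <- region_mask(region)
  if (!any(m)) stop("empty region")
  denom <- mean(image)
  if (denom == 0) stop("zero whole-image mean")
  mean(image[m]) / denom
}

#' Per-pixel SD in the region normalized to the region mean
#'
#' Population SD (divisor N) of the per-voxel intensities within the
#' region, divided by the region mean. Both this and
#' [normalized_mean_intensity()] are ratios, hence invariant under global
#' intensity scaling.
#'
#' @inheritParams normalized_mean_intensity
#' @return Dimensionless ratio.
#' @export
normalized_sd <- function(image, region) {
  v <- image[region_mask(region)]
  if (length(v) < 2) stop("region needs >= 2 voxels")
  m <- mean(v)
  if (m == 0) stop("zero region mean")
  sqrt(mean((v - m)^2)) / m
}

#' Soma diameter along the pole--pole axis
#'
#' Chord length of the soma mask along the line through the two spindle
#' poles, at the spindle plane; this also represents the full spindle
#' length including some astral extent.
#'
#' @param soma_mask logical matrix `[x, y]` (the spindle-plane section).
#' @param poles 2 x 2 matrix of pole positions (um).
#' @param spacing pixel size `c(x, y)` um.
#' @return Chord length in um.
#' @export
diameter_at_spindle_plane <- function(soma_mask, poles, spacing = c(1, 1)) {
  ctr <- colMeans(poles[, 1:2, drop = FALSE])
  axis <- unit(poles[2, 1:2] - poles[1, 1:2])
  d <- dim(soma_mask)
  lim <- sqrt(sum((d * spacing[1:2])^2))
  step <- 0.25 * min(spacing[1:2])
  ts <- seq(-lim, lim, by = step)
  px <- ctr[1] + ts * axis[1]
  py <- ctr[2] + ts * axis[2]
  ii <- round(px / spacing[1] + 0.5)
  jj <- round(py / spacing[2] + 0.5)
  ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
  inmask <- rep(FALSE, length(ts))
  inmask[ok] <- soma_mask[cbind(ii[ok], jj[ok])]
  if (!any(inmask)) stop("pole axis misses the soma mask")
  (max(ts[inmask]) - min(ts[inmask])) + step
}
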