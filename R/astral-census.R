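# Regional census of cortex-reaching astral microtubules.
#
# The mitotic soma is split into apical / central / basal regions by the
# two planes through the apical-most and basal-most peri/centromeric
# heterochromatin foci (the brightest DNA puncta). Astral rods are detected
# outside the dense central spindle, followed from their pole, and counted
# per region when their far endpoint reaches the cell periphery.

#' Detect peri/centromeric heterochromatin foci in the DNA channel
#'
#' Local intensity maxima inside the plate mask whose prominence over the
#' plate (value minus the median plate intensity) is at least
#' `min_prominence`; maxima closer than `min_sep_um` are merged keeping the
#' brighter one. Foci are returned sorted along the apico-basal (y) axis.
#'
#' @param dna an [image_stack()] with a `"dna"` channel, or a matrix.
#' @param plate_mask logical matrix from [segment_chromatin()].
#' @param min_prominence minimum peak height over the median plate
#'   intensity, in intensity units.
#' @param min_sep_um minimum separation between reported foci, um.
#' @param spacing pixel size `c(x, y)` um (taken from the stack if one is
#'   given).
#' @return data frame with columns `ix, iy` (pixel), `x_um, y_um`,
#'   `value`, sorted by `y_um`.
#' @export
detect_centromeric_foci <- function(dna, plate_mask, min_prominence = 0.3,
                                    min_sep_um = 0.45, spacing = c(1, 1)) {
  if (inherits(dna, "image_stack")) {
    spacing <- dna$spacing[1:2]
    img <- max_project(dna, "dna")
  } else img <- dna
  stopifnot(is.matrix(img), identical(dim(img), dim(plate_mask)))
  nx <- nrow(img); ny <- ncol(img)
  base <- stats::median(img[plate_mask])
  # strict-or-equal local maxima over the 8-neighbourhood
  pad <- matrix(-Inf, nx + 2, ny + 2)
  pad[2:(nx + 1), 2:(ny + 1)] <- img
  is_max <- matrix(TRUE, nx, ny)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & img >= pad[(2 + di):(nx + 1 + di),
                                  (2 + dj):(ny + 1 + dj)]
  }
  cand <- which(is_max & plate_mask & (img - base >= min_prominence),
                arr.ind = TRUE)
  if (!nrow(cand)) stop("no centromeric foci detected; partition undefined")
  vals <- img[cand]
  ord <- order(vals, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  keep <- logical(nrow(cand))
  kept_xy <- matrix(NA_real_, 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- c((cand[i, 1] - 0.5) * spacing[1], (cand[i, 2] - 0.5) * spacing[2])
    if (!nrow(kept_xy) ||
        min(sqrt((kept_xy[, 1] - p[1])^2 + (kept_xy[, 2] - p[2])^2)) >=
        min_sep_um) {
      keep[i] <- TRUE
      kept_xy <- rbind(kept_xy, p)
    }
  }
  cand <- cand[keep, , drop = FALSE]; vals <- vals[keep]
  # subpixel refinement: parabolic fit through the peak and its neighbours
  refine <- function(i, j) {
    off <- c(0, 0)
    if (i > 1 && i < nx) {
      den <- img[i - 1, j] - 2 * img[i, j] + img[i + 1, j]
      if (den < 0) off[1] <- 0.5 * (img[i - 1, j] - img[i + 1, j]) / den
    }
    if (j > 1 && j < ny) {
      den <- img[i, j - 1] - 2 * img[i, j] + img[i, j + 1]
      if (den < 0) off[2] <- 0.5 * (img[i, j - 1] - img[i, j + 1]) / den
    }
    pmin(pmax(off, -0.5), 0.5)
  }
  offs <- t(vapply(seq_len(nrow(cand)),
                   function(r) refine(cand[r, 1], cand[r, 2]), numeric(2)))
  out <- data.frame(ix = cand[, 1], iy = cand[, 2],
                    x_um = (cand[, 1] - 0.5 + offs[, 1]) * spacing[1],
                    y_um = (cand[, 2] - 0.5 + offs[, 2]) * spacing[2],
                    value = vals)
  out[order(out$y_um), , drop = FALSE]
}

#' Partition the soma into apical / central / basal regions
#'
#' The apical region runs from the ventricular surface to the plane just
#' apical of the apical-most focus (exclusive); the central region spans
#' the two planes inclusive (it contains all foci); the basal region is
#' everything more basal, to the basal end of the soma.
#'
#' @param foci data frame from [detect_centromeric_foci()] (needs `y_um`,
#'   and `ix, iy` for the in-soma check when a mask is supplied).
#' @param surface an [apical_surface()] (kept for orientation metadata).
#' @param soma_mask optional logical matrix; every focus must fall inside
#'   it.
#' @return An object of class `"region_partition"` with `apical_bound` and
#'   `basal_bound` (um, the two plane y-coordinates).
#' @export
partition_regions <- function(foci, surface = NULL, soma_mask = NULL) {
  if (!nrow(foci)) stop("no foci; partition undefined")
  if (!is.null(soma_mask)) {
    inside <- soma_mask[cbind(foci$ix, foci$iy)]
    if (!all(inside)) stop("focus outside the soma mask")
  }
  structure(list(apical_bound = min(foci$y_um),
                 basal_bound = max(foci$y_um),
                 orientation = "apical_low_y"),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> apical plane y = ", signif(x$apical_bound, 4),
      " um, basal plane y = ", signif(x$basal_bound, 4), " um\n", sep = "")
  invisible(x)
}

#' Region of a y-coordinate under a partition
#'
#' Points exactly on either plane belong to the central region (the
#' central region is defined to contain all foci).
#'
#' @param partition a [partition_regions()] result.
#' @param y y-coordinate(s), um.
#' @return Character vector: `"apical"`, `"central"` or `"basal"`.
#' @export
region_of_y <- function(partition, y) {
  stopifnot(inherits(partition, "region_partition"))
  ifelse(y < partition$apical_bound, "apical",
         ifelse(y > partition$basal_bound, "basal", "central"))
}

#' Locate the two spindle poles in the tubulin channel
#'
#' The poles are the two brightest tubulin maxima outside the (dilated)
#' plate mask, at least `min_sep_um` apart, refined to subpixel position.
#' With `constrain_axis = TRUE` (default) each pole is projected onto the
#' spindle axis -- the line through the plate centroid perpendicular to
#' the plate's principal axis -- using the geometric fact that a bipolar
#' spindle straddles its metaphase plate orthogonally; this suppresses
#' localization bias from the asymmetric astral fan around each
#' centrosome.
#'
#' @param tubulin an [image_stack()] with a `"tubulin"` channel, or a
#'   matrix.
#' @param plate_mask logical plate mask.
#' @param min_sep_um minimum pole separation, um.
#' @param constrain_axis project the poles onto the spindle axis derived
#'   from the plate mask.
#' @param spacing pixel size `c(x, y)` um.
#' @return 2 x 2 matrix of pole positions (um), columns `x, y`.
#' @export
find_spindle_poles <- function(tubulin, plate_mask, min_sep_um = 2,
                               constrain_axis = TRUE, spacing = c(1, 1)) {
  if (inherits(tubulin, "image_stack")) {
    spacing <- tubulin$spacing[1:2]
    img <- max_project(tubulin, "tubulin")
  } else img <- tubulin
  excl <- EBImage::dilate(ifelse(plate_mask, 1, 0),
                          EBImage::makeBrush(9, "disc")) > 0
  work <- img
  work[excl] <- -Inf
  nx <- nrow(img); ny <- ncol(img)
  poles <- matrix(NA_real_, 0, 2)
  while (nrow(poles) < 2) {
    i <- which.max(work)
    if (!is.finite(work[i])) stop("poles not found")
    ij <- arrayInd(i, dim(work))
    # subpixel refinement of the pole spot by a parabolic fit
    off <- c(0, 0)
    i0 <- ij[1]; j0 <- ij[2]
    if (i0 > 1 && i0 < nx) {
      den <- img[i0 - 1, j0] - 2 * img[i0, j0] + img[i0 + 1, j0]
      if (den < 0) off[1] <- 0.5 * (img[i0 - 1, j0] - img[i0 + 1, j0]) / den
    }
    if (j0 > 1 && j0 < ny) {
      den <- img[i0, j0 - 1] - 2 * img[i0, j0] + img[i0, j0 + 1]
      if (den < 0) off[2] <- 0.5 * (img[i0, j0 - 1] - img[i0, j0 + 1]) / den
    }
    off <- pmin(pmax(off, -0.5), 0.5)
    p <- c((ij[1] - 0.5 + off[1]) * spacing[1],
           (ij[2] - 0.5 + off[2]) * spacing[2])
    r2 <- outer(((seq_len(nx) - 0.5) * spacing[1] - p[1])^2,
                ((seq_len(ny) - 0.5) * spacing[2] - p[2])^2, "+")
    work[r2 < min_sep_um^2] <- -Inf
    poles <- rbind(poles, p)
  }
  if (constrain_axis) {
    idx <- which(plate_mask, arr.ind = TRUE)
    xy <- cbind((idx[, 1] - 0.5) * spacing[1], (idx[, 2] - 0.5) * spacing[2])
    ctr <- colMeans(xy)
    cc <- sweep(xy, 2, ctr)
    ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
    if ((ev$values[1] - ev$values[2]) / max(ev$values[1], 1e-12) > 1e-9) {
      axis <- c(-ev$vectors[2, 1], ev$vectors[1, 1])  # perp to plate axis
      for (p in 1:2)
        poles[p, ] <- ctr + sum((poles[p, ] - ctr) * axis) * axis
    }
  }
  colnames(poles) <- c("x", "y")
  poles
}

# bilinear image lookup at physical positions (um); outside -> 0
bilinear_at <- function(img, x, y, spacing) {
  px <- x / spacing[1] + 0.5
  py <- y / spacing[2] + 0.5
  i0 <- floor(px); j0 <- floor(py)
  fx <- px - i0; fy <- py - j0
  n1 <- nrow(img); n2 <- ncol(img)
  val <- function(i, j) {
    ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2
    out <- numeric(length(i))
    if (any(ok)) out[ok] <- img[cbind(i[ok], j[ok])]
    out
  }
  val(i0, j0) * (1 - fx) * (1 - fy) + val(i0 + 1L, j0) * fx * (1 - fy) +
    val(i0, j0 + 1L) * (1 - fx) * fy + val(i0 + 1L, j0 + 1L) * fx * fy
}

empty_segments <- function() {
  data.frame(pole = integer(0), angle_deg = numeric(0),
             x_end = numeric(0), y_end = numeric(0),
             length_um = numeric(0), dist_to_boundary_um = numeric(0),
             reaches = logical(0), region = character(0))
}

#' Detect astral microtubules and classify their cortical endpoints
#'
#' Rod-like tubulin structures are followed from each spindle pole
#' outward. Close to a pole individual astrals merge into one bright fan,
#' so each rod is identified where the fan has resolved: the tubulin
#' intensity is sampled on probe circles of radius `r_probe_um` around the
#' pole, and each angular intensity peak above threshold marks one rod
#' direction. Every rod is then traced outward along its ray until the
#' intensity drops below threshold; the last above-threshold point is its
#' far endpoint. Endpoints within `delta_cortex_um` of the soma boundary
#' are marked as reaching the cell periphery; regions come from the
#' endpoint's y-coordinate under the partition (endpoints exactly on a
#' partition plane count as central). Rods shorter than the smallest
#' probe radius are not seen (they never enter any census either way).
#'
#' @param tubulin an [image_stack()] with a `"tubulin"` channel, or a
#'   matrix `[x, y]`.
#' @param poles 2 x 2 matrix of pole positions (um), e.g. from
#'   [find_spindle_poles()].
#' @param soma_mask logical soma mask `[x, y]`.
#' @param partition a [partition_regions()] result.
#' @param threshold absolute rod intensity threshold; defaults to
#'   `thr_frac` of the brightest tubulin pixel beyond the probe radius.
#' @param delta_cortex_um maximum endpoint distance from the soma boundary
#'   to count as reaching the periphery.
#' @param r_probe_um probe-circle radii (um); a rod is registered at the
#'   first radius that resolves it.
#' @param thr_frac fraction of the far-field rod peak used for the default
#'   threshold.
#' @param spacing pixel size `c(x, y)` um.
#' @return data frame of segments: `pole`, `angle_deg` (direction around
#'   the pole), `x_end, y_end` (um), `length_um`,
#'   `dist_to_boundary_um`, `reaches`, `region`.
#' @export
detect_astrals <- function(tubulin, poles, soma_mask, partition,
                           threshold = NULL, delta_cortex_um = 1.0,
                           r_probe_um = c(2.1, 2.5), thr_frac = 0.35,
                           spacing = c(1, 1)) {
  if (inherits(tubulin, "image_stack")) {
    spacing <- tubulin$spacing[1:2]
    img <- max_project(tubulin, "tubulin")
  } else img <- tubulin
  if (is.null(poles) || nrow(poles) != 2) stop("poles not found")
  nx <- nrow(img); ny <- ncol(img)
  xs <- (seq_len(nx) - 0.5) * spacing[1]
  ys <- (seq_len(ny) - 0.5) * spacing[2]

  if (is.null(threshold)) {
    # far field: soma pixels farther than min(r_probe) from both poles
    X <- matrix(xs, nx, ny); Y <- matrix(ys, nx, ny, byrow = TRUE)
    far <- soma_mask &
      ((X - poles[1, 1])^2 + (Y - poles[1, 2])^2 > min(r_probe_um)^2) &
      ((X - poles[2, 1])^2 + (Y - poles[2, 2])^2 > min(r_probe_um)^2)
    peak <- if (any(far)) max(img[far]) else 0
    threshold <- thr_frac * peak
  }
  if (threshold <= 0) return(empty_segments())

  dist_b <- EBImage::distmap(ifelse(soma_mask, 1, 0)) * spacing[1]
  ctr <- colMeans(poles)
  phis <- seq(-89, 89, by = 0.5)
  step <- 0.5 * min(spacing)
  segs <- list()
  for (p in 1:2) {
    out <- unit(poles[p, ] - ctr)
    base <- atan2(out[2], out[1])
    found_phi <- numeric(0)
    for (r_star in sort(r_probe_um)) {
      a <- base + deg2rad(phis)
      vals <- bilinear_at(img, poles[p, 1] + r_star * cos(a),
                          poles[p, 2] + r_star * sin(a), spacing)
      nph <- length(phis)
      is_pk <- vals > threshold
      for (d in 1:4) {   # strictly-greater-or-equal peak over +/-2 deg
        is_pk <- is_pk &
          vals >= c(rep(-Inf, d), vals[seq_len(nph - d)]) &
          vals >= c(vals[-seq_len(d)], rep(-Inf, d))
      }
      for (k in which(is_pk)) {
        if (length(found_phi) && min(abs(found_phi - phis[k])) < 4) next
        found_phi <- c(found_phi, phis[k])
        # ridge following: step outward, re-centring the angular peak in a
        # +/-3 deg window at each radius, so small pole-localization
        # errors do not tilt the traced ray off the rod
        phi <- base + deg2rad(phis[k])
        r <- r_star
        repeat {
          r_next <- r + 0.4
          cand <- phi + deg2rad(seq(-3, 3, by = 0.25))
          v <- bilinear_at(img, poles[p, 1] + r_next * cos(cand),
                           poles[p, 2] + r_next * sin(cand), spacing)
          if (max(v) <= threshold) break
          phi <- cand[which.max(v)]
          r <- r_next
        }
        # fine trace of the rod tip along the final direction
        dirv <- c(cos(phi), sin(phi))
        rs <- seq(r, r + 0.45, by = step)
        v <- bilinear_at(img, poles[p, 1] + rs * dirv[1],
                         poles[p, 2] + rs * dirv[2], spacing)
        below <- which(v <= threshold)
        r_end <- if (!length(below)) max(rs) else rs[max(1L, below[1] - 1L)]
        ep <- poles[p, ] + r_end * dirv
        endb <- bilinear_at(dist_b, ep[1], ep[2], spacing)
        segs[[length(segs) + 1]] <- data.frame(
          pole = p, angle_deg = phis[k],
          x_end = ep[1], y_end = ep[2], length_um = r_end,
          dist_to_boundary_um = endb,
          reaches = endb <= delta_cortex_um,
          region = region_of_y(partition, ep[2]))
      }
    }
  }
  if (!length(segs)) return(empty_segments())
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Classify the spindle view as Front or Side
#'
#' Front view: the pole--pole axis lies mostly in the sectioning plane
#' (angle with the plane strictly below `theta_view_deg`) and the spindle
#' is fully visible within at most `max_sections` confocal sections.
#' Otherwise the view is Side. Central-region astrals are only assessed in
#' Side view (in Front view the dense central spindle hides them).
#'
#' @param poles 2 x 3 matrix of pole positions (um), columns `x, y, z`.
#' @param section_spacing_um z distance between confocal sections.
#' @param theta_view_deg view threshold (strict inequality).
#' @param max_sections maximum sections a Front-view spindle may span.
#' @return `"front"` or `"side"`.
#' @export
classify_view <- function(poles, section_spacing_um = 0.75,
                          theta_view_deg = 45, max_sections = 3L) {
  stopifnot(nrow(poles) == 2, ncol(poles) == 3)
  d <- poles[2, ] - poles[1, ]
  inplane <- sqrt(d[1]^2 + d[2]^2)
  ang <- rad2deg(atan2(abs(d[3]), inplane))
  n_span <- floor(abs(d[3]) / section_spacing_um) + 1L
  if (ang < theta_view_deg && n_span <= max_sections) "front" else "side"
}

#' Count cortex-reaching astrals per region
#'
#' Only segments reaching the periphery are counted. Apical and basal
#' counts are reported for any view; the central count is reported only
#' for Side-view cells and is `NA` ("not assessed") in Front view.
#'
#' @param segments data frame from [detect_astrals()] (or ground truth)
#'   with columns `reaches`, `region`.
#' @param view `"front"` or `"side"`.
#' @return An object of class `"astral_census"`: `apical`, `basal`,
#'   `central` (integer or `NA`), `view`.
#' @export
count_census <- function(segments, view = c("side", "front")) {
  view <- match.arg(view)
  rc <- segments[segments$reaches, , drop = FALSE]
  cen <- if (view == "front") NA_integer_ else
    sum(rc$region == "central")
  structure(list(apical = sum(rc$region == "apical"),
                 basal = sum(rc$region == "basal"),
                 central = cen, view = view),
            class = "astral_census")
}

#' @export
print.astral_census <- function(x, ...) {
  cen <- if (is.na(x$central)) "not assessed" else x$central
  cat("<astral_census> (", x$view, " view) apical ", x$apical,
      ", basal ", x$basal, ", central ", cen, "\n", sep = "")
  invisible(x)
}

#' Orientation-class census for basal progenitors
#'
#' BPs lack apical surface contact, so cortical regions cannot be anchored
#' on the ventricular surface; instead each cortex-reaching astral is
#' classed by the direction of its endpoint from the soma centroid:
#' apically oriented when within `sigma_deg` of the ventricle direction,
#' basally oriented when within `sigma_deg` of the pial (opposite)
#' direction, centrally oriented otherwise. Boundary angles (exactly
#' `sigma_deg`) count as apically/basally oriented.
#'
#' @param segments data frame with `reaches`, `x_end`, `y_end`.
#' @param centroid soma centroid `c(x, y)` um.
#' @param ventricle_direction unit-ish vector pointing from the cell
#'   toward the ventricle (default `c(0, -1)`: apical is -y).
#' @param sigma_deg sector half-angle.
#' @return Named integer vector: `apically_oriented`, `basally_oriented`,
#'   `centrally_oriented`.
#' @export
bp_orient_census <- function(segments, centroid,
                             ventricle_direction = c(0, -1),
                             sigma_deg = 45) {
  vd <- unit(ventricle_direction)
  rc <- segments[segments$reaches, , drop = FALSE]
  out <- c(apically_oriented = 0L, basally_oriented = 0L,
           centrally_oriented = 0L)
  if (!nrow(rc)) return(out)
  for (i in seq_len(nrow(rc))) {
    d <- unit(c(rc$x_end[i] - centroid[1], rc$y_end[i] - centroid[2]))
    ang <- rad2deg(acos(pmin(pmax(sum(d * vd), -1), 1)))
    cls <- if (ang <= sigma_deg) "apically_oriented"
    else if (ang >= 180 - sigma_deg) "basally_oriented"
    else "centrally_oriented"
    out[cls] <- out[cls] + 1L
  }
  out
}
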