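# Synthetic mitotic-cell rendering.
#
# The generator is first-class: its ground truth is the oracle against which
# every measurement operation is validated by parameter recovery.

# world geometry derived from a cell_spec (all um)
cell_geometry <- function(spec) {
  nd <- length(spec$soma_axes)
  ax <- spec$soma_axes[1]; ay <- spec$soma_axes[2]
  az <- if (nd == 3L) spec$soma_axes[3] else NA_real_
  m <- spec$margin
  width <- 2 * (ax + m)
  height <- 2 * ay + 2 * m
  centre <- c(width / 2, m + ay)
  surface_y <- m / 2
  theta <- deg2rad(spec$plate_angle_deg)
  u <- c(sin(theta), cos(theta))      # plate long axis (apico-basal at 0 deg)
  w <- c(cos(theta), -sin(theta))     # spindle (pole--pole) axis
  poles <- rbind(centre - spec$pole_offset * w,
                 centre + spec$pole_offset * w)
  if (nd == 3L) {
    depth <- 2 * az + 2 * spec$voxel_spacing[3]
    cz <- depth / 2
    poles <- cbind(poles, cz + spec$pole_dz)
  } else {
    depth <- NA_real_; cz <- NA_real_
  }
  foci_world <- NULL
  planes <- NULL
  if (!is.null(spec$foci_positions)) {
    fu <- spec$foci_positions[, 1]; fv <- spec$foci_positions[, 2]
    foci_world <- cbind(x = centre[1] + fu * u[1] + fv * w[1],
                        y = centre[2] + fu * u[2] + fv * w[2])
    planes <- c(apical = min(foci_world[, "y"]),
                basal = max(foci_world[, "y"]))
  }
  list(nd = nd, spacing = spec$voxel_spacing,
       width = width, height = height, depth = depth,
       centre = centre, cz = cz, surface_y = surface_y,
       soma_axes = spec$soma_axes,
       plate_axis = u, spindle_axis = w,
       plate_axes = spec$plate_axes, poles = poles,
       foci_world = foci_world, planes = planes,
       cortex_inset = spec$cortex_inset,
       stop_fraction = spec$stop_fraction)
}

# distance along a ray from 'p' with unit direction 'd' to the soma
# ellipse boundary (2D, central plane); NA if the ray never exits
ray_ellipse_exit <- function(p, d, centre, ax, ay) {
  px <- (p[1] - centre[1]) / ax; py <- (p[2] - centre[2]) / ay
  dx <- d[1] / ax; dy <- d[2] / ay
  a <- dx^2 + dy^2
  b <- 2 * (px * dx + py * dy)
  cc <- px^2 + py^2 - 1
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(NA_real_)
  (-b + sqrt(disc)) / (2 * a)
}

# rod direction for an astral: angle measured from the outward spindle-axis
# direction at its pole, positive tilting toward the apical (-y) side
astral_direction <- function(geom, pole, angle_deg) {
  out <- if (pole == 1) -geom$spindle_axis else geom$spindle_axis
  sgn <- if (pole == 1) 1 else -1
  phi <- deg2rad(sgn * angle_deg)
  c(cos(phi) * out[1] - sin(phi) * out[2],
    sin(phi) * out[1] + cos(phi) * out[2])
}

# endpoint (um, xy) of an astral rod, or NULL if the geometry is invalid
astral_endpoint <- function(geom, pole, angle_deg, reaches) {
  d <- astral_direction(geom, pole, angle_deg)
  p <- geom$poles[pole, 1:2]
  t_exit <- ray_ellipse_exit(p, d, geom$centre, geom$soma_axes[1],
                             geom$soma_axes[2])
  if (is.na(t_exit) || t_exit <= geom$cortex_inset) return(NULL)
  if (!reaches && (1 - geom$stop_fraction) * t_exit < 1.6)
    return(NULL)   # a "short" rod must stop clearly away from the cortex
  t_end <- if (reaches) t_exit - geom$cortex_inset else
    geom$stop_fraction * t_exit
  ep <- p + t_end * d
  if (segment_hits_ellipse(p, ep, geom$centre, geom$plate_axis,
                           geom$plate_axes[1], geom$plate_axes[2]))
    return(NULL)
  c(x = ep[1], y = ep[2])
}

# cortical region of an endpoint y relative to the two partition planes;
# NA when within 'margin' of either plane (used to reject ambiguous draws)
endpoint_region <- function(y, geom, margin = 0) {
  pl <- geom$planes
  if (is.null(pl)) stop("no foci, partition planes undefined")
  if (y < pl["apical"] - margin) return("apical")
  if (y > pl["basal"] + margin) return("basal")
  if (y >= pl["apical"] + margin && y <= pl["basal"] - margin) return("central")
  NA_character_
}

# deposit an anti-aliased unit-intensity rod into 'img' ([x, y] matrix);
# bilinear weights are accumulated along the segment and normalized by the
# sampling density, giving near-uniform intensity along the rod
splat_rod <- function(img, p0, p1, dx, dy, step_frac = 0.25) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / (step_frac * min(dx, dy))))
  ts <- seq(0, 1, length.out = n)
  px <- (p0[1] + ts * (p1[1] - p0[1])) / dx + 0.5
  py <- (p0[2] + ts * (p1[2] - p0[2])) / dy + 0.5
  i0 <- floor(px); j0 <- floor(py)
  fx <- px - i0; fy <- py - j0
  ii <- c(i0, i0 + 1L, i0, i0 + 1L)
  jj <- c(j0, j0, j0 + 1L, j0 + 1L)
  ww <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  keep <- ii >= 1 & ii <= nrow(img) & jj >= 1 & jj <= ncol(img)
  if (!any(keep)) return(img)
  acc <- stats::aggregate(w ~ i + j,
                          data.frame(i = ii[keep], j = jj[keep],
                                     w = ww[keep]), sum)
  step_px <- len / ((n - 1) * min(dx, dy))
  idx <- cbind(acc$i, acc$j)
  img[idx] <- img[idx] + acc$w * step_px
  img
}

# add a truncated 2D gaussian spot (amplitude 'amp', sigma um) at (x0, y0)
add_spot <- function(img, x0, y0, amp, sigma, xs, ys, zfac = 1) {
  if (zfac <= 1e-8) return(img)
  ix <- which(abs(xs - x0) <= 4 * sigma)
  iy <- which(abs(ys - y0) <= 4 * sigma)
  if (!length(ix) || !length(iy)) return(img)
  g <- outer(exp(-(xs[ix] - x0)^2 / (2 * sigma^2)),
             exp(-(ys[iy] - y0)^2 / (2 * sigma^2)))
  img[ix, iy] <- img[ix, iy] + amp * zfac * g
  img
}

blur_section <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  out <- EBImage::gblur(img, sigma = sigma_px)
  out <- as.numeric(out)
  dim(out) <- dim(img)
  out[out < 1e-10] <- 0
  out
}

#' Render a synthetic mitotic cell with full ground truth
#'
#' Renders the three fluorescence channels implied by a [cell_spec()]:
#'
#' * `dna` -- the metaphase plate as a uniform ellipse plus
#'   peri/centromeric heterochromatin foci as Gaussian spots whose peaks
#'   are twice the plate intensity, so the foci are the brightest DNA
#'   voxels by construction;
#' * `tubulin` -- a dense central spindle (ellipse spanning the two
#'   poles), bright pole spots, and one anti-aliased rod per astral
#'   microtubule, blurred by the in-plane PSF;
#' * `cortical` -- uniform cytoplasm inside the soma plus a one-pixel
#'   cortical band painted along the soma boundary chain with intensity
#'   `cytoplasm_level + cortical_profile_fn(s)`, where `s` is the
#'   normalized clockwise arc position starting at the apical midpoint.
#'
#' Shot (Poisson) and additive Gaussian noise are applied last, in that
#' order; both are off by default. Identical `spec` and `seed` give
#' voxel-identical stacks.
#'
#' @param spec a [cell_spec()]; its `foci_positions` must be set (use
#'   [random_cell_spec()] to sample a self-consistent spec).
#' @param seed integer seed for the one random generator used.
#' @return A list with components `stack` (an [image_stack()]) and
#'   `ground_truth` (class `"cell_ground_truth"`: every generative
#'   parameter, world-coordinate landmarks, the per-region census of
#'   cortex-reaching astrals, and the support masks of plate, central
#'   spindle and soma).
#' @export
make_mitotic_cell <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cell_spec"))
  if (is.null(spec$foci_positions))
    stop("spec has no foci_positions; a plate without foci cannot be ",
         "partitioned (use random_cell_spec())")
  set.seed(seed)
  geom <- cell_geometry(spec)
  nd <- geom$nd
  dx <- geom$spacing[1]; dy <- geom$spacing[2]
  nx <- ceiling(geom$width / dx); ny <- ceiling(geom$height / dy)
  nz <- if (nd == 3L) ceiling(geom$depth / geom$spacing[3]) else 1L
  xs <- (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dy
  zs <- if (nd == 3L) (seq_len(nz) - 0.5) * geom$spacing[3] else 0
  cz <- if (nd == 3L) geom$cz else 0

  # --- astral endpoints & census (ground truth) ------------------------
  astrals <- spec$astral_spec
  seg_tab <- NULL
  census <- c(apical = 0L, basal = 0L, central = 0L)
  if (!is.null(astrals) && nrow(astrals)) {
    eps <- matrix(NA_real_, nrow(astrals), 2)
    for (i in seq_len(nrow(astrals))) {
      ep <- astral_endpoint(geom, astrals$pole[i], astrals$angle_deg[i],
                            astrals$reaches[i])
      if (is.null(ep))
        stop("astral ", i, ": direction exits through the plate envelope ",
             "or misses the cortex (geometry error)")
      eps[i, ] <- ep
      true_reg <- endpoint_region(ep["y"], geom)
      if (astrals$reaches[i] && !identical(true_reg, astrals$region[i]))
        stop("astral ", i, ": declared region '", astrals$region[i],
             "' disagrees with the partition induced by the foci ('",
             true_reg, "')")
    }
    pz <- if (nd == 3L) geom$poles[astrals$pole, 3] else rep(0, nrow(astrals))
    seg_tab <- data.frame(
      pole = astrals$pole, angle_deg = astrals$angle_deg,
      reaches = astrals$reaches, region = astrals$region,
      x0 = geom$poles[astrals$pole, 1], y0 = geom$poles[astrals$pole, 2],
      x1 = eps[, 1], y1 = eps[, 2], z = pz)
    rc <- seg_tab[seg_tab$reaches, ]
    for (r in c("apical", "basal", "central"))
      census[r] <- sum(rc$region == r)
  }

  # --- support masks ---------------------------------------------------
  ax <- geom$soma_axes[1]; ay <- geom$soma_axes[2]
  az <- if (nd == 3L) geom$soma_axes[3] else NA_real_
  ex2 <- outer(((xs - geom$centre[1]) / ax)^2, ((ys - geom$centre[2]) / ay)^2, "+")
  soma <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    zq <- if (nd == 3L) ((zs[k] - cz) / az)^2 else 0
    soma[, , k] <- ex2 + zq <= 1
  }
  u <- geom$plate_axis; w <- geom$spindle_axis
  X <- matrix(xs, nx, ny) - geom$centre[1]
  Y <- matrix(ys, nx, ny, byrow = TRUE) - geom$centre[2]
  Pu <- X * u[1] + Y * u[2]
  Pv <- X * w[1] + Y * w[2]
  plate2d <- (Pu / spec$plate_axes[1])^2 + (Pv / spec$plate_axes[2])^2 <= 1
  body2d <- (Pv / spec$pole_offset)^2 + (Pu / (0.8 * spec$plate_axes[1]))^2 <= 1
  plate_z_half <- if (nd == 3L) min(1.0, az * 0.6) else Inf
  spind_z_half <- if (nd == 3L) min(1.0, az * 0.6) else Inf

  plate_sup <- array(FALSE, c(nx, ny, nz))
  body_sup <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    inz_p <- abs(zs[k] - cz) <= plate_z_half || nd == 2L
    inz_s <- abs(zs[k] - cz) <= spind_z_half || nd == 2L
    if (inz_p) plate_sup[, , k] <- plate2d
    if (inz_s) body_sup[, , k] <- body2d
  }

  # --- DNA channel -----------------------------------------------------
  # The plate is rendered and PSF-blurred; each sub-resolution focus then
  # adds a PSF-width Gaussian of amplitude 1 on top, so the focus peaks
  # are twice the plate intensity (the brightest DNA voxels) exactly.
  sigma_px <- spec$psf_sigma / dx
  foci_sigma <- sqrt(0.15^2 + spec$psf_sigma^2)
  dna <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    sec <- blur_section(ifelse(plate_sup[, , k], 1, 0), sigma_px)
    zf <- if (nd == 3L) exp(-(zs[k] - cz)^2 / (2 * 0.4^2)) else 1
    if (zf > 1e-8 && (nd == 2L || abs(zs[k] - cz) <= plate_z_half))
      for (i in seq_len(nrow(geom$foci_world)))
        sec <- add_spot(sec, geom$foci_world[i, 1], geom$foci_world[i, 2],
                        amp = 1, sigma = foci_sigma, xs, ys, zfac = zf)
    dna[, , k] <- sec
  }

  # --- tubulin channel -------------------------------------------------
  rod_z <- if (nd == 3L)
    vapply(seq_len(nrow(geom$poles)),
           function(p) which.min(abs(zs - geom$poles[p, 3])), integer(1))
  else c(1L, 1L)
  tub <- array(0, c(nx, ny, nz))
  spindle_sup <- array(FALSE, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    sec <- ifelse(body_sup[, , k], 0.6, 0)
    rods <- matrix(0, nx, ny)
    if (!is.null(seg_tab))
      for (i in seq_len(nrow(seg_tab)))
        if (rod_z[seg_tab$pole[i]] == k || nd == 2L) {
          # overlapping rods composite by maximum: tubulin stain density
          # along a rod does not add up where rods converge at the pole
          one <- splat_rod(matrix(0, nx, ny),
                           c(seg_tab$x0[i], seg_tab$y0[i]),
                           c(seg_tab$x1[i], seg_tab$y1[i]), dx, dy)
          rods <- pmax(rods, one)
        }
    sec <- pmax(sec, 2.5 * rods)   # rods must survive the PSF blur
    for (p in 1:2) {
      zf <- if (nd == 3L)
        exp(-(zs[k] - geom$poles[p, 3])^2 / (2 * 0.5^2)) else 1
      sec <- add_spot(sec, geom$poles[p, 1], geom$poles[p, 2],
                      amp = 1.5, sigma = 0.3, xs, ys, zfac = zf)
    }
    tub[, , k] <- blur_section(sec, sigma_px)
    # central spindle mask: everything the no-astral rendering touches
    base <- ifelse(body_sup[, , k], 0.6, 0)
    for (p in 1:2) {
      zf <- if (nd == 3L)
        exp(-(zs[k] - geom$poles[p, 3])^2 / (2 * 0.5^2)) else 1
      base <- add_spot(base, geom$poles[p, 1], geom$poles[p, 2],
                       amp = 1.5, sigma = 0.3, xs, ys, zfac = zf)
    }
    spindle_sup[, , k] <- blur_section(base, sigma_px) > 0
  }

  # --- cortical marker channel ----------------------------------------
  ctx <- array(0, c(nx, ny, nz))
  apical_mid <- c(geom$centre[1], geom$surface_y)
  contour_gt <- NULL
  kc <- if (nd == 3L) which.min(abs(zs - cz)) else 1L
  for (k in seq_len(nz)) {
    msk <- soma[, , k]
    if (!any(msk)) next
    sec <- ifelse(msk, spec$cytoplasm_level, 0)
    ch <- contour_chain(msk, apical_mid, spacing = c(dx, dy))
    vals <- spec$cytoplasm_level + pmax(spec$cortical_profile_fn(ch$s), 0)
    sec[ch$chain] <- vals
    ctx[, , k] <- sec
    if (k == kc)
      contour_gt <- list(chain = ch$chain, s = ch$s,
                         profile = spec$cortical_profile_fn(ch$s))
  }

  # --- noise -----------------------------------------------------------
  chans <- list(dna = dna, tubulin = tub, cortical = ctx)
  g <- spec$noise$poisson_gain
  sdg <- spec$noise$gaussian_sd
  if (g > 0)
    chans <- lapply(chans, function(a) {
      v <- stats::rpois(length(a), as.numeric(a) * g) / g
      array(v, dim(a))
    })
  if (sdg > 0)
    chans <- lapply(chans, function(a)
      a + array(stats::rnorm(length(a), 0, sdg), dim(a)))
  if (nd == 2L)
    chans <- lapply(chans, function(a) { dim(a) <- dim(a)[1:2]; a })

  surface <- apical_surface(cbind(x = c(0, geom$width),
                                  y = c(geom$surface_y, geom$surface_y)))
  stack <- image_stack(chans, spec$voxel_spacing,
                       metadata = list(apical_surface = unclass(surface)))
  drop2 <- function(a) if (nd == 2L) { dim(a) <- dim(a)[1:2]; a } else a
  gt <- structure(list(
    spec = spec, nd = nd, spacing = spec$voxel_spacing,
    dim = c(nx, ny, nz), centre = geom$centre, cz = cz,
    apical_surface = surface, surface_y = geom$surface_y,
    plate_angle_deg = spec$plate_angle_deg,
    plate_axes = spec$plate_axes, plate_axis_dir = u, spindle_axis = w,
    poles = geom$poles, foci_world = geom$foci_world,
    partition_planes = geom$planes,
    astrals = seg_tab, census = census,
    cortical_profile_fn = spec$cortical_profile_fn,
    cytoplasm_level = spec$cytoplasm_level,
    contour = contour_gt, central_z = kc,
    soma_mask = drop2(soma), plate_support = drop2(plate_sup),
    central_spindle_mask = drop2(spindle_sup)),
    class = "cell_ground_truth")
  list(stack = stack, ground_truth = gt)
}

#' @export
print.cell_ground_truth <- function(x, ...) {
  cat("<cell_ground_truth> plate angle ", signif(x$plate_angle_deg, 4),
      " deg, ", nrow(x$foci_world), " foci, census (apical/basal/central): ",
      paste(x$census, collapse = "/"), "\n", sep = "")
  invisible(x)
}
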