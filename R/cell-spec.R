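#' Specification of one synthetic mitotic cell
#'
#' Describes a mitotic neural progenitor as rendered by
#' [make_mitotic_cell()]: an ellipsoidal soma below a flat apical
#' (ventricular) surface, a metaphase chromosome plate tilted by
#' `plate_angle_deg` from the apico-basal axis and carrying bright
#' peri/centromeric heterochromatin foci, two spindle poles on the axis
#' perpendicular to the plate, astral microtubule rods fanning from the
#' poles toward the cortex, and a cortical marker band whose intensity
#' follows `cortical_profile_fn` along the normalized clockwise perimeter.
#'
#' @param soma_axes semi-axes of the soma in um: length 2 (`c(ax, ay)`,
#'   a single optical section is rendered) or 3 (`c(ax, ay, az)`, a 3D
#'   stack).
#' @param plate_angle_deg signed deviation of the plate main axis from the
#'   apico-basal axis, degrees in `[-90, 90]`; 0 is "vertical" (plate along
#'   the apico-basal axis), positive tilts the basal end toward +x.
#' @param plate_axes semi-axes of the plate ellipse in um,
#'   `c(long, short)`, long along the plate axis.
#' @param foci_positions n x 2 matrix of focus positions (um) relative to
#'   the plate centre, expressed in the plate frame (column 1 along the
#'   plate long axis, column 2 across); all must lie inside the plate
#'   envelope. `NULL` lets [make_mitotic_cell()] refuse; use
#'   [random_cell_spec()] to sample them.
#' @param pole_offset distance (um) from the plate centre to each spindle
#'   pole along the spindle (pole--pole) axis.
#' @param pole_dz optional z offset (um) of the two poles, `c(dz1, dz2)`,
#'   used to pose "side view" cells in 3D stacks.
#' @param astral_spec data frame with one row per astral microtubule:
#'   `pole` (1 or 2), `angle_deg` (direction of the rod measured from the
#'   outward spindle-axis direction at that pole, positive toward apical),
#'   `reaches` (logical, does the rod reach the cell periphery) and
#'   `region` (`"apical"`, `"basal"` or `"central"`, the cortical region of
#'   its endpoint). May be `NULL` for a cell without astrals.
#' @param cortical_profile_fn function of the normalized clockwise arc
#'   position `s` in `[0, 1)` (0 at the middle of the apical cortex)
#'   returning the cortical marker intensity above cytoplasm; intensities
#'   are non-negative (negative values are clipped at 0 when rendering).
#' @param cytoplasm_level diffuse cytoplasmic intensity of the cortical
#'   marker channel inside the soma.
#' @param noise list with `gaussian_sd` (additive, intensity units) and
#'   `poisson_gain` (photons per intensity unit; 0 disables shot noise).
#'   Both default to off.
#' @param voxel_spacing um per voxel, `c(x, y)` or `c(x, y, z)`.
#' @param psf_sigma in-plane Gaussian point-spread sigma in um applied to
#'   the DNA and tubulin channels (the cortical band is painted at pixel
#'   resolution and left unblurred).
#' @param cortex_inset distance (um) inside the soma boundary at which a
#'   cortex-reaching astral endpoint is placed.
#' @param stop_fraction fraction of the pole-to-cortex distance at which a
#'   non-reaching astral stops.
#' @param margin lateral free space (um) between the soma and the image
#'   border; the apical surface line sits halfway between the soma apex
#'   and the image border.
#' @return A validated object of class `"cell_spec"`.
#' @seealso [random_cell_spec()], [make_mitotic_cell()]
#' @export
cell_spec <- function(soma_axes = c(5.0, 6.2),
                      plate_angle_deg = 0,
                      plate_axes = NULL,
                      foci_positions = NULL,
                      pole_offset = NULL,
                      pole_dz = c(0, 0),
                      astral_spec = NULL,
                      cortical_profile_fn = function(s) rep(1, length(s)),
                      cytoplasm_level = 0.3,
                      noise = list(gaussian_sd = 0, poisson_gain = 0),
                      voxel_spacing = NULL,
                      psf_sigma = 0.10,
                      cortex_inset = 0.4,
                      stop_fraction = 0.65,
                      margin = 1.5) {
  soma_axes <- as.numeric(soma_axes)
  nd <- length(soma_axes)
  if (!nd %in% c(2L, 3L) || any(soma_axes <= 0))
    stop("'soma_axes' must be 2 or 3 positive semi-axes (um)")
  if (is.null(voxel_spacing))
    voxel_spacing <- if (nd == 2L) c(0.09, 0.09) else c(0.09, 0.09, 0.75)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) != nd || any(voxel_spacing <= 0))
    stop("'voxel_spacing' must be ", nd, " positive values")
  if (abs(plate_angle_deg) > 90) stop("'plate_angle_deg' must be in [-90, 90]")
  if (is.null(plate_axes))
    plate_axes <- c(0.5, 0.18) * min(soma_axes[1:2])
  if (length(plate_axes) != 2 || any(plate_axes <= 0) ||
      plate_axes[1] <= plate_axes[2])
    stop("'plate_axes' must be c(long, short) with long > short > 0")
  if (is.null(pole_offset)) pole_offset <- plate_axes[2] + 1.0
  if (pole_offset <= plate_axes[2])
    stop("'pole_offset' must place the poles outside the plate")

  if (!is.null(foci_positions)) {
    foci_positions <- as.matrix(foci_positions)
    if (ncol(foci_positions) != 2) stop("'foci_positions' must be n x 2")
    inside <- (foci_positions[, 1] / plate_axes[1])^2 +
      (foci_positions[, 2] / plate_axes[2])^2
    if (any(inside >= 1)) stop("all foci must lie inside the plate envelope")
  }
  if (!is.null(astral_spec)) {
    astral_spec <- as.data.frame(astral_spec)
    need <- c("pole", "angle_deg", "reaches", "region")
    if (!all(need %in% names(astral_spec)))
      stop("'astral_spec' needs columns: ", paste(need, collapse = ", "))
    if (!all(astral_spec$pole %in% c(1, 2)))
      stop("astral 'pole' must be 1 or 2")
    if (!all(astral_spec$region %in% c("apical", "basal", "central")))
      stop("astral 'region' must be apical, basal or central")
    if (any(abs(astral_spec$angle_deg) >= 90))
      stop("astral directions must stay within the outward hemisphere ",
           "(|angle_deg| < 90); rods may not exit through the plate")
  }
  if (is.null(noise$gaussian_sd)) noise$gaussian_sd <- 0
  if (is.null(noise$poisson_gain)) noise$poisson_gain <- 0
  if (noise$gaussian_sd < 0 || noise$poisson_gain < 0)
    stop("noise parameters must be non-negative")

  structure(list(
    soma_axes = soma_axes, plate_angle_deg = plate_angle_deg,
    plate_axes = plate_axes, foci_positions = foci_positions,
    pole_offset = pole_offset, pole_dz = pole_dz,
    astral_spec = astral_spec,
    cortical_profile_fn = cortical_profile_fn,
    cytoplasm_level = cytoplasm_level, noise = noise,
    voxel_spacing = voxel_spacing, psf_sigma = psf_sigma,
    cortex_inset = cortex_inset, stop_fraction = stop_fraction,
    margin = margin), class = "cell_spec")
}

#' Sample a randomized, self-consistent cell specification
#'
#' Draws focus positions and astral directions so that the rendered cell
#' carries exactly the requested census of cortex-reaching astrals per
#' region. Directions are sampled in the outward hemisphere of each pole
#' with a minimum angular separation (so rods stay resolvable) and
#' endpoints keep a safety margin in y from the two partition planes (so
#' the region label is unambiguous at pixel resolution).
#'
#' @param n_apical,n_basal,n_central cortex-reaching astral counts per
#'   region. Central astrals are split between poles; apical/basal ones
#'   are drawn from whichever pole admits a valid direction.
#' @param n_short number of additional astrals that stop short of the
#'   cortex (excluded from every census).
#' @param plate_angle_deg plate tilt; defaults to a small random tilt.
#' @param n_foci number of peri/centromeric foci (>= 2 so both partition
#'   planes are defined).
#' @param seed integer seed; all randomness comes from one generator.
#' @param min_sep_deg minimum angular separation between astrals of the
#'   same pole.
#' @param plane_margin minimum |y| distance (um) of astral endpoints from
#'   the two partition planes.
#' @param ... further arguments passed to [cell_spec()].
#' @return A `"cell_spec"` whose `foci_positions` and `astral_spec` are
#'   filled in.
#' @export
random_cell_spec <- function(n_apical = 5, n_basal = 6, n_central = 9,
                             n_short = 0,
                             plate_angle_deg = NULL,
                             n_foci = 8, seed = 1,
                             min_sep_deg = 8, plane_margin = 0.5, ...) {
  if (n_foci < 2) stop("need n_foci >= 2 to define both partition planes")
  set.seed(seed)
  if (is.null(plate_angle_deg)) plate_angle_deg <- stats::runif(1, -20, 20)
  sp <- cell_spec(plate_angle_deg = plate_angle_deg, ...)

  # one attempt: draw foci, classify the feasible angle windows per
  # (pole, region), and spread the census quota over them; NULL when the
  # windows cannot hold the quota at the required angular separation
  attempt_layout <- function() {
    # foci: inside the plate envelope (75% along, 45% across, so their
    # rendered spots stay within the plate), pairwise separation >= 0.55
    # um (still optically resolvable)
    foci <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(foci) < n_foci && tries < 4000) {
      tries <- tries + 1
      u <- stats::runif(1, -0.75, 0.75) * sp$plate_axes[1]
      v <- stats::runif(1, -0.45, 0.45) * sp$plate_axes[2]
      if (nrow(foci) &&
          min(sqrt((foci[, 1] - u)^2 + (foci[, 2] - v)^2)) < 0.55) next
      foci <- rbind(foci, c(u, v))
    }
    if (nrow(foci) < n_foci) return(NULL)

    geom <- cell_geometry(cell_spec(plate_angle_deg = plate_angle_deg,
                                    foci_positions = foci, ...))
    # candidate (pole, angle) grid, classified by endpoint region
    grid <- expand.grid(pole = 1:2, angle_deg = seq(-87, 87, by = 0.5))
    grid$region <- NA_character_
    for (i in seq_len(nrow(grid))) {
      ep <- astral_endpoint(geom, grid$pole[i], grid$angle_deg[i],
                            reaches = TRUE)
      if (!is.null(ep))
        grid$region[i] <- endpoint_region(ep["y"], geom,
                                          margin = plane_margin)
    }
    # contiguous feasible angle windows per (pole, region)
    windows <- list()
    for (pole in 1:2) {
      sub <- grid[grid$pole == pole, , drop = FALSE]
      sub <- sub[order(sub$angle_deg), , drop = FALSE]
      ok <- !is.na(sub$region)
      if (!any(ok)) next
      run_id <- cumsum(c(TRUE, diff(which(ok)) > 1 |
                           sub$region[ok][-1] != sub$region[ok][-sum(ok)]))
      oki <- which(ok)
      for (rid in unique(run_id)) {
        sel <- oki[run_id == rid]
        windows[[length(windows) + 1]] <-
          list(pole = pole, region = sub$region[sel[1]],
               lo = sub$angle_deg[sel[1]],
               hi = sub$angle_deg[sel[length(sel)]])
      }
    }
    quota <- c(apical = n_apical, basal = n_basal, central = n_central)
    rows <- list()
    angles_used <- list(numeric(0), numeric(0))
    for (reg in names(quota)) {
      need <- quota[reg]
      if (need == 0) next
      wr <- Filter(function(w) w$region == reg, windows)
      if (!length(wr)) return(NULL)
      caps <- vapply(wr, function(w)
        floor((w$hi - w$lo) / min_sep_deg) + 1, numeric(1))
      if (sum(caps) < need) return(NULL)
      ord <- order(caps, decreasing = TRUE)
      take <- integer(length(wr))
      rem <- need
      for (i in ord) {                  # largest windows first
        take[i] <- min(caps[i], rem)
        rem <- rem - take[i]
        if (rem == 0) break
      }
      for (i in seq_along(wr)) {
        if (!take[i]) next
        w <- wr[[i]]
        width <- w$hi - w$lo
        n <- take[i]
        if (n == 1) {
          centres <- w$lo + width / 2
          slack <- width / 2
        } else {
          centres <- w$lo + width * (seq_len(n) - 1) / (n - 1)
          slack <- max(0, (width / (n - 1) - min_sep_deg) / 2)
        }
        jit <- stats::runif(n, -1, 1) * min(1, slack)
        angs <- pmin(pmax(centres + jit, w$lo), w$hi)
        for (ang in angs) {
          angles_used[[w$pole]] <- c(angles_used[[w$pole]], ang)
          rows[[length(rows) + 1]] <-
            data.frame(pole = w$pole, angle_deg = ang, reaches = TRUE,
                       region = reg)
        }
      }
    }
    list(foci = foci, geom = geom, grid = grid, rows = rows,
         angles_used = angles_used)
  }

  layout <- NULL
  for (attempt in 1:12) {
    layout <- attempt_layout()
    if (!is.null(layout)) break
  }
  if (is.null(layout))
    stop("could not realize the requested foci and astral census; ",
         "reduce counts or min_sep_deg")
  foci <- layout$foci
  geom <- layout$geom
  grid <- layout$grid
  rows <- layout$rows
  angles_used <- layout$angles_used
  n_placed_short <- 0
  for (i in seq_len(nrow(grid))) {
    if (n_placed_short >= n_short) break
    pole <- grid$pole[i]; ang <- grid$angle_deg[i]
    if (length(angles_used[[pole]]) &&
        min(abs(angles_used[[pole]] - ang)) < min_sep_deg) next
    ep <- astral_endpoint(geom, pole, ang, reaches = FALSE)
    if (is.null(ep)) next
    reg <- endpoint_region(ep["y"], geom, margin = 0)
    angles_used[[pole]] <- c(angles_used[[pole]], ang)
    rows[[length(rows) + 1]] <-
      data.frame(pole = pole, angle_deg = ang, reaches = FALSE,
                 region = reg)
    n_placed_short <- n_placed_short + 1
  }
  astrals <- do.call(rbind, rows)
  cell_spec(plate_angle_deg = plate_angle_deg, foci_positions = foci,
            astral_spec = astrals, ...)
}
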