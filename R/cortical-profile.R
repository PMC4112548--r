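# Cortical marker (LGN) intensity profiling along the cell perimeter.

# ordered boundary chain of the largest object in a binary mask.
# Returns 1-based pixel indices ordered clockwise as displayed (apical side
# up, x rightward), starting at the chain point nearest 'apical_midpoint'
# (um), plus each point's normalized arc position s in [0, 1).
contour_chain <- function(mask, apical_midpoint, spacing) {
  lab <- EBImage::bwlabel(ifelse(mask, 1, 0))
  n_obj <- max(lab)
  if (n_obj < 1) stop("empty mask")
  sizes <- tabulate(lab[lab > 0], nbins = n_obj)
  big <- which.max(sizes)
  oc <- EBImage::ocontour(lab)[[big]]
  chain <- oc + 1L                       # ocontour is 0-based
  px <- (chain[, 1] - 0.5) * spacing[1]
  py <- (chain[, 2] - 0.5) * spacing[2]
  n <- nrow(chain)
  if (n < 3) stop("mask has no traceable boundary")
  nxt <- c(2:n, 1)
  shoelace <- sum(px * py[nxt] - px[nxt] * py)
  if (shoelace < 0) {                    # make it clockwise on display
    chain <- chain[n:1, , drop = FALSE]
    px <- rev(px); py <- rev(py)
  }
  start <- which.min((px - apical_midpoint[1])^2 + (py - apical_midpoint[2])^2)
  idx <- c(start:n, seq_len(start - 1))
  chain <- chain[idx, , drop = FALSE]
  px <- px[idx]; py <- py[idx]
  steps <- sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2)
  perim <- sum(steps)
  s <- c(0, cumsum(steps[-n])) / perim
  list(chain = chain, coords_um = cbind(x = px, y = py), s = s,
       perimeter_um = perim)
}

#' Extract the one-pixel cell contour, clockwise from the apical midpoint
#'
#' Traces the 8-connected boundary chain of a simply connected soma mask,
#' orients it clockwise (as displayed with the apical surface up), and
#' rotates it to start at the boundary point nearest `apical_midpoint` --
#' the point s = 0 of the normalized perimeter.
#'
#' @param mask logical or 0/1 matrix `[x, y]`, a single soma; must be one
#'   connected component without holes and with a non-empty interior.
#' @param apical_midpoint `c(x, y)` in um, the middle of the apical domain.
#' @param spacing pixel size in um, `c(x, y)`.
#' @return An object of class `"cell_contour"`: `chain` (n x 2 pixel
#'   indices), `coords_um`, `s` (normalized arc positions in `[0, 1)`),
#'   `perimeter_um`, `spacing`.
#' @export
extract_contour <- function(mask, apical_midpoint, spacing = c(1, 1)) {
  m <- ifelse(mask > 0, 1, 0)
  if (!sum(m)) stop("empty mask")
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1) stop("mask must be a single connected component")
  filled <- EBImage::fillHull(m)
  if (any(filled != m)) stop("mask has holes; contour undefined")
  ch <- contour_chain(m, apical_midpoint, spacing)
  interior <- sum(m) - nrow(unique(ch$chain))
  if (interior < 1) stop("mask has no interior (too thin to profile)")
  structure(c(ch, list(spacing = spacing)), class = "cell_contour")
}

#' Read image intensities along a contour
#'
#' @param contour a [extract_contour()] result.
#' @param image numeric matrix `[x, y]`, same geometry as the mask the
#'   contour was traced on.
#' @return Numeric vector of intensities, one per chain point.
#' @export
sample_contour_intensity <- function(contour, image) {
  stopifnot(inherits(contour, "cell_contour"))
  image[contour$chain]
}

#' Erode a soma mask to its cytoplasmic interior
#'
#' @param mask soma mask matrix.
#' @param band_width expected cortical-band width in pixels; the mask is
#'   eroded by a disc of this radius.
#' @return Logical matrix of interior pixels.
#' @export
soma_interior <- function(mask, band_width = 3) {
  m <- ifelse(mask > 0, 1, 0)
  er <- EBImage::erode(m, EBImage::makeBrush(2 * band_width + 1, "disc"))
  er > 0
}

#' Subtract the diffuse cytoplasmic signal from cortical intensities
#'
#' The cytoplasmic level is estimated as the median intensity over the
#' eroded soma interior (robust against the bright cortical band) and
#' subtracted from the raw contour intensities; negative results are
#' clipped at 0.
#'
#' @param raw numeric vector of raw contour intensities.
#' @param image the intensity image the values were read from.
#' @param interior logical matrix of cytoplasmic interior pixels, e.g.
#'   from [soma_interior()].
#' @return Numeric vector of background-corrected intensities (>= 0), with
#'   the estimated cytoplasmic level in attribute `"cytoplasm"`.
#' @export
subtract_cytoplasm <- function(raw, image, interior) {
  if (!any(interior)) stop("empty eroded interior; cannot estimate cytoplasm")
  bg <- stats::median(image[interior])
  structure(pmax(raw - bg, 0), cytoplasm = bg)
}

#' Resample contour intensities to 100 equidistant normalized positions
#'
#' Linear (periodic) interpolation of the corrected contour intensities at
#' the 100 positions s = 0.005, 0.015, ..., 0.995 of the normalized
#' perimeter, so profiles from cells of different sizes are comparable
#' point by point.
#'
#' @param values numeric vector of (corrected) intensities along the
#'   contour.
#' @param positions normalized arc positions in `[0, 1)` of `values`
#'   (e.g. `contour$s`); defaults to equidistant positions.
#' @param n number of output positions (100).
#' @return An object of class `"cortical_profile"`: `s` (the n positions)
#'   and `intensity`.
#' @export
resample_profile <- function(values, positions = NULL, n = 100L) {
  m <- length(values)
  if (m < 2) stop("need at least 2 contour values")
  if (is.null(positions)) positions <- (seq_len(m) - 1) / m
  if (length(positions) != m) stop("positions/values length mismatch")
  ord <- order(positions)
  positions <- positions[ord]; values <- values[ord]
  # periodic padding for interpolation across the s = 0 wrap
  xp <- c(positions[m] - 1, positions, positions[1] + 1)
  yp <- c(values[m], values, values[1])
  s_out <- (seq_len(n) - 0.5) / n
  out <- stats::approx(xp, yp, xout = s_out)$y
  structure(list(s = s_out, intensity = out), class = "cortical_profile")
}

#' @export
print.cortical_profile <- function(x, ...) {
  cat("<cortical_profile> ", length(x$s), " positions, intensity range ",
      paste(signif(range(x$intensity), 4), collapse = " .. "), "\n", sep = "")
  invisible(x)
}

#' Default cortical region windows on the 100-point profile
#'
#' Apical cortex is the 20% of perimeter centred on s = 0, the basal
#' cortex the 20% centred on s = 0.5 (directly opposite), and the two
#' central stretches the remainder (central-1 on the s-increasing side).
#' The fractions are a package default, adjustable per analysis; outputs
#' flag them as such.
#'
#' @param apical_half,basal_half half-widths of the apical and basal
#'   windows as fractions of perimeter.
#' @param n profile length.
#' @return Named list of index vectors (`apical`, `central1`, `basal`,
#'   `central2`) partitioning `1:n`.
#' @export
default_region_windows <- function(apical_half = 0.10, basal_half = 0.10,
                                   n = 100L) {
  s <- (seq_len(n) - 0.5) / n
  apical <- which(s < apical_half | s >= 1 - apical_half)
  basal <- which(s >= 0.5 - basal_half & s < 0.5 + basal_half)
  central1 <- setdiff(which(s < 0.5), c(apical, basal))
  central2 <- setdiff(seq_len(n), c(apical, basal, central1))
  list(apical = apical, central1 = central1, basal = basal,
       central2 = central2)
}

#' Mean corrected intensity per cortical region
#'
#' @param profile a [resample_profile()] result.
#' @param windows named list of index vectors partitioning the profile
#'   positions, as from [default_region_windows()].
#' @return Named list of means (`apical`, `central1`, `basal`, `central2`,
#'   `central_pooled`), with attribute `"windows_default"` flagging that
#'   the window fractions are a package choice, not a measured quantity.
#' @export
region_means <- function(profile, windows = default_region_windows()) {
  stopifnot(inherits(profile, "cortical_profile"))
  n <- length(profile$s)
  idx <- sort(unlist(windows, use.names = FALSE))
  if (length(idx) != n || !identical(idx, seq_len(n)))
    stop("windows must partition positions 1..", n,
         " without overlap or gaps")
  means <- lapply(windows, function(i) mean(profile$intensity[i]))
  means$central_pooled <-
    mean(profile$intensity[c(windows$central1, windows$central2)])
  structure(means, windows_default = TRUE)
}
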