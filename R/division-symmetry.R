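# Bisect-or-bypass classification of late-anaphase divisions with respect
# to the apical membrane domain.

#' Apical membrane domain on the surface polyline
#'
#' The cadherin-negative stretch of apical plasma membrane, given as an
#' arc-length interval along the apical surface polyline.
#'
#' @param start_arc,end_arc arc-length coordinates (um) of the domain ends
#'   along the surface polyline, `0 < end - start < total length`.
#' @param surface the [apical_surface()] the interval lives on.
#' @return An object of class `"apical_domain"`.
#' @export
apical_domain <- function(start_arc, end_arc, surface) {
  stopifnot(inherits(surface, "apical_surface"))
  total <- max(polyline_cumlen(unclass(surface)))
  len <- end_arc - start_arc
  if (len <= 0 || len >= total)
    stop("domain length must be positive and smaller than the surface")
  if (start_arc < 0 || end_arc > total)
    stop("domain must lie on the surface polyline")
  structure(list(start_arc = start_arc, end_arc = end_arc,
                 surface = surface), class = "apical_domain")
}

#' Cleavage-plane geometry in the coronal view
#'
#' The prospective cleavage plane as a line (point plus direction). At
#' anaphase onset the chromosome-plate angle is practically identical to
#' the cleavage angle of the soma, so the line is usually built as the
#' plate axis through the soma centre; the cleavage plane is perpendicular
#' to the anaphase separation axis by construction.
#'
#' @param point a point on the cleavage line, `c(x, y)` um.
#' @param direction direction of the line (normalized internally).
#' @return An object of class `"cleavage_geometry"` with the direction
#'   unit-normalized and `separation_axis` the perpendicular.
#' @export
cleavage_geometry <- function(point, direction) {
  dir <- unit(direction)
  structure(list(point = as.numeric(point), direction = dir,
                 separation_axis = c(-dir[2], dir[1])),
            class = "cleavage_geometry")
}

#' Classify a division as bisecting or bypassing the apical domain
#'
#' The cleavage line is intersected with the apical surface polyline;
#' the division bisects when the intersection falls strictly inside the
#' domain interval, and bypasses otherwise. An intersection exactly on a
#' domain endpoint is a bypass: bisection requires splitting the domain
#' into two non-empty parts.
#'
#' @param domain an [apical_domain()].
#' @param cleavage a [cleavage_geometry()].
#' @return `"bisect"` or `"bypass"`, with the intersection arc-length in
#'   attribute `"arc"`.
#' @export
classify_division <- function(domain, cleavage) {
  stopifnot(inherits(domain, "apical_domain"),
            inherits(cleavage, "cleavage_geometry"))
  hit <- line_polyline_intersection(cleavage$point, cleavage$direction,
                                    unclass(domain$surface))
  if (is.null(hit))
    stop("cleavage line does not intersect the apical surface")
  cls <- if (hit$arc > domain$start_arc && hit$arc < domain$end_arc)
    "bisect" else "bypass"
  structure(cls, arc = hit$arc)
}

#' Percentage of asymmetric (bypassing) divisions
#'
#' @param classifications character vector of `"bisect"` / `"bypass"`.
#' @return `100 * bypass / n`.
#' @export
percent_asymmetric <- function(classifications) {
  n <- length(classifications)
  if (!n) stop("no classifications")
  if (!all(classifications %in% c("bisect", "bypass")))
    stop("classifications must be 'bisect' or 'bypass'")
  100 * sum(classifications == "bypass") / n
}

#' Simulate division geometries over a centred apical domain
#'
#' Monte-Carlo geometry linking spindle-orientation variability to
#' division asymmetry: each division has a cleavage line through a cell
#' centre at depth `depth_um` below a flat apical surface, tilted from the
#' apico-basal axis by an angle drawn from N(0, `angle_sd_deg`); the
#' domain is a centred interval of half-width `domain_halfwidth_um`.
#' Larger angular spread moves more intersections outside the domain, so
#' the bypass percentage is non-decreasing in `angle_sd_deg`.
#'
#' @param n number of divisions.
#' @param angle_sd_deg SD of the cleavage-angle distribution, degrees.
#' @param domain_halfwidth_um half-width of the apical domain, um.
#' @param depth_um depth of the cell centre below the surface, um.
#' @param seed integer seed.
#' @return Character vector of classifications (length `n`).
#' @export
simulate_divisions <- function(n, angle_sd_deg, domain_halfwidth_um = 0.75,
                               depth_um = 5, seed = 1) {
  set.seed(seed)
  half_surf <- max(50, depth_um * 50)
  surf <- apical_surface(cbind(x = c(-half_surf, half_surf), y = c(0, 0)))
  total <- 2 * half_surf
  dom <- apical_domain(total / 2 - domain_halfwidth_um,
                       total / 2 + domain_halfwidth_um, surf)
  angles <- stats::rnorm(n, 0, angle_sd_deg)
  angles <- pmax(pmin(angles, 85), -85)   # keep an intersection defined
  vapply(angles, function(a) {
    cl <- cleavage_geometry(c(0, depth_um), c(sin(deg2rad(a)),
                                              -cos(deg2rad(a))))
    as.character(classify_division(dom, cl))
  }, character(1))
}
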