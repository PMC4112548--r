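# Internal geometry helpers.
#
# Conventions used package-wide:
#   * physical coordinates are in micrometres (um), points are c(x, y) or
#     c(x, y, z); x is lateral, y runs from the apical (ventricular) surface
#     toward the pial side, z is the optical axis;
#   * image arrays are indexed [x, y] (2D section) or [x, y, z]; voxel
#     (i, j, k) has its centre at ((i - 0.5) * dx, (j - 0.5) * dy,
#     (k - 0.5) * dz);
#   * angles of the plate axis are signed degrees from the apico-basal
#     (+y) axis, positive when the basal end of the axis is displaced
#     toward +x, folded into [-90, 90].

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' @noRd
axis_angle_deg <- function(v) {
  # signed deviation of an (undirected) axis from +y, in [-90, 90]
  if (v[2] < 0) v <- -v
  rad2deg(atan2(v[1], v[2]))
}

#' @noRd
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector has no direction")
  v / n
}

# arc length of an open polyline (n x 2 matrix), per-vertex cumulative
polyline_cumlen <- function(pts) {
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# intersection of segment p1-p2 with segment q1-q2; returns NULL or
# list(point, t, u) with t the parameter along p1-p2, u along q1-q2
segment_intersection <- function(p1, p2, q1, q2, tol = 1e-12) {
  r <- p2 - p1
  s <- q2 - q1
  denom <- r[1] * s[2] - r[2] * s[1]
  if (abs(denom) < tol) return(NULL)
  qp <- q1 - p1
  t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
  u <- (qp[1] * r[2] - qp[2] * r[1]) / denom
  if (t < -tol || t > 1 + tol || u < -tol || u > 1 + tol) return(NULL)
  list(point = p1 + t * r, t = t, u = u)
}

# first intersection of the infinite line point + s * dir with a polyline;
# returns NULL or list(point, arc) where arc is the arc-length position of
# the hit along the polyline
line_polyline_intersection <- function(point, dir, polyline) {
  dir <- unit(dir)
  cum <- polyline_cumlen(polyline)
  hits <- list()
  for (i in seq_len(nrow(polyline) - 1)) {
    q1 <- polyline[i, ]
    q2 <- polyline[i + 1, ]
    s <- q2 - q1
    denom <- dir[1] * s[2] - dir[2] * s[1]
    if (abs(denom) < 1e-12) next
    qp <- q1 - point
    t <- (qp[1] * s[2] - qp[2] * s[1]) / denom
    u <- (qp[1] * dir[2] - qp[2] * dir[1]) / denom
    if (u >= 0 && u <= 1) {
      seg <- sqrt(sum(s^2))
      hits[[length(hits) + 1]] <-
        list(point = point + t * dir, arc = cum[i] + u * seg, absdist = abs(t))
    }
  }
  if (!length(hits)) return(NULL)
  hits[[which.min(vapply(hits, `[[`, numeric(1), "absdist"))]]
}

# does the segment a-b pass through the ellipse given by centre, axis
# direction (unit), semi-axes (a_len along axis, b_len across)?
segment_hits_ellipse <- function(p, q, centre, axis_dir, semi_long, semi_short,
                                 n_check = 64) {
  ts <- seq(0, 1, length.out = n_check)
  px <- p[1] + ts * (q[1] - p[1]) - centre[1]
  py <- p[2] + ts * (q[2] - p[2]) - centre[2]
  u <- px * axis_dir[1] + py * axis_dir[2]
  v <- -px * axis_dir[2] + py * axis_dir[1]
  any((u / semi_long)^2 + (v / semi_short)^2 < 1)
}
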