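# Tissue-level censuses: zone assignment, marker fractions, events per
# unit surface and per unit area.

#' Assign nuclei to cortical zones by depth
#'
#' Zones are half-open bands `[lower, upper)` from the apical surface
#' toward the pial side, so a nucleus exactly on a boundary belongs to the
#' more basal zone. Nuclei outside every band are labelled `"other"`.
#'
#' @param y depth(s) of nucleus centroids, um from the apical surface.
#' @param breaks increasing vector of band edges (um), one more than
#'   `labels`.
#' @param labels zone names, apical to basal.
#' @return Character vector of zone labels.
#' @export
zone_assign <- function(y, breaks = c(0, 60, 100, 160),
                        labels = c("VZ", "SVZ", "CP")) {
  if (length(breaks) != length(labels) + 1)
    stop("need one more break than labels")
  if (any(diff(breaks) <= 0)) stop("breaks must increase apical -> basal")
  out <- rep("other", length(y))
  for (i in seq_along(labels))
    out[y >= breaks[i] & y < breaks[i + 1]] <- labels[i]
  out
}

#' Percentage of nuclei in a zone matching a marker predicate
#'
#' @param nuclei nuclei data frame with columns `zone` and `markers`.
#' @param zone zone to restrict to.
#' @param predicate either a marker name (counts nuclei carrying it) or a
#'   function taking the zone-restricted data frame and returning a
#'   logical vector (e.g. resident APs:
#'   `function(df) has_marker(df$markers, "Pax6") & !has_marker(df$markers, "Tbr2")`).
#' @return Percentage (0..100).
#' @export
marker_fractions <- function(nuclei, zone, predicate) {
  sel <- nuclei[nuclei$zone == zone, , drop = FALSE]
  if (!nrow(sel)) stop("zone '", zone, "' is empty")
  hit <- if (is.function(predicate)) predicate(sel) else
    has_marker(sel$markers, predicate)
  100 * sum(hit) / nrow(sel)
}

#' Events per window of surface length
#'
#' Counts normalized to events per `window` um of apical (ventricular) or
#' pial surface. Given a named count vector (e.g. mitoses per zone), the
#' per-zone rates are reported together with `All`, their sum over the
#' same normalizer.
#'
#' @param counts single count or named vector of counts per zone.
#' @param surface_length_um length of the normalizing surface.
#' @param window normalization window, default 100 um.
#' @return Numeric vector of rates (with `All` appended when `counts` is
#'   named).
#' @export
rate_per_surface <- function(counts, surface_length_um, window = 100) {
  if (surface_length_um <= 0) stop("surface length must be > 0")
  rates <- counts * window / surface_length_um
  if (!is.null(names(counts)) && length(counts) > 1)
    rates <- c(rates, All = sum(counts) * window / surface_length_um)
  rates
}

#' Events per window of tissue area
#'
#' @param count event count (e.g. caspase-3-positive cells).
#' @param area_um2 tissue area in um^2.
#' @param window normalization window, default 10,000 um^2.
#' @return Rate per `window` um^2.
#' @export
rate_per_area <- function(count, area_um2, window = 10000) {
  if (area_um2 <= 0) stop("area must be > 0")
  count * window / area_um2
}
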