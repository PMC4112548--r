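# Synthetic tissue scenes: nuclei with zone and marker labels along an
# apical and a pial surface, for tissue-level censuses.

#' Specification of one synthetic cortical-wall scene
#'
#' A rectangular stretch of dorsolateral cortical wall: the apical
#' (ventricular) surface at y = 0, the pial surface at
#' y = `tissue_height_y`, the VZ/SVZ boundary and the SVZ/CP boundary as
#' horizontal planes in between. Nuclei carry a position, a zone and a
#' set of marker flags (e.g. Pax6, Tbr2, Tbr1, Tis21, PH3, pVim, Casp3).
#'
#' @param nuclei data frame with columns `x_um`, `y_um`, `zone` (one of
#'   `"VZ"`, `"SVZ"`, `"CP"`, `"other"`) and `markers` (character,
#'   semicolon-separated marker names, possibly empty).
#' @param apical_surface_length,pial_surface_length lengths (um) of the
#'   two surfaces bounding the stretch.
#' @param vz_svz_boundary_y,svz_cp_boundary_y,tissue_height_y zone
#'   boundary depths (um from the apical surface), increasing.
#' @param seed integer seed (used when rendering).
#' @return An object of class `"tissue_spec"`. Errors if any nucleus zone
#'   is inconsistent with its y position under the stated boundaries.
#' @export
tissue_spec <- function(nuclei,
                        apical_surface_length = 200,
                        pial_surface_length = 200,
                        vz_svz_boundary_y = 60,
                        svz_cp_boundary_y = 100,
                        tissue_height_y = 160,
                        seed = 1) {
  if (apical_surface_length <= 0 || pial_surface_length <= 0)
    stop("surface lengths must be > 0")
  if (!(0 < vz_svz_boundary_y && vz_svz_boundary_y < svz_cp_boundary_y &&
        svz_cp_boundary_y < tissue_height_y))
    stop("zone boundaries must be ordered apical -> basal")
  nuclei <- as.data.frame(nuclei)
  need <- c("x_um", "y_um", "zone", "markers")
  if (!all(need %in% names(nuclei)))
    stop("'nuclei' needs columns: ", paste(need, collapse = ", "))
  breaks <- c(0, vz_svz_boundary_y, svz_cp_boundary_y, tissue_height_y)
  expected <- zone_assign(nuclei$y_um, breaks, c("VZ", "SVZ", "CP"))
  bad <- which(nuclei$zone != expected)
  if (length(bad))
    stop("nucleus ", bad[1], ": declared zone '", nuclei$zone[bad[1]],
         "' inconsistent with its position (expected '",
         expected[bad[1]], "')")
  nuclei$id <- seq_len(nrow(nuclei))
  structure(list(nuclei = nuclei,
                 apical_surface_length = apical_surface_length,
                 pial_surface_length = pial_surface_length,
                 vz_svz_boundary_y = vz_svz_boundary_y,
                 svz_cp_boundary_y = svz_cp_boundary_y,
                 tissue_height_y = tissue_height_y,
                 seed = seed), class = "tissue_spec")
}

#' Sample a randomized tissue specification
#'
#' Nuclei are placed uniformly within their zone (with a minimum pairwise
#' separation) and markers assigned by zone-typical rules: VZ nuclei are
#' newborn BPs (Tbr2+) with probability `p_tbr2_vz` and resident APs
#' (Pax6+, Tbr2-) otherwise; SVZ nuclei are Tbr2+ with probability
#' `p_tbr2_svz`; CP nuclei are Tbr1+ neurons with probability
#' `p_tbr1_cp`. Apical (VZ, y < 5 um) and basal (SVZ) mitoses carry PH3,
#' and `n_casp3` nuclei anywhere are apoptotic (Casp3+).
#'
#' @param n_vz,n_svz,n_cp interphase nuclei per zone.
#' @param n_mitoses_vz,n_mitoses_svz PH3+ mitotic figures at the apical
#'   surface (VZ) and abventricularly (SVZ).
#' @param n_casp3 apoptotic nuclei.
#' @param p_tbr2_vz,p_tbr2_svz,p_tbr1_cp marker probabilities.
#' @param seed integer seed.
#' @param ... passed to [tissue_spec()] (geometry).
#' @return A `"tissue_spec"`.
#' @export
random_tissue_spec <- function(n_vz = 60, n_svz = 30, n_cp = 40,
                               n_mitoses_vz = 8, n_mitoses_svz = 3,
                               n_casp3 = 2,
                               p_tbr2_vz = 0.34, p_tbr2_svz = 0.85,
                               p_tbr1_cp = 0.6, seed = 1, ...) {
  set.seed(seed)
  geo <- tissue_spec(data.frame(x_um = 1, y_um = 1, zone = "VZ",
                                markers = ""), seed = seed, ...)
  len <- geo$apical_surface_length
  place <- function(n, y0, y1, min_sep = 4.5) {
    pts <- matrix(NA_real_, 0, 2)
    tries <- 0
    while (nrow(pts) < n && tries < 50 * n + 500) {
      tries <- tries + 1
      p <- c(stats::runif(1, 3, len - 3), stats::runif(1, y0, y1))
      if (nrow(pts) &&
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) < min_sep)
        next
      pts <- rbind(pts, p)
    }
    if (nrow(pts) < n) stop("zone too crowded for the requested nuclei")
    pts
  }
  rows <- list()
  add <- function(pts, zone, markers) {
    if (!nrow(pts)) return(invisible())
    rows[[length(rows) + 1]] <<-
      data.frame(x_um = pts[, 1], y_um = pts[, 2],
                 zone = rep(zone, nrow(pts)), markers = markers)
  }
  b1 <- geo$vz_svz_boundary_y; b2 <- geo$svz_cp_boundary_y
  h <- geo$tissue_height_y
  vz <- place(n_vz, 6, b1 - 1)
  add(vz, "VZ", ifelse(stats::runif(n_vz) < p_tbr2_vz, "Tbr2", "Pax6"))
  if (n_mitoses_vz)
    add(place(n_mitoses_vz, 1, 5), "VZ", "PH3;pVim")
  sv <- place(n_svz, b1 + 1, b2 - 1)
  add(sv, "SVZ", ifelse(stats::runif(n_svz) < p_tbr2_svz, "Tbr2", "Pax6"))
  if (n_mitoses_svz)
    add(place(n_mitoses_svz, b1 + 1, b2 - 1), "SVZ", "PH3;pVim")
  cp <- place(n_cp, b2 + 1, h - 1)
  add(cp, "CP", ifelse(stats::runif(n_cp) < p_tbr1_cp, "Tbr1", ""))
  nuc <- do.call(rbind, rows)
  if (n_casp3) {
    idx <- sample(nrow(nuc), n_casp3)
    nuc$markers[idx] <- sub("^;", "", paste(nuc$markers[idx], "Casp3",
                                            sep = ";"))
  }
  tissue_spec(nuc, seed = seed, ...)
}

#' Render a tissue scene: label image, nuclei table and ground truth
#'
#' Nuclei are rendered as labelled discs (value = nucleus id) on a pixel
#' grid. The ground truth stores every census the tissue module measures,
#' computed directly from the specification.
#'
#' @param spec a [tissue_spec()].
#' @param pixel_um label-image pixel size, um.
#' @param nucleus_radius_um disc radius, um.
#' @param max_overlap_frac densities where more than this fraction of
#'   nuclei overlap another nucleus are rejected.
#' @return List with `label_image` (integer matrix `[x, y]`), `nuclei`
#'   (the table: id, x_um, y_um, zone, markers) and `ground_truth`
#'   (class `"tissue_ground_truth"`).
#' @export
make_tissue_scene <- function(spec, pixel_um = 0.5,
                              nucleus_radius_um = 2.2,
                              max_overlap_frac = 0.2) {
  stopifnot(inherits(spec, "tissue_spec"))
  nuc <- spec$nuclei
  n <- nrow(nuc)
  if (n > 1) {
    d <- as.matrix(stats::dist(nuc[, c("x_um", "y_um")]))
    diag(d) <- Inf
    overlapping <- apply(d < 2 * nucleus_radius_um, 1, any)
    if (mean(overlapping) > max_overlap_frac)
      stop("nucleus density too high: ",
           round(100 * mean(overlapping)), "% of nuclei overlap")
  }
  nx <- ceiling(spec$apical_surface_length / pixel_um)
  ny <- ceiling(spec$tissue_height_y / pixel_um)
  lab <- matrix(0L, nx, ny)
  xs <- (seq_len(nx) - 0.5) * pixel_um
  ys <- (seq_len(ny) - 0.5) * pixel_um
  r2 <- nucleus_radius_um^2
  for (i in seq_len(n)) {
    ix <- which(abs(xs - nuc$x_um[i]) <= nucleus_radius_um)
    iy <- which(abs(ys - nuc$y_um[i]) <= nucleus_radius_um)
    if (!length(ix) || !length(iy)) next
    sub <- outer((xs[ix] - nuc$x_um[i])^2, (ys[iy] - nuc$y_um[i])^2, "+") <= r2
    blk <- lab[ix, iy, drop = FALSE]
    blk[sub] <- nuc$id[i]
    lab[ix, iy] <- blk
  }

  has <- function(marker) has_marker(nuc$markers, marker)
  vz <- nuc$zone == "VZ"; svz <- nuc$zone == "SVZ"; cp <- nuc$zone == "CP"
  area <- spec$apical_surface_length * spec$tissue_height_y
  safe_pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  interphase_vz <- vz & !has("PH3")
  gt <- structure(list(
    n_nuclei = n,
    ap_fraction_vz = safe_pct(sum(interphase_vz & has("Pax6") & !has("Tbr2")),
                              sum(interphase_vz)),
    bp_fraction_vz = safe_pct(sum(interphase_vz & has("Tbr2")),
                              sum(interphase_vz)),
    tbr2_fraction_svz = safe_pct(sum(svz & !has("PH3") & has("Tbr2")),
                                 sum(svz & !has("PH3"))),
    mitoses_per_100um = c(
      VZ = 100 * sum(vz & has("PH3")) / spec$apical_surface_length,
      SVZ = 100 * sum(svz & has("PH3")) / spec$apical_surface_length,
      All = 100 * sum((vz | svz) & has("PH3")) /
        spec$apical_surface_length),
    neurons_per_100um = 100 * sum(cp & has("Tbr1")) /
      spec$pial_surface_length,
    casp3_per_10000um2 = 10000 * sum(has("Casp3")) / area,
    area_um2 = area), class = "tissue_ground_truth")
  list(label_image = lab, nuclei = nuc, ground_truth = gt)
}

#' Test marker flags in a semicolon-separated marker string
#'
#' @param markers character vector of semicolon-separated marker names.
#' @param marker single marker name.
#' @return Logical vector.
#' @export
has_marker <- function(markers, marker) {
  if (!length(markers)) return(logical(0))
  markers <- as.character(markers)
  markers[is.na(markers)] <- ""
  vapply(strsplit(markers, ";", fixed = TRUE),
         function(m) marker %in% trimws(m), logical(1))
}

#' Write a nuclei table as CSV
#'
#' Columns: `id, x_um, y_um, zone, markers`.
#'
#' @param nuclei nuclei data frame (as in [make_tissue_scene()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nuclei_csv <- function(nuclei, path) {
  utils::write.csv(nuclei[, c("id", "x_um", "y_um", "zone", "markers")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a nuclei table written by [write_nuclei_csv()]
#'
#' @param path CSV path.
#' @return data frame with the schema checked; a missing column raises an
#'   error naming it.
#' @export
read_nuclei_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x_um", "y_um", "zone", "markers")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("nuclei table is missing column(s): ",
         paste(missing, collapse = ", "))
  df$markers[is.na(df$markers)] <- ""
  df
}
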