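# End-to-end orchestration: configuration, per-cell and per-tissue runs,
# and result tables with provenance.

#' Pipeline run configuration
#'
#' Bundles every tunable of the measurement chain with the simulation (or
#' input) specification. The object is a plain nested list of atomic
#' values, so it round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param seed master integer seed; per-cell seeds are derived from it.
#' @param cells list of cell groups, each a list with `name`, `n` and
#'   `params` (arguments for [random_cell_spec()]).
#' @param tissues list of tissue groups, each a list with `name`, `n` and
#'   `params` (arguments for [random_tissue_spec()]).
#' @param delta_cortex_um astral endpoint-to-boundary tolerance
#'   ("reaching the cell periphery").
#' @param theta_view_deg,max_sections Front/Side view rule.
#' @param sigma_deg BP orientation sector half-angle.
#' @param band_width_px cortical-band width used to erode the soma
#'   interior for the cytoplasm estimate.
#' @param apical_half,basal_half cortical region-window fractions.
#' @param r_pole_um lateral pole extension of the main spindle region.
#' @param domain_halfwidth_um apical-domain half-width for the
#'   bisect/bypass call.
#' @param threshold_policy chromatin threshold policy.
#' @param trajectory list of trajectory-model tunables
#'   (`stiffness_per_anchor`, `noise_sd`, `dt`, `duration`,
#'   `central_fraction`).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(seed = 1,
                       cells = list(),
                       tissues = list(),
                       delta_cortex_um = 1.0,
                       theta_view_deg = 45,
                       max_sections = 3,
                       sigma_deg = 45,
                       band_width_px = 3,
                       apical_half = 0.10,
                       basal_half = 0.10,
                       r_pole_um = 1.5,
                       domain_halfwidth_um = 0.75,
                       threshold_policy = "otsu",
                       trajectory = list(stiffness_per_anchor = 0.08,
                                         noise_sd = 7.5, dt = 1,
                                         duration = 15,
                                         central_fraction = 0.1)) {
  structure(list(seed = as.integer(seed), cells = cells, tissues = tissues,
                 delta_cortex_um = delta_cortex_um,
                 theta_view_deg = theta_view_deg,
                 max_sections = max_sections,
                 sigma_deg = sigma_deg, band_width_px = band_width_px,
                 apical_half = apical_half, basal_half = basal_half,
                 r_pole_um = r_pole_um,
                 domain_halfwidth_um = domain_halfwidth_um,
                 threshold_policy = threshold_policy,
                 trajectory = trajectory),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  do.call(run_config, cfg)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_run_config(config, f)
  unname(tools::md5sum(f))
}

#' Segment the soma from the cortical-marker channel
#'
#' The threshold is placed halfway between the background level (median of
#' the image border) and the diffuse cytoplasmic level (median of the
#' clearly-above-background pixels); this is robust to a bright cortical
#' band, which a global two-class threshold can mistake for the only
#' foreground. Holes are filled and the largest connected component
#' returned.
#'
#' @param cortical an [image_stack()] with a `"cortical"` channel, or a
#'   matrix (a single section).
#' @param z section to use for a 3D stack (default: central section).
#' @return Logical matrix `[x, y]`.
#' @export
segment_soma <- function(cortical, z = NULL) {
  if (inherits(cortical, "image_stack")) {
    ch <- get_channel(cortical, "cortical")
    if (length(dim(ch)) == 3L) {
      if (is.null(z)) z <- ceiling(dim(ch)[3] / 2)
      ch <- ch[, , z]
    }
  } else ch <- cortical
  rng <- range(ch)
  if (diff(rng) <= 0) stop("flat cortical channel; no soma")
  border <- c(ch[1, ], ch[nrow(ch), ], ch[, 1], ch[, ncol(ch)])
  bg <- stats::median(border)
  above <- ch[ch > bg + 0.05 * (rng[2] - bg)]
  if (!length(above)) stop("no soma found")
  cyto <- stats::median(above)
  thr <- (bg + cyto) / 2
  bin <- EBImage::fillHull(ifelse(ch > thr, 1, 0))
  lab <- EBImage::bwlabel(bin)
  if (max(lab) == 0) stop("no soma found")
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  lab == which.max(sizes)
}

# full measurement chain for one rendered cell; 'surface' from stack
# metadata, tunables from config
measure_cell <- function(stack, config) {
  spacing <- stack$spacing[1:2]
  surface <- apical_surface(stack$metadata$apical_surface)
  plate <- segment_chromatin(stack, config$threshold_policy)
  angle <- plate_axis_angle(plate, surface, spacing)
  soma <- segment_soma(stack)
  foci <- detect_centromeric_foci(stack, plate)
  part <- partition_regions(foci, surface, soma)
  poles <- find_spindle_poles(stack, plate)
  segs <- detect_astrals(stack, poles, soma, part,
                         delta_cortex_um = config$delta_cortex_um)
  census <- count_census(segs, view = "side")

  idx <- which(soma, arr.ind = TRUE)
  centroid <- c(mean((idx[, 1] - 0.5) * spacing[1]),
                mean((idx[, 2] - 0.5) * spacing[2]))
  surf_y <- min(unclass(surface)[, "y"])
  contour <- extract_contour(soma, c(centroid[1], surf_y), spacing)
  raw <- sample_contour_intensity(contour, get_channel(stack, "cortical"))
  corr <- subtract_cytoplasm(raw, get_channel(stack, "cortical"),
                             soma_interior(soma, config$band_width_px))
  prof <- resample_profile(corr, contour$s)
  rm_ <- region_means(prof, default_region_windows(config$apical_half,
                                                   config$basal_half))

  region <- main_spindle_region(soma, poles,
                                c(part$apical_bound, part$basal_bound),
                                spacing, r_pole_um = config$r_pole_um)
  tub <- max_project(stack, "tubulin")
  area <- spindle_area(region, spacing)
  nmi <- normalized_mean_intensity(tub, region)
  nsd <- normalized_sd(tub, region)
  diam <- diameter_at_spindle_plane(soma, poles, spacing)

  # prospective cleavage: the plate axis through the soma centroid
  dom_centre_arc <- centroid[1]   # flat synthetic surface starts at x = 0
  total <- max(polyline_cumlen(unclass(surface)))
  dom <- apical_domain(max(0, dom_centre_arc - config$domain_halfwidth_um),
                       min(total, dom_centre_arc + config$domain_halfwidth_um),
                       surface)
  cleav <- cleavage_geometry(centroid,
                             c(sin(deg2rad(angle)), -cos(deg2rad(angle))))
  sym <- tryCatch(as.character(classify_division(dom, cleav)),
                  error = function(e) NA_character_)

  data.frame(plate_angle_deg = angle, n_foci = nrow(foci),
             apical_astrals = census$apical, basal_astrals = census$basal,
             central_astrals = census$central,
             profile_apical = rm_$apical, profile_basal = rm_$basal,
             profile_central = rm_$central_pooled,
             spindle_area_um2 = area, spindle_norm_intensity = nmi,
             spindle_norm_sd = nsd, soma_diameter_um = diam,
             division_class = sym)
}

#' Run the single-cell pipeline over configured groups
#'
#' For each configured cell group, simulates `n` ground-truthed cells,
#' runs the full measurement chain (plate orientation, astral census,
#' cortical profile, spindle metrics, division symmetry), simulates a
#' plate-angle trajectory whose anchor counts are the measured
#' apical+basal and central astral censuses, and returns one row per
#' cell. A failing cell yields a row with `error` set; the run continues.
#'
#' @param config a [run_config()] with a non-empty `cells` list.
#' @return data frame (one row per cell) with attributes `config_hash`,
#'   `seed` and `version`.
#' @export
run_cell_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  if (!length(config$cells))
    warning("empty input list; returning an empty table")
  for (gi in seq_along(config$cells)) {
    grp <- config$cells[[gi]]
    for (ci in seq_len(grp$n)) {
      cell_seed <- config$seed + 7919L * gi + ci
      row <- tryCatch({
        spec <- do.call(random_cell_spec,
                        c(grp$params, list(seed = cell_seed)))
        sim <- make_mitotic_cell(spec, seed = cell_seed)
        m <- measure_cell(sim$stack, config)
        tp <- trajectory_params(
          n_anchors_polar = m$apical_astrals + m$basal_astrals,
          n_anchors_central = ifelse(is.na(m$central_astrals), 0,
                                     m$central_astrals),
          stiffness_per_anchor = config$trajectory$stiffness_per_anchor,
          noise_sd = config$trajectory$noise_sd,
          dt = config$trajectory$dt,
          duration = config$trajectory$duration,
          central_fraction = config$trajectory$central_fraction,
          seed = cell_seed)
        track <- simulate_plate_trajectory(tp)
        cbind(data.frame(group = grp$name, cell = ci, seed = cell_seed,
                         error = NA_character_),
              m,
              data.frame(amplitude_deg = track_amplitude(track),
                         track_category = classify_track(track)))
      }, error = function(e) {
        data.frame(group = grp$name, cell = ci, seed = cell_seed,
                   error = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- if (length(rows)) merge_rows(rows) else
    data.frame(group = character(0), cell = integer(0),
               seed = integer(0), error = character(0))
  attr(out, "config_hash") <- config_hash(config)
  attr(out, "seed") <- config$seed
  attr(out, "version") <-
    as.character(utils::packageVersion("mitospindle"))
  out
}

# rbind rows with unequal columns (error rows are short)
merge_rows <- function(rows) {
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[, cols]
  })
  do.call(rbind, rows)
}

#' Run the tissue pipeline over configured groups
#'
#' Each configured tissue group yields `n` simulated scenes; for each, the
#' nuclei table is re-measured (zones re-assigned from positions, marker
#' fractions, mitoses per 100 um apical surface, neurons per 100 um pial
#' surface, apoptotic cells per 10,000 um^2) and returned as one row.
#'
#' @param config a [run_config()] with a non-empty `tissues` list.
#' @return data frame, one row per scene, with provenance attributes.
#' @export
run_tissue_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rows <- list()
  if (!length(config$tissues))
    warning("empty input list; returning an empty table")
  for (gi in seq_along(config$tissues)) {
    grp <- config$tissues[[gi]]
    for (si in seq_len(grp$n)) {
      seed_i <- config$seed + 104729L * gi + si
      row <- tryCatch({
        spec <- do.call(random_tissue_spec,
                        c(grp$params, list(seed = seed_i)))
        scene <- make_tissue_scene(spec)
        cbind(data.frame(group = grp$name, scene = si, seed = seed_i,
                         error = NA_character_),
              measure_tissue(scene$nuclei, spec))
      }, error = function(e) {
        data.frame(group = grp$name, scene = si, seed = seed_i,
                   error = conditionMessage(e))
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- if (length(rows)) merge_rows(rows) else
    data.frame(group = character(0), scene = integer(0),
               seed = integer(0), error = character(0))
  attr(out, "config_hash") <- config_hash(config)
  attr(out, "seed") <- config$seed
  attr(out, "version") <-
    as.character(utils::packageVersion("mitospindle"))
  out
}

# tissue measurements from a nuclei table plus scene geometry
measure_tissue <- function(nuclei, spec) {
  nuclei$zone <- zone_assign(nuclei$y_um,
                             c(0, spec$vz_svz_boundary_y,
                               spec$svz_cp_boundary_y,
                               spec$tissue_height_y))
  interphase <- !has_marker(nuclei$markers, "PH3")
  iph <- nuclei[interphase, , drop = FALSE]
  ap_pct <- marker_fractions(iph, "VZ", function(df)
    has_marker(df$markers, "Pax6") & !has_marker(df$markers, "Tbr2"))
  bp_pct <- marker_fractions(iph, "VZ", "Tbr2")
  mit <- c(VZ = sum(nuclei$zone == "VZ" & !interphase),
           SVZ = sum(nuclei$zone == "SVZ" & !interphase))
  mit_rates <- rate_per_surface(mit, spec$apical_surface_length)
  neurons <- sum(nuclei$zone == "CP" & has_marker(nuclei$markers, "Tbr1"))
  casp <- sum(has_marker(nuclei$markers, "Casp3"))
  area <- spec$apical_surface_length * spec$tissue_height_y
  data.frame(ap_fraction_vz = ap_pct, bp_fraction_vz = bp_pct,
             mitoses_vz_per_100um = unname(mit_rates["VZ"]),
             mitoses_svz_per_100um = unname(mit_rates["SVZ"]),
             mitoses_all_per_100um = unname(mit_rates["All"]),
             neurons_per_100um = rate_per_surface(neurons,
                                                  spec$pial_surface_length),
             casp3_per_10000um2 = rate_per_area(casp, area))
}

#' Write a results table with its configuration sidecar
#'
#' @param results table from [run_cell_pipeline()] or
#'   [run_tissue_pipeline()].
#' @param config the [run_config()] used.
#' @param dir output directory (created if needed).
#' @param name base name for the files.
#' @return Paths, invisibly.
#' @export
write_results <- function(results, config, dir, name = "results") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(results, csv, row.names = FALSE)
  side <- file.path(dir, paste0(name, "_config.json"))
  prov <- list(config = unclass(config),
               provenance = list(config_hash = attr(results, "config_hash"),
                                 seed = attr(results, "seed"),
                                 version = attr(results, "version")))
  jsonlite::write_json(prov, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv, config = side))
}
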