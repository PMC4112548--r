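test_that("zone assignment uses half-open bands and flags outsiders", {
  breaks <- c(0, 60, 100, 160)
  expect_identical(zone_assign(c(0, 59.9, 60, 99.9, 100, 159.9, 160),
                               breaks),
                   c("VZ", "VZ", "SVZ", "SVZ", "CP", "CP", "other"))
  expect_identical(zone_assign(c(10, 20), breaks), c("VZ", "VZ"))
  expect_error(zone_assign(1, c(0, 10), c("a", "b")), "one more break")
  expect_error(zone_assign(1, c(10, 0), "a"), "increase")
})

test_that("tissue_spec rejects zone labels inconsistent with position", {
  nuc <- data.frame(x_um = 10, y_um = 10, zone = "SVZ", markers = "")
  expect_error(tissue_spec(nuc), "inconsistent")
  ok <- tissue_spec(data.frame(x_um = 10, y_um = 10, zone = "VZ",
                               markers = ""))
  expect_s3_class(ok, "tissue_spec")
  expect_error(tissue_spec(ok$nuclei, apical_surface_length = -1), "> 0")
})

test_that("scene ground truth matches hand-computable censuses", {
  nuc <- data.frame(
    x_um = seq(5, 95, length.out = 19),
    y_um = c(rep(10, 10), rep(2, 8), 130),
    zone = c(rep("VZ", 18), "CP"),
    markers = c(rep("Tbr2", 4), rep("Pax6", 6), rep("PH3", 8), "Tbr1"))
  spec <- tissue_spec(nuc, apical_surface_length = 100,
                      pial_surface_length = 100)
  scene <- make_tissue_scene(spec)
  gt <- scene$ground_truth
  expect_equal(unname(gt$mitoses_per_100um["VZ"]), 8)
  expect_equal(unname(gt$mitoses_per_100um["All"]), 8)
  expect_equal(gt$bp_fraction_vz, 40)     # 4 Tbr2+ of 10 interphase VZ
  expect_equal(gt$ap_fraction_vz, 60)
  expect_equal(gt$neurons_per_100um, 1)
  expect_equal(gt$casp3_per_10000um2, 0)
})

test_that("an empty scene has all-zero count censuses", {
  spec <- tissue_spec(data.frame(x_um = numeric(0), y_um = numeric(0),
                                 zone = character(0),
                                 markers = character(0)))
  scene <- make_tissue_scene(spec)
  gt <- scene$ground_truth
  expect_equal(unname(gt$mitoses_per_100um), c(0, 0, 0))
  expect_equal(gt$neurons_per_100um, 0)
  expect_equal(gt$casp3_per_10000um2, 0)
  expect_true(all(scene$label_image == 0))
})

test_that("overcrowded scenes are rejected", {
  nuc <- data.frame(x_um = rep(10, 6) + runif(6, 0, 0.5),
                    y_um = rep(10, 6), zone = "VZ", markers = "")
  spec <- tissue_spec(nuc)
  expect_error(make_tissue_scene(spec), "density")
})

test_that("label image renders one disc per nucleus id", {
  spec <- random_tissue_spec(n_vz = 10, n_svz = 5, n_cp = 5,
                             n_mitoses_vz = 2, n_mitoses_svz = 1,
                             n_casp3 = 1, seed = 2)
  scene <- make_tissue_scene(spec)
  ids <- sort(unique(as.vector(scene$label_image)))
  expect_true(all(scene$nuclei$id %in% ids))
})

test_that("marker fractions follow their predicates", {
  nuc <- data.frame(zone = rep("VZ", 10),
                    markers = c(rep("Tbr2", 4), rep("Pax6", 6)))
  expect_equal(marker_fractions(nuc, "VZ", "Tbr2"), 40)
  dbl <- data.frame(zone = "VZ", markers = "Pax6;Tbr2")
  expect_equal(marker_fractions(dbl, "VZ", function(df)
    has_marker(df$markers, "Pax6") & !has_marker(df$markers, "Tbr2")), 0)
  expect_error(marker_fractions(nuc, "SVZ", "Tbr2"), "empty")
})

test_that("surface and area rates normalize and add over zones", {
  expect_equal(unname(rate_per_surface(8, 400)), 2)
  expect_equal(unname(rate_per_surface(0, 400)), 0)
  r <- rate_per_surface(c(VZ = 6, SVZ = 2), 200)
  expect_equal(unname(r["All"]), unname(r["VZ"] + r["SVZ"]))
  expect_equal(unname(r["All"]), 4)
  expect_error(rate_per_surface(1, 0), "> 0")
  expect_equal(rate_per_area(3, 20000), 1.5)
  expect_equal(rate_per_area(0, 20000), 0)
  expect_error(rate_per_area(1, 0), "> 0")
})

test_that("random scenes measure back to their ground truth exactly", {
  spec <- random_tissue_spec(seed = 5)
  scene <- make_tissue_scene(spec)
  gt <- scene$ground_truth
  nuc <- scene$nuclei
  nuc$zone2 <- zone_assign(nuc$y_um,
                           c(0, spec$vz_svz_boundary_y,
                             spec$svz_cp_boundary_y, spec$tissue_height_y))
  expect_identical(nuc$zone2, nuc$zone)
  iph <- nuc[!has_marker(nuc$markers, "PH3"), ]
  expect_equal(marker_fractions(iph, "VZ", "Tbr2"), gt$bp_fraction_vz)
  mit <- c(VZ = sum(nuc$zone == "VZ" & has_marker(nuc$markers, "PH3")),
           SVZ = sum(nuc$zone == "SVZ" & has_marker(nuc$markers, "PH3")))
  r <- rate_per_surface(mit, spec$apical_surface_length)
  expect_equal(unname(r["All"]), unname(gt$mitoses_per_100um["All"]))
})

test_that("nuclei tables round-trip through CSV with schema checks", {
  spec <- random_tissue_spec(n_vz = 5, n_svz = 2, n_cp = 3,
                             n_mitoses_vz = 1, n_mitoses_svz = 0,
                             n_casp3 = 0, seed = 3)
  scene <- make_tissue_scene(spec)
  f <- file.path(tempdir(), "nuclei.csv")
  write_nuclei_csv(scene$nuclei, f)
  back <- read_nuclei_csv(f)
  expect_equal(nrow(back), nrow(scene$nuclei))
  bad <- back; bad$zone <- NULL
  f2 <- file.path(tempdir(), "bad.csv")
  utils::write.csv(bad, f2, row.names = FALSE)
  expect_error(read_nuclei_csv(f2), "zone")
})
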