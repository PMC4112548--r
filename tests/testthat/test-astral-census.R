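test_that("rendered foci are recovered within one voxel", {
  sim <- fixture_cell(seed = 3)
  st <- sim$stack
  foci <- detect_centromeric_foci(st, segment_chromatin(st))
  gt <- sim$ground_truth$foci_world
  expect_equal(nrow(foci), nrow(gt))
  px <- st$spacing[1]
  for (i in seq_len(nrow(gt))) {
    d <- sqrt((foci$x_um - gt[i, 1])^2 + (foci$y_um - gt[i, 2])^2)
    expect_lt(min(d), px)
  }
  expect_true(!is.unsorted(foci$y_um))
})

test_that("a featureless plate yields no foci and a clear error", {
  img <- matrix(0, 50, 50)
  img[10:40, 20:30] <- 1
  mask <- img > 0.5
  expect_error(detect_centromeric_foci(img, mask), "no centromeric foci")
})

test_that("heavy blur merges foci without raising an error", {
  spec <- random_cell_spec(n_apical = 2, n_basal = 2, n_central = 2,
                           seed = 31, psf_sigma = 0.45)
  sim <- make_mitotic_cell(spec, seed = 31)
  st <- sim$stack
  foci <- detect_centromeric_foci(st, segment_chromatin(st))
  expect_lte(nrow(foci), nrow(sim$ground_truth$foci_world))
  expect_gte(nrow(foci), 1)
})

test_that("partition planes reproduce the generative planes", {
  for (seed in c(3, 21)) {
    sim <- fixture_cell(seed = seed, n_apical = 4, n_basal = 4,
                        n_central = 5)
    m <- measure_fixture(sim)
    pl <- sim$ground_truth$partition_planes
    px <- sim$stack$spacing[2]
    expect_lt(abs(m$partition$apical_bound - pl["apical"]), px)
    expect_lt(abs(m$partition$basal_bound - pl["basal"]), px)
  }
})

test_that("partition_regions validates its inputs", {
  foci <- data.frame(ix = 5, iy = 5, x_um = 5, y_um = 5, value = 1)
  soma <- matrix(FALSE, 10, 10)
  expect_error(partition_regions(foci, soma_mask = soma), "outside")
  expect_error(partition_regions(foci[0, ]), "no foci")
  soma[5, 5] <- TRUE
  p <- partition_regions(foci, soma_mask = soma)
  # single focus: a one-plane central band, everything else apical/basal
  expect_identical(region_of_y(p, c(4.9, 5, 5.1)),
                   c("apical", "central", "basal"))
})

test_that("points exactly on a partition plane are central", {
  p <- structure(list(apical_bound = 2, basal_bound = 6,
                      orientation = "apical_low_y"),
                 class = "region_partition")
  expect_identical(region_of_y(p, c(1.99, 2, 4, 6, 6.01)),
                   c("apical", "central", "central", "central", "basal"))
})

test_that("voxel-wise brute-force labeling agrees with the partition", {
  for (seed in c(3, 21, 33)) {
    sim <- fixture_cell(seed = seed, n_apical = 3, n_basal = 3,
                        n_central = 4)
    m <- measure_fixture(sim)
    soma_idx <- which(m$soma, arr.ind = TRUE)
    y <- (soma_idx[, 2] - 0.5) * m$spacing[2]
    brute <- ifelse(y < m$partition$apical_bound, "apical",
                    ifelse(y > m$partition$basal_bound, "basal", "central"))
    expect_identical(region_of_y(m$partition, y), brute)
  }
})

test_that("spindle poles are found at the rendered positions", {
  sim <- fixture_cell(seed = 3)
  m <- measure_fixture(sim)
  expect_lt(max(abs(m$poles - sim$ground_truth$poles[, 1:2])), 0.15)
})

test_that("noise-free astral census is recovered exactly with true regions", {
  for (seed in c(3, 21)) {
    sim <- fixture_cell(seed = seed, n_apical = 4, n_basal = 4,
                        n_central = 5)
    m <- measure_fixture(sim)
    expect_equal(c(m$census$apical, m$census$basal, m$census$central),
                 unname(sim$ground_truth$census))
    # every detected cortex-reaching endpoint matches a true one in region
    reach <- m$segments[m$segments$reaches, ]
    gt <- sim$ground_truth$astrals
    gt <- gt[gt$reaches, ]
    for (i in seq_len(nrow(reach))) {
      d <- sqrt((gt$x1 - reach$x_end[i])^2 + (gt$y1 - reach$y_end[i])^2)
      j <- which.min(d)
      expect_lt(min(d), 0.5)
      expect_identical(reach$region[i], gt$region[j])
    }
  }
})

test_that("astrals stopping short of the cortex are excluded", {
  sim <- fixture_cell(seed = 41, n_apical = 3, n_basal = 3, n_central = 3,
                      n_short = 3)
  m <- measure_fixture(sim)
  expect_equal(c(m$census$apical, m$census$basal, m$census$central),
               unname(sim$ground_truth$census))
  short_detected <- m$segments[!m$segments$reaches, ]
  if (nrow(short_detected))
    expect_true(all(short_detected$dist_to_boundary_um > 1.0))
})

test_that("census with no noise is within one count under 10% rod noise", {
  sim <- fixture_cell(seed = 402, n_apical = 4, n_basal = 5, n_central = 6,
                      noise = list(gaussian_sd = 0.09, poisson_gain = 0))
  m <- measure_fixture(sim)
  dev <- abs(c(m$census$apical, m$census$basal, m$census$central) -
               sim$ground_truth$census)
  expect_true(all(dev <= 1))
})

test_that("view classification follows the angle and section rules", {
  flat <- rbind(c(0, 0, 2), c(5, 0, 2))
  expect_identical(classify_view(flat, 0.75), "front")
  axial <- rbind(c(0, 0, 0), c(0.5, 0, 6))
  expect_identical(classify_view(axial, 0.75), "side")
  # axis at exactly 45 degrees: side (strict inequality)
  diag45 <- rbind(c(0, 0, 0), c(1, 0, 1))
  expect_identical(classify_view(diag45, 0.75, theta_view_deg = 45), "side")
  # in-plane but spanning too many sections
  wide <- rbind(c(0, 0, 0), c(10, 0, 3))
  expect_identical(classify_view(wide, 0.75), "side")
})

test_that("count_census honours the view rule and conserves totals", {
  segs <- data.frame(
    reaches = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    region = c("apical", "basal", "central", "central", "apical"))
  side <- count_census(segs, "side")
  expect_equal(c(side$apical, side$basal, side$central), c(1, 1, 2))
  expect_equal(side$apical + side$basal + side$central, sum(segs$reaches))
  front <- count_census(segs, "front")
  expect_equal(front$apical, 1)
  expect_true(is.na(front$central))
  empty <- count_census(segs[0, ], "side")
  expect_equal(c(empty$apical, empty$basal, empty$central), c(0, 0, 0))
})

test_that("BP orientation classes follow the sector geometry", {
  centroid <- c(0, 0)
  segs <- data.frame(reaches = TRUE,
                     x_end = c(0, 0, 5, -5),
                     y_end = c(-5, 5, 0, 0))
  out <- bp_orient_census(segs, centroid)
  expect_equal(unname(out),
               c(1L, 1L, 2L))   # toward ventricle, toward pia, 2 lateral
  # brute-force oracle on random endpoints
  set.seed(2)
  n <- 200
  ang <- runif(n, 0, 2 * pi)
  segs <- data.frame(reaches = TRUE, x_end = cos(ang), y_end = sin(ang))
  out <- bp_orient_census(segs, centroid, sigma_deg = 45)
  # ventricle direction (0,-1): angle from it
  theta <- acos(pmin(pmax(-sin(ang), -1), 1)) * 180 / pi
  oracle <- c(sum(theta <= 45), sum(theta >= 135),
              sum(theta > 45 & theta < 135))
  expect_equal(unname(out), as.integer(oracle))
})
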