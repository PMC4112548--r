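test_that("apical_surface rejects degenerate or self-crossing polylines", {
  expect_error(apical_surface(cbind(1, 1)), "n >= 2")
  bowtie <- cbind(x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))
  expect_error(apical_surface(bowtie), "self-intersect")
  expect_s3_class(apical_surface(cbind(x = c(0, 10), y = c(0, 0))),
                  "apical_surface")
})

test_that("segment_chromatin keeps the largest component and flags empties", {
  img <- matrix(0, 40, 40)
  img[5:8, 5:8] <- 1            # 16 px
  img[20:35, 20:30] <- 1        # 176 px
  mask <- segment_chromatin(img, threshold_policy = 0.5)
  expect_false(mask[6, 6])
  expect_true(mask[25, 25])
  expect_error(segment_chromatin(matrix(0, 10, 10), 0.5), "no chromatin")
  expect_error(segment_chromatin(matrix(0, 10, 10)), "no chromatin")
})

test_that("segmented plate matches the rendered support within one voxel", {
  sim <- fixture_cell(seed = 3)
  mask <- segment_chromatin(sim$stack)
  support <- sim$ground_truth$plate_support
  grow <- function(m) EBImage::dilate(ifelse(m, 1, 0),
                                      EBImage::makeBrush(3, "box")) > 0
  expect_true(all(!mask | grow(support)))   # mask within dilated support
  expect_true(all(!support | grow(mask)))   # support within dilated mask
})

test_that("plate_axis_angle follows the stated sign and zero conventions", {
  surf <- apical_surface(cbind(x = c(0, 40), y = c(0, 0)))
  vertical <- ellipse_mask(80, 80, 20, 20, ax = 4, ay = 12, angle_deg = 0,
                           spacing = c(0.5, 0.5))
  expect_lt(abs(plate_axis_angle(vertical, surf, c(0.5, 0.5))), 0.5)
  horizontal <- ellipse_mask(80, 80, 20, 20, 4, 12, 90, c(0.5, 0.5))
  expect_lt(90 - abs(plate_axis_angle(horizontal, surf, c(0.5, 0.5))), 0.5)
  tilted <- ellipse_mask(120, 120, 30, 30, 4, 12, 25, c(0.5, 0.5))
  expect_lt(abs(plate_axis_angle(tilted, surf, c(0.5, 0.5)) - 25), 0.5)
  iso <- ellipse_mask(80, 80, 20, 20, 8, 8 + 1e-9, 0, c(0.5, 0.5))
  expect_error(plate_axis_angle(iso, surf, c(0.5, 0.5)), "undefined")
})

test_that("reported angle is invariant under joint rotation of mask and surface", {
  for (phi in c(-20, 10, 35)) {
    surf0 <- apical_surface(cbind(x = c(-40, 120), y = c(-20, -20)))
    m0 <- ellipse_mask(320, 320, 40, 40, 4, 12, 12, c(0.25, 0.25))
    a0 <- plate_axis_angle(m0, surf0, c(0.25, 0.25))
    # rotate the scene: tilt the ellipse by phi and the surface with it
    m1 <- ellipse_mask(320, 320, 40, 40, 4, 12, 12 + phi, c(0.25, 0.25))
    th <- -phi * pi / 180
    rot <- function(p, c0) {
      sweep((p - matrix(c0, nrow(p), 2, byrow = TRUE)) %*%
              rbind(c(cos(th), sin(th)), c(-sin(th), cos(th))),
            2, -c0)
    }
    surf1 <- apical_surface(rot(cbind(c(-40, 120), c(-20, -20)),
                                c(40, 40)))
    a1 <- plate_axis_angle(m1, surf1, c(0.25, 0.25))
    expect_lt(abs(a1 - a0), 0.5)
  }
})

test_that("plate angle is recovered within 1 degree across the tilt range", {
  for (ang in seq(-60, 60, by = 20)) {
    sim <- fixture_cell(seed = 600 + ang, n_apical = 0, n_basal = 0,
                        n_central = 0, plate_angle_deg = ang)
    st <- sim$stack
    surf <- apical_surface(st$metadata$apical_surface)
    got <- plate_axis_angle(segment_chromatin(st), surf, st$spacing[1:2])
    expect_lt(abs(got - ang), 1)
  }
})

test_that("track amplitude is the metaphase-window range", {
  expect_equal(track_amplitude(plate_track(1:3, c(12, 12, 12))), 0)
  expect_equal(track_amplitude(plate_track(1:3, c(-5, 3, 10))), 15)
  expect_error(track_amplitude(plate_track(1, 5, phase = "anaphase_onset")),
               ">= 2 samples")
  # prometaphase samples are excluded from the window
  tr <- plate_track(1:4, c(80, 1, 2, 3),
                    phase = c("prometaphase", "metaphase", "metaphase",
                              "anaphase_onset"))
  expect_equal(track_amplitude(tr), 2)
})

test_that("amplitude is invariant to constant offsets and time reversal", {
  set.seed(1)
  for (i in 1:20) {
    a <- runif(8, -40, 40)
    base <- track_amplitude(plate_track(1:8, a))
    expect_equal(track_amplitude(plate_track(1:8, a + 5)), base)
    expect_equal(track_amplitude(plate_track(1:8, rev(a))), base)
  }
})

test_that("OU track amplitude equals brute-force max minus min", {
  tr <- simulate_plate_trajectory(trajectory_params(seed = 13))
  expect_identical(track_amplitude(tr),
                   max(tr$angles_deg) - min(tr$angles_deg))
})

test_that("angle bins own their edges toward zero", {
  expect_identical(angle_bin(c(31, 30, 15.5, 15, 0, -0.01, -15, -15.5,
                               -30, -31)),
                   c("blue", "cyan", "cyan", "green", "green", "yellow",
                     "yellow", "red", "red", "dark_red"))
})

test_that("tracks are categorized by the dominant range", {
  expect_identical(classify_track(plate_track(1:3, c(20, 20, 20))), "cyan")
  expect_identical(classify_track(plate_track(1:3, c(-40, -40, -40))),
                   "dark_red")
  expect_identical(classify_track(plate_track(1:3, c(2, 4, 20))), "green")
  # no strict majority: falls back to the bin of the median angle
  expect_identical(classify_track(plate_track(1:4, c(-20, 2, 20, 40))),
                   "green")
})
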