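test_that("spindle area is voxel count times pixel area", {
  r <- matrix(FALSE, 50, 50)
  r[1:40, 1:25] <- TRUE    # 1000 voxels
  expect_equal(spindle_area(r, c(0.09, 0.09)), 8.1)
  expect_equal(spindle_area(r & FALSE, c(0.09, 0.09)), 0)
})

test_that("3D area averages the two central-most sections", {
  r <- array(FALSE, c(40, 40, 4))
  r[1:30, 1:30, 2] <- TRUE                 # 900
  r[1:40, 1:25, 3] <- TRUE                 # 1000... adjust to 1100
  r[31:40, 26:35, 3] <- TRUE               # +100 -> 1100
  expect_equal(sum(r[, , 2]), 900)
  expect_equal(sum(r[, , 3]), 1100)
  expect_equal(spindle_area(r, c(0.09, 0.09, 0.75)), 8.1)
})

test_that("area scales with the square of pixel size", {
  r <- matrix(FALSE, 30, 30); r[5:20, 5:20] <- TRUE
  a1 <- spindle_area(r, c(0.1, 0.1))
  a2 <- spindle_area(r, c(0.2, 0.2))
  expect_equal(a2, 4 * a1)
})

test_that("normalized mean intensity matches closed forms", {
  img <- matrix(1, 10, 10)
  reg <- matrix(FALSE, 10, 10); reg[1:5, ] <- TRUE
  expect_equal(normalized_mean_intensity(img, reg), 1)
  img2 <- img; img2[reg] <- 2       # half at 2, half at 1
  expect_equal(normalized_mean_intensity(img2, reg), 2 / 1.5)
  expect_error(normalized_mean_intensity(img * 0, reg), "zero")
  expect_error(normalized_mean_intensity(img, reg & FALSE), "empty")
})

test_that("normalized SD is the population SD over the region mean", {
  img <- matrix(0, 4, 4)
  reg <- matrix(FALSE, 4, 4); reg[1, 1:2] <- TRUE
  img[1, 1] <- 1; img[1, 2] <- 3
  expect_equal(normalized_sd(img, reg), 0.5)
  img[1, 1:2] <- 7
  expect_equal(normalized_sd(img, reg), 0)
  expect_error(normalized_sd(img, reg & FALSE), ">= 2")
})

test_that("intensity ratios are invariant under global scaling", {
  sim <- fixture_cell(seed = 3)
  m <- measure_fixture(sim)
  reg <- main_spindle_region(m$soma, m$poles,
                             c(m$partition$apical_bound,
                               m$partition$basal_bound), m$spacing)
  tub <- max_project(sim$stack, "tubulin")
  expect_equal(normalized_mean_intensity(5 * tub, reg),
               normalized_mean_intensity(tub, reg))
  expect_equal(normalized_sd(5 * tub, reg), normalized_sd(tub, reg))
})

test_that("main spindle region covers the central spindle, not the caps", {
  sim <- fixture_cell(seed = 3)
  gt <- sim$ground_truth
  reg <- main_spindle_region(gt$soma_mask, gt$poles[, 1:2],
                             gt$partition_planes, gt$spacing[1:2])
  # both pole positions inside
  for (p in 1:2) {
    i <- round(gt$poles[p, 1] / gt$spacing[1] + 0.5)
    j <- round(gt$poles[p, 2] / gt$spacing[2] + 0.5)
    expect_true(reg$mask[i, j])
  }
  # no region voxel beyond the planes + pole-disc allowance
  idx <- which(reg$mask, arr.ind = TRUE)
  y <- (idx[, 2] - 0.5) * gt$spacing[2]
  r_pole <- 1.5
  expect_true(all(y >= gt$partition_planes["apical"] - r_pole - 0.1))
  expect_true(all(y <= gt$partition_planes["basal"] + r_pole + 0.1))
  # region never leaves the soma
  expect_true(all(gt$soma_mask[reg$mask]))
  expect_error(main_spindle_region(gt$soma_mask,
                                   rbind(c(0.5, 0.5), gt$poles[2, 1:2]),
                                   gt$partition_planes, gt$spacing[1:2]),
               "outside")
})

test_that("degenerate foci planes give a one-plane band plus pole discs", {
  soma <- ellipse_mask(100, 100, 25, 25, 20, 20, 0, c(0.5, 0.5))
  poles <- rbind(c(15, 25), c(35, 25))
  reg <- main_spindle_region(soma, poles, c(25, 25), c(0.5, 0.5),
                             r_pole_um = 1.5)
  idx <- which(reg$mask, arr.ind = TRUE)
  y <- (idx[, 2] - 0.5) * 0.5
  expect_true(all(abs(y - 25) <= 1.5 + 0.5))
})

test_that("soma diameter along the pole axis matches analytic chords", {
  soma <- ellipse_mask(120, 120, 30, 30, 20, 20, 0, c(0.5, 0.5))
  poles <- rbind(c(20, 30), c(40, 30))
  d <- diameter_at_spindle_plane(soma, poles, c(0.5, 0.5))
  expect_lt(abs(d - 40), 0.6)
  expect_error(diameter_at_spindle_plane(soma,
                                         rbind(c(1, 58), c(58, 58.5)),
                                         c(0.5, 0.5)),
               "misses")
  # rendered ellipsoidal soma: chord through the true pole axis
  sim <- fixture_cell(seed = 3)
  gt <- sim$ground_truth
  m <- measure_fixture(sim)
  th <- atan2(gt$poles[2, 2] - gt$poles[1, 2],
              gt$poles[2, 1] - gt$poles[1, 1])
  ax <- gt$spec$soma_axes[1]; ay <- gt$spec$soma_axes[2]
  chord <- 2 / sqrt((cos(th) / ax)^2 + (sin(th) / ay)^2)
  got <- diameter_at_spindle_plane(m$soma, m$poles, m$spacing)
  expect_lt(abs(got - chord), 0.2)
})
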