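test_that("contour of a disc has the right length and orientation", {
  m <- ellipse_mask(64, 64, 16, 16, 20 * 0.5, 20 * 0.5, 0, c(0.5, 0.5))
  ct <- extract_contour(m, c(16, 0), c(0.5, 0.5))
  # digital-circle perimeter of radius 20 px within 5% of 2*pi*20 (in um:
  # radius 10)
  expect_lt(abs(ct$perimeter_um - 2 * pi * 10) / (2 * pi * 10), 0.05)
  # clockwise as displayed: positive shoelace in (x, y-down) coordinates
  px <- ct$coords_um[, 1]; py <- ct$coords_um[, 2]
  nxt <- c(2:length(px), 1)
  expect_gt(sum(px * py[nxt] - px[nxt] * py), 0)
  # start point nearest the apical midpoint
  expect_equal(ct$s[1], 0)
  expect_lt(abs(px[1] - 16), 1)
  expect_lt(py[1], 7)
})

test_that("mirrored masks are re-oriented to the same handedness", {
  m <- ellipse_mask(64, 48, 16, 12, 8, 5, 30, c(0.5, 0.5))
  ct1 <- extract_contour(m, c(16, 0), c(0.5, 0.5))
  m2 <- m[nrow(m):1, ]
  ct2 <- extract_contour(m2, c(16, 0), c(0.5, 0.5))
  sl <- function(ct) {
    px <- ct$coords_um[, 1]; py <- ct$coords_um[, 2]
    nxt <- c(2:length(px), 1)
    sum(px * py[nxt] - px[nxt] * py)
  }
  expect_gt(sl(ct1), 0)
  expect_gt(sl(ct2), 0)
})

test_that("degenerate masks are rejected", {
  tiny <- matrix(FALSE, 10, 10); tiny[5, 5] <- TRUE
  expect_error(extract_contour(tiny, c(2.5, 0)), "interior|boundary")
  holey <- matrix(TRUE, 12, 12)
  holey[6, 6] <- FALSE
  expect_error(extract_contour(holey, c(3, 0)), "holes")
  two <- matrix(FALSE, 20, 20)
  two[2:5, 2:5] <- TRUE; two[12:15, 12:15] <- TRUE
  expect_error(extract_contour(two, c(1, 0)), "single connected")
})

test_that("cytoplasm subtraction uses the interior median and clips at 0", {
  img <- matrix(30, 20, 20)
  interior <- matrix(FALSE, 20, 20); interior[8:12, 8:12] <- TRUE
  expect_equal(as.numeric(subtract_cytoplasm(100, img, interior)), 70)
  expect_equal(as.numeric(subtract_cytoplasm(c(10, 50), img, interior)),
               c(0, 20))
  expect_error(subtract_cytoplasm(1, img, interior & FALSE), "empty")
})

test_that("resampling is exact for constants and aligned grids", {
  p <- resample_profile(rep(3.5, 57))
  expect_equal(p$intensity, rep(3.5, 100))
  expect_equal(p$s, seq(0.005, 0.995, by = 0.01))
  # 100 samples already placed on the output grid: identity
  vals <- rnorm(100)
  p2 <- resample_profile(vals, positions = (seq_len(100) - 0.5) / 100)
  expect_equal(p2$intensity, vals)
  expect_error(resample_profile(1), "at least 2")
})

test_that("a smooth profile is interpolated to better than 1e-3", {
  f <- function(s) 1 + sin(2 * pi * s)
  s300 <- (seq_len(300) - 1) / 300
  p <- resample_profile(f(s300), positions = s300)
  expect_lt(max(abs(p$intensity - f(p$s))), 1e-3)
})

test_that("shifting the start point circularly shifts the profile", {
  vals <- rnorm(100)
  pos <- (seq_len(100) - 0.5) / 100
  base <- resample_profile(vals, pos)
  k <- 10
  shifted <- resample_profile(c(vals[-(1:k)], vals[1:k]), pos)
  expect_equal(shifted$intensity,
               c(base$intensity[-(1:k)], base$intensity[1:k]))
})

test_that("region means partition the profile and pool the centrals", {
  p <- resample_profile(rep(5, 100))
  rm_ <- region_means(p)
  expect_equal(rm_$apical, 5)
  expect_equal(rm_$basal, 5)
  expect_equal(rm_$central_pooled, 5)
  w <- default_region_windows()
  expect_identical(sort(unlist(w, use.names = FALSE)), 1:100)
  bad <- w; bad$apical <- bad$apical[-1]
  expect_error(region_means(p, bad), "partition")
  overlap <- w; overlap$apical <- c(overlap$apical, 50)
  expect_error(region_means(p, overlap), "partition")
})

test_that("generative cortical profiles are recovered through the chain", {
  f <- function(s) 1.2 + 0.8 * sin(2 * pi * s)
  sim <- fixture_cell(seed = 301, n_apical = 3, n_basal = 4, n_central = 5,
                      cortical_profile_fn = f)
  st <- sim$stack
  spc <- st$spacing[1:2]
  soma <- segment_soma(st)
  surf <- apical_surface(st$metadata$apical_surface)
  idx <- which(soma, arr.ind = TRUE)
  mid <- c(mean((idx[, 1] - 0.5) * spc[1]), min(surf[, "y"]))
  ct <- extract_contour(soma, mid, spc)
  raw <- sample_contour_intensity(ct, get_channel(st, "cortical"))
  corr <- subtract_cytoplasm(raw, get_channel(st, "cortical"),
                             soma_interior(soma))
  expect_equal(attr(corr, "cytoplasm"), 0.3)
  prof <- resample_profile(corr, ct$s)
  expect_lt(max(abs(prof$intensity - f(prof$s))), 1e-3)
})

test_that("an elevated basal band is recovered as a doubled region mean", {
  f <- function(s) ifelse(s >= 0.4 & s < 0.6, 2, 1)
  sim <- fixture_cell(seed = 302, n_apical = 3, n_basal = 3, n_central = 4,
                      cortical_profile_fn = f)
  st <- sim$stack
  soma <- segment_soma(st)
  surf <- apical_surface(st$metadata$apical_surface)
  idx <- which(soma, arr.ind = TRUE)
  spc <- st$spacing[1:2]
  mid <- c(mean((idx[, 1] - 0.5) * spc[1]), min(surf[, "y"]))
  ct <- extract_contour(soma, mid, spc)
  corr <- subtract_cytoplasm(sample_contour_intensity(ct,
                                get_channel(st, "cortical")),
                             get_channel(st, "cortical"),
                             soma_interior(soma))
  rm_ <- region_means(resample_profile(corr, ct$s))
  expect_gt(rm_$basal / rm_$apical, 1.8)
  expect_lt(rm_$basal / rm_$apical, 2.2)
})

test_that("corrected profiles scale with global image intensity", {
  sim <- fixture_cell(seed = 301, n_apical = 3, n_basal = 4, n_central = 5,
                      cortical_profile_fn = function(s) 1.2 +
                        0.8 * sin(2 * pi * s))
  st <- sim$stack
  img <- get_channel(st, "cortical")
  soma <- segment_soma(st)
  surf <- apical_surface(st$metadata$apical_surface)
  idx <- which(soma, arr.ind = TRUE)
  spc <- st$spacing[1:2]
  mid <- c(mean((idx[, 1] - 0.5) * spc[1]), min(surf[, "y"]))
  ct <- extract_contour(soma, mid, spc)
  one <- subtract_cytoplasm(sample_contour_intensity(ct, img), img,
                            soma_interior(soma))
  alpha <- 3.7
  scaled <- subtract_cytoplasm(sample_contour_intensity(ct, alpha * img),
                               alpha * img, soma_interior(soma))
  expect_equal(as.numeric(scaled), alpha * as.numeric(one))
})

test_that("profiles are size-invariant through perimeter normalization", {
  f <- function(s) 1 + 0.5 * cos(2 * pi * s)
  p <- lapply(c(0.5, 1.0), function(scale) {
    m <- ellipse_mask(160, 160, 40, 40, 30 * scale * 0.5, 30 * scale * 0.5,
                      0, c(0.5, 0.5))
    ct <- extract_contour(m, c(40, 0), c(0.5, 0.5))
    resample_profile(f(ct$s), ct$s)$intensity
  })
  expect_lt(max(abs(p[[1]] - p[[2]])), 5e-3)
})
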