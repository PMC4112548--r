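# Shared fixtures: rendered cells are cached per (args, seed) so several
# test files can reuse the same stacks without re-rendering.

.fixture_cache <- new.env(parent = emptyenv())

fixture_cell <- function(seed = 3, n_apical = 5, n_basal = 6, n_central = 9,
                         ...) {
  key <- paste(deparse(list(seed, n_apical, n_basal, n_central, ...)),
               collapse = "")
  key <- digest_key(key)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- random_cell_spec(n_apical = n_apical, n_basal = n_basal,
                           n_central = n_central, seed = seed, ...)
  sim <- make_mitotic_cell(spec, seed = seed)
  .fixture_cache[[key]] <- sim
  sim
}

digest_key <- function(s) paste0("k", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))))

# the standard measurement chain on a rendered cell
measure_fixture <- function(sim) {
  st <- sim$stack
  spc <- st$spacing[1:2]
  surf <- apical_surface(st$metadata$apical_surface)
  plate <- segment_chromatin(st)
  soma <- segment_soma(st)
  foci <- detect_centromeric_foci(st, plate)
  part <- partition_regions(foci, surf, soma)
  poles <- find_spindle_poles(st, plate)
  segs <- detect_astrals(st, poles, soma, part)
  list(stack = st, spacing = spc, surface = surf, plate = plate,
       soma = soma, foci = foci, partition = part, poles = poles,
       segments = segs, census = count_census(segs, "side"))
}

# analytic ellipse mask on a pixel grid (independent of the renderer)
ellipse_mask <- function(nx, ny, cx, cy, ax, ay, angle_deg = 0,
                         spacing = c(1, 1)) {
  xs <- (seq_len(nx) - 0.5) * spacing[1]
  ys <- (seq_len(ny) - 0.5) * spacing[2]
  th <- angle_deg * pi / 180
  X <- matrix(xs, nx, ny) - cx
  Y <- matrix(ys, nx, ny, byrow = TRUE) - cy
  U <- X * sin(th) + Y * cos(th)       # along the tilted "long" axis
  V <- X * cos(th) - Y * sin(th)
  (U / ay)^2 + (V / ax)^2 <= 1
}
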