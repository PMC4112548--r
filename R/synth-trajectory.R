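# Mean-reverting plate-angle trajectories: the "guy ropes" picture made
# quantitative. Astral microtubules anchored at the apical/basal cortex act
# like guy ropes on a tent pole: each anchored rod contributes a restoring
# stiffness pulling the plate axis back toward the apico-basal axis, while
# thermal/motor fluctuations perturb it. The simplest dynamics with these
# ingredients is an Ornstein-Uhlenbeck process in the plate angle,
#
#   d(theta) = -k_eff * theta * dt + noise_sd * dW,
#   k_eff    = stiffness_per_anchor * (n_polar + eps * n_central),
#
# whose stationary SD is noise_sd / sqrt(2 * k_eff): fewer anchors, larger
# angular excursions. Central-cortex anchors pull nearly orthogonally to
# the tilt direction, so they enter with a small weight eps.

#' Parameters of the anchored plate-angle trajectory model
#'
#' @param n_anchors_polar number of astral anchors at the apical/basal
#'   (polar) cortex; the main source of angular stiffness.
#' @param n_anchors_central anchors at the central cortex; contribute a
#'   fraction `central_fraction` of the polar per-anchor stiffness.
#' @param stiffness_per_anchor restoring coefficient per polar anchor,
#'   1/min (relaxation rate of the angle per anchor).
#' @param noise_sd angular forcing, deg/sqrt(min).
#' @param dt sampling interval, min.
#' @param duration length of the metaphase window, min.
#' @param central_fraction weight of a central anchor relative to a polar
#'   one.
#' @param seed integer seed.
#' @return An object of class `"trajectory_params"`.
#' @export
trajectory_params <- function(n_anchors_polar = 12,
                              n_anchors_central = 9,
                              stiffness_per_anchor = 0.08,
                              noise_sd = 7.5,
                              dt = 1, duration = 15,
                              central_fraction = 0.1,
                              seed = 1) {
  if (n_anchors_polar < 0 || n_anchors_central < 0)
    stop("anchor counts must be >= 0")
  if (dt <= 0) stop("'dt' must be > 0")
  if (duration < dt) stop("'duration' must be >= dt")
  if (stiffness_per_anchor < 0 || noise_sd < 0)
    stop("stiffness and noise must be non-negative")
  structure(list(n_anchors_polar = n_anchors_polar,
                 n_anchors_central = n_anchors_central,
                 stiffness_per_anchor = stiffness_per_anchor,
                 noise_sd = noise_sd, dt = dt, duration = duration,
                 central_fraction = central_fraction, seed = seed),
            class = "trajectory_params")
}

#' Time series of signed plate-angle deviations with phase labels
#'
#' @param times sampling times in min, strictly increasing; by convention
#'   0 is anaphase onset (so metaphase times are negative).
#' @param angles_deg signed deviations from the apico-basal axis, degrees
#'   in `[-90, 90]`.
#' @param phase per-sample labels among `"prometaphase"`, `"metaphase"`,
#'   `"anaphase_onset"`; exactly one `"anaphase_onset"`, the last sample.
#' @return An object of class `"plate_track"`.
#' @export
plate_track <- function(times, angles_deg, phase = NULL) {
  n <- length(times)
  if (length(angles_deg) != n) stop("times/angles length mismatch")
  if (n && any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(abs(angles_deg) > 90 + 1e-9)) stop("|angle| must be <= 90 deg")
  if (is.null(phase))
    phase <- c(rep("metaphase", max(0, n - 1)), "anaphase_onset")
  if (length(phase) != n) stop("phase/times length mismatch")
  if (!all(phase %in% c("prometaphase", "metaphase", "anaphase_onset")))
    stop("unknown phase label")
  if (sum(phase == "anaphase_onset") != 1 || phase[n] != "anaphase_onset")
    stop("exactly one anaphase_onset sample is required, the last")
  structure(list(times = as.numeric(times),
                 angles_deg = as.numeric(angles_deg),
                 phase = phase), class = "plate_track")
}

#' @export
print.plate_track <- function(x, ...) {
  cat("<plate_track> ", length(x$times), " samples over ",
      signif(diff(range(x$times)), 4), " min, angle range ",
      paste(signif(range(x$angles_deg), 4), collapse = " .. "),
      " deg\n", sep = "")
  invisible(x)
}

#' Simulate a mean-reverting plate-angle trajectory
#'
#' Exact-discretization sampling of the anchored-spindle
#' Ornstein--Uhlenbeck model (see [trajectory_params()]): with
#' `a = exp(-k_eff dt)`,
#' `theta[i+1] = a theta[i] + sigma_st sqrt(1 - a^2) Z`, where
#' `sigma_st = noise_sd / sqrt(2 k_eff)` is the stationary SD. The track
#' starts at theta(0) = 0. With zero anchors the angle performs pure
#' diffusion; with zero noise it stays identically 0. Angles are
#' reflected at +/-90 deg (an axis deviation cannot exceed orthogonality).
#' All samples are labelled metaphase except the last, anaphase onset,
#' and times are shifted so anaphase onset is t = 0.
#'
#' @param params a [trajectory_params()].
#' @return A [plate_track()].
#' @export
simulate_plate_trajectory <- function(params) {
  stopifnot(inherits(params, "trajectory_params"))
  set.seed(params$seed)
  k <- params$stiffness_per_anchor *
    (params$n_anchors_polar +
       params$central_fraction * params$n_anchors_central)
  m <- floor(params$duration / params$dt)
  theta <- numeric(m + 1)
  if (k > 0) {
    a <- exp(-k * params$dt)
    innov_sd <- params$noise_sd / sqrt(2 * k) * sqrt(1 - a^2)
  } else {
    a <- 1
    innov_sd <- params$noise_sd * sqrt(params$dt)
  }
  for (i in seq_len(m)) {
    th <- a * theta[i] + innov_sd * stats::rnorm(1)
    # reflect at orthogonality
    while (abs(th) > 90) th <- sign(th) * 180 - th
    theta[i + 1] <- th
  }
  times <- seq(0, m) * params$dt - m * params$dt
  plate_track(times, theta)
}
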