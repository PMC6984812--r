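#' Parameter set for the looming visual stimulus
#'
#' A 500 ms sequence of radially expanding white annuli: each annulus starts
#' in the centre at 0.25 degrees visual angle and expands at 15.52 deg/s up to
#' 3.88 deg; a new annulus starts every 125 ms.
#'
#' @param start_radius_deg starting radius, degrees visual angle.
#' @param speed_deg_per_s radial expansion speed, deg/s.
#' @param max_radius_deg maximum radius, degrees visual angle.
#' @param onset_interval_ms spacing between successive annulus onsets, ms.
#' @param duration_ms sequence duration, ms.
#' @return an object of class `looming_visual_spec`.
#' @export
looming_visual_spec <- function(start_radius_deg = 0.25,
                                speed_deg_per_s = 15.52,
                                max_radius_deg = 3.88,
                                onset_interval_ms = 125,
                                duration_ms = 500) {
  stopifnot_positive(start_radius_deg = start_radius_deg,
                     speed_deg_per_s = speed_deg_per_s,
                     max_radius_deg = max_radius_deg,
                     onset_interval_ms = onset_interval_ms,
                     duration_ms = duration_ms)
  if (start_radius_deg >= max_radius_deg) {
    stop("start_radius_deg must be smaller than max_radius_deg", call. = FALSE)
  }
  if (onset_interval_ms > duration_ms) {
    stop("onset_interval_ms must not exceed duration_ms", call. = FALSE)
  }
  structure(list(start_radius_deg = start_radius_deg,
                 speed_deg_per_s = speed_deg_per_s,
                 max_radius_deg = max_radius_deg,
                 onset_interval_ms = onset_interval_ms,
                 duration_ms = duration_ms),
            class = "looming_visual_spec")
}

#' Parameter set for the looming sound
#'
#' A 500 ms complex of pure tones whose amplitude grows exponentially,
#' `A(t) = A0 * exp(0.68 t) - 1` with t in seconds, and whose frequencies ramp
#' linearly by two thirds of the base frequency over the duration.  The
#' printed form of the amplitude law is typographically ambiguous; the
#' alternative grouping `A0 * exp(0.68 t - 1)` is not used here.
#'
#' @param base_frequencies_hz pure-tone base frequencies, Hz (sorted).
#' @param amp_exponent_per_s exponential growth-rate constant, 1/s.
#' @param freq_ramp_fraction fractional frequency increase over the duration.
#' @param base_amplitude initial baseline amplitude A0 per tone.
#' @param duration_ms sound duration, ms.
#' @return an object of class `looming_sound_spec`.
#' @export
looming_sound_spec <- function(base_frequencies_hz = c(55, 110, 150, 220, 330,
                                                       380, 440, 660, 880, 990,
                                                       1110, 1500, 2500, 3000),
                               amp_exponent_per_s = 0.68,
                               freq_ramp_fraction = 2 / 3,
                               base_amplitude = 1,
                               duration_ms = 500) {
  stopifnot_positive(base_frequencies_hz = base_frequencies_hz,
                     base_amplitude = base_amplitude,
                     duration_ms = duration_ms)
  if (is.unsorted(base_frequencies_hz, strictly = TRUE)) {
    stop("base_frequencies_hz must be strictly increasing", call. = FALSE)
  }
  if (freq_ramp_fraction < 0) {
    stop("freq_ramp_fraction must be non-negative", call. = FALSE)
  }
  structure(list(base_frequencies_hz = base_frequencies_hz,
                 amp_exponent_per_s = amp_exponent_per_s,
                 freq_ramp_fraction = freq_ramp_fraction,
                 base_amplitude = base_amplitude,
                 duration_ms = duration_ms),
            class = "looming_sound_spec")
}

#' Annulus trajectories of the looming visual stimulus
#'
#' One trajectory per onset in `{0, 125, 250, ...} < duration`.  Each radius
#' function grows linearly, `r(t) = start + speed * t`, and the annulus is
#' removed once it reaches the maximum radius: the trajectory is defined on
#' `[0, t_max]` and returns `NA` beyond.
#'
#' @param spec a [looming_visual_spec()].
#' @return a list with one element per annulus: `onset_ms`, `t_max_s` (time to
#'   reach the maximum radius) and `radius`, a function of time in seconds
#'   since the annulus onset.
#' @export
visual_annulus_trajectories <- function(spec = looming_visual_spec()) {
  stopifnot(inherits(spec, "looming_visual_spec"))
  n_on <- ceiling(spec$duration_ms / spec$onset_interval_ms - 1e-9)
  onsets_ms <- (seq_len(n_on) - 1) * spec$onset_interval_ms
  t_max <- (spec$max_radius_deg - spec$start_radius_deg) / spec$speed_deg_per_s
  lapply(onsets_ms, function(on) {
    radius <- local({
      r0 <- spec$start_radius_deg
      v <- spec$speed_deg_per_s
      tm <- t_max
      function(t) ifelse(t < 0 | t > tm, NA_real_, r0 + v * t)
    })
    list(onset_ms = on, t_max_s = t_max, radius = radius)
  })
}

#' Per-tone amplitude and frequency trajectories of the looming sound
#'
#' @param spec a [looming_sound_spec()].
#' @return a list with one element per pure tone: `base_hz`, `amplitude` and
#'   `frequency`, both functions of time in seconds from sound onset.
#' @export
auditory_looming_trajectories <- function(spec = looming_sound_spec()) {
  stopifnot(inherits(spec, "looming_sound_spec"))
  dur_s <- spec$duration_ms / 1000
  lapply(spec$base_frequencies_hz, function(f0) {
    amplitude <- local({
      a0 <- spec$base_amplitude
      k <- spec$amp_exponent_per_s
      function(t) a0 * exp(k * t) - 1
    })
    frequency <- local({
      f <- f0
      ramp <- spec$freq_ramp_fraction
      d <- dur_s
      function(t) f * (1 + ramp * t / d)
    })
    list(base_hz = f0, amplitude = amplitude, frequency = frequency)
  })
}
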