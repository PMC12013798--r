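#' Electrode layout description
#'
#' Describes one linear SEEG depth electrode: number of contacts, their
#' tuber-relative integer positions (0 = tuber core, negative = deep white
#' matter, positive = superficial grey matter), inter-contact spacing and
#' sampling rate.
#'
#' @param positions strictly increasing integer positions, at most one zero.
#' @param contact_spacing_mm centre-to-centre contact spacing in mm
#'   (default 3.5; the recovered gradient slope converts to a speed through
#'   this value, see [propagation_speed()]).
#' @param sampling_rate sampling rate in Hz (default 1000).
#' @return an `tw_layout` object.
#' @export
electrode_layout <- function(positions = -2:2, contact_spacing_mm = 3.5,
                             sampling_rate = 1000) {
  stopifnot(length(positions) >= 2L, all(diff(positions) > 0),
            sum(positions == 0) <= 1L, sampling_rate > 0,
            contact_spacing_mm > 0)
  structure(list(n_channels = length(positions),
                 positions = as.integer(positions),
                 contact_spacing_mm = contact_spacing_mm,
                 sampling_rate = sampling_rate),
            class = "tw_layout")
}

#' Planted spike-wave specification
#'
#' Parameters of the parametric spike-wave events planted by
#' [make_travelling_spike_recording()]. The per-channel event onset follows
#' the linear spatiotemporal model `t = a * f(p) + b + jitter`, with
#' `f(p) = 0` (uniform), `p` (depth-to-surface) or `|p|` (core-to-periphery).
#'
#' @param delay_model `"uniform"`, `"depth_to_surface"` or
#'   `"core_to_periphery"`.
#' @param a gradient slope in ms per position unit (ignored for uniform).
#' @param b intercept in ms.
#' @param jitter_sd per-channel Gaussian onset jitter SD in ms (default 2).
#' @param spike_amplitude_uv peak amplitude of the fast spike component
#'   (microvolts, default 100).
#' @param spike_width_ms full width at half maximum of the spike (< 20 ms
#'   for detectable events, default 10).
#' @param slow_wave_amplitude_uv amplitude of the trailing slow half-sine
#'   wave (default 40).
#' @param slow_wave_duration_ms duration of the slow wave (200-400 ms,
#'   default 300).
#' @param noise_sd_uv background noise SD (default 10).
#' @param noise_kind `"pink"` (1/f-shaped, default) or `"white"`.
#' @param n_events number of planted events (>= 1 unless explicitly 0).
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @return a `tw_wavespec` object.
#' @export
planted_wave_spec <- function(delay_model = c("core_to_periphery",
                                              "depth_to_surface", "uniform"),
                              a = 5, b = 0, jitter_sd = 2,
                              spike_amplitude_uv = 100, spike_width_ms = 10,
                              slow_wave_amplitude_uv = 40,
                              slow_wave_duration_ms = 300,
                              noise_sd_uv = 10,
                              noise_kind = c("pink", "white"),
                              n_events = 20, seed = 1L) {
  delay_model <- match.arg(delay_model)
  noise_kind <- match.arg(noise_kind)
  stopifnot(spike_width_ms > 0, n_events >= 0, jitter_sd >= 0,
            noise_sd_uv >= 0, slow_wave_duration_ms >= 100)
  structure(list(delay_model = delay_model, a = a, b = b,
                 jitter_sd = jitter_sd,
                 spike_amplitude_uv = spike_amplitude_uv,
                 spike_width_ms = spike_width_ms,
                 slow_wave_amplitude_uv = slow_wave_amplitude_uv,
                 slow_wave_duration_ms = slow_wave_duration_ms,
                 noise_sd_uv = noise_sd_uv, noise_kind = noise_kind,
                 n_events = n_events, seed = as.integer(seed)),
            class = "tw_wavespec")
}

delay_model_f <- function(model, p) {
  switch(model,
         uniform = rep(0, length(p)),
         depth_to_surface = p,
         core_to_periphery = abs(p),
         stop("unknown delay model: ", model))
}

# biphasic spike: difference of two Gaussians; sd chosen so the full width at
# half maximum of the positive lobe equals width_ms
spike_template <- function(t_ms, amplitude, width_ms) {
  s1 <- width_ms / 2.355
  main <- exp(-t_ms^2 / (2 * s1^2))
  after <- exp(-(t_ms - 1.6 * width_ms)^2 / (2 * (1.3 * s1)^2))
  amplitude * (main - 0.45 * after)
}

slow_wave_template <- function(t_ms, amplitude, onset_ms, duration_ms) {
  u <- (t_ms - onset_ms) / duration_ms
  ifelse(u >= 0 & u <= 1, amplitude * sin(pi * u), 0)
}

# 1/f-shaped ("pink") Gaussian noise via spectral shaping, unit variance
pink_noise <- function(n, fs) {
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  amp <- 1 / sqrt(pmax(f, 1))           # flat below 1 Hz, 1/f above
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) full[nf + 1] <- complex(real = amp[nf])
  full[n:(n - nf + 2)] <- Conj(full[2:nf])
  x <- Re(stats::fft(full, inverse = TRUE))
  as.numeric(scale(x))
}

background_noise <- function(nch, n, fs, sd, kind) {
  if (sd <= 0) return(matrix(0, nch, n))
  t(vapply(seq_len(nch), function(i) {
    if (kind == "pink") sd * pink_noise(n, fs) else stats::rnorm(n, 0, sd)
  }, numeric(n)))
}

#' Generate a recording with planted travelling spike-wave events
#'
#' Each event appears on every channel as a biphasic spike plus trailing
#' slow wave. The per-channel spike peak time is
#' `t_event + a * f(p) + b + jitter`, where `f(p)` follows the chosen delay
#' model. The exact planted peak times are returned as ground truth.
#'
#' @param layout an [electrode_layout()].
#' @param spec a [planted_wave_spec()].
#' @param duration_s recording duration in seconds; defaults to
#'   `max(n_events + 1, 10)` seconds with events spaced >= 1 s apart.
#' @param event_times_s optional explicit event reference times (seconds);
#'   inter-event intervals below 0.5 s are rejected.
#' @return list with elements `recording` (bipolar-convention
#'   `tw_recording`), `events` (data frame: event, channel, position,
#'   planted_peak_ms) and `spec`.
#' @export
make_travelling_spike_recording <- function(layout, spec, duration_s = NULL,
                                            event_times_s = NULL) {
  stopifnot(inherits(layout, "tw_layout"), inherits(spec, "tw_wavespec"))
  fs <- layout$sampling_rate
  if (is.null(event_times_s)) {
    if (is.null(duration_s)) duration_s <- max(spec$n_events + 1, 10)
    if (spec$n_events > 0) {
      if (duration_s < spec$n_events * 1)
        stop("duration too short: need >= 1 s per event")
      event_times_s <- seq(0.75, duration_s - 0.6,
                           length.out = max(spec$n_events, 2))[seq_len(spec$n_events)]
    } else event_times_s <- numeric(0)
  } else {
    if (is.null(duration_s)) duration_s <- max(event_times_s) + 1
    if (length(event_times_s) > 1 && min(diff(sort(event_times_s))) < 0.5)
      stop("overlapping events: inter-event interval < 500 ms")
  }
  n <- round(duration_s * fs)
  set.seed(spec$seed)
  x <- background_noise(layout$n_channels, n, fs, spec$noise_sd_uv,
                        spec$noise_kind)
  tt <- (seq_len(n) - 1L) / fs * 1000   # ms
  offs <- delay_model_f(spec$delay_model, layout$positions)
  events <- NULL
  for (e in seq_along(event_times_s)) {
    t0 <- event_times_s[e] * 1000
    jit <- if (spec$jitter_sd > 0)
      stats::rnorm(layout$n_channels, 0, spec$jitter_sd) else
      rep(0, layout$n_channels)
    peaks <- t0 + spec$a * offs + spec$b + jit
    for (ch in seq_len(layout$n_channels)) {
      rel <- tt - peaks[ch]
      sel <- which(rel > -100 & rel < 600)
      x[ch, sel] <- x[ch, sel] +
        spike_template(rel[sel], spec$spike_amplitude_uv, spec$spike_width_ms) +
        slow_wave_template(rel[sel], spec$slow_wave_amplitude_uv,
                           1.2 * spec$spike_width_ms,
                           spec$slow_wave_duration_ms)
    }
    events <- rbind(events,
                    data.frame(event = e, channel = seq_len(layout$n_channels),
                               position = layout$positions,
                               planted_peak_ms = peaks))
  }
  rec <- new_recording(x, fs,
                       sprintf("B%02d", seq_len(layout$n_channels)),
                       "bipolar", layout$positions)
  list(recording = rec, events = events, spec = spec)
}

#' Generate negative-control recordings violating one detection criterion
#'
#' Plants events that violate exactly one of the three spike-detection
#' criteria (amplitude in SD units, limb slope, width) while satisfying the
#' other two, so a conforming detector must return zero detections.
#'
#' For the amplitude control the channel variance is supplied by a large
#' 3 Hz background rhythm rather than broadband noise, and the steep,
#' narrow spikes are planted at its zero crossings at about 3 SD: the
#' sub-threshold margin is then deterministic instead of riding on noise
#' excursions.
#'
#' @param layout an [electrode_layout()].
#' @param which_criterion `"amplitude"`, `"slope"` or `"width"`.
#' @param n_events planted events per channel (default 5); 0 gives baseline
#'   noise only.
#' @param noise_sd_uv background noise SD; default is per-criterion (10 for
#'   amplitude, 4 for slope, 5 for width) so the two satisfied criteria hold
#'   with margin in the presence of noise.
#' @param seed integer seed.
#' @return list with `recording`, `events` and `which_criterion`.
#' @export
make_distractor_events <- function(layout,
                                   which_criterion = c("amplitude", "slope",
                                                       "width"),
                                   n_events = 5, noise_sd_uv = NULL, seed = 1L) {
  which_criterion <- match.arg(which_criterion)
  stopifnot(inherits(layout, "tw_layout"))
  if (is.null(noise_sd_uv))
    noise_sd_uv <- switch(which_criterion, amplitude = 1, slope = 4, width = 5)
  fs <- layout$sampling_rate
  duration_s <- max(n_events + 1, 10)
  n <- round(duration_s * fs)
  set.seed(as.integer(seed))
  x <- background_noise(layout$n_channels, n, fs, noise_sd_uv, "pink")
  tt <- (seq_len(n) - 1L) / fs * 1000
  if (which_criterion == "amplitude") {
    bg_amp <- 30                       # 3 Hz rhythm carrying the variance
    bg <- bg_amp * sin(2 * pi * 3 * tt / 1000)
    x <- sweep(x, 2L, bg, `+`)
    sd0 <- sqrt(bg_amp^2 / 2 + noise_sd_uv^2)
  } else sd0 <- noise_sd_uv
  events <- NULL
  if (n_events > 0) {
    times <- seq(0.75, duration_s - 0.6, length.out = max(n_events, 2))[seq_len(n_events)]
    if (which_criterion == "amplitude")  # snap onto rhythm zero crossings
      times <- round(times * 6) / 6
    for (e in seq_along(times)) {
      t0 <- times[e] * 1000
      for (ch in seq_len(layout$n_channels)) {
        rel <- tt - t0
        sel <- which(rel > -150 & rel < 150)
        tpl <- switch(which_criterion,
          # ~3 SD peak, narrow and steep: slope and width criteria pass
          amplitude = spike_template(rel[sel], 3 * sd0, 4),
          # > 4 SD and narrow, but gentle Gaussian: max slope well below
          # 7 uV/ms on both limbs
          slope = 4.8 * sd0 * exp(-rel[sel]^2 / (2 * (18 / 2.355)^2)),
          # large and steep but 30 ms wide at half maximum
          width = 40 * sd0 * exp(-rel[sel]^2 / (2 * (30 / 2.355)^2)))
        x[ch, sel] <- x[ch, sel] + tpl
      }
      events <- rbind(events, data.frame(event = e, planted_peak_ms = t0))
    }
  }
  rec <- new_recording(x, fs, sprintf("B%02d", seq_len(layout$n_channels)),
                       "bipolar", layout$positions)
  list(recording = rec, events = events, which_criterion = which_criterion)
}
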