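#' Detect interictal spikes on each channel
#'
#' A candidate peak is accepted as a spike when it satisfies all three
#' criteria: (1) absolute peak deflection more than `amp_sd_threshold`
#' standard deviations from the channel mean (mean and SD taken over the
#' whole segment), (2) ascending and descending limb slopes both above
#' `slope_threshold` in absolute value, and (3) full width at half of the
#' peak deflection below `max_width_ms`. Detection operates on the absolute
#' deflection, so it is invariant to a global sign flip.
#'
#' @param rec a band-pass filtered `tw_recording` (see [preprocess()]) of at
#'   least 1 s.
#' @param amp_sd_threshold amplitude threshold in SD units (default 4).
#' @param slope_threshold limb slope threshold in microvolts/ms (default 7).
#' @param max_width_ms maximum spike width in ms (default 20).
#' @param robust use median/MAD instead of mean/SD for the baseline.
#' @param refractory_ms minimum separation of detections on one channel;
#'   the larger peak wins (default 60).
#' @return data frame of spike events sorted by time: `channel`, `label`,
#'   `position`, `peak_time_ms`, `peak_amplitude_uv`, `peak_amplitude_sd`,
#'   `ascending_slope`, `descending_slope`, `width_ms`.
#' @export
detect_spikes <- function(rec, amp_sd_threshold = 4, slope_threshold = 7,
                          max_width_ms = 20, robust = FALSE,
                          refractory_ms = 60) {
  stopifnot(inherits(rec, "tw_recording"),
            amp_sd_threshold > 0, slope_threshold > 0, max_width_ms > 0)
  if (duration_s(rec) < 1) stop("segment shorter than 1 s: SD unreliable")
  fs <- rec$sampling_rate
  out <- NULL
  for (ch in seq_len(n_channels(rec))) {
    x <- rec$samples[ch, ]
    mu <- if (robust) stats::median(x) else mean(x)
    sdv <- if (robust) stats::mad(x) else stats::sd(x)
    if (sdv <= 0) next
    d <- x - mu                      # deflection from baseline
    ad <- abs(d)
    thr <- amp_sd_threshold * sdv
    above <- ad > thr
    if (!any(above)) next
    # local maxima of |deflection| above threshold
    cand <- which(above)
    cand <- cand[cand > 1L & cand < length(x)]
    cand <- cand[ad[cand] >= ad[cand - 1L] & ad[cand] >= ad[cand + 1L]]
    if (!length(cand)) next
    # enforce refractory period, larger peak wins
    keep <- logical(length(cand))
    ord <- order(ad[cand], decreasing = TRUE)
    taken <- rep(FALSE, length(x))
    refr <- round(refractory_ms / 1000 * fs)
    for (i in ord) {
      p <- cand[i]
      if (!taken[p]) {
        keep[i] <- TRUE
        lo <- max(1L, p - refr); hi <- min(length(x), p + refr)
        taken[lo:hi] <- TRUE
      }
    }
    cand <- sort(cand[keep])
    for (p in cand) {
      m <- measure_spike(d, p, fs)
      if (is.null(m)) next
      if (m$width_ms >= max_width_ms) next
      if (abs(m$asc) <= slope_threshold || abs(m$desc) <= slope_threshold) next
      out <- rbind(out, data.frame(
        channel = ch, label = rec$channel_labels[ch],
        position = if (is.null(rec$positions)) NA else rec$positions[ch],
        peak_time_ms = (p - 1L) / fs * 1000,
        peak_amplitude_uv = d[p],
        peak_amplitude_sd = ad[p] / sdv,
        ascending_slope = m$asc, descending_slope = m$desc,
        width_ms = m$width_ms))
    }
  }
  if (is.null(out))
    out <- data.frame(channel = integer(0), label = character(0),
                      position = numeric(0), peak_time_ms = numeric(0),
                      peak_amplitude_uv = numeric(0),
                      peak_amplitude_sd = numeric(0),
                      ascending_slope = numeric(0),
                      descending_slope = numeric(0), width_ms = numeric(0))
  out[order(out$peak_time_ms), , drop = FALSE]
}

# slopes (max |first difference| over each limb, uV/ms) and full width at
# half the peak deflection; limbs run from the peak to the half-amplitude
# crossings, searched up to 50 ms either side
measure_spike <- function(d, p, fs, search_ms = 50) {
  n <- length(d)
  half <- abs(d[p]) / 2
  w <- round(search_ms / 1000 * fs)
  sgn <- sign(d[p])
  seg <- sgn * d                     # peak positive in seg
  li <- p
  lo <- max(1L, p - w)
  while (li > lo && seg[li - 1L] > half) li <- li - 1L
  ri <- p
  hi <- min(n, p + w)
  while (ri < hi && seg[ri + 1L] > half) ri <- ri + 1L
  # li/ri are the outermost samples still above half; if the walk hit the
  # search bound the deflection never crossed half within 50 ms -> "wide"
  width_ms <- if (li > lo && ri < hi) (ri - li) / fs * 1000 else Inf
  asc_idx <- max(1L, li - 1L):p
  desc_idx <- p:min(n, ri + 1L)
  dt_ms <- 1000 / fs
  asc <- if (length(asc_idx) > 1) max(abs(diff(d[asc_idx]))) / dt_ms else 0
  desc <- if (length(desc_idx) > 1) max(abs(diff(d[desc_idx]))) / dt_ms else 0
  list(asc = asc, desc = desc, width_ms = width_ms)
}

#' Group co-occurring spikes across channels of one electrode
#'
#' Events are clustered in time by single linkage: sorted peak times are
#' chained while consecutive gaps stay within `group_window_ms`. Groups need
#' members on at least two distinct channels; when one channel contributes
#' several spikes to a group, the largest-amplitude one is kept, so each
#' event belongs to at most one group.
#'
#' @param events spike data frame from [detect_spikes()] (one electrode).
#' @param group_window_ms grouping window in ms (default 200).
#' @param linkage `"single"` (default, chains within the window) or
#'   `"clique"` (all members within the window of each other).
#' @return list of `tw_spikegroup` objects, each with `members` (event rows)
#'   and `reference_time_ms` (earliest member peak).
#' @export
group_spikes <- function(events, group_window_ms = 200,
                         linkage = c("single", "clique")) {
  linkage <- match.arg(linkage)
  if (nrow(events) == 0) return(list())
  ev <- events[order(events$peak_time_ms), , drop = FALSE]
  gaps <- diff(ev$peak_time_ms)
  cl <- cumsum(c(1, gaps > group_window_ms))
  groups <- list()
  for (g in unique(cl)) {
    mem <- ev[cl == g, , drop = FALSE]
    if (linkage == "clique") {
      # trim to the densest window of width group_window_ms
      span <- max(mem$peak_time_ms) - min(mem$peak_time_ms)
      if (span > group_window_ms) {
        t0 <- mem$peak_time_ms
        counts <- vapply(t0, function(s)
          sum(t0 >= s & t0 <= s + group_window_ms), integer(1))
        s <- t0[which.max(counts)]
        mem <- mem[mem$peak_time_ms >= s &
                   mem$peak_time_ms <= s + group_window_ms, , drop = FALSE]
      }
    }
    # one spike per channel: largest deflection wins
    mem <- mem[order(-abs(mem$peak_amplitude_uv)), , drop = FALSE]
    mem <- mem[!duplicated(mem$channel), , drop = FALSE]
    mem <- mem[order(mem$peak_time_ms), , drop = FALSE]
    if (nrow(mem) < 2) next
    groups[[length(groups) + 1L]] <-
      structure(list(members = mem,
                     reference_time_ms = min(mem$peak_time_ms)),
                class = "tw_spikegroup")
  }
  groups
}

#' Per-channel local maxima around a spike group
#'
#' For delay analysis every channel contributes a timing estimate, including
#' channels whose deflection did not meet the full detection criteria: the
#' time of the absolute-maximum deflection within the group window. Channels
#' whose maximum stays below `floor_sd` standard deviations (or that are
#' flat) are reported as missing and excluded downstream.
#'
#' @param rec the `tw_recording` the group was detected on.
#' @param group a `tw_spikegroup`.
#' @param window_ms window length centred on the group reference time
#'   (default 200).
#' @param floor_sd inclusion floor in SD units for channels without a
#'   detected spike (default 2).
#' @return data frame: `channel`, `position`, `peak_time_ms` (NA when below
#'   floor), `peak_sd`.
#' @export
local_maxima_around_group <- function(rec, group, window_ms = 200,
                                      floor_sd = 2) {
  stopifnot(inherits(rec, "tw_recording"), inherits(group, "tw_spikegroup"))
  fs <- rec$sampling_rate
  half <- round(window_ms / 2 / 1000 * fs)
  c0 <- round(group$reference_time_ms / 1000 * fs) + 1L
  lo <- max(1L, c0 - half); hi <- min(n_samples(rec), c0 + half)
  out <- NULL
  for (ch in seq_len(n_channels(rec))) {
    x <- rec$samples[ch, ]
    mu <- mean(x); sdv <- stats::sd(x)
    seg <- abs(x[lo:hi] - mu)
    detected <- ch %in% group$members$channel
    if (sdv <= 0) {
      pk <- NA_real_; z <- 0
    } else {
      i <- which.max(seg)
      z <- seg[i] / sdv
      pk <- if (detected || z >= floor_sd) (lo + i - 2L) / fs * 1000 else NA_real_
    }
    out <- rbind(out, data.frame(
      channel = ch,
      position = if (is.null(rec$positions)) NA else rec$positions[ch],
      peak_time_ms = pk, peak_sd = z))
  }
  out
}
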