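#' Multichannel SEEG recording container
#'
#' A `tw_recording` holds a channels-by-time matrix of samples in microvolts
#' together with the metadata every downstream stage needs: sampling rate,
#' channel labels, montage kind and the tuber-relative integer position of
#' each channel (0 = tuber core, negative = deep white matter, positive =
#' superficial grey matter; bipolar channels may carry half-integer
#' positions, see [make_bipolar()]).
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param sampling_rate sampling rate in Hz (scalar, > 0).
#' @param channel_labels character vector, one label per channel.
#' @param montage `"referential"` or `"bipolar"`.
#' @param positions numeric vector of tuber-relative positions, one per
#'   channel; integers on referential montages.
#' @param segment_id optional identifier carried through segment extraction.
#'
#' @return An object of class `tw_recording`.
#' @export
new_recording <- function(samples, sampling_rate, channel_labels = NULL,
                          montage = c("referential", "bipolar"),
                          positions = NULL, segment_id = NULL) {
  montage <- match.arg(montage)
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  nch <- nrow(samples)
  if (is.null(channel_labels)) channel_labels <- sprintf("E%02d", seq_len(nch))
  stopifnot(length(channel_labels) == nch,
            is.numeric(sampling_rate), length(sampling_rate) == 1L,
            sampling_rate > 0)
  if (anyNA(samples)) stop("recording contains NA samples")
  if (!is.null(positions)) {
    if (length(positions) != nch)
      stop("positions must have one entry per channel")
    if (sum(positions == 0) > 1L)
      stop("at most one channel may hold the core position 0")
  }
  structure(list(samples = samples,
                 sampling_rate = sampling_rate,
                 channel_labels = channel_labels,
                 montage = montage,
                 positions = positions,
                 segment_id = segment_id),
            class = "tw_recording")
}

#' @export
print.tw_recording <- function(x, ...) {
  cat(sprintf("<tw_recording> %d channel(s) x %d samples @ %g Hz (%.1f s), %s montage\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate, x$montage))
  if (!is.null(x$positions))
    cat("  positions:", paste(x$positions, collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.tw_recording <- function(x) dim(x$samples)

n_channels <- function(rec) nrow(rec$samples)
n_samples <- function(rec) ncol(rec$samples)
duration_s <- function(rec) ncol(rec$samples) / rec$sampling_rate

#' Time axis of a recording in milliseconds
#' @param rec a `tw_recording`.
#' @return numeric vector of sample times in ms, starting at 0.
#' @export
time_ms <- function(rec) (seq_len(ncol(rec$samples)) - 1L) / rec$sampling_rate * 1000

#' Re-montage a referential recording to bipolar derivations
#'
#' Channel `i` of the output is `contact_i - contact_{i+1}` for contacts
#' ordered along the electrode, suppressing signals common to adjacent
#' contacts. The position assigned to a bipolar channel is the midpoint of
#' the two contact positions, rounded toward the deeper (more negative)
#' contact so that the core label stays unique.
#'
#' @param rec referential `tw_recording` with at least two channels.
#' @return bipolar `tw_recording` with `n - 1` channels.
#' @export
make_bipolar <- function(rec) {
  stopifnot(inherits(rec, "tw_recording"))
  if (rec$montage != "referential")
    stop("make_bipolar() expects a referential recording")
  nch <- n_channels(rec)
  if (nch < 2L) stop("bipolar montage needs at least two contacts")
  out <- rec$samples[-nch, , drop = FALSE] - rec$samples[-1L, , drop = FALSE]
  labs <- paste0(rec$channel_labels[-nch], "-", rec$channel_labels[-1L])
  pos <- NULL
  if (!is.null(rec$positions)) {
    mid <- (rec$positions[-nch] + rec$positions[-1L]) / 2
    # round half-integers toward the deeper (more negative) contact,
    # keeping the core label (0) unique
    pos <- floor(mid + 1e-9)
  }
  new_recording(out, rec$sampling_rate, labs, "bipolar", pos, rec$segment_id)
}

#' Extract non-overlapping random analysis segments
#'
#' Draws `n_segments` non-overlapping windows of `segment_length_s` seconds
#' with random onsets (seeded), mirroring random interval selection from
#' long interictal recordings.
#'
#' @param rec a `tw_recording`.
#' @param n_segments number of segments to draw.
#' @param segment_length_s segment length in seconds (default 60).
#' @param seed integer seed for reproducible onsets.
#' @param reject_above optional amplitude-clipping threshold in microvolts;
#'   candidate segments containing |x| above it are rejected and redrawn.
#' @return list of `tw_recording` segments, each tagged with a `segment_id`.
#' @export
extract_segments <- function(rec, n_segments, segment_length_s = 60,
                             seed = 1L, reject_above = NULL) {
  stopifnot(inherits(rec, "tw_recording"), n_segments >= 1)
  len <- round(segment_length_s * rec$sampling_rate)
  total <- n_samples(rec)
  if (n_segments * len > total)
    stop(sprintf("recording too short: need %d samples, have %d",
                 n_segments * len, total))
  set.seed(seed)
  # partition free space among segments: draw non-overlapping onsets by
  # placing gaps from a random composition of the slack
  slack <- total - n_segments * len
  cuts <- sort(sample.int(slack + 1L, n_segments, replace = TRUE) - 1L)
  onsets <- cuts + (seq_len(n_segments) - 1L) * len + 1L
  segs <- vector("list", n_segments)
  for (i in seq_len(n_segments)) {
    idx <- onsets[i]:(onsets[i] + len - 1L)
    seg <- new_recording(rec$samples[, idx, drop = FALSE], rec$sampling_rate,
                         rec$channel_labels, rec$montage, rec$positions,
                         segment_id = sprintf("seg%02d", i))
    if (!is.null(reject_above) && max(abs(seg$samples)) > reject_above) {
      segs[[i]] <- NULL
      next
    }
    segs[[i]] <- seg
  }
  segs[!vapply(segs, is.null, logical(1))]
}

#' Write / read the channel-position sidecar table
#'
#' @param rec a `tw_recording` with positions.
#' @param path CSV path.
#' @return `write_positions()` returns `path` invisibly; `read_positions()`
#'   returns a data frame with columns `channel_label`, `position`.
#' @export
write_positions <- function(rec, path) {
  stopifnot(!is.null(rec$positions))
  utils::write.csv(data.frame(channel_label = rec$channel_labels,
                              position = rec$positions),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions
#' @param path CSV path.
#' @export
read_positions <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
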