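# Minimal EDF / EDF+C reader and writer.
#
# EDF stores a 256-byte fixed-width ASCII header, 256 further header bytes per
# signal, then data records of little-endian int16 samples scaled between the
# per-signal physical and digital ranges. Only continuous files (EDF, EDF+C)
# are supported; discontinuous EDF+D files are rejected.

edf_pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1L, n)
  formatC(x, width = -n, flag = " ")
}

edf_num <- function(x, n) edf_pad(format(x, trim = TRUE, scientific = FALSE), n)

#' Write a recording to an EDF+C file
#'
#' Samples are quantised to 16-bit integers over the per-channel physical
#' range, the usual EDF resolution. An `EDF Annotations` signal carrying the
#' record timestamps is included for EDF+ compliance.
#'
#' @param rec a `tw_recording` (samples in microvolts).
#' @param path output file path.
#' @param record_duration_s data record length in seconds (default 1).
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path, record_duration_s = 1) {
  stopifnot(inherits(rec, "tw_recording"))
  fs <- rec$sampling_rate
  spr <- round(fs * record_duration_s)
  if (abs(spr - fs * record_duration_s) > 1e-9)
    stop("sampling_rate x record_duration_s must be an integer sample count")
  x <- rec$samples
  nch <- nrow(x)
  n_rec <- ceiling(ncol(x) / spr)
  pad <- n_rec * spr - ncol(x)
  if (pad > 0) x <- cbind(x, matrix(0, nch, pad))

  pmin_ <- apply(x, 1L, min); pmax_ <- apply(x, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L

  ns <- nch + 1L  # + annotations signal
  ann_spr <- 16L  # 32 bytes per record for the timekeeping TAL
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    edf_num(256L * (ns + 1L), 8), edf_pad("EDF+C", 44),
    edf_num(n_rec, 8), edf_num(record_duration_s, 8), edf_num(ns, 4))
  writeChar(hdr, con, eos = NULL)
  lab <- c(vapply(rec$channel_labels, edf_pad, "", n = 16), edf_pad("EDF Annotations", 16))
  put <- function(v, n) writeChar(paste(vapply(v, edf_pad, "", n = n), collapse = ""),
                                  con, eos = NULL)
  put(lab, 16)
  put(rep("", ns), 80)                                   # transducer
  put(c(rep("uV", nch), ""), 8)                          # physical dimension
  put(c(format(pmin_, trim = TRUE), "-1"), 8)            # physical min
  put(c(format(pmax_, trim = TRUE), "1"), 8)             # physical max
  put(c(rep(format(dmin), nch), format(dmin)), 8)        # digital min
  put(c(rep(format(dmax), nch), format(dmax)), 8)        # digital max
  put(rep("", ns), 80)                                   # prefiltering
  put(c(rep(format(spr), nch), format(ann_spr)), 8)      # samples per record
  put(rep("", ns), 32)                                   # reserved

  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    dig <- round((x[, idx, drop = FALSE] - pmin_) * gain + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    # interleave per signal: all samples of signal 1, then signal 2, ...
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
    tal <- sprintf("+%s\x14\x14", format((r - 1L) * record_duration_s,
                                         trim = TRUE, scientific = FALSE))
    tal_raw <- c(charToRaw(tal), raw(2L * ann_spr - nchar(tal, "bytes")))
    writeBin(tal_raw, con)
  }
  invisible(path)
}

#' Read an EDF / EDF+C file into a recording
#'
#' Samples are rescaled to physical units (microvolts expected). Annotation
#' signals are dropped. Discontinuous (EDF+D) files and files mixing
#' sampling rates across data channels are rejected.
#'
#' @param path EDF file path.
#' @param positions optional numeric vector of tuber-relative positions for
#'   the data channels, or a sidecar CSV path as written by
#'   [write_positions()].
#' @param montage montage of the stored channels (metadata only).
#' @return a `tw_recording`.
#' @export
read_edf <- function(path, positions = NULL, montage = "referential") {
  con <- file(path, "rb")
  on.exit(close(con))
  getn <- function(n) readChar(con, n, useBytes = TRUE)
  getn(8)                          # version
  getn(80); getn(80); getn(8); getn(8)
  as.integer(getn(8))              # header bytes
  reserved <- trimws(getn(44))
  if (identical(reserved, "EDF+D"))
    stop("discontinuous EDF+D files are not supported (only continuous segments)")
  n_rec <- as.integer(getn(8))
  rec_dur <- as.numeric(getn(8))
  ns <- as.integer(getn(4))
  fld <- function(n) vapply(seq_len(ns), function(i) trimws(getn(n)), "")
  labels <- fld(16); fld(80)
  dims <- fld(8)
  pmin_ <- as.numeric(fld(8)); pmax_ <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)

  is_ann <- labels %in% c("EDF Annotations", "BDF Annotations")
  keep <- which(!is_ann)
  if (length(keep) == 0L) stop("no data signals in file")
  if (any(dims[keep] == ""))
    stop("missing physical dimension for channel(s): ",
         paste(labels[keep][dims[keep] == ""], collapse = ", "))
  if (length(unique(spr[keep])) != 1L) {
    tab <- paste(sprintf("%s=%d", labels[keep], spr[keep]), collapse = ", ")
    stop("mixed sampling rates across channels: ", tab)
  }
  fs <- spr[keep[1L]] / rec_dur
  out <- matrix(0, length(keep), n_rec * spr[keep[1L]])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      if (is_ann[s]) {
        readBin(con, "raw", 2L * spr[s])
      } else {
        dig <- readBin(con, "integer", spr[s], size = 2L, signed = TRUE,
                       endian = "little")
        k <- match(s, keep)
        out[k, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
          pmin_[s] + (dig - dmin[s]) * scale[s]
      }
    }
  }
  if (is.character(positions)) {
    tab <- read_positions(positions)
    positions <- tab$position[match(labels[keep], tab$channel_label)]
  }
  new_recording(out, fs, labels[keep], montage, positions)
}
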