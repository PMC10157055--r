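# Minimal European Data Format (EDF) ingestion. EDF is a fixed-layout ASCII
# header followed by interleaved 16-bit little-endian data records; this
# reader covers plain continuous EDF (no EDF+ annotations, no discontinuous
# records), which is what PSG epoch extraction needs.

edf_read_field <- function(con, n) {
  trimws(readChar(con, n, useBytes = TRUE))
}

read_edf_header <- function(con) {
  version <- edf_read_field(con, 8)
  patient <- edf_read_field(con, 80)
  recording <- edf_read_field(con, 80)
  startdate <- edf_read_field(con, 8)
  starttime <- edf_read_field(con, 8)
  header_bytes <- as.integer(edf_read_field(con, 8))
  reserved <- edf_read_field(con, 44)
  n_records <- as.integer(edf_read_field(con, 8))
  record_duration <- as.numeric(edf_read_field(con, 8))
  ns <- as.integer(edf_read_field(con, 4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF file: bad signal count")
  field_block <- function(width) {
    vapply(seq_len(ns), function(i) edf_read_field(con, width), character(1))
  }
  labels <- field_block(16)
  transducer <- field_block(80)
  phys_dim <- field_block(8)
  phys_min <- as.numeric(field_block(8))
  phys_max <- as.numeric(field_block(8))
  dig_min <- as.numeric(field_block(8))
  dig_max <- as.numeric(field_block(8))
  prefilter <- field_block(80)
  n_samp <- as.integer(field_block(8))
  field_block(32)  # per-signal reserved
  list(version = version, patient = patient, recording = recording,
       startdate = startdate, starttime = starttime,
       header_bytes = header_bytes, reserved = reserved,
       n_records = n_records, record_duration = record_duration, ns = ns,
       labels = labels, phys_min = phys_min, phys_max = phys_max,
       dig_min = dig_min, dig_max = dig_max, n_samp = n_samp)
}

#' Read an EDF recording and segment it into fixed-length epochs
#'
#' Reads the requested channels from a (plain, continuous) EDF file, converts
#' digital values to physical units with the per-signal calibration in the
#' header, and cuts the recording into non-overlapping epochs of
#' `epoch_seconds`. A trailing partial epoch is dropped. All requested
#' channels must share one sampling rate.
#'
#' @param path Path to the EDF file.
#' @param channel_names Channel labels to extract, in the desired row order.
#' @param epoch_seconds Epoch length in seconds (default 30, the standard
#'   sleep-staging epoch).
#' @return List of epoch matrices (`n_channels x samples_per_epoch`), each
#'   with attributes `sampling_rate` and `epoch_index`.
#' @export
read_edf_epochs <- function(path, channel_names, epoch_seconds = 30) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_edf_header(con)
  missing_ch <- setdiff(channel_names, hdr$labels)
  if (length(missing_ch) > 0) {
    stop("channel(s) not present in EDF file: ",
         paste(missing_ch, collapse = ", "),
         "; available channels: ", paste(hdr$labels, collapse = ", "))
  }
  sel <- match(channel_names, hdr$labels)
  fs <- hdr$n_samp[sel] / hdr$record_duration
  if (length(unique(fs)) != 1) {
    stop("requested channels have differing sampling rates: ",
         paste(fs, collapse = ", "))
  }
  fs <- fs[1]
  # read all records; per record, signals are stored back to back as int16
  per_record <- sum(hdr$n_samp)
  raw <- readBin(con, "integer", n = per_record * hdr$n_records,
                 size = 2, signed = TRUE, endian = "little")
  if (length(raw) < per_record * hdr$n_records) {
    stop("unreadable EDF file: truncated data section")
  }
  offsets <- c(0, cumsum(hdr$n_samp))
  scale <- (hdr$phys_max - hdr$phys_min) / (hdr$dig_max - hdr$dig_min)
  out <- lapply(sel, function(si) {
    idx <- as.vector(outer(offsets[si] + seq_len(hdr$n_samp[si]),
                           (seq_len(hdr$n_records) - 1) * per_record, "+"))
    (raw[idx] - hdr$dig_min[si]) * scale[si] + hdr$phys_min[si]
  })
  x <- do.call(rbind, out)
  samples_per_epoch <- as.integer(round(fs * epoch_seconds))
  n_epochs <- floor(ncol(x) / samples_per_epoch)
  if (n_epochs < 1) stop("recording shorter than one epoch")
  lapply(seq_len(n_epochs), function(e) {
    ep <- x[, ((e - 1) * samples_per_epoch + 1):(e * samples_per_epoch),
            drop = FALSE]
    structure(ep, sampling_rate = fs, epoch_index = e)
  })
}

# Internal EDF writer (testing utility): writes a plain continuous EDF file
# from a channels x samples matrix, one-second records, 16-bit quantization
# over the observed physical range.
write_edf <- function(x, path, channel_names, sampling_rate,
                      phys_min = NULL, phys_max = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(channel_names))
  ns <- nrow(x)
  record_duration <- 1
  n_samp <- rep(as.integer(sampling_rate), ns)
  n_records <- floor(ncol(x) / sampling_rate)
  stopifnot(n_records >= 1)
  x <- x[, seq_len(n_records * sampling_rate), drop = FALSE]
  # shortest %g rendering that fits the 8-char EDF numeric fields; the parsed
  # value is reused for scaling so writer and reader agree exactly
  num8 <- function(v) {
    vapply(v, function(z) {
      for (d in 6:1) {
        s <- sprintf(paste0("%.", d, "g"), z)
        if (nchar(s) <= 8) return(s)
      }
      stop("value does not fit EDF numeric field: ", z)
    }, character(1))
  }
  if (is.null(phys_min)) phys_min <- apply(x, 1, min) - 1e-3
  if (is.null(phys_max)) phys_max <- apply(x, 1, max) + 1e-3
  phys_min_s <- num8(phys_min); phys_min <- as.numeric(phys_min_s)
  phys_max_s <- num8(phys_max); phys_max <- as.numeric(phys_max_s)
  dig_min <- rep(-32768, ns)
  dig_max <- rep(32767, ns)
  pad <- function(v, w) {
    s <- substr(as.character(v), 1, w)
    sprintf(paste0("%-", w, "s"), s)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s) writeChar(s, con, nchars = nchar(s, type = "bytes"),
                                 eos = NULL, useBytes = TRUE)
  header_bytes <- 256L + 256L * ns
  wchar(pad("0", 8)); wchar(pad("X", 80)); wchar(pad("synthetic", 80))
  wchar(pad("01.01.00", 8)); wchar(pad("00.00.00", 8))
  wchar(pad(header_bytes, 8)); wchar(pad("", 44))
  wchar(pad(n_records, 8)); wchar(pad(record_duration, 8)); wchar(pad(ns, 4))
  wchar(paste0(vapply(channel_names, pad, character(1), w = 16), collapse = ""))
  wchar(strrep(pad("", 80), ns))
  wchar(strrep(pad("uV", 8), ns))
  wchar(paste0(pad(phys_min_s, 8), collapse = ""))
  wchar(paste0(pad(phys_max_s, 8), collapse = ""))
  wchar(paste0(pad(dig_min, 8), collapse = ""))
  wchar(paste0(pad(dig_max, 8), collapse = ""))
  wchar(strrep(pad("", 80), ns))
  wchar(paste0(pad(n_samp, 8), collapse = ""))
  wchar(strrep(pad("", 32), ns))
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (si in seq_len(ns)) {
      seg <- x[si, ((r - 1) * sampling_rate + 1):(r * sampling_rate)]
      dig <- as.integer(round((seg - phys_min[si]) / scale[si] + dig_min[si]))
      dig <- pmin(32767L, pmax(-32768L, dig))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}
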