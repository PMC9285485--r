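#' Read an EDF/EDF+ file into a recording
#'
#' Parses the fixed 256-byte EDF header plus per-signal headers, reads the
#' 16-bit little-endian data records and rescales to physical units (uV).
#' All selected channels must share one sampling rate; annotation channels
#' (`"EDF Annotations"`) are always dropped.
#'
#' @param path path to an EDF/EDF+ file.
#' @param channels optional character vector of channel labels to keep
#'   (exact match after trimming); default keeps all ordinary signals.
#' @return A [recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd_num <- function(n) as.numeric(rd_str(n))

  rd_str(8)                       # version
  rd_str(80); rd_str(80)          # patient / recording id
  rd_str(8); rd_str(8)            # start date / time
  header_bytes <- rd_num(8)
  rd_str(44)                      # reserved
  n_records <- rd_num(8)
  record_dur <- rd_num(8)
  ns <- as.integer(rd_num(4))
  if (!is.finite(ns) || ns < 1L) stop("not a valid EDF file: ", path)

  fld <- function(w) vapply(seq_len(ns), function(i) rd_str(w), "")
  labels <- fld(16)
  fld(80); fld(8)                 # transducer, physical dimension
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)                         # prefiltering
  spr <- as.integer(fld(8))       # samples per record
  fld(32)                         # reserved
  stopifnot(header_bytes == 256L * (ns + 1L))

  keep <- labels != "EDF Annotations"
  if (!is.null(channels)) keep <- keep & labels %in% channels
  if (!any(keep)) stop("no matching channels in ", path)
  if (length(unique(spr[keep])) != 1L) {
    stop("selected channels have mixed sampling rates")
  }
  fs <- spr[keep][1L] / record_dur

  raw <- readBin(con, "integer", n = n_records * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_records * sum(spr)) stop("truncated EDF data")

  idx_keep <- which(keep)
  data <- matrix(0, nrow = length(idx_keep), ncol = n_records * spr[idx_keep[1L]])
  offs <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  for (j in seq_along(idx_keep)) {
    ch <- idx_keep[j]
    pos <- outer(offs[ch] + seq_len(spr[ch]), (seq_len(n_records) - 1L) * per_rec, "+")
    gain <- (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
    data[j, ] <- (raw[as.vector(pos)] - dmin[ch]) * gain + pmin[ch]
  }
  recording(data, fs, labels[idx_keep])
}

#' Write a recording to an EDF file
#'
#' Serializes a [recording()] as plain EDF with 1-s data records and a
#' configurable physical range (default +/-1000 uV, wide enough for
#' >150 uV artefacts without clipping).  Samples are quantized to the
#' 16-bit digital range; the number of samples must be a whole number of
#' seconds so that records are complete.
#'
#' @param rec a [recording()]; `n_samples(rec)` must be divisible by
#'   `rec$fs` and `fs` must be a whole number.
#' @param path output file path.
#' @param physical_range numeric length-2: physical min and max in uV.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, physical_range = c(-1000, 1000)) {
  fs <- rec$fs
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  if (n_samples(rec) %% fs != 0) {
    stop("write_edf requires a whole number of seconds of data")
  }
  n_records <- n_samples(rec) %/% fs
  ns <- n_channels(rec)
  pmin <- physical_range[1L]; pmax <- physical_range[2L]
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) {
    s <- formatC(as.character(x), width = -w)
    s <- substr(s, 1L, w)
    writeChar(paste(s, collapse = ""), con, nchars = w * length(x), eos = NULL)
  }
  wr("0", 8)
  wr("synthetic", 80); wr("synthetic neonatal EEG", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256L * (ns + 1L), 8)
  wr("", 44)
  wr(n_records, 8)
  wr("1", 8)
  wr(ns, 4)
  wr(rec$channel_names, 16)
  wr(rep("", ns), 80)
  wr(rep("uV", ns), 8)
  wr(rep(pmin, ns), 8)
  wr(rep(pmax, ns), 8)
  wr(rep(dmin, ns), 8)
  wr(rep(dmax, ns), 8)
  wr(rep("", ns), 80)
  wr(rep(as.integer(fs), ns), 8)
  wr(rep("", ns), 32)

  gain <- (pmax - pmin) / (dmax - dmin)
  dig <- round((rec$data - pmin) / gain) + dmin
  dig[dig < dmin] <- dmin; dig[dig > dmax] <- dmax
  # interleave: per record, all samples of signal 1, then signal 2, ...
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}
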