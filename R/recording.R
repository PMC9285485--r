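#' Multichannel EEG recording
#'
#' A `recording` holds a channels-by-samples matrix of EEG amplitudes in
#' microvolts together with its sampling rate and channel labels.  Time is
#' measured in seconds from the start of the acquisition; sample `i`
#' (1-based) covers the half-open interval `[(i-1)/fs, i/fs)`.
#'
#' @param data numeric matrix, channels in rows, samples in columns, in uV.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector of channel labels, one per row of
#'   `data`.  Defaults to `"Ch1"`, `"Ch2"`, ...
#'
#' @return An object of class `recording`: a list with elements `data`,
#'   `fs` and `channel_names`.
#' @examples
#' rec <- recording(matrix(rnorm(500), nrow = 2), fs = 250)
#' rec_duration(rec)
#' @export
recording <- function(data, fs, channel_names = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), is.numeric(data))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("'fs' must be a positive scalar sampling rate in Hz")
  }
  if (any(!is.finite(data))) {
    stop("recording contains non-finite samples (NaN/Inf)")
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("Ch", seq_len(nrow(data)))
  }
  if (length(channel_names) != nrow(data)) {
    stop("length of 'channel_names' must equal the number of channels (rows)")
  }
  structure(
    list(data = data, fs = as.numeric(fs),
         channel_names = as.character(channel_names)),
    class = "recording"
  )
}

#' @rdname recording
#' @param x a `recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname recording
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname recording
#' @export
rec_duration <- function(x) ncol(x$data) / x$fs

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              n_channels(x), n_samples(x), x$fs, rec_duration(x)))
  cat("  channels:", paste(utils::head(x$channel_names, 8), collapse = ", "),
      if (n_channels(x) > 8) "..." else "", "\n")
  invisible(x)
}
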