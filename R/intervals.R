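#' Labelled time-interval sets
#'
#' An `interval_set` is a data frame with columns `start_s`, `end_s` and
#' `label`, holding half-open intervals `[start_s, end_s)` in seconds.
#' Intervals are kept sorted by onset and intervals sharing a label are
#' pairwise disjoint: overlapping or touching same-label intervals are
#' merged on construction.  Labels are restricted to `"flatline"`,
#' `"large_amplitude"` and `"other"`.
#'
#' @param start_s,end_s numeric vectors of onsets and offsets in seconds;
#'   every `end_s` must exceed its `start_s`.
#' @param label character vector (recycled) of interval labels.
#'
#' @return A data frame of class `interval_set`.
#' @examples
#' interval_set(c(10, 12), c(15, 18), "large_amplitude")  # merges to [10,18)
#' @export
interval_set <- function(start_s = numeric(), end_s = numeric(),
                         label = character()) {
  if (length(start_s) == 0L) {
    out <- data.frame(start_s = numeric(), end_s = numeric(),
                      label = character(), stringsAsFactors = FALSE)
    class(out) <- c("interval_set", "data.frame")
    return(out)
  }
  if (length(label) == 0L) label <- "other"
  label <- rep_len(as.character(label), length(start_s))
  stopifnot(length(end_s) == length(start_s))
  if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
    stop("interval bounds must be finite")
  }
  if (any(end_s <= start_s)) stop("every end_s must be > start_s")
  bad <- setdiff(unique(label), c("flatline", "large_amplitude", "other"))
  if (length(bad)) {
    stop("unknown interval label(s): ", paste(bad, collapse = ", "))
  }
  pieces <- lapply(split(seq_along(start_s), label), function(idx) {
    merge_touching(start_s[idx], end_s[idx], label[idx[1L]])
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$start_s, out$end_s), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interval_set", "data.frame")
  out
}

# merge overlapping or touching intervals of one label
merge_touching <- function(start_s, end_s, label) {
  o <- order(start_s, end_s)
  start_s <- start_s[o]; end_s <- end_s[o]
  ms <- start_s[1L]; me <- end_s[1L]
  outs <- numeric(); oute <- numeric()
  for (i in seq_along(start_s)[-1L]) {
    if (start_s[i] <= me) {
      me <- max(me, end_s[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start_s[i]; me <- end_s[i]
    }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  data.frame(start_s = outs, end_s = oute, label = label,
             stringsAsFactors = FALSE)
}

#' @rdname interval_set
#' @export
empty_interval_set <- function() interval_set()

#' @rdname interval_set
#' @param x an `interval_set`.
#' @export
is_interval_set <- function(x) inherits(x, "interval_set")

#' Clip an interval set to a recording duration
#'
#' Intersects every interval with `[0, duration_s)`; intervals falling
#' entirely outside are dropped.
#'
#' @param intervals an [interval_set()].
#' @param duration_s recording duration in seconds.
#' @return A clipped `interval_set`.
#' @export
clip_intervals <- function(intervals, duration_s) {
  if (nrow(intervals) == 0L) return(intervals)
  s <- pmax(intervals$start_s, 0)
  e <- pmin(intervals$end_s, duration_s)
  keep <- e > s
  interval_set(s[keep], e[keep], intervals$label[keep])
}

#' Merge intervals separated by at most a given gap
#'
#' Same-label intervals whose separation is less than or equal to `gap_s`
#' seconds (inclusive) are fused into one interval, as done when combining
#' selected artefact segments into removal intervals.
#'
#' @param intervals an [interval_set()].
#' @param gap_s maximal gap, in seconds, that is still bridged.
#' @return An `interval_set` with gaps of at most `gap_s` closed.
#' @examples
#' iv <- interval_set(c(0, 9), c(3, 12), "large_amplitude")
#' merge_within_gap(iv, 6)   # one interval [0, 12)
#' @export
merge_within_gap <- function(intervals, gap_s) {
  stopifnot(gap_s >= 0)
  if (nrow(intervals) <= 1L) return(intervals)
  pieces <- lapply(split(intervals, intervals$label), function(d) {
    d <- d[order(d$start_s), , drop = FALSE]
    # widen by gap/2 on each side, merge touching, then shrink back
    m <- merge_touching(d$start_s, d$end_s + gap_s, d$label[1L])
    m$end_s <- m$end_s - gap_s
    m
  })
  out <- do.call(rbind, pieces)
  interval_set(out$start_s, out$end_s, out$label)
}

#' Convert intervals to a per-sample logical mask
#'
#' Sample `i` (1-based) is `TRUE` iff its time `(i-1)/fs` lies inside some
#' interval, using the half-open `[start_s, end_s)` convention.  Intervals
#' are clipped to the mask extent.
#'
#' @param intervals an [interval_set()].
#' @param fs sampling rate in Hz.
#' @param n_samples mask length.
#' @return Logical vector of length `n_samples`.
#' @export
intervals_to_mask <- function(intervals, fs, n_samples) {
  stopifnot(n_samples >= 0, fs > 0)
  mask <- logical(n_samples)
  if (nrow(intervals) == 0L || n_samples == 0L) return(mask)
  eps <- 1e-9
  for (k in seq_len(nrow(intervals))) {
    i0 <- ceiling(intervals$start_s[k] * fs - eps) + 1      # first sample in
    i1 <- ceiling(intervals$end_s[k] * fs - eps)            # last sample in
    i0 <- max(i0, 1L); i1 <- min(i1, n_samples)
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  mask
}

#' Convert a logical mask to intervals
#'
#' Maximal runs of `TRUE` samples become intervals on the sample grid:
#' a run spanning samples `i..j` (1-based) becomes `[(i-1)/fs, j/fs)`.
#' Inverse of [intervals_to_mask()] for grid-aligned disjoint sets.
#'
#' @param mask logical vector.
#' @param fs sampling rate in Hz.
#' @param label label given to all produced intervals.
#' @return An [interval_set()].
#' @export
mask_to_intervals <- function(mask, fs, label = "other") {
  stopifnot(is.logical(mask), fs > 0)
  if (!any(mask)) return(empty_interval_set())
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  interval_set((starts[keep] - 1L) / fs, ends[keep] / fs, label)
}

#' Remove artefact intervals from a recording
#'
#' Cuts the union of `intervals` out of the recording and returns the
#' maximal clean sub-recordings, each carrying its original onset in the
#' attribute `onset_s`, plus the kept intervals.  Time is conserved: kept
#' plus removed durations sum to the recording duration on the sample grid.
#'
#' @param rec a [recording()].
#' @param intervals an [interval_set()] of segments to remove.
#' @return A list with `segments` (list of `recording`s) and `kept`
#'   (an `interval_set` of the retained stretches, labelled `"other"`).
#' @export
apply_removal <- function(rec, intervals) {
  mask <- intervals_to_mask(intervals, rec$fs, n_samples(rec))
  kept <- mask_to_intervals(!mask, rec$fs, "other")
  segments <- lapply(seq_len(nrow(kept)), function(k) {
    i0 <- round(kept$start_s[k] * rec$fs) + 1L
    i1 <- round(kept$end_s[k] * rec$fs)
    seg <- recording(rec$data[, i0:i1, drop = FALSE], rec$fs,
                     rec$channel_names)
    attr(seg, "onset_s") <- kept$start_s[k]
    seg
  })
  list(segments = segments, kept = kept)
}

#' Read and write artefact annotation tables
#'
#' Annotations are plain CSV with header `onset_s,duration_s,label`.
#' On reading, overlapping same-label rows are merged; rows with labels
#' other than `flatline`/`large_amplitude`/`other` are kept as `"other"`
#' with a warning; negative durations are an error.  A write/read round
#' trip reproduces the set to within 1e-9 s.
#'
#' @param path CSV file path.
#' @return `read_annotations` returns an [interval_set()].
#' @export
read_annotations <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(tab))) {
    stop("annotation CSV must have columns onset_s, duration_s, label")
  }
  if (nrow(tab) == 0L) return(empty_interval_set())
  if (any(tab$duration_s < 0)) stop("negative duration in annotation file")
  known <- c("flatline", "large_amplitude", "other")
  if (any(!tab$label %in% known)) {
    warning("unknown annotation label(s) kept as 'other': ",
            paste(unique(tab$label[!tab$label %in% known]), collapse = ", "))
    tab$label[!tab$label %in% known] <- "other"
  }
  tab <- tab[tab$duration_s > 0, , drop = FALSE]
  interval_set(tab$onset_s, tab$onset_s + tab$duration_s, tab$label)
}

#' @rdname read_annotations
#' @param intervals an [interval_set()] to serialize.
#' @export
write_annotations <- function(intervals, path) {
  tab <- data.frame(onset_s = intervals$start_s,
                    duration_s = intervals$end_s - intervals$start_s,
                    label = intervals$label)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_annotations
#' @export
write_intervals_json <- function(intervals, path) {
  lst <- lapply(seq_len(nrow(intervals)), function(k) {
    list(start_s = intervals$start_s[k], end_s = intervals$end_s[k],
         label = intervals$label[k])
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
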