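#' Detector configuration
#'
#' Collects every threshold and duration of the artefact detector, with
#' defaults tuned for term-equivalent-age neonatal EEG at 250-256 Hz.
#'
#' Flat-line parameters: `flat_threshold` (uV) bounds the absolute second
#' difference below which a sample counts as flat; at least
#' `flat_min_flags_per_second` such samples within a 1-s bin are required;
#' flagged samples at most `flat_group_gap_s` apart are grouped; a grouped
#' interval is accepted when at least `round(consensus_fraction * C)` of the
#' `C` channels contain it (14/19 and 7/9 at the default 0.75); accepted
#' intervals are padded by `pad_short_s` or `pad_long_s` on each side
#' depending on whether they are at most, or longer than, `pad_cutoff_s`.
#'
#' Large-amplitude parameters: windows of `window_s` seconds (1-7 s
#' admissible, 3 s recommended); `pt100`/`pt150` are the physiological
#' amplitude thresholds in uV; `mafd_mult` and `rfc_mult` scale the
#' channel-specific `median + MAD` thresholds of the first-difference and
#' high-frequency-ratio criteria; `rfc_cut_hz` is the spectral split point;
#' selected intervals closer than `merge_gap_s` are fused.
#'
#' @param flat_threshold,flat_min_flags_per_second,flat_group_gap_s,consensus_fraction,pad_short_s,pad_long_s,pad_cutoff_s
#'   flat-line detector parameters (see Details).
#' @param window_s,pt100,pt150,mafd_mult,rfc_mult,rfc_cut_hz,merge_gap_s
#'   large-amplitude detector parameters (see Details).
#' @param notch_hz,bandpass_hz pre-processing: notch frequency and band-pass
#'   edges in Hz.
#' @param criteria logical length-4 vector enabling removal criteria 1-4.
#' @param detect_flat,detect_large enable either detector in the pipeline.
#' @return A validated list of class `detector_config`.
#' @export
detector_config <- function(flat_threshold = 1e-4,
                            flat_min_flags_per_second = 2,
                            flat_group_gap_s = 2.5,
                            consensus_fraction = 0.75,
                            pad_short_s = 1,
                            pad_long_s = 3,
                            pad_cutoff_s = 5,
                            window_s = 3,
                            pt100 = 100,
                            pt150 = 150,
                            mafd_mult = 4.5,
                            rfc_mult = 1.5,
                            rfc_cut_hz = 50,
                            merge_gap_s = 6,
                            notch_hz = 50,
                            bandpass_hz = c(0.5, 40),
                            criteria = c(TRUE, TRUE, TRUE, TRUE),
                            detect_flat = TRUE,
                            detect_large = TRUE) {
  cfg <- list(flat_threshold = flat_threshold,
              flat_min_flags_per_second = flat_min_flags_per_second,
              flat_group_gap_s = flat_group_gap_s,
              consensus_fraction = consensus_fraction,
              pad_short_s = pad_short_s, pad_long_s = pad_long_s,
              pad_cutoff_s = pad_cutoff_s, window_s = window_s,
              pt100 = pt100, pt150 = pt150, mafd_mult = mafd_mult,
              rfc_mult = rfc_mult, rfc_cut_hz = rfc_cut_hz,
              merge_gap_s = merge_gap_s, notch_hz = notch_hz,
              bandpass_hz = bandpass_hz, criteria = criteria,
              detect_flat = detect_flat, detect_large = detect_large)
  validate_config(cfg)
  class(cfg) <- "detector_config"
  cfg
}

validate_config <- function(cfg) {
  bad <- character()
  chk <- function(ok, keys) if (!isTRUE(ok)) bad <<- c(bad, keys)
  chk(cfg$flat_threshold > 0, "flat_threshold")
  chk(cfg$flat_min_flags_per_second >= 1, "flat_min_flags_per_second")
  chk(cfg$flat_group_gap_s >= 0, "flat_group_gap_s")
  chk(cfg$consensus_fraction > 0 && cfg$consensus_fraction <= 1,
      "consensus_fraction")
  chk(cfg$pad_short_s >= 0, "pad_short_s")
  chk(cfg$pad_long_s >= 0, "pad_long_s")
  chk(cfg$pad_cutoff_s >= 0, "pad_cutoff_s")
  chk(cfg$window_s > 0, "window_s")
  chk(cfg$pt100 < cfg$pt150, c("pt100", "pt150"))
  chk(cfg$merge_gap_s >= 0, "merge_gap_s")
  chk(cfg$notch_hz > 0, "notch_hz")
  chk(length(cfg$bandpass_hz) == 2 && cfg$bandpass_hz[1] > 0 &&
        cfg$bandpass_hz[1] < cfg$bandpass_hz[2], "bandpass_hz")
  chk(is.logical(cfg$criteria) && length(cfg$criteria) == 4, "criteria")
  if (length(bad)) {
    stop("invalid detector configuration, offending key(s): ",
         paste(unique(bad), collapse = ", "))
  }
  invisible(cfg)
}

#' Load a detector configuration from YAML or JSON
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [detector_config()].  An empty file yields the full default
#' configuration.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `detector_config`.
#' @export
load_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(detector_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(detector_config, vals)
}

#' @rdname load_config
#' @param cfg a `detector_config` to serialize.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
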