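# Response-pattern classification of GnRH responders.

#' Classify a responder's GnRH-evoked calcium pattern
#'
#' Deterministic decision rules over the GnRH response window, mirroring the
#' visual classes seen in gonadotrophs:
#'
#' 1. **oscillatory** — at least `min_peaks` detected transients whose median
#'    inter-peak trough drops below `trough_frac` x the maximum amplitude
#'    (spikes returning toward baseline between peaks);
#' 2. **biphasic** — otherwise, if dF/F - 1 stays at or above
#'    `plateau_frac` x the maximum amplitude for at least `plateau_s`
#'    contiguous seconds after the first peak (initial peak followed by a
#'    sustained plateau);
#' 3. **transitory** — otherwise (a single short low-amplitude transient).
#'
#' A trace meeting both the oscillatory and biphasic criteria is oscillatory:
#' troughs returning toward baseline are the defining oscillatory feature.
#'
#' @param dff Numeric dF/F trace of a GnRH responder.
#' @param protocol The recording's `stim_protocol`.
#' @param params Optional list overriding thresholds: `min_peaks` (2),
#'   `trough_frac` (0.5), `plateau_frac` (0.3), `plateau_s` (30).
#' @param theta_amp,min_prominence,min_separation Passed to
#'   [detect_transients()].
#' @return A list of class `pattern_label`: `pattern`, `long_lasting`, and
#'   `features` (`n_peaks`, `plateau_time` s, `trough_ratio`,
#'   `max_amplitude`).
#' @examples
#' rec <- synth_recording("control", 30, seed = 1)
#' norm <- preprocess(rec)
#' classify_pattern(norm$dff[, 1], norm$protocol)
#' @export
classify_pattern <- function(dff, protocol, params = list(),
                             theta_amp = 0.10, min_prominence = 0.05,
                             min_separation = 1) {
  p <- utils::modifyList(list(min_peaks = 2, trough_frac = 0.5,
                              plateau_frac = 0.3, plateau_s = 30), params)
  rw <- response_window(protocol)
  if (!is_gnrh_responder(dff, protocol, theta_resp = theta_amp))
    stop("classify_pattern() requires a GnRH responder", call. = FALSE)
  idx <- window_frames(protocol, rw)
  x <- dff[idx] - 1
  tt <- protocol_time(protocol)[idx]
  max_amp <- max(x)
  ev <- detect_transients(dff, protocol, rw, theta_amp, min_prominence,
                          min_separation)
  n_peaks <- nrow(ev)
  trough_ratio <- NA_real_
  if (n_peaks >= 2) {
    troughs <- vapply(seq_len(n_peaks - 1), function(i) {
      seg <- x[tt >= ev$peak_time[i] & tt <= ev$peak_time[i + 1]]
      min(seg)
    }, 0)
    trough_ratio <- stats::median(troughs) / max_amp
  }
  # longest contiguous run at/above plateau_frac * max after the first peak
  plateau_time <- 0
  if (n_peaks >= 1) {
    post <- x[tt >= ev$peak_time[1]]
    above <- post >= p$plateau_frac * max_amp
    r <- rle(above)
    runs <- r$lengths[r$values]
    if (length(runs)) plateau_time <- max(runs) * protocol$dt
  }
  pattern <- if (n_peaks >= p$min_peaks && !is.na(trough_ratio) &&
                 trough_ratio < p$trough_frac) {
    "oscillatory"
  } else if (plateau_time >= p$plateau_s) {
    "biphasic"
  } else {
    "transitory"
  }
  ll <- flag_long_lasting(dff, protocol, theta_amp = theta_amp,
                          min_prominence = min_prominence,
                          min_separation = min_separation)
  # a single transient cannot carry oscillations past the pulse
  if (pattern == "transitory") ll <- FALSE
  structure(list(pattern = pattern, long_lasting = ll,
                 features = list(n_peaks = n_peaks,
                                 plateau_time = plateau_time,
                                 trough_ratio = trough_ratio,
                                 max_amplitude = max_amp)),
            class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat("<pattern_label> ", x$pattern,
      if (isTRUE(x$long_lasting)) " (long-lasting)", "\n", sep = "")
  invisible(x)
}

#' Flag long-lasting oscillatory activity
#'
#' Long-lasting cells keep oscillating well past the GnRH pulse, into washout
#' and the high-potassium window. The flag is true if any transient is
#' detected later than `late_s` seconds after GnRH offset (but before KCl
#' onset, whose own depolarization response must not count), or if at least
#' two transients fall inside the KCl window — a single KCl peak is the
#' normal depolarization response, repeated spiking there is the hallmark of
#' long-lasting cells.
#'
#' @inheritParams classify_pattern
#' @param late_s Latency threshold after GnRH offset, seconds (default 120).
#' @return Logical flag.
#' @export
flag_long_lasting <- function(dff, protocol, late_s = 120,
                              theta_amp = 0.10, min_prominence = 0.05,
                              min_separation = 1) {
  late_win <- c(protocol$gnrh[2] + late_s, protocol$kcl[1])
  late <- if (late_win[2] > late_win[1]) {
    nrow(detect_transients(dff, protocol, late_win, theta_amp,
                           min_prominence, min_separation))
  } else 0
  kcl_n <- nrow(detect_transients(dff, protocol,
                                  c(protocol$kcl[1], protocol$kcl[2]),
                                  theta_amp, min_prominence, min_separation))
  late >= 1 || kcl_n >= 2
}
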