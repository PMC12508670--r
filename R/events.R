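# Transient detection and per-cell response metrics.

#' Detect calcium transients in a dF/F trace
#'
#' Finds local maxima inside a time window whose height above the dF/F floor
#' (`value - 1`) reaches `theta_amp`, whose topographic prominence reaches
#' `min_prominence`, and which are separated by at least `min_separation`
#' seconds (when two candidate peaks are closer, the smaller is dropped).
#' Prominence is the height of a peak above the higher of the two deepest
#' troughs separating it from larger peaks (or the window edge).
#'
#' @param dff Numeric dF/F trace (floor 1).
#' @param protocol The recording's `stim_protocol`.
#' @param window Numeric `c(t0, t1)` in seconds; the epoch searched.
#' @param theta_amp Amplitude threshold on dF/F - 1 (default 0.10, the
#'   10%-of-Fmin criterion).
#' @param min_prominence Minimum peak prominence (default 0.05).
#' @param min_separation Minimum peak separation in seconds (default 1).
#' @return A tibble of events: `peak_time` (s), `amplitude` (dF/F - 1),
#'   `prominence`, `width` (s at half-prominence), ordered by time.
#' @examples
#' p <- make_protocol()
#' cell <- synth_cell(default_group_params("control"),
#'                    list(pattern = "oscillatory", n_spikes_true = 5),
#'                    p, noise_sd = 0, bleach_rate = 0)
#' detect_transients(normalize_dff(cell$F), p, response_window(p))
#' @export
detect_transients <- function(dff, protocol, window,
                              theta_amp = 0.10, min_prominence = 0.05,
                              min_separation = 1) {
  idx <- window_frames(protocol, window)
  if (!length(idx)) stop("empty detection window", call. = FALSE)
  x <- dff[idx]
  tt <- protocol_time(protocol)[idx]
  n <- length(x)
  empty <- tibble::tibble(peak_time = numeric(), amplitude = numeric(),
                          prominence = numeric(), width = numeric())
  if (n < 3) return(empty)
  # strict local maxima; plateaus take their first frame
  is_pk <- which(diff(sign(diff(x))) < 0) + 1L
  is_pk <- is_pk[x[is_pk] - 1 >= theta_amp]
  if (!length(is_pk)) return(empty)
  prom <- vapply(is_pk, function(p) {
    h <- x[p]
    left <- x[seq_len(p - 1)]
    hi_l <- which(left > h)
    sad_l <- if (length(hi_l)) min(x[(max(hi_l) + 1):(p - 1)]) else min(left)
    right <- x[(p + 1):n]
    hi_r <- which(right > h)
    sad_r <- if (length(hi_r)) min(right[seq_len(min(hi_r) - 1)]) else min(right)
    h - max(sad_l, sad_r)
  }, 0)
  keep <- prom >= min_prominence
  pk <- is_pk[keep]; prom <- prom[keep]
  if (!length(pk)) return(empty)
  # enforce separation: greedy from the tallest peak down
  ord <- order(x[pk], decreasing = TRUE)
  sel <- logical(length(pk))
  for (i in ord) {
    if (!any(sel & abs(tt[pk] - tt[pk[i]]) < min_separation)) sel[i] <- TRUE
  }
  pk <- pk[sel]; prom <- prom[sel]
  o <- order(pk)
  pk <- pk[o]; prom <- prom[o]
  width <- vapply(seq_along(pk), function(i) {
    half <- x[pk[i]] - prom[i] / 2
    l <- pk[i]; while (l > 1 && x[l] > half) l <- l - 1
    r <- pk[i]; while (r < n && x[r] > half) r <- r + 1
    (r - l) * protocol$dt
  }, 0)
  tibble::tibble(peak_time = tt[pk], amplitude = x[pk] - 1,
                 prominence = prom, width = width)
}

#' Is a cell spontaneously active?
#'
#' A cell is scored spontaneously active if it shows at least one calcium
#' transient greater than 10% of Fmin (dF/F - 1 > `theta_amp`) within the
#' first 4 minutes of the pre-stimulus baseline. If the baseline is shorter
#' than 240 s the available epoch is used with a warning.
#'
#' @inheritParams detect_transients
#' @param theta_amp Amplitude criterion (default 0.10).
#' @return Logical flag.
#' @export
is_spontaneously_active <- function(dff, protocol, theta_amp = 0.10) {
  win <- c(protocol$baseline[1], min(protocol$baseline[2],
                                     protocol$baseline[1] + 240))
  if (diff(protocol$baseline) < 240 - 1e-9)
    warning("baseline epoch is ", diff(protocol$baseline),
            " s (< 240 s); scoring spontaneous activity on the available epoch",
            call. = FALSE)
  if (diff(win) <= 0) return(FALSE)
  ev <- detect_transients(dff, protocol, win, theta_amp = theta_amp)
  nrow(ev) >= 1
}

#' Does a cell respond to GnRH?
#'
#' A cell is a GnRH responder — operationally, a gonadotroph — if its dF/F
#' exceeds `1 + theta_resp` anywhere between GnRH onset and 10 s before KCl
#' onset.
#'
#' @inheritParams detect_transients
#' @param theta_resp Response threshold on dF/F - 1 (default 0.10).
#' @return Logical flag.
#' @export
is_gnrh_responder <- function(dff, protocol, theta_resp = 0.10) {
  win <- c(protocol$gnrh[1], protocol$kcl[1] - 10)
  idx <- window_frames(protocol, win)
  max(dff[idx]) - 1 >= theta_resp
}

#' Count oscillations in an event set
#'
#' @param events An event tibble from [detect_transients()].
#' @return Integer event count.
#' @export
count_oscillations <- function(events) {
  nrow(events)
}

#' Maximal intensity of fluorescence (MIF)
#'
#' The peak dF/F inside the window — the standard proxy for the magnitude of
#' calcium mobilization.
#'
#' @inheritParams detect_transients
#' @return Numeric scalar (dF/F units, >= 1).
#' @export
compute_mif <- function(dff, protocol, window = response_window(protocol)) {
  idx <- window_frames(protocol, window)
  max(dff[idx])
}

#' Area under the dF/F curve (AUC)
#'
#' Trapezoidal integral of `max(dF/F - 1, 0)` over the closed window
#' `[t0, t1]`, in (dF/F - 1) x seconds, reported as arbitrary units. The
#' baseline is the dF/F floor of 1 implied by F/Fmin normalization. Using the
#' closed interval makes AUC exactly additive over abutting windows.
#'
#' @inheritParams detect_transients
#' @return Numeric scalar >= 0.
#' @export
compute_auc <- function(dff, protocol, window = response_window(protocol)) {
  tt <- protocol_time(protocol)
  idx <- which(tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9)
  y <- pmax(dff[idx] - 1, 0)
  if (length(y) < 2) return(0)
  sum((y[-1] + y[-length(y)]) / 2) * protocol$dt
}

#' Per-cell metrics, flags, and pattern labels for a recording
#'
#' Runs the full per-cell analysis on a preprocessed recording: spontaneous
#' activity (10%-of-Fmin / 4-min criterion), GnRH responder status, response
#' pattern classification (responders only), long-lasting flag, MIF, AUC, and
#' oscillation count (over the extended window for long-lasting cells).
#'
#' @param normalized A `ca_normalized` object from [preprocess()].
#' @param theta_resp,theta_amp,min_prominence,min_separation Detection
#'   thresholds; see [detect_transients()] and [is_gnrh_responder()].
#' @param classify_params Threshold list for [classify_pattern()].
#' @return A tibble with one row per retained ROI: `animal_id`, `group`,
#'   `cell_id`, `responder`, `spontaneous`, `pattern`, `long_lasting`,
#'   `mif`, `auc`, `n_oscillations` (NA for non-responders).
#' @examples
#' rec <- synth_recording("control", 30, seed = 1)
#' cell_metrics(preprocess(rec))
#' @export
cell_metrics <- function(normalized,
                         theta_resp = 0.10, theta_amp = 0.10,
                         min_prominence = 0.05, min_separation = 1,
                         classify_params = list()) {
  stopifnot(inherits(normalized, "ca_normalized"))
  proto <- normalized$protocol
  rw <- response_window(proto)
  purrr::map_dfr(seq_along(normalized$roi_ids), function(j) {
    x <- normalized$dff[, j]
    responder <- is_gnrh_responder(x, proto, theta_resp)
    spont <- is_spontaneously_active(x, proto, theta_amp)
    pattern <- NA_character_
    long_lasting <- NA
    n_osc <- NA_integer_
    mif <- NA_real_
    auc <- NA_real_
    if (responder) {
      lab <- classify_pattern(x, proto, params = classify_params,
                              theta_amp = theta_amp,
                              min_prominence = min_prominence,
                              min_separation = min_separation)
      pattern <- lab$pattern
      long_lasting <- lab$long_lasting
      count_win <- response_window(proto, extended = long_lasting)
      ev <- detect_transients(x, proto, count_win, theta_amp,
                              min_prominence, min_separation)
      n_osc <- count_oscillations(ev)
      mif <- compute_mif(x, proto, rw)
      auc <- compute_auc(x, proto, rw)
    }
    tibble::tibble(
      animal_id = normalized$animal_id %||% NA_character_,
      group = normalized$group %||% NA_character_,
      cell_id = normalized$roi_ids[j],
      responder = responder, spontaneous = spont,
      pattern = pattern, long_lasting = long_lasting,
      mif = mif, auc = auc, n_oscillations = n_osc
    )
  })
}
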