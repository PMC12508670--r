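# Preprocessing: photobleaching detrend, dF/F normalization, viability gating.

#' Correct a fluorescence trace for photobleaching
#'
#' Fits a single-exponential decay to the trace's sub-event baseline and
#' divides it out, rescaling to the fit's initial value so an event-free trace
#' is returned flat at its starting level. The baseline is estimated as the
#' 10th percentile of consecutive 20 s blocks restricted to the pre-stimulus
#' epoch (calcium transients only push fluorescence up, so a low percentile
#' tracks the bleaching envelope through sparse activity). The exponential is
#' fitted as a linear model on the log scale; if that fails (non-positive
#' baseline values) a linear fit on the raw scale is used with a warning.
#'
#' @param trace Numeric fluorescence trace (one ROI), length >= 100 frames.
#' @param protocol The recording's `stim_protocol`.
#' @param block_s Baseline block length in seconds (default 20).
#' @param prob Baseline percentile (default 0.10).
#' @return Numeric detrended trace, same length.
#' @examples
#' p <- make_protocol()
#' f <- 100 * exp(-5e-4 * protocol_time(p))
#' range(detrend_bleach(f, p))  # constant 100
#' @export
detrend_bleach <- function(trace, protocol, block_s = 20, prob = 0.10) {
  validate_protocol(protocol)
  if (length(trace) < 100)
    stop("trace too short to detrend (< 100 frames)", call. = FALSE)
  idx <- window_frames(protocol, protocol$baseline)
  if (length(idx) < 10) idx <- seq_len(min(length(trace), 500))
  tt <- protocol_time(protocol)[idx]
  block <- floor((tt - tt[1]) / block_s)
  qs <- tapply(trace[idx], block, stats::quantile, probs = prob, names = FALSE)
  tc <- tapply(tt, block, mean)
  full_t <- protocol_time(protocol)
  fit_ok <- all(qs > 0)
  if (fit_ok) {
    co <- stats::coef(stats::lm(log(qs) ~ tc))
    curve <- exp(co[1] + co[2] * full_t)
    c0 <- exp(co[1])
  } else {
    warning("non-positive baseline; falling back to linear detrend",
            call. = FALSE)
    co <- stats::coef(stats::lm(qs ~ tc))
    curve <- co[1] + co[2] * full_t
    c0 <- co[1]
  }
  trace / curve * c0
}

#' Normalize a trace to dF/F = F / Fmin
#'
#' Divides the trace by its minimum, so the output floor is exactly 1.0 and a
#' transient of amplitude `a` reads as `1 + a` (i.e. `a` x 100% of Fmin above
#' baseline). Idempotent: normalizing an already-normalized trace changes
#' nothing.
#'
#' @param trace Strictly positive numeric trace.
#' @return Numeric dF/F trace with `min(out) == 1`.
#' @examples
#' normalize_dff(c(100, 150, 100))  # 1.0 1.5 1.0
#' @export
normalize_dff <- function(trace) {
  fmin <- min(trace)
  if (!is.finite(fmin) || fmin <= 0)
    stop("cannot normalize: minimum fluorescence is not positive", call. = FALSE)
  trace / fmin
}

#' Preprocess a raw recording into viability-gated dF/F traces
#'
#' Per ROI: detrend photobleaching, light low-pass denoising (centred running
#' mean over `smooth_frames` frames), then dF/F = F/Fmin normalization with
#' Fmin taken post-detrend over the whole recording. ROIs are retained only if
#' their dF/F exceeds `1 + theta_kcl` inside the KCl window (cells that
#' respond to the terminal depolarization are alive); the retained set is the
#' 100% denominator for all population fractions. Set `gate = FALSE` for
#' calcium-free paradigms in which even viable cells cannot respond to KCl.
#'
#' @param recording A `ca_recording` (from [synth_recording()] or
#'   [read_trace_matrix()]).
#' @param theta_kcl Viability threshold on dF/F - 1 in the KCl window
#'   (default 0.10, the same 10%-of-Fmin criterion used for transients).
#' @param gate If `FALSE`, skip the viability filter and retain every ROI.
#' @param smooth_frames Width of the denoising running mean in frames
#'   (default 3, i.e. 0.6 s at 0.2 s sampling); 1 disables smoothing.
#' @param detrend If `FALSE`, skip bleaching correction.
#' @return An object of class `ca_normalized`: list with `dff` (frames x
#'   retained ROIs, per-column minimum exactly 1), `time`, `protocol`,
#'   `roi_ids`, `fmin` (per-ROI normalizer), `animal_id`, `group`, and
#'   `truth` (subset rows for retained ROIs, if the recording carried ground
#'   truth).
#' @examples
#' rec <- synth_recording("control", 20, seed = 1)
#' norm <- preprocess(rec)
#' ncol(norm$dff) <= ncol(rec$F)
#' @export
preprocess <- function(recording, theta_kcl = 0.10, gate = TRUE,
                       smooth_frames = 3, detrend = TRUE) {
  stopifnot(inherits(recording, "ca_recording"))
  proto <- recording$protocol
  Fm <- recording$F
  dff <- matrix(NA_real_, nrow = nrow(Fm), ncol = ncol(Fm))
  fmin <- numeric(ncol(Fm))
  for (j in seq_len(ncol(Fm))) {
    x <- Fm[, j]
    if (detrend) x <- detrend_bleach(x, proto)
    x <- .smooth_boxcar(x, smooth_frames)
    fmin[j] <- min(x)
    dff[, j] <- normalize_dff(x)
  }
  colnames(dff) <- colnames(Fm)
  keep <- rep(TRUE, ncol(dff))
  if (gate) {
    kidx <- window_frames(proto, proto$kcl)
    if (!length(kidx))
      stop("protocol has no KCl epoch; use gate = FALSE", call. = FALSE)
    keep <- apply(dff[kidx, , drop = FALSE], 2, max) > 1 + theta_kcl
    if (!any(keep))
      stop("no ROIs passed the KCl viability gate", call. = FALSE)
  }
  truth <- recording$truth
  if (!is.null(truth)) truth <- truth[keep, , drop = FALSE]
  structure(list(
    dff = dff[, keep, drop = FALSE],
    time = recording$time,
    protocol = proto,
    roi_ids = colnames(dff)[keep],
    fmin = fmin[keep],
    animal_id = recording$animal_id,
    group = recording$group,
    truth = truth
  ), class = "ca_normalized")
}

#' @rdname preprocess
#' @details `viability_filter()` is an alias for [preprocess()]: the KCl gate
#'   is where raw recordings become analysable populations.
#' @export
viability_filter <- preprocess

#' @export
print.ca_normalized <- function(x, ...) {
  cat("<ca_normalized> ", x$animal_id %||% "", " (", x$group %||% "?", "): ",
      ncol(x$dff), " viable ROIs x ", nrow(x$dff), " frames\n", sep = "")
  invisible(x)
}
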