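#' Build a perifusion stimulus protocol
#'
#' A protocol places the epochs of a perifusion calcium-imaging recording on a
#' shared time base: a pre-stimulus baseline used to score spontaneous
#' activity, a 30 s GnRH pulse, a washout, and a terminal 30 s high-potassium
#' (KCl) depolarization used as the cell-viability gate. Times are in seconds
#' from recording start; epochs are half-open intervals `[t0, t1)`.
#'
#' The default protocol is 480 s (2,400 frames at 0.2 s/frame): baseline
#' `[0, 240)`, GnRH `[240, 270)`, washout `[270, 440)`, KCl `[440, 470)`, with
#' a 10 s tail. The 240 s baseline is the 4-minute epoch over which basal
#' activity is scored. If `n_frames` caps the recording below the requested
#' epochs, the baseline (and, if still needed, the washout) is truncated with
#' a warning so that the GnRH and KCl pulses always fit.
#'
#' @param dt Sampling interval in seconds per frame (default 0.2).
#' @param baseline_s Baseline duration in seconds (default 240).
#' @param gnrh_s GnRH pulse duration in seconds (default 30).
#' @param washout_s Washout duration in seconds (default 170).
#' @param kcl_s High-potassium pulse duration in seconds (default 30).
#' @param tail_s Post-KCl tail in seconds (default 10).
#' @param n_frames Optional total frame count; when given it overrides the sum
#'   of the epoch durations and epochs are truncated to fit.
#' @param interventions Optional list of interventions, each a list with
#'   elements `kind` (`"nifedipine"` or `"ca_free"`) and `window = c(t0, t1)`.
#'
#' @return An object of class `stim_protocol`: a list with `dt`, `n_frames`,
#'   and epoch windows `baseline`, `gnrh`, `washout`, `kcl`, `interventions`.
#' @examples
#' p <- make_protocol()
#' diff(p$gnrh)  # 30 s pulse
#' @export
make_protocol <- function(dt = 0.2,
                          baseline_s = 240,
                          gnrh_s = 30,
                          washout_s = 170,
                          kcl_s = 30,
                          tail_s = 10,
                          n_frames = NULL,
                          interventions = list()) {
  stopifnot(dt > 0, gnrh_s > 0, kcl_s > 0, baseline_s >= 0,
            washout_s >= 0, tail_s >= 0)
  if (!is.null(n_frames)) {
    total <- n_frames * dt
    need <- baseline_s + gnrh_s + washout_s + kcl_s + tail_s
    if (need > total + 1e-9) {
      cut <- need - total
      new_base <- max(baseline_s - cut, 0)
      cut <- cut - (baseline_s - new_base)
      baseline_s <- new_base
      if (cut > 1e-9) {
        new_wash <- max(washout_s - cut, 0)
        cut <- cut - (washout_s - new_wash)
        washout_s <- new_wash
      }
      if (cut > 1e-9) {
        stop("protocol epochs (GnRH ", gnrh_s, " s + KCl ", kcl_s,
             " s + tail) do not fit in ", total, " s recording", call. = FALSE)
      }
      warning("recording is ", total, " s; baseline/washout truncated to ",
              baseline_s, "/", washout_s, " s to fit", call. = FALSE)
    }
  } else {
    n_frames <- as.integer(round((baseline_s + gnrh_s + washout_s + kcl_s + tail_s) / dt))
  }
  t0 <- 0
  baseline <- c(t0, t0 + baseline_s)
  gnrh <- c(baseline[2], baseline[2] + gnrh_s)
  washout <- c(gnrh[2], gnrh[2] + washout_s)
  kcl <- c(washout[2], washout[2] + kcl_s)
  proto <- structure(
    list(dt = dt, n_frames = as.integer(n_frames),
         baseline = baseline, gnrh = gnrh, washout = washout, kcl = kcl,
         interventions = interventions),
    class = "stim_protocol"
  )
  validate_protocol(proto)
  proto
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  eps <- 1e-9
  total <- p$dt * p$n_frames
  wins <- list(baseline = p$baseline, gnrh = p$gnrh, washout = p$washout, kcl = p$kcl)
  for (nm in names(wins)) {
    w <- wins[[nm]]
    if (length(w) != 2 || w[2] < w[1] - eps)
      stop("epoch '", nm, "' is not a valid [t0, t1) window", call. = FALSE)
    if (w[1] < -eps || w[2] > total + eps)
      stop("epoch '", nm, "' [", w[1], ", ", w[2], ") lies outside [0, ",
           total, ")", call. = FALSE)
  }
  nms <- names(wins)
  for (i in seq_along(wins)) {
    for (j in seq_along(wins)) {
      if (i >= j) next
      a <- wins[[i]]; b <- wins[[j]]
      if (a[1] < b[2] - eps && b[1] < a[2] - eps)
        stop("epochs '", nms[i], "' and '", nms[j], "' overlap", call. = FALSE)
    }
  }
  for (iv in p$interventions) {
    if (!is.list(iv) || is.null(iv$kind) || is.null(iv$window))
      stop("each intervention needs 'kind' and 'window'", call. = FALSE)
    if (!iv$kind %in% c("nifedipine", "ca_free"))
      stop("unknown intervention kind '", iv$kind,
           "'; valid kinds: nifedipine, ca_free", call. = FALSE)
    if (iv$window[1] < -eps || iv$window[2] > total + eps)
      stop("intervention window outside recording", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol> ", x$n_frames, " frames @ ", x$dt, " s (",
      x$dt * x$n_frames, " s)\n", sep = "")
  fmt <- function(w) sprintf("[%g, %g) s", w[1], w[2])
  cat("  baseline ", fmt(x$baseline), "\n", sep = "")
  cat("  GnRH     ", fmt(x$gnrh), "\n", sep = "")
  cat("  washout  ", fmt(x$washout), "\n", sep = "")
  cat("  KCl      ", fmt(x$kcl), "\n", sep = "")
  for (iv in x$interventions)
    cat("  intervention ", iv$kind, " ", fmt(iv$window), "\n", sep = "")
  invisible(x)
}

#' Time axis of a protocol
#'
#' @param protocol A `stim_protocol`.
#' @return Numeric vector of frame times in seconds (frame centres at
#'   `0, dt, 2 dt, ...`).
#' @export
protocol_time <- function(protocol) {
  validate_protocol(protocol)
  seq(0, by = protocol$dt, length.out = protocol$n_frames)
}

#' GnRH response window
#'
#' The window over which GnRH-evoked metrics (MIF, AUC, oscillation count,
#' responder status) are computed: from GnRH onset to `max_length` seconds
#' later, never closer than 10 s to KCl onset so the depolarization response
#' cannot contaminate GnRH metrics.
#'
#' @param protocol A `stim_protocol`.
#' @param max_length Maximum window length in seconds (default 160).
#' @param extended If `TRUE`, extend the window to the end of the recording
#'   (used for counting spikes of long-lasting cells).
#' @return Numeric `c(t0, t1)` in seconds.
#' @export
response_window <- function(protocol, max_length = 160, extended = FALSE) {
  validate_protocol(protocol)
  t0 <- protocol$gnrh[1]
  if (extended) return(c(t0, protocol$dt * protocol$n_frames))
  c(t0, min(t0 + max_length, protocol$kcl[1] - 10))
}

# frame indices (1-based) covered by a [t0, t1) window
window_frames <- function(protocol, window) {
  tt <- protocol_time(protocol)
  which(tt >= window[1] - 1e-9 & tt < window[2] - 1e-9)
}
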