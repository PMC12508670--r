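# CSV/JSON input-output for recordings and results.

#' Write a recording to CSV with a JSON sidecar
#'
#' The CSV holds time (seconds, column 1) and one column per ROI. The sidecar
#' `<stem>_meta.json` stores the protocol, animal id, group, and — when the
#' recording is synthetic — the ground-truth table.
#'
#' @param recording A `ca_recording`.
#' @param path Output CSV path (sidecar written next to it).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "ca_recording"))
  df <- tibble::as_tibble(recording$F)
  df <- dplyr::bind_cols(tibble::tibble(time = recording$time), df)
  readr::write_csv(df, path)
  proto <- recording$protocol
  truth <- recording$truth
  meta <- list(
    animal_id = recording$animal_id,
    group = recording$group,
    protocol = list(dt = proto$dt, n_frames = proto$n_frames,
                    baseline = proto$baseline, gnrh = proto$gnrh,
                    washout = proto$washout, kcl = proto$kcl,
                    interventions = proto$interventions),
    truth = if (!is.null(truth)) {
      t2 <- truth
      t2$spont_event_times <- purrr::map(t2$spont_event_times, as.numeric)
      t2
    }
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.csv$", "_meta.json", path)
}

#' Write normalized dF/F traces with a JSON sidecar
#'
#' The CSV holds time plus one dF/F column per retained ROI; the sidecar
#' records the per-ROI Fmin normalizers and the retained ROI ids.
#'
#' @param normalized A `ca_normalized` from [preprocess()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_normalized <- function(normalized, path) {
  stopifnot(inherits(normalized, "ca_normalized"))
  df <- dplyr::bind_cols(tibble::tibble(time = normalized$time),
                         tibble::as_tibble(normalized$dff))
  readr::write_csv(df, path)
  meta <- list(animal_id = normalized$animal_id,
               group = normalized$group,
               roi_ids = normalized$roi_ids,
               fmin = normalized$fmin)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace matrix from CSV
#'
#' Reads a time x ROI fluorescence CSV (time in column 1) and validates it:
#' uniform sampling (tolerance 1e-6 s), finite, strictly positive
#' fluorescence. If the JSON sidecar written by [write_recording()] is
#' present, the protocol (and ground truth) are restored from it; otherwise a
#' `protocol` must be supplied.
#'
#' @param path CSV path.
#' @param protocol Optional `stim_protocol`; overrides/replaces the sidecar.
#' @param time_unit `"s"` (default) or `"ms"`; millisecond time columns are
#'   converted to seconds.
#' @return A `ca_recording`.
#' @export
read_trace_matrix <- function(path, protocol = NULL, time_unit = c("s", "ms")) {
  time_unit <- match.arg(time_unit)
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(df) < 2) stop("expected a time column plus at least one ROI",
                         call. = FALSE)
  tt <- df[[1]]
  if (time_unit == "ms") tt <- tt / 1000
  if (any(!is.finite(tt)) || is.unsorted(tt, strictly = TRUE))
    stop("time column must be finite and strictly increasing", call. = FALSE)
  dts <- diff(tt)
  if (max(dts) - min(dts) > 1e-6)
    stop("non-uniform sampling at row ", which.max(abs(dts - dts[1])) + 1,
         call. = FALSE)
  Fm <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(Fm) | Fm <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-positive or missing fluorescence at row ", bad[1, 1],
         ", ROI '", colnames(Fm)[bad[1, 2]], "'", call. = FALSE)
  meta <- NULL
  sp <- sidecar_path(path)
  if (is.null(protocol) && file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    protocol <- make_protocol(
      dt = meta$protocol$dt,
      n_frames = meta$protocol$n_frames,
      baseline_s = diff(meta$protocol$baseline),
      gnrh_s = diff(meta$protocol$gnrh),
      washout_s = diff(meta$protocol$washout),
      kcl_s = diff(meta$protocol$kcl),
      tail_s = meta$protocol$dt * meta$protocol$n_frames -
        meta$protocol$kcl[2]
    )
  }
  if (is.null(protocol))
    stop("no protocol: supply one or keep the JSON sidecar next to the CSV",
         call. = FALSE)
  dt_obs <- stats::median(dts)
  if (abs(dt_obs - protocol$dt) > 1e-6)
    stop("CSV sampling interval (", dt_obs, " s) does not match protocol dt (",
         protocol$dt, " s)", call. = FALSE)
  truth <- NULL
  if (!is.null(meta$truth) && length(meta$truth)) {
    truth <- tibble::as_tibble(meta$truth)
    if ("spont_event_times" %in% names(truth))
      truth$spont_event_times <- purrr::map(truth$spont_event_times, as.numeric)
  }
  structure(list(F = Fm, time = tt, protocol = protocol,
                 animal_id = meta$animal_id %||% basename(path),
                 group = meta$group %||% NA_character_,
                 truth = truth),
            class = "ca_recording")
}
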