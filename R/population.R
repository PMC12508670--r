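# Population synchrony and per-animal / group aggregation.

#' Pairwise correlation matrix of GnRH responses
#'
#' Zero-lag Pearson correlation between the response-window dF/F segments of
#' every pair of cells — the static cell-by-cell synchrony picture. A
#' constant trace has no defined correlation; its entries are set to 0 by
#' convention (with a message). With `max_lag_s > 0` the maximum correlation
#' over integer-frame lags up to that bound is used instead.
#'
#' @param normalized A `ca_normalized` object, or a numeric matrix of dF/F
#'   traces (frames x cells) together with `protocol`.
#' @param protocol Required when `normalized` is a bare matrix.
#' @param window Numeric `c(t0, t1)`; defaults to the GnRH response window.
#' @param cells Optional character vector of cell ids (columns) to include.
#' @param max_lag_s Maximum lag in seconds for lagged cross-correlation
#'   (default 0 = zero-lag).
#' @return A symmetric correlation matrix with unit diagonal, of class
#'   `ca_cor` (plain matrix with cell ids as dimnames).
#' @examples
#' norm <- preprocess(synth_recording("control", 20, seed = 1))
#' R <- correlation_matrix(norm)
#' mean_pairwise_correlation(R)
#' @export
correlation_matrix <- function(normalized, protocol = NULL, window = NULL,
                               cells = NULL, max_lag_s = 0) {
  if (inherits(normalized, "ca_normalized")) {
    mat <- normalized$dff
    protocol <- normalized$protocol
  } else {
    mat <- normalized
    if (is.null(protocol)) stop("protocol required with a bare matrix", call. = FALSE)
  }
  if (!is.null(cells)) mat <- mat[, cells, drop = FALSE]
  if (ncol(mat) < 2) stop("need at least 2 cells for a correlation matrix",
                          call. = FALSE)
  window <- window %||% response_window(protocol)
  idx <- window_frames(protocol, window)
  if (length(idx) < 10) stop("correlation window shorter than 10 samples",
                             call. = FALSE)
  seg <- mat[idx, , drop = FALSE]
  const <- apply(seg, 2, stats::sd) == 0
  if (any(const))
    message(sum(const), " constant trace(s); correlations set to 0")
  if (max_lag_s > 0) {
    L <- floor(max_lag_s / protocol$dt)
    n <- ncol(seg)
    R <- diag(1, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (const[i] || const[j]) { R[i, j] <- R[j, i] <- 0; next }
      cc <- stats::ccf(seg[, i], seg[, j], lag.max = L, plot = FALSE)$acf
      R[i, j] <- R[j, i] <- max(cc)
    }
  } else {
    R <- suppressWarnings(stats::cor(seg))
    R[const, ] <- 0
    R[, const] <- 0
  }
  diag(R) <- 1
  dimnames(R) <- list(colnames(mat), colnames(mat))
  R
}

#' Mean pairwise correlation
#'
#' Mean of the strict upper triangle of a correlation matrix — a scalar
#' summary of population synchrony.
#'
#' @param R A square correlation matrix.
#' @return Numeric scalar.
#' @export
mean_pairwise_correlation <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R))
    stop("R must be a square matrix", call. = FALSE)
  if (nrow(R) < 2)
    stop("mean pairwise correlation undefined for a single cell", call. = FALSE)
  mean(R[upper.tri(R)])
}

#' Summarize one recording (one animal) into a single row
#'
#' Applies the published denominator conventions: responder and spontaneous
#' fractions are relative to the KCl-viable cells (the 100% population);
#' pattern proportions are relative to GnRH responders; MIF and AUC are
#' averaged over responders; the oscillation count is averaged over cells
#' classified oscillatory. With fewer than `2` responders metric means are
#' reported as `NA`.
#'
#' @param cells A per-cell tibble from [cell_metrics()] (viability-gated).
#' @param truth Optional ground-truth tibble (from a synthetic recording,
#'   aligned by `cell_id`); when given, a label confusion table is attached
#'   as attribute `"confusion"` for QC.
#' @param mean_correlation Optional scalar from
#'   [mean_pairwise_correlation()] to carry along.
#' @return A one-row tibble: `animal_id`, `group`, `n_cells`, `n_responders`,
#'   `frac_responder`, `frac_spontaneous` (gonadotrophs only),
#'   `frac_oscillatory`, `frac_biphasic`, `frac_transitory`,
#'   `frac_long_lasting`, `mean_mif`, `mean_auc`, `mean_n_osc`,
#'   `mean_correlation`.
#' @export
summarize_recording <- function(cells, truth = NULL,
                                mean_correlation = NA_real_) {
  stopifnot(is.data.frame(cells))
  n <- nrow(cells)
  resp <- dplyr::filter(cells, .data$responder)
  nr <- nrow(resp)
  frac_pat <- function(p) if (nr) mean(resp$pattern == p) else 0
  tibble::tibble(
    animal_id = cells$animal_id[1],
    group = cells$group[1],
    n_cells = n,
    n_responders = nr,
    frac_responder = nr / n,
    frac_spontaneous = if (nr) mean(resp$spontaneous) else 0,
    frac_oscillatory = frac_pat("oscillatory"),
    frac_biphasic = frac_pat("biphasic"),
    frac_transitory = frac_pat("transitory"),
    frac_long_lasting = if (nr) mean(resp$long_lasting) else 0,
    mean_mif = if (nr) mean(resp$mif) else NA_real_,
    mean_auc = if (nr) mean(resp$auc) else NA_real_,
    mean_n_osc = {
      osc <- resp$n_oscillations[resp$pattern == "oscillatory"]
      if (length(osc)) mean(osc) else NA_real_
    },
    mean_correlation = mean_correlation
  ) -> out
  if (!is.null(truth)) {
    lab <- function(resp, pat) ifelse(resp, pat, "non-responder")
    m <- dplyr::inner_join(cells, truth, by = "cell_id")
    attr(out, "confusion") <- m |>
      dplyr::count(
        truth = lab(m$is_gonadotroph, m$pattern.y),
        detected = lab(m$responder, m$pattern.x)
      )
  }
  out
}

#' Aggregate per-animal summaries into group mean +/- SD
#'
#' Statistics are computed over per-animal means (each animal contributes one
#' value per metric), never by pooling cells — the group mean of per-animal
#' means is the published quantity. SD uses the sample (n-1) denominator and
#' is `NA` for single-animal groups.
#'
#' @param summaries A tibble of per-animal rows from [summarize_recording()].
#' @return A tibble with one row per (group, metric): `group`, `metric`,
#'   `mean`, `sd`, `n_animals`.
#' @examples
#' # two animals, one group
#' s <- dplyr::bind_rows(
#'   summarize_recording(cell_metrics(preprocess(synth_recording("control", 20, 1)))),
#'   summarize_recording(cell_metrics(preprocess(synth_recording("control", 20, 2))))
#' )
#' aggregate_groups(s)
#' @export
aggregate_groups <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  metrics <- setdiff(names(summaries),
                     c("animal_id", "group", "n_cells", "n_responders"))
  summaries |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$group, .data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = if (sum(!is.na(.data$value)) > 1)
        stats::sd(.data$value, na.rm = TRUE) else NA_real_,
      n_animals = sum(!is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean = ifelse(is.nan(.data$mean), NA_real_, .data$mean))
}
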