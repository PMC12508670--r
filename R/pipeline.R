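# End-to-end orchestration: simulate -> preprocess -> metrics -> aggregate ->
# statistics, with a machine-readable comparison against the calibration.

#' Build an experiment configuration
#'
#' @param groups Character vector of groups to simulate.
#' @param n_animals Named or scalar number of animals per group (published
#'   design: 6 per group, 5 for Cd21).
#' @param n_cells Cells (ROIs) per animal.
#' @param seed Master seed; animal a of group g uses
#'   `seed * 100 + animal index` within the run.
#' @param protocol A `stim_protocol`.
#' @param thresholds Named list of detection/classification thresholds
#'   (`theta_resp`, `theta_amp`, `min_prominence`, `min_separation`, plus
#'   [classify_pattern()] params).
#' @param params_overrides Named list (per group) of [default_group_params()]
#'   overrides.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(groups = c("control", "Cd21", "Cd35", "Cd56"),
                              n_animals = c(control = 6, Cd21 = 5,
                                            Cd35 = 6, Cd56 = 6),
                              n_cells = 60,
                              seed = 1,
                              protocol = make_protocol(),
                              thresholds = list(),
                              params_overrides = list()) {
  if (length(n_animals) == 1 && is.null(names(n_animals)))
    n_animals <- stats::setNames(rep(n_animals, length(groups)), groups)
  stopifnot(all(groups %in% names(n_animals)))
  structure(list(groups = groups, n_animals = n_animals, n_cells = n_cells,
                 seed = seed, protocol = protocol, thresholds = thresholds,
                 params_overrides = params_overrides),
            class = "experiment_config")
}

#' Serialize / restore an experiment configuration
#'
#' Round-trips losslessly through YAML (the protocol is stored by its
#' constructor arguments).
#'
#' @param config An `experiment_config`.
#' @param path YAML file path.
#' @return `read_config()` returns an `experiment_config`.
#' @export
write_config <- function(config, path) {
  p <- config$protocol
  x <- list(groups = config$groups,
            n_animals = as.list(config$n_animals),
            n_cells = config$n_cells, seed = config$seed,
            protocol = list(dt = p$dt, n_frames = p$n_frames,
                            baseline_s = diff(p$baseline),
                            gnrh_s = diff(p$gnrh),
                            washout_s = diff(p$washout),
                            kcl_s = diff(p$kcl)),
            thresholds = config$thresholds,
            params_overrides = config$params_overrides)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  pr <- x$protocol
  tail_s <- pr$dt * pr$n_frames -
    (pr$baseline_s + pr$gnrh_s + pr$washout_s + pr$kcl_s)
  experiment_config(
    groups = unlist(x$groups),
    n_animals = unlist(x$n_animals),
    n_cells = x$n_cells,
    seed = x$seed,
    protocol = make_protocol(dt = pr$dt, baseline_s = pr$baseline_s,
                             gnrh_s = pr$gnrh_s, washout_s = pr$washout_s,
                             kcl_s = pr$kcl_s, tail_s = tail_s),
    thresholds = x$thresholds %||% list(),
    params_overrides = x$params_overrides %||% list()
  )
}

#' Analyse one recording end to end
#'
#' preprocess -> per-cell metrics -> correlation -> one-row summary.
#'
#' @param recording A `ca_recording`.
#' @param thresholds Threshold list as in [experiment_config()].
#' @param gate Apply the KCl viability gate (default TRUE).
#' @return List with `cells` (per-cell tibble), `summary` (one-row tibble),
#'   `correlation` (matrix or NULL when < 2 responders).
#' @export
analyze_recording <- function(recording, thresholds = list(), gate = TRUE) {
  th <- utils::modifyList(
    list(theta_resp = 0.10, theta_amp = 0.10, min_prominence = 0.05,
         min_separation = 1, theta_kcl = 0.10, smooth_frames = 3),
    thresholds)
  norm <- preprocess(recording, theta_kcl = th$theta_kcl, gate = gate,
                     smooth_frames = th$smooth_frames)
  cls_par <- th[intersect(names(th),
                          c("min_peaks", "trough_frac", "plateau_frac",
                            "plateau_s"))]
  cells <- cell_metrics(norm, theta_resp = th$theta_resp,
                        theta_amp = th$theta_amp,
                        min_prominence = th$min_prominence,
                        min_separation = th$min_separation,
                        classify_params = cls_par)
  resp_ids <- cells$cell_id[cells$responder]
  R <- NULL
  mpc <- NA_real_
  if (length(resp_ids) >= 2) {
    R <- correlation_matrix(norm, cells = resp_ids)
    mpc <- mean_pairwise_correlation(R)
  }
  list(cells = cells,
       summary = summarize_recording(cells, truth = norm$truth,
                                     mean_correlation = mpc),
       correlation = R, normalized = norm)
}

#' Run a simulated multi-group experiment
#'
#' Simulates every animal of every configured group, analyses each recording
#' end to end, aggregates per-animal summaries into group statistics, runs
#' Kruskal-Wallis + Dunn (Holm-adjusted) across groups for each metric, and
#' compares the recovered group means against the generator calibration
#' table. Fully deterministic given the config seed. If `out_dir` is given,
#' per-cell, per-animal, group-summary, statistics, and comparison CSVs plus
#' the resolved YAML config are written there.
#'
#' @param config An `experiment_config`.
#' @param out_dir Optional output directory.
#' @return List of class `ca_experiment`: `cells`, `animals`, `groups`
#'   (tibbles), `stats` (Dunn tables per metric), `kruskal` (KW row per
#'   metric), `comparison` (recovered vs calibration), `config`.
#' @examples
#' \donttest{
#' res <- run_experiment(experiment_config(groups = "control",
#'                                         n_animals = 2, n_cells = 30))
#' res$groups
#' }
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  all_cells <- list()
  all_sum <- list()
  failures <- character()
  for (g in config$groups) {
    overr <- config$params_overrides[[g]] %||% list()
    params <- do.call(default_group_params, c(list(group = g), overr))
    for (a in seq_len(config$n_animals[[g]])) {
      aid <- sprintf("%s_a%d", g, a)
      res <- tryCatch({
        rec <- synth_recording(params, config$n_cells,
                               seed = config$seed * 100 + a,
                               protocol = config$protocol, animal_id = aid)
        analyze_recording(rec, config$thresholds)
      }, error = function(e) {
        warning("animal ", aid, " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
      if (is.null(res)) { failures <- c(failures, aid); next }
      all_cells[[aid]] <- res$cells
      all_sum[[aid]] <- res$summary
    }
  }
  if (!length(all_sum)) stop("every animal failed", call. = FALSE)
  cells <- dplyr::bind_rows(all_cells)
  animals <- dplyr::bind_rows(all_sum)
  groups <- aggregate_groups(animals)

  metrics <- c("frac_responder", "frac_spontaneous", "frac_oscillatory",
               "frac_biphasic", "mean_mif", "mean_auc", "mean_n_osc")
  kw <- NULL
  dunn <- NULL
  if (length(unique(animals$group)) >= 2) {
    kw <- purrr::map_dfr(metrics, function(m) {
      d <- animals[!is.na(animals[[m]]), ]
      if (length(unique(d$group)) < 2 || nrow(d) < 3) return(NULL)
      dplyr::mutate(kruskal_wallis(d, .data[[m]], .data$group),
                    metric = m, .before = 1)
    })
    dunn <- purrr::map_dfr(metrics, function(m) {
      d <- animals[!is.na(animals[[m]]), ]
      if (length(unique(d$group)) < 2) return(NULL)
      dplyr::mutate(dunn_posthoc(d, .data[[m]], .data$group),
                    metric = m, .before = 1)
    })
  }

  calib <- calibration_table() |>
    dplyr::filter(.data$group %in% config$groups) |>
    dplyr::select("group", "frac_responder", "frac_spontaneous",
                  "frac_oscillatory", "frac_biphasic",
                  target_mif = "mif_mean", target_auc = "auc_target",
                  target_n_osc = "spike_count_mean") |>
    tidyr::pivot_longer(-"group", names_to = "metric", values_to = "target") |>
    dplyr::mutate(metric = dplyr::recode(.data$metric,
                                         target_mif = "mean_mif",
                                         target_auc = "mean_auc",
                                         target_n_osc = "mean_n_osc"))
  comparison <- groups |>
    dplyr::inner_join(calib, by = c("group", "metric")) |>
    dplyr::mutate(deviation = .data$mean - .data$target)

  out <- structure(list(cells = cells, animals = animals, groups = groups,
                        kruskal = kw, stats = dunn, comparison = comparison,
                        failures = failures, config = config),
                   class = "ca_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(cells, file.path(out_dir, "cells.csv"))
    readr::write_csv(animals, file.path(out_dir, "animals.csv"))
    readr::write_csv(groups, file.path(out_dir, "group_summary.csv"))
    if (!is.null(dunn)) readr::write_csv(dunn, file.path(out_dir, "stats_dunn.csv"))
    if (!is.null(kw)) readr::write_csv(kw, file.path(out_dir, "stats_kruskal.csv"))
    readr::write_csv(comparison, file.path(out_dir, "comparison.csv"))
    write_config(config, file.path(out_dir, "config.yaml"))
  }
  out
}

#' Paired before/after contrast for a pharmacological intervention
#'
#' Simulates the same cells with and without an intervention (identical
#' seeds, so each cell is its own control), computes per-cell response
#' metrics for both, and tests the paired difference with the Wilcoxon
#' signed-rank test — the within-preparation design used for nifedipine and
#' calcium-free challenges.
#'
#' @param recording_spec As in [apply_intervention()].
#' @param kind,window,config As in [apply_intervention()].
#' @param gate Apply the KCl viability gate (disable for `ca_free` windows
#'   covering the KCl pulse, where even viable cells cannot respond).
#' @param thresholds As in [analyze_recording()].
#' @return A list: `cells` (per-cell tibble with `_pre`/`_post` metric
#'   columns for cells retained in both runs) and `tests` (Wilcoxon rows for
#'   `auc`, `mif`, `n_oscillations`).
#' @examples
#' \donttest{
#' ic <- intervention_contrast(list(group = "control", n_cells = 40, seed = 2),
#'                             "nifedipine", c(240, 480))
#' ic$tests
#' }
#' @export
intervention_contrast <- function(recording_spec, kind, window,
                                  config = NULL, gate = TRUE,
                                  thresholds = list()) {
  pre <- synth_recording(group = recording_spec$group,
                         n_cells = recording_spec$n_cells,
                         seed = recording_spec$seed,
                         protocol = recording_spec$protocol %||% make_protocol())
  post <- apply_intervention(recording_spec, kind, window, config)
  a_pre <- analyze_recording(pre, thresholds, gate = gate)
  a_post <- analyze_recording(post, thresholds, gate = gate)
  merged <- dplyr::inner_join(
    a_pre$cells, a_post$cells,
    by = c("animal_id", "group", "cell_id"), suffix = c("_pre", "_post"))
  tests <- purrr::map_dfr(c("auc", "mif", "n_oscillations"), function(m) {
    x <- merged[[paste0(m, "_pre")]]
    y <- merged[[paste0(m, "_post")]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) return(NULL)
    dplyr::mutate(wilcoxon_signed_rank(x[ok], y[ok]), metric = m,
                  mean_pre = mean(x[ok]), mean_post = mean(y[ok]),
                  .before = 1)
  })
  list(cells = merged, tests = tests)
}

#' @export
print.ca_experiment <- function(x, ...) {
  cat("<ca_experiment> ", nrow(x$animals), " animals, ",
      nrow(x$cells), " cells, groups: ",
      paste(unique(x$animals$group), collapse = ", "), "\n", sep = "")
  if (length(x$failures))
    cat("  failed animals: ", paste(x$failures, collapse = ", "), "\n", sep = "")
  print(x$comparison, n = Inf)
  invisible(x)
}
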