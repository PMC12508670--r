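# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# long tibble of traces for either recording class
tidy_traces <- function(x) {
  mat <- if (inherits(x, "ca_normalized")) x$dff else x$F
  tibble::as_tibble(mat) |>
    dplyr::mutate(time = x$time, .before = 1) |>
    tidyr::pivot_longer(-"time", names_to = "cell_id", values_to = "value")
}

#' Tidy a recording into a long tibble
#'
#' @param x A `ca_recording` or `ca_normalized`.
#' @param ... Unused.
#' @return A tibble with `time`, `cell_id`, `value` (raw F or dF/F).
#' @method tidy ca_recording
#' @export
tidy.ca_recording <- function(x, ...) tidy_traces(x)

#' @rdname tidy.ca_recording
#' @method tidy ca_normalized
#' @export
tidy.ca_normalized <- function(x, ...) tidy_traces(x)

#' Tidy an experiment: per-animal summary rows
#'
#' @param x A `ca_experiment`.
#' @param ... Unused.
#' @return The per-animal summary tibble.
#' @method tidy ca_experiment
#' @export
tidy.ca_experiment <- function(x, ...) x$animals

#' One-line experiment overview
#'
#' @param x A `ca_experiment`.
#' @param ... Unused.
#' @return A one-row tibble: groups, animals, cells, responders, failures.
#' @method glance ca_experiment
#' @export
glance.ca_experiment <- function(x, ...) {
  tibble::tibble(
    n_groups = length(unique(x$animals$group)),
    n_animals = nrow(x$animals),
    n_cells = nrow(x$cells),
    n_responders = sum(x$cells$responder),
    n_failed = length(x$failures)
  )
}
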