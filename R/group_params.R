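#' Calibration parameters for an experimental group
#'
#' Returns the generator calibration for one exposure group. The values are
#' the published population statistics for cadmium-exposed mouse pituitaries
#' (control and 21/35/56 days post-exposure): the fraction of KCl-viable
#' cells that respond to GnRH (the gonadotrophs), the fraction of gonadotrophs
#' with spontaneous basal activity, the mixture of GnRH response patterns
#' among responders, the spike-count distribution of oscillatory cells, and
#' the target population mean MIF (maximal dF/F) and AUC.
#'
#' `pattern_mix` is renormalized to sum to one. `frac_long_lasting` is the
#' fraction of oscillatory/biphasic responders whose oscillations persist into
#' washout and the high-potassium pulse; no published fraction exists, so the
#' default (0.25 at 35/56 days, 0 otherwise) is a configurable placeholder.
#'
#' @param group One of `"control"`, `"Cd21"`, `"Cd35"`, `"Cd56"`.
#' @param ... Named overrides of any field (e.g. `frac_responder = 1` to
#'   simulate a pure gonadotroph population).
#' @return An object of class `group_params` (named list).
#' @examples
#' default_group_params("control")$frac_responder  # 0.27
#' @export
default_group_params <- function(group, ...) {
  tab <- list(
    control = list(
      frac_responder = 0.27, frac_spontaneous = 0.428,
      pattern_mix = c(oscillatory = 0.7753, biphasic = 0.2240, transitory = 0.0004),
      frac_long_lasting = 0,
      spike_count_mean = 17.60, spike_count_sd = 9.06,
      mif_mean = 1.31, mif_sd = 0.14, auc_target = 14.03
    ),
    Cd21 = list(
      frac_responder = 0.0744, frac_spontaneous = 0.567,
      pattern_mix = c(oscillatory = 0.0032, biphasic = 0.9972, transitory = 0),
      frac_long_lasting = 0,
      spike_count_mean = 5.50, spike_count_sd = 0.71,
      mif_mean = 1.12, mif_sd = 0.05, auc_target = 4.76
    ),
    Cd35 = list(
      frac_responder = 0.307, frac_spontaneous = 0.66,
      pattern_mix = c(oscillatory = 0.3140, biphasic = 0.6467, transitory = 0.0393),
      frac_long_lasting = 0.25,
      spike_count_mean = 23.9, spike_count_sd = 27.3,
      mif_mean = 1.23, mif_sd = 0.16, auc_target = 10.32
    ),
    Cd56 = list(
      frac_responder = 0.392, frac_spontaneous = 0.776,
      pattern_mix = c(oscillatory = 0.2026, biphasic = 0.7800, transitory = 0.0174),
      frac_long_lasting = 0.25,
      spike_count_mean = 64.6, spike_count_sd = 45.6,
      mif_mean = 1.21, mif_sd = 0.13, auc_target = 12.13
    )
  )
  if (!group %in% names(tab))
    stop("unknown group '", group, "'; valid groups: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  p <- tab[[group]]
  p$group <- group
  # generator nuisance parameters shared across groups
  p$spont_rate <- 0.5       # spontaneous events per minute in active cells
  p$bleach_rate <- 5e-4     # photobleaching decay, 1/s
  p$noise_sd <- 0.003       # additive noise SD as a fraction of resting F0
  p$frac_nonviable <- 0.05  # cells failing the KCl viability gate
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p))
      stop("unknown group_params field '", nm, "'", call. = FALSE)
    p[[nm]] <- dots[[nm]]
  }
  p$pattern_mix <- p$pattern_mix / sum(p$pattern_mix)
  validate_group_params(p)
  structure(p, class = "group_params")
}

validate_group_params <- function(p) {
  props <- c(p$frac_responder, p$frac_spontaneous, p$frac_long_lasting,
             p$frac_nonviable, p$pattern_mix)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p$pattern_mix) - 1) > 1e-12)
    stop("pattern_mix must sum to 1", call. = FALSE)
  if (p$spike_count_mean <= 0) stop("spike_count_mean must be > 0", call. = FALSE)
  invisible(p)
}

#' Calibration table for all groups
#'
#' @return A tibble with one row per group and one column per calibration
#'   parameter (pattern mixture unnested into the three pattern columns).
#' @export
calibration_table <- function() {
  purrr::map_dfr(c("control", "Cd21", "Cd35", "Cd56"), function(g) {
    p <- default_group_params(g)
    tibble::tibble(
      group = g,
      frac_responder = p$frac_responder,
      frac_spontaneous = p$frac_spontaneous,
      frac_oscillatory = unname(p$pattern_mix["oscillatory"]),
      frac_biphasic = unname(p$pattern_mix["biphasic"]),
      frac_transitory = unname(p$pattern_mix["transitory"]),
      frac_long_lasting = p$frac_long_lasting,
      spike_count_mean = p$spike_count_mean,
      spike_count_sd = p$spike_count_sd,
      mif_mean = p$mif_mean,
      mif_sd = p$mif_sd,
      auc_target = p$auc_target
    )
  })
}
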