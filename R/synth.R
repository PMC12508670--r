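# Synthetic perifusion recordings with per-cell ground truth.
#
# Waveform model per cell:
#   F(t) = F0 * exp(-bleach_rate * t) * (1 + r(t)) + eps(t)
# where r(t) is a sum of double-exponential transients (spontaneous events in
# the baseline epoch, the GnRH-evoked response, a KCl depolarization kernel)
# and eps is white Gaussian noise with SD = noise_sd * F0. The GnRH-evoked
# component is rescaled so its peak dF/F - 1 equals the cell's drawn response
# amplitude, which calibrates the population MIF directly.

# double-exponential kernel normalized to unit peak; t is time since onset
.kernel <- function(t, tr, td) {
  tpk <- log(td / tr) * tr * td / (td - tr)
  kpk <- exp(-tpk / td) - exp(-tpk / tr)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / td) - exp(-t[pos] / tr)) / kpk
  out
}

# shape constants (seconds); spike/biphasic decay set by amplitude-area
# calibration against the control MIF/AUC targets (see methods vignette)
.shapes <- list(
  spike      = c(tr = 0.3, td = 2.05),
  spont      = c(tr = 0.5, td = 3.0),
  transitory = c(tr = 0.5, td = 4.0),
  biphasic   = c(tr = 0.5, td = 37.5),
  kcl        = c(tr = 0.5, td = 5.0)
)

.gap_min <- 1.5       # minimum inter-spike interval, s
.amp_floor <- 0.105   # smallest drawable response amplitude (dF/F - 1);
                      # just above the 0.10 detection criterion so every
                      # simulated gonadotroph is in principle detectable

# latent mean of a lower-truncated normal whose truncated mean equals target
.trunc_mu <- local({
  cache <- new.env(parent = emptyenv())
  function(target, sd, lower) {
    key <- paste(target, sd, lower)
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- function(mu) {
      a <- (lower - mu) / sd
      mu + sd * dnorm(a) / pnorm(a, lower.tail = FALSE) - target
    }
    mu <- if (f(target) >= 0) {
      lo <- target - 10 * sd
      if (f(lo) >= 0) lo  # target at/below the floor: closest achievable
      else stats::uniroot(f, c(lo, target), tol = 1e-10)$root
    } else {
      target
    }
    cache[[key]] <- mu
    mu
  }
})

# one draw from N(mu, sd) truncated below at lower (inverse-CDF on the upper
# tail, stable even when the floor sits many SDs above the mean)
.rtnorm <- function(mu, sd, lower) {
  q0 <- pnorm((lower - mu) / sd, lower.tail = FALSE)
  qnorm(stats::runif(1) * q0, lower.tail = FALSE) * sd + mu
}

# response amplitude (dF/F - 1) calibrated so the population mean equals
# mif_mean despite the detectability floor; oscillatory cells use a higher
# floor because dense spike trains lose a few percent of peak height to
# kernel overlap and low-pass denoising
.draw_amp <- function(params, floor = .amp_floor) {
  mu <- .trunc_mu(params$mif_mean - 1, params$mif_sd, floor)
  .rtnorm(mu, params$mif_sd, floor)
}

# spike count of an oscillatory cell, truncated at >= 2 (a single-spike trace
# is not identifiable as oscillatory); NB matched to mean/SD, rounded-Gaussian
# fallback when SD^2 <= mean
.draw_spike_count <- function(params) {
  m <- params$spike_count_mean
  v <- params$spike_count_sd^2
  for (i in 1:100) {
    n <- if (v > m) {
      stats::rnbinom(1, size = m^2 / (v - m), mu = m)
    } else {
      round(stats::rnorm(1, m, sqrt(v)))
    }
    if (n >= 2) return(as.integer(n))
  }
  2L
}

# n ordered times in [start, end] with gaps >= gap_min and quasi-regular
# jittered spacing (GnRH-evoked oscillations are roughly rhythmic; regular
# spacing also keeps inter-spike troughs resolvable). If pin_last, the final
# time is exactly `end`.
.spread_times <- function(n, start, end, gap_min, pin_last = FALSE) {
  n_cap <- max(1L, floor((end - start) / gap_min) + 1L)
  n <- min(n, n_cap)
  free <- (end - start) - gap_min * (n - 1)
  k <- if (pin_last) n else n + 1L  # slack slots (incl. lead-in / tail)
  w <- stats::runif(k, 0.6, 1.4)
  slack <- free * w / sum(w)
  start + cumsum(slack)[seq_len(n)] + gap_min * (0:(n - 1))
}

# draw the latent per-cell labels
.draw_truth <- function(params) {
  viable <- stats::runif(1) < 1 - params$frac_nonviable
  gonad <- viable && stats::runif(1) < params$frac_responder
  spont <- FALSE
  pattern <- NA_character_
  long_lasting <- FALSE
  if (gonad) {
    spont <- stats::runif(1) < params$frac_spontaneous
    pattern <- sample(names(params$pattern_mix), 1, prob = params$pattern_mix)
    if (pattern %in% c("oscillatory", "biphasic"))
      long_lasting <- stats::runif(1) < params$frac_long_lasting
  }
  list(viable = viable, is_gonadotroph = gonad, spontaneous = spont,
       pattern = pattern, long_lasting = long_lasting,
       n_spikes_true = NA_integer_, amp = NA_real_,
       spont_event_times = numeric(0))
}

# spike kernels narrow as trains densify so individual oscillations remain
# resolvable (fast-oscillating cells have correspondingly brief transients)
.spike_td <- function(times) {
  if (length(times) < 2) return(.shapes$spike[["td"]])
  mean_isi <- (max(times) - min(times)) / (length(times) - 1)
  max(0.6, min(.shapes$spike[["td"]], 0.42 * mean_isi))
}

# complete a truth spec and lay out the cell's transient events.
# Returns list(truth, events); events: kind, time, amp (relative within the
# resp group, absolute otherwise), tr/td kernel shape, resp flag.
.plan_cell <- function(params, truth, protocol) {
  ev <- list()
  add <- function(kind, time, amp, resp, tr = NULL, td = NULL) {
    sh <- .shapes[[kind]]
    ev[[length(ev) + 1]] <<- tibble::tibble(
      kind = kind, time = time, amp = amp,
      tr = tr %||% sh[["tr"]], td = td %||% sh[["td"]], resp = resp)
  }
  gn_on <- protocol$gnrh[1]; gn_off <- protocol$gnrh[2]
  kcl_on <- protocol$kcl[1]; kcl_off <- protocol$kcl[2]
  t_end <- protocol$dt * protocol$n_frames

  if (isTRUE(truth$spontaneous)) {
    base_len <- diff(protocol$baseline)
    n_ev <- max(1L, stats::rpois(1, params$spont_rate * base_len / 60))
    times <- .spread_times(n_ev, protocol$baseline[1] + 5,
                           max(protocol$baseline[2] - 15,
                               protocol$baseline[1] + 6), 8)
    amps <- vapply(times, function(...) .rtnorm(0.18, 0.05, .amp_floor), 0)
    add("spont", times, amps, FALSE)
    truth$spont_event_times <- times
  }

  if (isTRUE(truth$is_gonadotroph)) {
    if (is.na(truth$amp)) {
      truth$amp <- if (identical(truth$pattern, "transitory")) {
        .rtnorm(0.15, 0.03, .amp_floor)
      } else if (identical(truth$pattern, "oscillatory")) {
        .draw_amp(params, floor = 0.13)
      } else {
        .draw_amp(params)
      }
    }
    latency <- stats::runif(1, 1, 3)
    if (truth$pattern == "oscillatory") {
      if (is.na(truth$n_spikes_true))
        truth$n_spikes_true <- .draw_spike_count(params)
      if (truth$long_lasting) {
        t_last <- kcl_on + stats::runif(1, 5, diff(protocol$kcl) - 5)
        times <- .spread_times(truth$n_spikes_true, gn_on + latency, t_last,
                               .gap_min, pin_last = TRUE)
      } else {
        times <- .spread_times(truth$n_spikes_true, gn_on + latency,
                               gn_off + 90, .gap_min)
      }
      truth$n_spikes_true <- length(times)
      # first spike gets full height: without a predecessor's tail it would
      # otherwise sit below the stacked steady-state that sets the peak scale
      rel <- stats::runif(length(times), 0.95, 1)
      rel[1] <- 1
      add("spike", times, rel, TRUE, td = .spike_td(times))
    } else if (truth$pattern == "biphasic") {
      add("biphasic", gn_on + latency, 1, TRUE)
      truth$n_spikes_true <- 1L
      if (truth$long_lasting) {
        # persisting oscillations after the plateau: absolute amplitudes so
        # they neither rescale nor outgrow the primary biphasic peak
        n_extra <- .draw_spike_count(params)
        t_last <- kcl_on + stats::runif(1, 5, diff(protocol$kcl) - 5)
        rw_end <- response_window(protocol)[2]
        times <- .spread_times(n_extra, rw_end + 5, t_last, .gap_min,
                               pin_last = TRUE)
        amps <- vapply(times, function(...) .rtnorm(0.18, 0.04, 0.13), 0)
        add("spike", times, amps, FALSE, td = .spike_td(times))
      }
    } else { # transitory
      add("transitory", gn_on + latency, 1, TRUE)
      truth$n_spikes_true <- 1L
    }
  }

  # terminal depolarization: every viable cell responds to KCl; long-lasting
  # cells' persisting spike train is itself the KCl-window response
  if (isTRUE(truth$viable) && !isTRUE(truth$long_lasting)) {
    add("kcl", kcl_on + 1, .rtnorm(0.5, 0.15, 0.2), FALSE)
  }

  events <- if (length(ev)) dplyr::bind_rows(ev) else
    tibble::tibble(kind = character(), time = numeric(), amp = numeric(),
                   tr = numeric(), td = numeric(), resp = logical())
  # fix the response scale now: the peak of the unperturbed GnRH-evoked
  # component equals the cell's drawn amplitude; interventions applied later
  # scale relative to this, so amplitude suppression is preserved
  scale <- 1
  if (any(events$resp)) {
    m <- max(.sum_kernels(events[events$resp, ], protocol))
    if (m > 0) scale <- truth$amp / m
  }
  list(truth = truth, events = events, scale = scale)
}

# superpose kernel transients on the protocol's time grid
.sum_kernels <- function(events, protocol) {
  tt <- protocol_time(protocol)
  r <- numeric(length(tt))
  for (i in seq_len(nrow(events))) {
    r <- r + events$amp[i] * .kernel(tt - events$time[i],
                                     events$tr[i], events$td[i])
  }
  r
}

# render an event plan into a fluorescence trace; `noise` is a pre-drawn
# standard-normal vector (so interventions cannot perturb the noise stream)
.render_plan <- function(plan, protocol, F0, bleach_rate, noise_sd,
                         noise = NULL) {
  tt <- protocol_time(protocol)
  events <- plan$events
  r <- numeric(length(tt))
  if (nrow(events)) {
    resp <- events$resp
    if (any(resp)) r <- r + plan$scale * .sum_kernels(events[resp, ], protocol)
    if (any(!resp)) r <- r + .sum_kernels(events[!resp, ], protocol)
  }
  out <- F0 * exp(-bleach_rate * tt) * (1 + r)
  if (noise_sd > 0) {
    if (is.null(noise)) noise <- stats::rnorm(length(tt))
    out <- out + noise * noise_sd * F0
  }
  out
}

.cell_seed <- function(seed, idx, salt = 0) {
  (as.numeric(seed) * 48271 + idx * 1299709 + salt * 7907) %% 2147483629
}

.with_preserved_rng <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  force(code)
}

#' Synthesize a single-cell fluorescence trace
#'
#' Renders one cell from an explicit ground-truth specification — useful for
#' constructing exactly-known fixtures (e.g. a noise-free long-lasting
#' oscillatory cell with a fixed spike count).
#'
#' @param params A `group_params` object (see [default_group_params()]).
#' @param truth A list giving the cell's labels; recognized fields:
#'   `viable`, `is_gonadotroph`, `spontaneous`, `pattern`
#'   (`"oscillatory"`, `"biphasic"`, `"transitory"` or `NA`), `long_lasting`,
#'   `n_spikes_true`, `amp` (peak dF/F - 1; drawn from the group calibration
#'   when omitted). Unspecified fields default to a viable gonadotroph.
#' @param protocol A `stim_protocol`.
#' @param seed Integer seed for the cell's private random stream.
#' @param F0 Resting fluorescence level (arbitrary units).
#' @param bleach_rate,noise_sd Override the group's photobleaching decay (1/s)
#'   and noise SD (fraction of `F0`); `NULL` uses the group values.
#' @return A list with `F` (numeric trace), `time`, and the completed `truth`.
#' @examples
#' p <- make_protocol()
#' cell <- synth_cell(default_group_params("control"),
#'                    list(pattern = "oscillatory", n_spikes_true = 10),
#'                    p, seed = 1, noise_sd = 0, bleach_rate = 0)
#' @export
synth_cell <- function(params, truth = list(), protocol = make_protocol(),
                       seed = 1, F0 = 100, bleach_rate = NULL, noise_sd = NULL) {
  validate_protocol(protocol)
  base <- list(viable = TRUE, is_gonadotroph = TRUE, spontaneous = FALSE,
               pattern = "oscillatory", long_lasting = FALSE,
               n_spikes_true = NA_integer_, amp = NA_real_,
               spont_event_times = numeric(0))
  base[names(truth)] <- truth
  if (!isTRUE(base$is_gonadotroph)) base$pattern <- NA_character_
  if (!is.na(base$n_spikes_true)) base$n_spikes_true <- as.integer(base$n_spikes_true)
  bleach <- if (is.null(bleach_rate)) params$bleach_rate else bleach_rate
  noise <- if (is.null(noise_sd)) params$noise_sd else noise_sd
  .with_preserved_rng({
    set.seed(.cell_seed(seed, 1))
    plan <- .plan_cell(params, base, protocol)
    Fv <- .render_plan(plan, protocol, F0, bleach, noise)
    list(F = Fv, time = protocol_time(protocol), truth = plan$truth)
  })
}

#' Synthesize a multi-cell perifusion recording
#'
#' Draws `n_cells` cells whose labels follow the group's calibration
#' proportions and renders their fluorescence traces. Each cell uses a private
#' random substream derived from (`seed`, cell index), so the same arguments
#' always give bit-identical output and increasing `n_cells` leaves earlier
#' cells unchanged.
#'
#' @param group Group label (`"control"`, `"Cd21"`, `"Cd35"`, `"Cd56"`) or a
#'   `group_params` object.
#' @param n_cells Number of ROIs to simulate.
#' @param seed Master integer seed.
#' @param protocol A `stim_protocol`.
#' @param animal_id Identifier stored with the recording.
#' @param interventions Optional list of interventions applied at render time;
#'   see [apply_intervention()].
#' @return An object of class `ca_recording`: list with `F` (frames x ROIs
#'   matrix, strictly positive), `time`, `protocol`, `animal_id`, `group`,
#'   and `truth` (tibble, one row per ROI, aligned with the columns of `F`).
#' @examples
#' rec <- synth_recording("control", n_cells = 20, seed = 1)
#' dim(rec$F)
#' @export
synth_recording <- function(group, n_cells, seed, protocol = make_protocol(),
                            animal_id = paste0(if (is.character(group)) group else group$group, "_a1"),
                            interventions = NULL) {
  stopifnot(n_cells >= 1)
  params <- if (inherits(group, "group_params")) group else default_group_params(group)
  validate_protocol(protocol)
  tt <- protocol_time(protocol)
  Fm <- matrix(NA_real_, nrow = length(tt), ncol = n_cells)
  truths <- vector("list", n_cells)
  .with_preserved_rng({
    for (i in seq_len(n_cells)) {
      set.seed(.cell_seed(seed, i))
      tr <- .draw_truth(params)
      plan <- .plan_cell(params, tr, protocol)
      F0 <- exp(stats::rnorm(1, log(100), 0.15))
      noise <- if (params$noise_sd > 0) stats::rnorm(length(tt)) else NULL
      if (!is.null(interventions))
        plan <- .apply_plan_interventions(plan, interventions, params,
                                          .cell_seed(seed, i, salt = 1))
      Fm[, i] <- .render_plan(plan, protocol, F0,
                              params$bleach_rate, params$noise_sd, noise)
      truths[[i]] <- plan$truth
    }
  })
  ids <- sprintf("roi_%03d", seq_len(n_cells))
  colnames(Fm) <- ids
  truth <- tibble::tibble(
    cell_id = ids,
    viable = purrr::map_lgl(truths, "viable"),
    is_gonadotroph = purrr::map_lgl(truths, "is_gonadotroph"),
    spontaneous = purrr::map_lgl(truths, "spontaneous"),
    pattern = purrr::map_chr(truths, "pattern"),
    long_lasting = purrr::map_lgl(truths, "long_lasting"),
    n_spikes_true = purrr::map_int(truths, "n_spikes_true"),
    amp_true = purrr::map_dbl(truths, "amp"),
    spont_event_times = purrr::map(truths, "spont_event_times")
  )
  structure(list(F = Fm, time = tt, protocol = protocol,
                 animal_id = animal_id,
                 group = params$group, truth = truth),
            class = "ca_recording")
}

#' @export
print.ca_recording <- function(x, ...) {
  cat("<ca_recording> ", x$animal_id, " (", x$group, "): ",
      ncol(x$F), " ROIs x ", nrow(x$F), " frames @ ", x$protocol$dt, " s\n",
      sep = "")
  cat("  viable ", sum(x$truth$viable), ", gonadotrophs ",
      sum(x$truth$is_gonadotroph), "\n", sep = "")
  invisible(x)
}

# modify a cell's event plan for a pharmacological intervention
.apply_plan_interventions <- function(plan, interventions, params, thin_seed) {
  ev <- plan$events
  truth <- plan$truth
  for (iv in interventions) {
    w <- iv$window
    in_w <- ev$time >= w[1] & ev$time < w[2]
    if (iv$kind == "nifedipine") {
      cfg <- utils::modifyList(
        list(amp_factor = 0.5, rate_factor = 0.5,
             ll_amp_factor = 0.8, ll_rate_factor = 0.85),
        iv$config %||% list())
      af <- if (isTRUE(truth$long_lasting)) cfg$ll_amp_factor else cfg$amp_factor
      rf <- if (isTRUE(truth$long_lasting)) cfg$ll_rate_factor else cfg$rate_factor
      ev$amp[in_w & ev$resp] <- ev$amp[in_w & ev$resp] * af
      if (rf < 1) {
        spikes <- which(in_w & ev$kind == "spike")
        if (length(spikes)) {
          set.seed(thin_seed)
          keep <- stats::runif(length(spikes)) < rf
          drop <- spikes[!keep]
          if (length(drop)) {
            ev <- ev[-drop, ]
            if (identical(truth$pattern, "oscillatory"))
              truth$n_spikes_true <- sum(ev$kind == "spike")
          }
        }
      }
    } else if (iv$kind == "ca_free") {
      cfg <- utils::modifyList(list(residual_amp = 0, ll_residual_amp = 0.35),
                               iv$config %||% list())
      # extracellular-entry events are abolished in the window ...
      kill <- in_w & ev$kind %in% c("spont", "kcl")
      ev$amp[kill] <- ev$amp[kill] * cfg$residual_amp
      # ... long-lasting oscillations are blunted, recovering after the window
      blunt <- in_w & ev$kind == "spike" & isTRUE(truth$long_lasting)
      ev$amp[blunt] <- ev$amp[blunt] * cfg$ll_residual_amp
      ev <- ev[ev$amp > 0, ]
    } else {
      stop("unknown intervention kind '", iv$kind,
           "'; valid kinds: nifedipine, ca_free", call. = FALSE)
    }
  }
  plan$truth <- truth
  plan$events <- ev
  plan
}

#' Apply a pharmacological intervention to a recording specification
#'
#' Re-synthesizes a recording with an intervention window applied to the
#' underlying event plans, leaving everything outside the window bit-identical
#' to the unperturbed recording (same seed, same substreams).
#'
#' `nifedipine` (L-type calcium-channel block) multiplies evoked amplitudes
#' and thins oscillation spikes inside the window; suppression is weaker for
#' long-lasting cells (`ll_*` factors), mirroring their reduced sensitivity.
#' `ca_free` (extracellular-calcium removal with EGTA) abolishes spontaneous
#' transients and the KCl response inside the window, blunts long-lasting
#' oscillations by `ll_residual_amp` (small residual transients, as seen at 56
#' days post-exposure), and leaves events after the window untouched so
#' activity recovers when calcium is returned.
#'
#' @param recording_spec A list with the arguments of [synth_recording()]:
#'   `group`, `n_cells`, `seed`, and optionally `protocol`, `animal_id`.
#' @param kind `"nifedipine"` or `"ca_free"`.
#' @param window Numeric `c(t0, t1)` in seconds, inside the recording.
#' @param config Optional named list of factors; see Details above for names
#'   and defaults. `nifedipine` factors of 1 leave the recording unchanged.
#' @return A `ca_recording` (with the intervention recorded in its protocol).
#' @examples
#' spec <- list(group = "Cd56", n_cells = 30, seed = 7)
#' rec <- apply_intervention(spec, "nifedipine", c(240, 480))
#' @export
apply_intervention <- function(recording_spec, kind, window, config = NULL) {
  if (!kind %in% c("nifedipine", "ca_free"))
    stop("unknown intervention kind '", kind,
         "'; valid kinds: nifedipine, ca_free", call. = FALSE)
  proto <- recording_spec$protocol %||% make_protocol()
  total <- proto$dt * proto$n_frames
  if (window[1] < 0 || window[2] > total)
    stop("intervention window outside recording", call. = FALSE)
  iv <- list(kind = kind, window = window, config = config)
  proto$interventions <- c(proto$interventions, list(iv[c("kind", "window")]))
  synth_recording(group = recording_spec$group,
                  n_cells = recording_spec$n_cells,
                  seed = recording_spec$seed,
                  protocol = proto,
                  animal_id = recording_spec$animal_id %||%
                    paste0(recording_spec$group, "_a1"),
                  interventions = list(iv))
}
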