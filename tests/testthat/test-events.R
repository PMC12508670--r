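test_that("detector finds single kernels, rejects flat traces", {
  p <- default_protocol
  cell <- fx_cell(list(pattern = "transitory"))
  dff <- normalize_dff(cell$F)
  ev <- detect_transients(dff, p, response_window(p))
  expect_equal(nrow(ev), 1)
  expect_gt(ev$amplitude, 0.10)
  flat <- rep(1, p$n_frames)
  expect_equal(nrow(detect_transients(flat, p, response_window(p))), 0)
  expect_error(detect_transients(dff, p, c(100, 100)), "empty")
})

test_that("noise-free long-lasting trace with 140 true spikes yields 140 events", {
  p <- default_protocol
  cell <- synth_cell(default_group_params("Cd56"),
                     list(pattern = "oscillatory", long_lasting = TRUE,
                          n_spikes_true = 140, amp = 0.25,
                          spontaneous = FALSE),
                     p, seed = 1, noise_sd = 0, bleach_rate = 0)
  expect_equal(cell$truth$n_spikes_true, 140L)
  ev <- detect_transients(normalize_dff(cell$F), p,
                          response_window(p, extended = TRUE))
  expect_identical(count_oscillations(ev), 140L)
})

test_that("event times are ordered, inside the window, amplitudes positive", {
  res <- fx_noisy()
  p <- res$normalized$protocol
  rw <- response_window(p)
  for (j in seq_len(min(10, ncol(res$normalized$dff)))) {
    ev <- detect_transients(res$normalized$dff[, j], p, rw)
    if (nrow(ev) < 2) next
    expect_true(all(diff(ev$peak_time) > 0))
    expect_true(all(ev$peak_time >= rw[1] & ev$peak_time < rw[2]))
    expect_true(all(ev$amplitude > 0))
  }
})

test_that("spontaneous activity uses the 10%-of-Fmin / 4-min criterion", {
  p <- default_protocol
  tt <- protocol_time(p)
  base <- rep(1, p$n_frames)
  bump <- function(amp, at) amp * gonadotrace:::.kernel(tt - at, 0.5, 3)
  expect_true(is_spontaneously_active(base + bump(0.12, 100), p))
  expect_false(is_spontaneously_active(base + bump(0.05, 100), p))
  # events after the 4-min epoch do not count
  expect_false(is_spontaneously_active(base + bump(0.3, 300), p))
  short <- suppressWarnings(make_protocol(n_frames = 1000))
  expect_warning(is_spontaneously_active(base[1:1000] + 0, short), "240 s")
})

test_that("responder calls respect the threshold and the window", {
  p <- default_protocol
  cell <- fx_cell(list(pattern = "transitory", amp = 0.15))
  expect_true(is_gnrh_responder(normalize_dff(cell$F), p))
  nong <- fx_cell(list(is_gonadotroph = FALSE, spontaneous = FALSE))
  expect_false(is_gnrh_responder(normalize_dff(nong$F), p))
})

test_that("responder and spontaneous flags are monotone in their thresholds", {
  res <- fx_noisy()
  p <- res$normalized$protocol
  for (j in seq_len(ncol(res$normalized$dff))) {
    x <- res$normalized$dff[, j]
    r <- vapply(c(0.05, 0.10, 0.20, 0.40),
                function(th) is_gnrh_responder(x, p, th), logical(1))
    expect_true(all(diff(as.integer(r)) <= 0))
    s <- vapply(c(0.05, 0.10, 0.20, 0.40),
                function(th) is_spontaneously_active(x, p, th), logical(1))
    expect_true(all(diff(as.integer(s)) <= 0))
  }
})

test_that("oscillation counts round-trip ground truth exactly when clean", {
  p <- default_protocol
  cell <- fx_cell(list(pattern = "oscillatory", n_spikes_true = 17))
  ev <- detect_transients(normalize_dff(cell$F), p, response_window(p))
  expect_identical(count_oscillations(ev), 17L)
  biph <- fx_cell(list(pattern = "biphasic"))
  evb <- detect_transients(normalize_dff(biph$F), p, response_window(p))
  expect_identical(count_oscillations(evb), 1L)
})

test_that("MIF is the windowed dF/F maximum with floor 1", {
  p <- default_protocol
  tt <- protocol_time(p)
  x <- rep(1, p$n_frames)
  x[tt >= 250 & tt < 260] <- 1.5
  expect_equal(compute_mif(x, p), 1.5)
  expect_equal(compute_mif(rep(1, p$n_frames), p), 1)
})

test_that("AUC integrates (dF/F - 1) rectangles exactly and is additive", {
  p <- default_protocol
  tt <- protocol_time(p)
  x <- rep(1, p$n_frames)
  win <- c(250, 280)
  x[tt >= win[1] & tt <= win[2]] <- 1.1
  expect_equal(compute_auc(x, p, win), 3.0)
  expect_equal(compute_auc(rep(1, p$n_frames), p), 0)
  # additivity over abutting windows, on a real trace
  cell <- fx_cell(list(pattern = "oscillatory", n_spikes_true = 9))
  d <- normalize_dff(cell$F)
  expect_equal(compute_auc(d, p, c(240, 320)) + compute_auc(d, p, c(320, 400)),
               compute_auc(d, p, c(240, 400)), tolerance = 1e-10)
  expect_gte(compute_auc(d, p, c(240, 400)), 0)
})

test_that("per-cell metrics table is complete and internally consistent", {
  res <- fx_noisy()
  cells <- res$cells
  expect_true(all(c("responder", "spontaneous", "pattern", "long_lasting",
                    "mif", "auc", "n_oscillations") %in% names(cells)))
  expect_identical(is.na(cells$pattern), !cells$responder)
  expect_true(all(cells$mif[cells$responder] >= 1))
  expect_true(all(cells$auc[cells$responder] >= 0))
})
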