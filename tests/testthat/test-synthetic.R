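test_that("identical seeds give bit-identical recordings", {
  a <- synth_recording("control", 25, seed = 5)
  b <- synth_recording("control", 25, seed = 5)
  expect_identical(a$F, b$F)
  expect_identical(a$truth, b$truth)
})

test_that("per-cell substreams are stable under n_cells changes", {
  small <- synth_recording("Cd35", 10, seed = 9)
  big <- synth_recording("Cd35", 30, seed = 9)
  expect_identical(small$F, big$F[, 1:10])
  expect_identical(small$truth$pattern, big$truth$pattern[1:10])
})

test_that("label proportions converge to the calibration (binomial CI)", {
  # label machinery only (no trace rendering) at n = 10^4
  n <- 10000
  params <- default_group_params("control")
  draws <- vapply(seq_len(n), function(i) {
    set.seed(gonadotrace:::.cell_seed(1, i))
    tr <- gonadotrace:::.draw_truth(params)
    c(tr$viable, tr$is_gonadotroph, tr$spontaneous,
      identical(tr$pattern, "oscillatory"))
  }, logical(4))
  viable <- draws[1, ]
  se <- function(p, m) sqrt(p * (1 - p) / m)
  p_gon <- mean(draws[2, viable])
  expect_lt(abs(p_gon - 0.27), 3 * se(0.27, sum(viable)))
  gon <- draws[2, ]
  expect_lt(abs(mean(draws[3, gon]) - 0.428), 3 * se(0.428, sum(gon)))
  expect_lt(abs(mean(draws[4, gon]) - 0.7753), 3 * se(0.7753, sum(gon)))
  # Cd21: oscillatory labels nearly absent among responders
  params21 <- default_group_params("Cd21")
  osc21 <- vapply(seq_len(n), function(i) {
    set.seed(gonadotrace:::.cell_seed(2, i))
    tr <- gonadotrace:::.draw_truth(params21)
    c(tr$is_gonadotroph, identical(tr$pattern, "oscillatory"))
  }, logical(2))
  # rare-event label: exact binomial test instead of a normal band
  n_gon <- sum(osc21[1, ])
  k_osc <- sum(osc21[2, osc21[1, ]])
  expect_gt(binom.test(k_osc, n_gon, 0.0032)$p.value, 1e-3)
})

test_that("a viable non-gonadotroph shows exactly one event, in the KCl window", {
  cell <- fx_cell(list(is_gonadotroph = FALSE, spontaneous = FALSE))
  p <- default_protocol
  dff <- normalize_dff(cell$F)
  ev <- detect_transients(dff, p, c(0, 480))
  expect_equal(nrow(ev), 1)
  expect_gte(ev$peak_time, p$kcl[1])
  expect_lt(ev$peak_time, p$kcl[2])
})

test_that("a silent cell without bleaching renders as constant F0", {
  cell <- fx_cell(list(viable = FALSE, is_gonadotroph = FALSE,
                       spontaneous = FALSE))
  expect_equal(cell$F, rep(cell$F[1], length(cell$F)))
})

test_that("response amplitudes calibrate the population MIF mean", {
  params <- default_group_params("control")
  set.seed(42)
  draws <- replicate(5000, gonadotrace:::.draw_amp(params))
  expect_lt(abs(mean(draws) - 0.31), 3 * sd(draws) / sqrt(5000))
  expect_true(all(draws >= gonadotrace:::.amp_floor))
})

test_that("oscillatory ground truth always has at least two spikes", {
  for (g in c("control", "Cd21", "Cd35", "Cd56")) {
    tr <- synth_recording(g, 80, seed = 13)$truth
    osc <- tr$n_spikes_true[!is.na(tr$pattern) & tr$pattern == "oscillatory"]
    if (length(osc)) expect_true(all(osc >= 2))
  }
})

test_that("ground truth aligns with ROI columns and respects invariants", {
  rec <- synth_recording("Cd56", 50, seed = 2)
  expect_identical(rec$truth$cell_id, colnames(rec$F))
  expect_true(all(rec$F > 0))
  expect_equal(nrow(rec$F), rec$protocol$n_frames)
  # pattern defined iff gonadotroph
  expect_identical(!is.na(rec$truth$pattern), rec$truth$is_gonadotroph)
  # long-lasting only among oscillatory/biphasic responders
  ll <- rec$truth$long_lasting
  expect_true(all(rec$truth$pattern[ll] %in% c("oscillatory", "biphasic")))
})

test_that("nifedipine with unit factors is the identity", {
  spec <- list(group = "Cd56", n_cells = 20, seed = 7)
  base <- synth_recording("Cd56", 20, seed = 7)
  same <- apply_intervention(spec, "nifedipine", c(240, 480),
                             config = list(amp_factor = 1, rate_factor = 1,
                                           ll_amp_factor = 1,
                                           ll_rate_factor = 1))
  expect_identical(same$F, base$F)
})

test_that("nifedipine suppresses evoked mobilization (AUC, MIF, spikes)", {
  ic <- intervention_contrast(list(group = "control", n_cells = 40, seed = 2),
                              "nifedipine", c(240, 480))
  tests <- ic$tests
  expect_lt(tests$mean_post[tests$metric == "auc"],
            tests$mean_pre[tests$metric == "auc"])
  expect_lt(tests$mean_post[tests$metric == "mif"],
            tests$mean_pre[tests$metric == "mif"])
  expect_lt(tests$mean_post[tests$metric == "n_oscillations"],
            tests$mean_pre[tests$metric == "n_oscillations"])
})

test_that("calcium-free window silences long-lasting spiking until washout", {
  # Cd56 long-lasting cells, window ending mid-washout: spike rate after the
  # window must exceed the rate inside it (recovery on calcium return)
  gp <- default_group_params("Cd56", frac_responder = 1, frac_nonviable = 0,
                             frac_long_lasting = 1,
                             pattern_mix = c(oscillatory = 1, biphasic = 0,
                                             transitory = 0))
  win <- c(300, 380)
  rec <- apply_intervention(list(group = gp, n_cells = 15, seed = 4),
                            "ca_free", win)
  norm <- preprocess(rec, gate = FALSE)
  rate_in <- rate_after <- 0
  for (j in seq_len(ncol(norm$dff))) {
    rate_in <- rate_in +
      nrow(detect_transients(norm$dff[, j], norm$protocol, win)) / diff(win)
    rate_after <- rate_after +
      nrow(detect_transients(norm$dff[, j], norm$protocol, c(380, 460))) / 80
  }
  expect_gt(rate_after, rate_in)
})

test_that("calcium-free KCl abolishes the control viability response", {
  spec <- list(group = "control", n_cells = 25, seed = 6)
  rec <- apply_intervention(spec, "ca_free", c(430, 480))
  # the gate would now reject everything: that is the expected failure mode
  expect_error(preprocess(rec, gate = TRUE), "viability")
  norm <- preprocess(rec, gate = FALSE)
  expect_equal(ncol(norm$dff), 25)
})

test_that("unknown intervention kind errors", {
  expect_error(apply_intervention(list(group = "control", n_cells = 2,
                                       seed = 1), "caffeine", c(0, 10)),
               "nifedipine, ca_free")
})
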