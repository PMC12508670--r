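test_that("detrending recovers a pure exponential bleach exactly", {
  p <- default_protocol
  f <- 100 * exp(-5e-4 * protocol_time(p))
  out <- detrend_bleach(f, p)
  expect_true(all(abs(out - 100) / 100 < 0.005))
})

test_that("detrending leaves a constant trace unchanged", {
  p <- default_protocol
  f <- rep(50, p$n_frames)
  expect_equal(detrend_bleach(f, p), f, tolerance = 1e-10)
})

test_that("post-detrend baseline slope is negligible for an active cell", {
  cell <- synth_cell(default_group_params("control"),
                     list(pattern = "oscillatory", n_spikes_true = 12,
                          spontaneous = TRUE),
                     default_protocol, seed = 3, noise_sd = 0,
                     bleach_rate = 5e-4)
  out <- detrend_bleach(cell$F, default_protocol)
  idx <- gonadotrace:::window_frames(default_protocol,
                                     default_protocol$baseline)
  tt <- protocol_time(default_protocol)[idx]
  # slope of the 10th-percentile envelope, in F0 fractions per 100 s
  blocks <- floor(tt / 20)
  q <- tapply(out[idx], blocks, quantile, probs = 0.1)
  tc <- tapply(tt, blocks, mean)
  slope <- coef(lm(q ~ tc))[2] * 100 / out[1]
  expect_lt(abs(slope), 0.01)
})

test_that("dF/F = F/Fmin with floor exactly 1, and is idempotent", {
  expect_equal(normalize_dff(c(100, 150, 100)), c(1, 1.5, 1))
  expect_equal(normalize_dff(rep(50, 10)), rep(1, 10))
  set.seed(1)
  for (i in 1:20) {
    x <- exp(rnorm(500, 4, 0.3))
    d <- normalize_dff(x)
    expect_identical(min(d), 1)
    expect_identical(normalize_dff(d), d)
  }
  expect_error(normalize_dff(c(1, 0, 2)), "not positive")
  expect_error(normalize_dff(c(-1, 2)), "not positive")
})

test_that("detrend + normalize leave clean synthetic traces unchanged", {
  cell <- fx_cell(list(pattern = "oscillatory", n_spikes_true = 8))
  p <- default_protocol
  direct <- normalize_dff(cell$F)
  via_detrend <- normalize_dff(detrend_bleach(cell$F, p))
  expect_equal(via_detrend, direct, tolerance = 1e-6)
})

test_that("KCl viability gate retains exactly the ground-truth viable set", {
  res <- fx_noisefree()
  rec <- res$recording
  expect_setequal(res$normalized$roi_ids,
                  rec$truth$cell_id[rec$truth$viable])
  # per-column dff minimum is exactly 1
  expect_true(all(apply(res$normalized$dff, 2, min) == 1))
})

test_that("gate can be disabled and errors when nothing is viable", {
  rec <- fx_noisefree()$recording
  all_in <- preprocess(rec, gate = FALSE)
  expect_equal(ncol(all_in$dff), ncol(rec$F))
  # all-dead recording
  gp <- default_group_params("control", frac_nonviable = 1, noise_sd = 0)
  dead <- synth_recording(gp, 5, seed = 1)
  expect_error(preprocess(dead), "viability")
})

test_that("MIF and AUC are invariant to bleaching after preprocessing", {
  p <- default_protocol
  tr <- list(pattern = "biphasic", spontaneous = FALSE)
  clean <- synth_cell(default_group_params("control"), tr, p, seed = 8,
                      noise_sd = 0, bleach_rate = 0)
  bleached <- synth_cell(default_group_params("control"), tr, p, seed = 8,
                         noise_sd = 0, bleach_rate = 8e-4)
  d1 <- normalize_dff(detrend_bleach(clean$F, p))
  d2 <- normalize_dff(detrend_bleach(bleached$F, p))
  expect_equal(compute_mif(d2, p), compute_mif(d1, p), tolerance = 0.01)
  expect_equal(compute_auc(d2, p), compute_auc(d1, p), tolerance = 0.01)
})

test_that("recordings round-trip through CSV + sidecar", {
  rec <- synth_recording("control", 6, seed = 21)
  path <- file.path(withr::local_tempdir(), "rec.csv")
  write_recording(rec, path)
  back <- read_trace_matrix(path)
  expect_equal(back$F, rec$F, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$protocol$n_frames, rec$protocol$n_frames)
  expect_equal(back$group, "control")
  expect_equal(back$truth$pattern, rec$truth$pattern)
})

test_that("normalized exports carry Fmin and retained ROIs", {
  res <- fx_noisy(n = 10, seed = 8)
  path <- file.path(withr::local_tempdir(), "norm.csv")
  write_normalized(res$normalized, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back), c("time", res$normalized$roi_ids))
  meta <- jsonlite::read_json(sub("\\.csv$", "_meta.json", path),
                              simplifyVector = TRUE)
  expect_equal(meta$fmin, res$normalized$fmin, tolerance = 1e-12)
})

test_that("trace CSV validation reports bad rows and converts units", {
  dir <- withr::local_tempdir()
  p <- suppressWarnings(make_protocol(baseline_s = 4, gnrh_s = 1,
                                      washout_s = 2, kcl_s = 1, tail_s = 0))
  tt <- protocol_time(p)
  good <- data.frame(time = tt, roi_001 = exp(rnorm(length(tt), 4, 0.1)))
  bad <- good
  bad$roi_001[17] <- -3
  fb <- file.path(dir, "bad.csv")
  readr::write_csv(bad, fb)
  expect_error(read_trace_matrix(fb, protocol = p), "row 17")
  # millisecond time column
  ms <- good
  ms$time <- ms$time * 1000
  fm <- file.path(dir, "ms.csv")
  readr::write_csv(ms, fm)
  back <- read_trace_matrix(fm, protocol = p, time_unit = "ms")
  expect_equal(back$time, tt)
  # non-uniform sampling
  nu <- good
  nu$time[5] <- nu$time[5] + 0.01
  fn <- file.path(dir, "nu.csv")
  readr::write_csv(nu, fn)
  expect_error(read_trace_matrix(fn, protocol = p), "non-uniform|increasing")
})
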