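# Shared fixtures, built once per test run and cached.

.fix <- new.env(parent = emptyenv())

# analyzed noise-free recording (exact ground-truth recovery regime)
fx_noisefree <- function(group = "control", n = 100, seed = 11) {
  key <- paste0("nf_", group, "_", n, "_", seed)
  if (is.null(.fix[[key]])) {
    gp <- default_group_params(group, noise_sd = 0, bleach_rate = 0)
    rec <- synth_recording(gp, n, seed = seed)
    .fix[[key]] <- c(analyze_recording(rec), list(recording = rec))
  }
  .fix[[key]]
}

# analyzed default-noise recording
fx_noisy <- function(group = "control", n = 40, seed = 3) {
  key <- paste0("ny_", group, "_", n, "_", seed)
  if (is.null(.fix[[key]])) {
    rec <- synth_recording(group, n, seed = seed)
    .fix[[key]] <- c(analyze_recording(rec), list(recording = rec))
  }
  .fix[[key]]
}

# one noise-free, bleach-free cell with fully specified truth
fx_cell <- function(truth, group = "control", seed = 1) {
  synth_cell(default_group_params(group), truth, make_protocol(),
             seed = seed, noise_sd = 0, bleach_rate = 0)
}

default_protocol <- make_protocol()
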