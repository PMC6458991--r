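# Shared fixtures, computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Construct sensor epochs directly from a per-trial source signal generator:
# signal_fun(trial_index, is_stim) -> source time series (1 s at `rate`).
make_epochs_from_source <- function(signal_fun, n_stim = 8L, n_rest = 8L,
                                    rate = 600,
                                    source_loc = c(0.01, -0.05, 0.02),
                                    contrast = 1, array = meg_sensor_array(),
                                    head = head_model(), noise_sd = 0,
                                    seed = 1) {
  set.seed(seed)
  gain <- as.numeric(reduce_orientation(sphere_leadfield(source_loc, array,
                                                         head)))
  n_tr <- n_stim + n_rest
  data <- array(0, dim = c(n_tr, length(gain), rate))
  is_stim <- c(rep(TRUE, n_stim), rep(FALSE, n_rest))
  for (i in seq_len(n_tr)) {
    s <- signal_fun(i, is_stim[i])
    sig <- outer(gain, s)
    if (noise_sd > 0) {
      sig <- sig + matrix(rnorm(length(sig), sd = noise_sd * median(abs(gain))),
                          nrow(sig))
    }
    data[i, , ] <- sig
  }
  labels <- tibble::tibble(
    trial = seq_len(n_tr),
    condition = ifelse(is_stim, as.character(contrast * 100), "rest"),
    contrast = ifelse(is_stim, contrast, NA_real_),
    block = seq_len(n_tr))
  sensor_epochs(data, rate, labels, array, head, "left")
}

# Small standard MEG simulation + scan, reused by several suites.
std_meg_run <- function() {
  fixture("std_meg_run", function() {
    truth <- subject_truth("control", seed = 42)
    sched <- make_schedule(42, "left")
    ep <- simulate_meg(truth, sched, trials_per_block = 3L, noise_sd = 0.1,
                       source_loc = c(0.01, -0.05, 0.02), seed = 42)
    grid <- source_grid(head_model(), spacing = 0.01)
    map <- scan_percent_change(ep, grid, mask_only = TRUE)
    list(truth = truth, sched = sched, ep = ep, grid = grid, map = map)
  })
}
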