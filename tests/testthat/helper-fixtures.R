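# Shared fixture builders. Everything is generated in code at test time; the
# sizes are scaled to keep the default run fast while preserving the stated
# statistical structure.

# plain white-noise tensor
noise_tensor <- function(n_leads = 2, n_trials = 16, n_samples = 1500,
                         fs = 1000, onset_index = 1000, seed = 1,
                         tasks = "gender") {
  set.seed(seed)
  trial_labels <- tibble::tibble(
    task = rep(tasks, length.out = n_trials),
    truncation = "full", static_duration_ms = 575, response_time_ms = 830
  )
  trial_tensor(array(rnorm(n_leads * n_trials * n_samples),
                     dim = c(n_leads, n_trials, n_samples)),
               fs = fs, onset_index = onset_index,
               trial_labels = trial_labels)
}

# a gc_trace-shaped tibble with prescribed baseline / response values
synthetic_gc_trace <- function(base_F, resp_F, source = "A", target = "B",
                               ns_factor = 1) {
  nb <- length(base_F); nr <- length(resp_F)
  start <- c(seq(-900, by = 10, length.out = nb),
             seq(100, by = 10, length.out = nr))
  out <- tibble::tibble(
    source = source, target = target, ns_factor = ns_factor,
    window = seq_len(nb + nr),
    window_start_ms = start, window_center_ms = start + 50,
    window_end_ms = start + 100,
    F = c(base_F, resp_F)
  )
  class(out) <- c("gc_trace", class(out))
  out
}

# common-driver motif: L3 -> L1 (2 ms) and L3 -> L2 (4 ms), no direct link;
# gate spans the whole activation so the 0.1-0.4 s screen sees stationary
# windows
common_driver_sim <- function(seed, n_trials = 64, gain = 0.8) {
  cp <- rbind(
    coupling_spec("L3", "L1", lag_ms = 2, gain = gain, window_s = c(0, 0.6)),
    coupling_spec("L3", "L2", lag_ms = 4, gain = gain, window_s = c(0, 0.6))
  )
  simulate_dataset(n_leads = 4, n_trials_per_task = n_trials, tasks = "gender",
                   pre_onset_s = 1, post_onset_s = 0.8, couplings = cp,
                   seed = seed)
}
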