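# shared fixture builders: everything is generated in code at test time

# a hand-written minimal samples table
toy_samples <- function(n = 10L, fs = 21) {
  full <- data.frame(
    time_ms = floor((seq_len(max(n, 1L)) - 1L) * 1000 / fs),
    ax = 0, ay = 0, az = 9.81,
    gx = 0, gy = 0, gz = 0,
    f1 = 2000L, f2 = 1800L)
  full[seq_len(n), ]
}

toy_session <- function(n = 10L, exercise = "basket", anomalous = FALSE,
                        fs = 21, mutate = identity) {
  glove_session("subjA", exercise, anomalous, fs, mutate(toy_samples(n, fs)))
}

# small simulated session, fixed profile
sim_session <- function(exercise = "rolling", anomaly_mode = "none",
                        duration = 20, seed = 42L, profile_seed = 7L,
                        variation = 1) {
  p <- subject_profile("subjSim", seed = profile_seed, variation = variation)
  generate_session(p, exercise, anomaly_mode, duration = duration,
                   fs = 21, seed = seed)
}
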