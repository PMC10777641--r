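# Shared fixtures. All fixtures are built in code; no files.

# Noise-free, disturbance-free sham plant.
gt_clean <- function(...) {
  gt_sham(noise_sd = 0, gain_volatility = 0, ...)
}

# Plant parameterized to the closed-loop replication example (animal #2):
# ECAPT 0.014 mA, MT 0.060 mA, amplitude at MT 0.6507 mV.
gt_animal2 <- function(...) {
  ground_truth(slope = 0.6507 / (0.060 - 0.014),
               ecapt_true = 0.014, mt_true = 0.060, ...)
}

# Short pulse train at a fixed current.
prog_fixed <- function(current, n_pulses = 5, frequency = 2) {
  stimulus_program(frequency, 200, duration_s = n_pulses / frequency,
                   current_ma = current)
}

# Manually built single-channel-of-interest recording from a matrix of
# sweeps (pulses x samples), channel 1 of a 2-contact lead (stim at 2).
recording_from_matrix <- function(m, sample_rate = 30000) {
  geom <- lead_geometry(n_contacts = 2, stim_index = 2,
                        contact_labels = c("a", "b"))
  n_p <- nrow(m)
  prog <- stimulus_program(2, 200, duration_s = n_p / 2, current_ma = 0)
  sweeps <- array(0, dim = c(n_p, 2, ncol(m)))
  sweeps[, 1, ] <- m
  structure(list(sweeps = sweeps,
                 time_ms = (seq_len(ncol(m)) - 1) / sample_rate * 1000,
                 sample_rate = sample_rate, geometry = geom,
                 program = prog),
            class = "multichannel_recording")
}
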