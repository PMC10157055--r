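# Shared fixtures, all built in code at test time.

# A tiny two-channel coupling: channel 1 drives channel 2 at a fixed lag.
pair_spec <- function(lag = 5, gain = 1, noise_sd = 0) {
  coupling_spec(data.frame(source = 1, target = 2, lag = lag, gain = gain),
                noise_sd = noise_sd)
}

# Small desk-scale training configuration: short epochs and higher learning
# rate suit a few hundred synthetic contexts (the package defaults mirror the
# full-scale reference setting and barely move in 200 epochs at desk scale).
desk_config <- function(epochs = 60, ...) {
  stdpgcn_config(epochs = epochs, batch_size = 32, learning_rate = 1e-3, ...)
}

# Tiny dataset for fast pipeline tests: short epochs (low sample count), few
# subjects. Sampling rate 50 Hz keeps BSA/STDP cheap.
tiny_dataset <- function(n_subjects = 2, epochs_per_subject = 30, seed = 1,
                         n_samples = 600, subject_shift_sd = 0.2) {
  generate_stage_dataset(n_subjects, epochs_per_subject,
                         stage_specs = default_stage_specs(6, noise_sd = 0.2),
                         subject_shift_sd = subject_shift_sd,
                         n_channels = 6, n_samples = n_samples,
                         sampling_rate = 50, seed = seed)
}

rand_spike_train <- function(n, density, seed) {
  with_seed <- stdpgcn:::with_seed
  with_seed(seed, as.integer(stats::rbinom(n, 1, density)))
}
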