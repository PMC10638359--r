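# Small simulation helpers shared across test files.

# A compact noiseless configuration: predictions lie exactly on the bias line.
noiseless_config <- function(seed = 1L, n = 40, intercept = 15.2, slope = 0.7,
                             modalities = c("MPRAGE", "T2w")) {
  tab <- stats::setNames(
    lapply(modalities, function(m) list(prevalence = 1,
                                        repetitions = c(`1` = 1))),
    modalities)
  generator_config(
    n_participants = n, modality_table = tab,
    bias_intercept = intercept, bias_slope = slope,
    modality_offsets = stats::setNames(rep(0, length(modalities)), modalities),
    modality_noise_sd = stats::setNames(rep(0, length(modalities)), modalities),
    subject_effect_sd = 0, failure_modality = NULL,
    slice_count = 0, seed = seed)
}

# A small noisy multi-modality configuration for protocol tests.
small_noisy_config <- function(seed = 1L, n = 120, noise = 5,
                               subject_sd = 3, failure = FALSE) {
  mods <- c("MPRAGE", "T1w", "T2w")
  tab <- stats::setNames(
    lapply(mods, function(m) list(prevalence = 1,
                                  repetitions = c(`1` = 0.7, `2` = 0.3))),
    mods)
  generator_config(
    n_participants = n, modality_table = tab,
    bias_intercept = 15.2, bias_slope = 0.7,
    modality_offsets = stats::setNames(rep(0, 3), mods),
    modality_noise_sd = stats::setNames(rep(noise, 3), mods),
    subject_effect_sd = subject_sd,
    failure_modality = if (failure)
      list(modality = "T2w", intercept = 55, slope = 0.1, noise_sd = noise)
    else NULL,
    slice_count = 0, seed = seed)
}

# Configuration with a strong between-modality slope gap (0.5 vs 1.1) at
# moderate noise: the modality-moderated bias model clearly outperforms the
# marginal one under correction, without the variance blow-up a near-zero
# slope would cause.
het_slopes_config <- function(seed = 1L, n = 120) {
  mods <- c("MPRAGE", "T1w", "T2w")
  tab <- stats::setNames(
    lapply(mods, function(m) list(prevalence = 1,
                                  repetitions = c(`1` = 0.7, `2` = 0.3))),
    mods)
  generator_config(
    n_participants = n, modality_table = tab,
    bias_intercept = 15.2, bias_slope = 0.5,
    modality_offsets = stats::setNames(rep(0, 3), mods),
    modality_noise_sd = stats::setNames(rep(3, 3), mods),
    subject_effect_sd = 2,
    failure_modality = list(modality = "T2w", intercept = 5, slope = 1.1,
                            noise_sd = 3),
    slice_count = 0, seed = seed)
}

# Cohort where every participant has exactly one scan per listed modality
# with the given brain-PAD values (deterministic; no generator involved).
balanced_records <- function(pad_by_modality, n = 30, age_seq = NULL) {
  mods <- names(pad_by_modality)
  ages <- age_seq %||% seq(20, 90, length.out = n)
  do.call(rbind, lapply(mods, function(m) {
    data.frame(participant_id = sprintf("P%03d", seq_len(n)),
               age = ages, sex = "F", modality = m, scanner = "Aera",
               repetition = 1L,
               predicted_brain_age = ages + pad_by_modality[[m]],
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
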