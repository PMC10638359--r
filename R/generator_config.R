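#' Default modality table of the synthetic cohort
#'
#' Per-modality participant prevalence (probability that a participant carries
#' at least one scan of the modality) and the distribution of the number of
#' repetitions (1--4) given that the modality is present. The seven modality
#' labels are those of a multi-protocol clinical MRI archive: the
#' research-grade MPRAGE plus six 2D clinical sequences. Counts for the
#' well-attested modalities follow the reference cohort's scan table; the
#' remaining rows are approximate marginals that preserve the cohort's overall
#' scans-per-participant load (about 4.1 scans over 1540 participants).
#'
#' @return Named list; each element has `prevalence` (scalar in (0, 1]) and
#'   `repetitions` (named probability vector over "1".."4").
#' @export
default_modality_table <- function() {
  tab <- list(
    MPRAGE   = list(n_subjects = 928,  repetitions = c(`1` = 916, `2` = 12)),
    T1w      = list(n_subjects = 1100, repetitions = c(`1` = 0.62, `2` = 0.33, `3` = 0.04, `4` = 0.01)),
    T2w      = list(n_subjects = 1392, repetitions = c(`1` = 601, `2` = 756, `3` = 32, `4` = 3)),
    T1wFLAIR = list(n_subjects = 70,   repetitions = c(`1` = 50, `2` = 20)),
    T2wFLAIR = list(n_subjects = 990,  repetitions = c(`1` = 971, `2` = 19)),
    T2wGRE   = list(n_subjects = 170,  repetitions = c(`1` = 0.6, `2` = 0.3, `3` = 0.1)),
    IR       = list(n_subjects = 154,  repetitions = c(`1` = 1))
  )
  lapply(tab, function(m) {
    list(prevalence = m$n_subjects / 1540,
         repetitions = m$repetitions / sum(m$repetitions))
  })
}

#' Default scanner table of the synthetic cohort
#'
#' Per-modality scanner prevalences over the eight scanner models. The bulk
#' of the cohort sits on six Siemens scanners whose marginal shares follow
#' the reference cohort's scan totals; the two scanners the study never
#' trained on (Signa HDxt and Skyra) are concentrated on the rare modalities
#' that co-occur with them (IR and the T2w gradient-echo failure modality run
#' entirely on the Signa HDxt; the T1w FLAIR partly on the Skyra), so that a
#' realistic minority of participants carries them. A single named
#' prevalence vector may be supplied instead for fully marginal assignment.
#'
#' @return Named list (one element per modality) of named prevalence vectors,
#'   each summing to 1.
#' @export
default_scanner_table <- function() {
  siemens <- c(Aera = 1054, Avanto = 1416, Prisma = 964, Sola = 178,
               `Titan 3T` = 364, Verio = 1249)
  siemens <- siemens / sum(siemens)
  list(MPRAGE = siemens, T1w = siemens, T2w = siemens, T2wFLAIR = siemens,
       T1wFLAIR = c(siemens * 0.7, Skyra = 0.3),
       T2wGRE = c(`Signa HDxt` = 1),
       IR = c(`Signa HDxt` = 1))
}

default_modality_offsets <- function() {
  c(MPRAGE = 0, T1w = 2, T2w = 1, T1wFLAIR = 2, T2wFLAIR = 1, T2wGRE = 0, IR = 1)
}

default_modality_noise_sd <- function() {
  c(MPRAGE = 5, T1w = 7, T2w = 5.5, T1wFLAIR = 6.5, T2wFLAIR = 5.5,
    T2wGRE = 8, IR = 6.5)
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the statistical structure of a simulated multi-modality brain-age
#' cohort: a truncated-normal age distribution calibrated to target moments,
#' per-modality prevalence and repetition counts, a linear "regression
#' dilution" bias in the predictions (young ages overestimated, old ages
#' underestimated, i.e. slope below 1), an additive participant-level random
#' effect shared by all of a participant's scans, modality-specific offsets
#' and noise, an optional grossly miscalibrated failure modality, optional
#' per-slice predictions, and a null mode with no age signal.
#'
#' @param n_participants number of participants.
#' @param age_bounds numeric length-2, lower and upper age truncation (years).
#' @param age_mean_target target mean of the truncated age distribution.
#' @param age_sd_target target SD of the truncated age distribution; 0 gives a
#'   degenerate distribution at `age_mean_target`.
#' @param female_fraction proportion of female participants.
#' @param modality_table see [default_modality_table()].
#' @param scanner_table named prevalence vector (or a named list of such
#'   vectors keyed by modality); see [default_scanner_table()].
#' @param bias_intercept,bias_slope generating linear bias of the predictions:
#'   `prediction = bias_intercept + bias_slope * age + ...`. The slope must be
#'   nonzero.
#' @param modality_offsets named numeric, additive offset (years) per modality.
#' @param modality_noise_sd named numeric, scan-level noise SD (years) per
#'   modality.
#' @param subject_effect_sd SD (years) of the participant-level random effect.
#' @param failure_modality `NULL`, or a list with `modality`, `intercept`,
#'   `slope`, `noise_sd` giving a modality its own (mis)calibration, emulating
#'   a modality on which the prediction model fails outright.
#' @param null_mode logical; if `TRUE` predictions are produced by
#'   [generate_null_predictions()] and carry no age information.
#' @param null_features number of pure-noise features used in null mode.
#' @param slice_count number of per-slice predictions per scan (0 disables
#'   slice emission; when positive, scan-level predictions are left unset and
#'   must be produced by [aggregate_slices()]).
#' @param slice_noise_sd SD (years) of independent slice-level noise.
#' @param seed master integer seed for the generator.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 1540,
                             age_bounds = c(15, 95),
                             age_mean_target = 53.5,
                             age_sd_target = 18,
                             female_fraction = 1039 / 1540,
                             modality_table = default_modality_table(),
                             scanner_table = default_scanner_table(),
                             bias_intercept = 15.2,
                             bias_slope = 0.7,
                             modality_offsets = default_modality_offsets(),
                             modality_noise_sd = default_modality_noise_sd(),
                             subject_effect_sd = 3,
                             failure_modality = list(modality = "T2wGRE",
                                                     intercept = 55,
                                                     slope = 0.1,
                                                     noise_sd = 8),
                             null_mode = FALSE,
                             null_features = 10,
                             slice_count = 80,
                             slice_noise_sd = 4,
                             seed = 1L) {
  stopifnot(n_participants >= 1,
            length(age_bounds) == 2, age_bounds[1] < age_bounds[2],
            age_sd_target >= 0, subject_effect_sd >= 0, slice_noise_sd >= 0,
            all(modality_noise_sd >= 0),
            female_fraction >= 0, female_fraction <= 1,
            bias_slope != 0,
            slice_count >= 0, null_features >= 1,
            length(modality_table) >= 1)
  for (m in names(modality_table)) {
    entry <- modality_table[[m]]
    if (is.null(entry$prevalence) || entry$prevalence <= 0 || entry$prevalence > 1)
      stop("modality_table[['", m, "']]$prevalence must be in (0, 1]")
    reps <- entry$repetitions
    if (abs(sum(reps) - 1) > 1e-8)
      stop("repetition distribution for modality '", m, "' must sum to 1")
    if (!all(names(reps) %in% as.character(1:4)))
      stop("repetition counts must be labelled 1..4 (modality '", m, "')")
  }
  if (is.list(scanner_table)) {
    lapply(scanner_table, function(s) stopifnot(abs(sum(s) - 1) < 1e-8))
  } else {
    stopifnot(abs(sum(scanner_table) - 1) < 1e-8)
  }
  if (!is.null(failure_modality)) {
    stopifnot(is.list(failure_modality),
              all(c("modality", "intercept", "slope", "noise_sd") %in%
                    names(failure_modality)),
              failure_modality$noise_sd >= 0)
  }
  structure(list(n_participants = as.integer(n_participants),
                 age_bounds = as.numeric(age_bounds),
                 age_mean_target = age_mean_target,
                 age_sd_target = age_sd_target,
                 female_fraction = female_fraction,
                 modality_table = modality_table,
                 scanner_table = scanner_table,
                 bias_intercept = bias_intercept,
                 bias_slope = bias_slope,
                 modality_offsets = modality_offsets,
                 modality_noise_sd = modality_noise_sd,
                 subject_effect_sd = subject_effect_sd,
                 failure_modality = failure_modality,
                 null_mode = isTRUE(null_mode),
                 null_features = as.integer(null_features),
                 slice_count = as.integer(slice_count),
                 slice_noise_sd = slice_noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic brain-age cohort generator\n")
  cat(sprintf("  %d participants, ages %g-%g (target mean %g, SD %g)\n",
              x$n_participants, x$age_bounds[1], x$age_bounds[2],
              x$age_mean_target, x$age_sd_target))
  cat(sprintf("  %d modalities; bias: %g + %g * age; subject effect SD %g\n",
              length(x$modality_table), x$bias_intercept, x$bias_slope,
              x$subject_effect_sd))
  if (x$null_mode) cat("  null mode: predictions carry no age signal\n")
  if (!is.null(x$failure_modality))
    cat(sprintf("  failure modality: %s (%g + %g * age, noise SD %g)\n",
                x$failure_modality$modality, x$failure_modality$intercept,
                x$failure_modality$slope, x$failure_modality$noise_sd))
  invisible(x)
}

#' Generator configuration matched to a bias-estimation-set simulation
#'
#' A compact configuration for parameter-recovery simulations sized like a
#' bias-estimation sample: 186 participants carrying on average 4.52 scans
#' each (about 841 scans) over four modalities, predictions following
#' `intercept + slope * age` plus a 3-year participant effect and 5-year scan
#' noise, with no modality offsets, no failure modality and no slice emission.
#'
#' @param seed master seed.
#' @param bias_intercept,bias_slope generating bias parameters.
#' @return A `generator_config`.
#' @export
bias_estimation_sim_config <- function(seed = 1L,
                                       bias_intercept = 15.2,
                                       bias_slope = 0.7) {
  modalities <- list(
    MPRAGE   = list(prevalence = 1, repetitions = c(`1` = 1)),
    T1w      = list(prevalence = 1, repetitions = c(`1` = 0.9, `2` = 0.1)),
    T2w      = list(prevalence = 1, repetitions = c(`1` = 0.68, `2` = 0.32)),
    T2wFLAIR = list(prevalence = 1, repetitions = c(`1` = 0.9, `2` = 0.1))
  )
  generator_config(
    n_participants = 186,
    modality_table = modalities,
    bias_intercept = bias_intercept,
    bias_slope = bias_slope,
    modality_offsets = c(MPRAGE = 0, T1w = 0, T2w = 0, T2wFLAIR = 0),
    modality_noise_sd = c(MPRAGE = 5, T1w = 5, T2w = 5, T2wFLAIR = 5),
    subject_effect_sd = 3,
    failure_modality = NULL,
    slice_count = 0,
    seed = seed)
}

#' Write / read a generator configuration as YAML
#'
#' Field names in the file match the arguments of [generator_config()].
#'
#' @param cfg a `generator_config`.
#' @param path file path.
#' @return `read_generator_config()` returns a `generator_config`.
#' @export
write_generator_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "generator_config"))
  out <- unclass(cfg)
  out$modality_table <- lapply(out$modality_table, function(m) {
    list(prevalence = m$prevalence, repetitions = as.list(m$repetitions))
  })
  # named numeric vectors must become lists, or YAML drops their names
  out$scanner_table <- if (is.list(out$scanner_table))
    lapply(out$scanner_table, as.list) else as.list(out$scanner_table)
  out$modality_offsets <- as.list(out$modality_offsets)
  out$modality_noise_sd <- as.list(out$modality_noise_sd)
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$modality_table <- lapply(raw$modality_table, function(m) {
    list(prevalence = m$prevalence, repetitions = unlist(m$repetitions))
  })
  st <- raw$scanner_table
  if (is.list(st) && !is.list(st[[1]])) raw$scanner_table <- unlist(st)
  if (is.list(st) && is.list(st[[1]])) raw$scanner_table <- lapply(st, unlist)
  raw$modality_offsets <- unlist(raw$modality_offsets)
  raw$modality_noise_sd <- unlist(raw$modality_noise_sd)
  do.call(generator_config, raw)
}
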