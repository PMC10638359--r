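#' Moments of a truncated normal distribution
#'
#' Closed-form mean and SD of a normal distribution with location `mu` and
#' scale `sigma` truncated to `[lower, upper]`.
#'
#' @param mu,sigma location and scale of the untruncated normal (sigma > 0).
#' @param lower,upper truncation bounds.
#' @return Named numeric vector `c(mean, sd)`.
#' @export
truncated_normal_moments <- function(mu, sigma, lower, upper) {
  stopifnot(sigma > 0, lower < upper)
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  if (z <= 0) stop("truncation interval has no mass under (mu, sigma)")
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  r <- (da - db) / z
  m <- mu + sigma * r
  v <- sigma^2 * (1 + (a * da - b * db) / z - r^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

#' Calibrate a truncated normal to target mean and SD
#'
#' Numerically solves for the underlying (mu, sigma) such that the truncated
#' distribution on `bounds` has exactly the target mean and SD. Errors when no
#' parameter pair achieves the targets (e.g. an SD unattainable on the given
#' interval).
#'
#' @param target_mean,target_sd target moments of the truncated distribution.
#' @param bounds numeric length-2 truncation interval.
#' @param tol acceptable residual on each moment.
#' @return List with `mu`, `sigma`, `achieved_mean`, `achieved_sd`.
#' @export
calibrate_truncated_normal <- function(target_mean, target_sd, bounds,
                                       tol = 1e-6) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2], target_sd > 0)
  if (target_mean <= bounds[1] || target_mean >= bounds[2])
    stop("calibration error: target mean outside the truncation bounds")
  obj <- function(par) {
    mo <- tryCatch(
      truncated_normal_moments(par[1], exp(par[2]), bounds[1], bounds[2]),
      error = function(e) c(mean = Inf, sd = Inf))
    if (!all(is.finite(mo))) return(1e10)
    (mo[["mean"]] - target_mean)^2 + (mo[["sd"]] - target_sd)^2
  }
  start <- c(target_mean, log(target_sd))
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  mo <- tryCatch(truncated_normal_moments(mu, sigma, bounds[1], bounds[2]),
                 error = function(e) c(mean = Inf, sd = Inf))
  if (!all(is.finite(mo)) ||
      abs(mo[["mean"]] - target_mean) > tol || abs(mo[["sd"]] - target_sd) > tol)
    stop(sprintf(paste0("calibration error: no (mu, sigma) reaches mean %g, ",
                        "SD %g on [%g, %g] (best: mean %.6f, SD %.6f)"),
                 target_mean, target_sd, bounds[1], bounds[2],
                 mo[["mean"]], mo[["sd"]]))
  list(mu = mu, sigma = sigma,
       achieved_mean = mo[["mean"]], achieved_sd = mo[["sd"]])
}

#' Sample chronological ages from the calibrated cohort distribution
#'
#' Draws from a truncated normal on `cfg$age_bounds` whose underlying
#' parameters are calibrated so the truncated mean and SD equal the configured
#' targets. A zero target SD returns the degenerate distribution at the target
#' mean.
#'
#' @param n number of draws.
#' @param cfg a [generator_config()].
#' @param seed integer seed (defaults to the config's "ages" stream).
#' @return Numeric vector of ages (years), all within `cfg$age_bounds`.
#' @export
sample_ages <- function(n, cfg, seed = derive_seed(cfg$seed, "ages")) {
  stopifnot(n >= 1, inherits(cfg, "generator_config"))
  if (cfg$age_sd_target == 0) return(rep(cfg$age_mean_target, n))
  cal <- calibrate_truncated_normal(cfg$age_mean_target, cfg$age_sd_target,
                                    cfg$age_bounds)
  lo <- stats::pnorm((cfg$age_bounds[1] - cal$mu) / cal$sigma)
  hi <- stats::pnorm((cfg$age_bounds[2] - cal$mu) / cal$sigma)
  with_seed(seed, {
    u <- stats::runif(n, lo, hi)
    cal$mu + cal$sigma * stats::qnorm(u)
  })
}

#' Build a synthetic cohort of scans (without predictions)
#'
#' Each participant receives one age, one sex, a set of modalities drawn from
#' the per-modality prevalences, a repetition count per carried modality, and
#' a scanner model per scan. Participants drawing no modality at all are given
#' a single scan of the most prevalent modality so every participant
#' contributes at least one scan.
#'
#' @param cfg a [generator_config()].
#' @return Data frame with columns `participant_id`, `age`, `sex`, `modality`,
#'   `scanner`, `repetition`; one row per scan, `(participant_id, modality,
#'   repetition)` unique.
#' @export
build_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (length(cfg$modality_table) == 0)
    stop("configuration error: empty modality_table")
  n <- cfg$n_participants
  ages <- sample_ages(n, cfg)
  mods <- names(cfg$modality_table)
  with_seed(derive_seed(cfg$seed, "cohort"), {
    sex <- ifelse(stats::runif(n) < cfg$female_fraction, "F", "M")
    reps_per <- matrix(0L, nrow = n, ncol = length(mods),
                       dimnames = list(NULL, mods))
    for (m in mods) {
      entry <- cfg$modality_table[[m]]
      carrier <- stats::runif(n) < entry$prevalence
      k <- sum(carrier)
      if (k > 0) {
        counts <- as.integer(names(entry$repetitions))
        reps_per[carrier, m] <- sample(counts, k, replace = TRUE,
                                       prob = entry$repetitions)
      }
    }
    none <- rowSums(reps_per) == 0
    if (any(none)) {
      top <- mods[which.max(vapply(cfg$modality_table, `[[`, 0, "prevalence"))]
      reps_per[none, top] <- 1L
    }
    rows <- vector("list", length(mods))
    for (j in seq_along(mods)) {
      m <- mods[j]
      cnt <- reps_per[, j]
      who <- which(cnt > 0)
      if (!length(who)) next
      pid <- rep(who, cnt[who])
      rep_idx <- sequence(cnt[who])
      rows[[j]] <- data.frame(p = pid, modality = m, repetition = rep_idx,
                              stringsAsFactors = FALSE)
    }
    scans <- do.call(rbind, rows)
    scans <- scans[order(scans$p, scans$modality, scans$repetition), ]
    scan_tab <- cfg$scanner_table
    if (is.list(scan_tab)) {
      scanner <- character(nrow(scans))
      for (m in unique(scans$modality)) {
        tab <- scan_tab[[m]]
        if (is.null(tab)) stop("no scanner table for modality '", m, "'")
        idx <- scans$modality == m
        scanner[idx] <- sample(names(tab), sum(idx), replace = TRUE, prob = tab)
      }
    } else {
      scanner <- sample(names(scan_tab), nrow(scans), replace = TRUE,
                        prob = scan_tab)
    }
    data.frame(participant_id = sprintf("P%05d", scans$p),
               age = ages[scans$p],
               sex = sex[scans$p],
               modality = scans$modality,
               scanner = scanner,
               repetition = scans$repetition,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Generate biased brain-age predictions for a cohort
#'
#' Predictions follow the generating model
#' `bias_intercept + bias_slope * age + modality_offset + subject_effect +
#' scan_noise`; the configured failure modality instead uses its own
#' intercept, slope and noise. With `slice_count > 0`, per-slice predictions
#' (scan value plus independent slice noise) are emitted in columns
#' `slice_001..` and the scan-level `predicted_brain_age` is left `NA`, to be
#' produced by [aggregate_cohort_slices()].
#'
#' @param cohort output of [build_cohort()].
#' @param cfg the [generator_config()] used to build it (not in null mode).
#' @return The cohort with a `predicted_brain_age` column (and slice columns
#'   when configured).
#' @export
generate_predictions <- function(cohort, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$null_mode)
    stop("cfg is in null mode; use generate_null_predictions()")
  fail <- cfg$failure_modality
  known <- names(cfg$modality_offsets)
  if (!is.null(fail)) known <- union(known, fail$modality)
  unknown <- setdiff(unique(cohort$modality), known)
  if (length(unknown))
    stop("labeling error: modalities in cohort but not in config: ",
         paste(unknown, collapse = ", "))
  with_seed(derive_seed(cfg$seed, "predictions"), {
    pid <- factor(cohort$participant_id)
    subj_eff <- stats::rnorm(nlevels(pid), 0, cfg$subject_effect_sd)[as.integer(pid)]
    is_fail <- if (is.null(fail)) rep(FALSE, nrow(cohort)) else
      cohort$modality == fail$modality
    intercept <- ifelse(is_fail, fail$intercept %||% 0, cfg$bias_intercept)
    slope <- ifelse(is_fail, fail$slope %||% 0, cfg$bias_slope)
    offset <- ifelse(is_fail, 0, cfg$modality_offsets[cohort$modality])
    noise_sd <- ifelse(is_fail, fail$noise_sd %||% 0,
                       cfg$modality_noise_sd[cohort$modality])
    value <- intercept + slope * cohort$age + offset + subj_eff +
      stats::rnorm(nrow(cohort), 0, noise_sd)
    if (cfg$slice_count > 0) {
      slices <- matrix(stats::rnorm(nrow(cohort) * cfg$slice_count,
                                    mean = value, sd = cfg$slice_noise_sd),
                       nrow = nrow(cohort))
      colnames(slices) <- sprintf("slice_%03d", seq_len(cfg$slice_count))
      cohort$predicted_brain_age <- NA_real_
      cohort <- cbind(cohort, as.data.frame(slices))
    } else {
      cohort$predicted_brain_age <- value
    }
    cohort
  })
}

#' Generate null predictions carrying no age information
#'
#' Emulates an honestly fitted but uninformative learner: an ordinary
#' least-squares predictor of age on pure-noise features is trained on a
#' separate draw of ages from the cohort distribution and then evaluated on
#' fresh noise features for every scan. The predictions are asymptotically
#' uncorrelated with age, yet have the reduced variance of a fitted learner
#' (about `p/n` times the age variance).
#'
#' @param cohort output of [build_cohort()].
#' @param cfg a [generator_config()] with `null_mode = TRUE`.
#' @return The cohort with a `predicted_brain_age` column.
#' @export
generate_null_predictions <- function(cohort, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!cfg$null_mode) stop("cfg must have null_mode = TRUE")
  p <- cfg$null_features
  n_train <- max(nrow(cohort), 50L)
  if (p >= n_train - 1)
    stop("ill-posed configuration: feature count (", p,
         ") must be well below the training sample size (", n_train, ")")
  train_ages <- sample_ages(n_train, cfg, derive_seed(cfg$seed, "null-train-ages"))
  with_seed(derive_seed(cfg$seed, "null"), {
    x_train <- matrix(stats::rnorm(n_train * p), n_train, p)
    beta <- stats::lm.fit(cbind(1, x_train), train_ages)$coefficients
    x_new <- matrix(stats::rnorm(nrow(cohort) * p), nrow(cohort), p)
    cohort$predicted_brain_age <- drop(cbind(1, x_new) %*% beta)
    cohort
  })
}

#' Median aggregation of per-slice predictions
#'
#' The scan-level brain age is the median of the slice-wise predictions; even
#' counts use the midpoint of the two central values.
#'
#' @param slice_predictions nonempty numeric vector of per-slice predictions.
#' @return The median, in years.
#' @export
aggregate_slices <- function(slice_predictions) {
  if (length(slice_predictions) == 0)
    stop("cannot aggregate an empty set of slice predictions")
  stats::median(slice_predictions)
}

#' Fill scan-level predictions from slice columns
#'
#' @param cohort a cohort with `slice_*` columns.
#' @param drop_slices drop the slice columns after aggregation.
#' @return The cohort with `predicted_brain_age` set to the per-scan median.
#' @export
aggregate_cohort_slices <- function(cohort, drop_slices = TRUE) {
  slice_cols <- grep("^slice_\\d+$", names(cohort), value = TRUE)
  if (!length(slice_cols)) stop("cohort has no slice_* columns")
  m <- as.matrix(cohort[, slice_cols, drop = FALSE])
  cohort$predicted_brain_age <- apply(m, 1, stats::median)
  if (drop_slices) cohort <- cohort[, setdiff(names(cohort), slice_cols)]
  cohort
}

#' Write / read a cohort as CSV
#'
#' UTF-8, "." decimal separator, missing values as empty fields. Columns:
#' `participant_id, age, sex, modality, scanner, repetition,
#' predicted_brain_age` plus optional `slice_*` columns.
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @return `read_cohort()` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(participant_id = "character"))
  need <- c("participant_id", "age", "sex", "modality", "scanner", "repetition")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols))
    stop("cohort file lacks columns: ", paste(missing_cols, collapse = ", "))
  out
}
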