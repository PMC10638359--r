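#' Bootstrap specification for accuracy metrics
#'
#' @param base_reps base number of bootstrap replicates; the effective count
#'   is `base_reps * N_r` per modality and `base_reps * N_r * N_m` pooled,
#'   where `N_r` is the maximum number of repetitions of a modality within a
#'   participant and `N_m` the number of modalities.
#' @param alpha complement of the confidence level (default 0.05).
#' @param bonferroni_m number of simultaneous comparisons dividing `alpha`;
#'   `NULL` defaults to the number of rows of the emitted accuracy table.
#' @param seed integer seed.
#' @return An object of class `bootstrap_spec`.
#' @export
bootstrap_spec <- function(base_reps = 10000, alpha = 0.05,
                           bonferroni_m = NULL, seed = 1L) {
  stopifnot(base_reps >= 1, alpha > 0, alpha < 1,
            is.null(bonferroni_m) || bonferroni_m >= 1)
  structure(list(base_reps = as.integer(base_reps), alpha = alpha,
                 bonferroni_m = bonferroni_m, seed = as.integer(seed)),
            class = "bootstrap_spec")
}

#' Constrained coefficient of determination
#'
#' R-squared of the model `brain age = chronological age + error` (slope
#' fixed at 1, intercept at 0): `R2 = 1 - RSS/TSS` with
#' `RSS = sum((prediction - age)^2)` and the total sum of squares taken about
#' the mean of the predictions, `TSS = sum((prediction - mean(prediction))^2)`.
#' Unlike the ordinary R-squared it can be negative when the predictions
#' poorly follow the identity line. Constant predictions (TSS = 0) make the
#' statistic undefined; `NA` is returned with a warning.
#'
#' @param predictions predicted brain ages.
#' @param ages chronological ages.
#' @return A single number, at most 1 (or `NA` when undefined).
#' @export
constrained_r2 <- function(predictions, ages) {
  stopifnot(length(predictions) == length(ages), length(ages) >= 2)
  rss <- sum((predictions - ages)^2)
  tss <- sum((predictions - mean(predictions))^2)
  if (tss == 0) {
    warning("constant predictions: constrained R-squared is undefined")
    return(NA_real_)
  }
  1 - rss / tss
}

# metrics for one resampled set of scans; r2 computed inline (no warning
# machinery inside the bootstrap loop)
.acc_metrics <- function(pred, age) {
  mae <- mean(abs(pred - age))
  r <- if (stats::sd(pred) == 0 || stats::sd(age) == 0) NA_real_ else
    stats::cor(pred, age)
  tss <- sum((pred - mean(pred))^2)
  r2 <- if (tss == 0) NA_real_ else 1 - sum((pred - age)^2) / tss
  c(mae, r, r2)
}

#' Repeated-measures bootstrap of accuracy metrics
#'
#' Accuracy (MAE, Pearson correlation, constrained R-squared) is computed on
#' resamples that draw participants with replacement and, within each drawn
#' participant, one repetition uniformly at random -- so repeated scans of a
#' participant never inflate the metrics. Reported are the across-replicate
#' mean and the percentile interval at level `1 - alpha/bonferroni_m`.
#' Per-modality resamples use `base_reps * N_r` replicates; the pooled
#' resample (one scan per participant-modality pair) uses
#' `base_reps * N_r * N_m`.
#'
#' @param records scans with `predicted_brain_age`, `age`, `participant_id`,
#'   `modality`.
#' @param spec a [bootstrap_spec()].
#' @param pooled also emit a row pooling all modalities.
#' @param modalities optional subset of modalities to report.
#' @return Data frame with one row per modality (plus `"(pooled)"`), columns
#'   `modality, n_participants, n_replicates, mae, mae_lo, mae_hi, r, r_lo,
#'   r_hi, r2, r2_lo, r2_hi`; attributes record `alpha`, `bonferroni_m`,
#'   `N_r`, `N_m` and skipped modalities.
#' @export
bootstrap_accuracy <- function(records, spec = bootstrap_spec(),
                               pooled = FALSE, modalities = NULL) {
  stopifnot(inherits(spec, "bootstrap_spec"))
  if (!is.null(modalities))
    records <- records[records$modality %in% modalities, , drop = FALSE]
  records <- records[!is.na(records$predicted_brain_age), , drop = FALSE]
  mods <- sort(unique(records$modality))
  pm_key <- paste(records$participant_id, records$modality, sep = "\r")
  n_r <- max(table(pm_key))
  n_m <- length(mods)
  n_rows <- n_m + as.integer(pooled)
  m_adj <- spec$bonferroni_m %||% n_rows
  probs <- c(spec$alpha / m_adj / 2, 1 - spec$alpha / m_adj / 2)
  skipped <- character()
  rows <- list()

  boot_one <- function(idx_by_group, group_of_p, pred, age, reps, seed) {
    starts <- cumsum(c(0L, lengths(idx_by_group)[-length(idx_by_group)]))
    lens <- lengths(idx_by_group)
    flat <- unlist(idx_by_group, use.names = FALSE)
    n_p <- length(group_of_p)
    out <- matrix(NA_real_, nrow = reps, ncol = 3)
    with_seed(seed, {
      for (b in seq_len(reps)) {
        ps <- sample.int(n_p, n_p, replace = TRUE)
        gs <- unlist(group_of_p[ps], use.names = FALSE)
        pick <- flat[starts[gs] + 1L + floor(stats::runif(length(gs)) * lens[gs])]
        out[b, ] <- .acc_metrics(pred[pick], age[pick])
      }
    })
    out
  }

  summarize <- function(label, boot, n_p, reps) {
    q <- apply(boot, 2, stats::quantile, probs = probs, na.rm = TRUE)
    data.frame(modality = label, n_participants = n_p, n_replicates = reps,
               mae = mean(boot[, 1], na.rm = TRUE),
               mae_lo = q[1, 1], mae_hi = q[2, 1],
               r = mean(boot[, 2], na.rm = TRUE),
               r_lo = q[1, 2], r_hi = q[2, 2],
               r2 = mean(boot[, 3], na.rm = TRUE),
               r2_lo = q[1, 3], r2_hi = q[2, 3],
               stringsAsFactors = FALSE)
  }

  for (m in mods) {
    sub <- which(records$modality == m)
    by_p <- split(sub, records$participant_id[sub])
    if (length(by_p) < 2) {
      skipped <- c(skipped, m)
      message("modality ", m, " skipped: fewer than 2 participants")
      next
    }
    reps <- spec$base_reps * n_r
    boot <- boot_one(by_p, as.list(seq_along(by_p)),
                     records$predicted_brain_age, records$age, reps,
                     derive_seed(spec$seed, paste0("boot-", m)))
    rows[[m]] <- summarize(m, boot, length(by_p), reps)
  }

  if (pooled) {
    by_pm <- split(seq_len(nrow(records)), pm_key)
    p_of_pm <- sub("\r.*$", "", names(by_pm))
    group_of_p <- split(seq_along(by_pm), p_of_pm)
    if (length(group_of_p) >= 2) {
      reps <- spec$base_reps * n_r * n_m
      boot <- boot_one(by_pm, group_of_p,
                       records$predicted_brain_age, records$age, reps,
                       derive_seed(spec$seed, "boot-pooled"))
      rows[["(pooled)"]] <- summarize("(pooled)", boot,
                                      length(group_of_p), reps)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- spec$alpha
  attr(out, "bonferroni_m") <- m_adj
  attr(out, "N_r") <- n_r
  attr(out, "N_m") <- n_m
  attr(out, "skipped") <- skipped
  out
}

#' Slope-removal tests on brain-PAD
#'
#' Fits `brain-PAD ~ modality * age` by least squares over all scans (scans
#' treated as independent, matching the reported omnibus degrees of freedom;
#' the repeated-measures caveat is recorded in the result). Returns the
#' omnibus F-test that all modality-specific slopes are zero, per-modality
#' slope t-tests (uncorrected, as post-hoc tests), and a contrast testing the
#' mean slope over a caller-chosen modality subset (e.g. excluding a failure
#' modality).
#'
#' @param records scans with `modality` and `age`.
#' @param pad brain-PAD values (typically bias-corrected), one per scan.
#' @param average_subset modalities over which to average the slope for the
#'   contrast test (default: all).
#' @return List with `omnibus` (`F`, `df1`, `df2`, `p`), `slopes` (data
#'   frame), `average` (estimate, se, t, df, p, modalities) and `caveat`.
#' @export
pad_slope_test <- function(records, pad, average_subset = NULL) {
  stopifnot(length(pad) == nrow(records))
  d <- data.frame(pad = pad, modality = factor(records$modality),
                  age = records$age)
  counts <- table(d$modality)
  if (nlevels(d$modality) < 2 || sum(counts >= 3) < 2) {
    message("fewer than 2 modalities with 3+ scans; fitting reduced model")
    fit <- stats::lm(pad ~ age, data = d)
    s <- suppressWarnings(summary(fit))$coefficients
    slopes <- data.frame(modality = levels(d$modality)[1],
                         slope = s["age", 1], se = s["age", 2],
                         t = s["age", 3], p = s["age", 4])
    return(list(omnibus = NULL, slopes = slopes, average = NULL,
                caveat = "single-modality data: reduced model pad ~ age"))
  }
  full <- stats::lm(pad ~ 0 + modality + modality:age, data = d)
  reduced <- stats::lm(pad ~ 0 + modality, data = d)
  an <- stats::anova(reduced, full)
  omnibus <- list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2],
                  p = an$`Pr(>F)`[2])
  # suppress the "essentially perfect fit" note on exactly linear inputs
  s <- suppressWarnings(summary(full))$coefficients
  slope_rows <- grep(":age$", rownames(s))
  slope_names <- sub("^modality", "", sub(":age$", "", rownames(s)[slope_rows]))
  slopes <- data.frame(modality = slope_names,
                       slope = s[slope_rows, 1], se = s[slope_rows, 2],
                       t = s[slope_rows, 3], p = s[slope_rows, 4],
                       row.names = NULL, stringsAsFactors = FALSE)
  subset_mods <- average_subset %||% slopes$modality
  subset_mods <- intersect(subset_mods, slopes$modality)
  lvec <- rep(0, length(stats::coef(full)))
  names(lvec) <- names(stats::coef(full))
  lvec[rownames(s)[slope_rows][slopes$modality %in% subset_mods]] <-
    1 / length(subset_mods)
  est <- sum(lvec * stats::coef(full))
  se <- sqrt(drop(t(lvec) %*% suppressWarnings(stats::vcov(full)) %*% lvec))
  tval <- est / se
  dfres <- stats::df.residual(full)
  average <- list(estimate = est, se = se, t = tval, df = dfres,
                  p = 2 * stats::pt(-abs(tval), dfres),
                  modalities = subset_mods)
  list(omnibus = omnibus, slopes = slopes, average = average,
       caveat = paste("scans treated as independent; repeated measures",
                      "within participants are not modeled here"))
}

#' Mixed-effects within-subject comparison of absolute brain-PAD
#'
#' Fits `|brain-PAD| ~ modality + subject + (1|subject)` by REML: fixed
#' effects for each subject and each modality plus a subject random
#' intercept, accounting for the repeated measures when comparing modalities
#' within subjects. Reports, per modality, the contrast against the
#' reference modality (`beta_m - beta_ref`) with Wald confidence intervals
#' (Bonferroni-adjusted across contrasts by default), a "population" MAE
#' estimate `MAE-hat_m = mean(s_i) + beta_m`, and the across-modality mean of
#' the latter. Modalities never observed together with the reference within
#' a subject are flagged as between-subject-only comparisons. Subject
#' appearing both as fixed effect and random intercept follows the stated
#' estimand; the random-intercept variance is then weakly identified and
#' convergence messages are captured and reported rather than silenced.
#'
#' @param records scans with `participant_id` and `modality`.
#' @param pad brain-PAD values (typically bias-corrected), one per scan.
#' @param reference reference modality label (default `"MPRAGE"`).
#' @param alpha complement of the confidence level.
#' @param bonferroni adjust contrast CIs/p-values across the contrasts.
#' @return List with `contrasts`, `mae_hat`, `total_mae`, `reference`,
#'   `converged`, `messages` and the fitted `model`.
#' @export
mixed_abs_pad_model <- function(records, pad, reference = "MPRAGE",
                                alpha = 0.05, bonferroni = TRUE) {
  stopifnot(length(pad) == nrow(records))
  mods <- unique(as.character(records$modality))
  if (!reference %in% mods)
    stop("reference modality '", reference, "' not present")
  if (length(mods) < 2) stop("need at least 2 modalities")
  d <- data.frame(y = abs(pad),
                  subject = factor(records$participant_id),
                  modality = stats::relevel(factor(records$modality),
                                            ref = reference))
  if (stats::sd(d$y) < 1e-8) {
    # responses numerically identical: every contrast is zero and REML is
    # meaningless; return the degenerate answer rather than a failed fit
    mod_names <- setdiff(levels(d$modality), reference)
    ybar <- mean(d$y)
    zero <- data.frame(modality = mod_names, estimate = 0, se = 0,
                       lo = 0, hi = 0, z = NA_real_, p = NA_real_,
                       within_subject = NA, stringsAsFactors = FALSE)
    all_mods <- levels(d$modality)
    mh <- data.frame(modality = all_mods, estimate = ybar, se = 0,
                     lo = ybar, hi = ybar, stringsAsFactors = FALSE)
    return(list(contrasts = zero, mae_hat = mh,
                total_mae = list(estimate = ybar, se = 0,
                                 lo = ybar, hi = ybar),
                reference = reference, converged = TRUE,
                messages = "degenerate: zero-variance response",
                model = NULL))
  }
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(y ~ 0 + subject + modality + (1 | subject), data = d,
               REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore")),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  subj_idx <- grep("^subject", names(fe))
  mod_idx <- grep("^modality", names(fe))
  mod_names <- sub("^modality", "", names(fe)[mod_idx])

  # within-subject pairing with the reference
  has_ref <- unique(d$subject[d$modality == reference])
  paired <- vapply(mod_names, function(m) {
    length(intersect(unique(d$subject[d$modality == m]), has_ref)) > 0
  }, logical(1))

  m_adj <- if (bonferroni) length(mod_idx) else 1
  zq <- stats::qnorm(1 - alpha / m_adj / 2)
  est <- unname(fe[mod_idx])
  se <- sqrt(diag(V)[mod_idx])
  contrasts <- data.frame(modality = mod_names, estimate = est, se = se,
                          lo = est - zq * se, hi = est + zq * se,
                          z = est / se,
                          p = 2 * stats::pnorm(-abs(est / se)),
                          within_subject = paired,
                          row.names = NULL, stringsAsFactors = FALSE)

  all_mods <- c(reference, mod_names)
  n_subj <- length(subj_idx)
  lmat <- matrix(0, nrow = length(all_mods), ncol = length(fe),
                 dimnames = list(all_mods, names(fe)))
  lmat[, subj_idx] <- 1 / n_subj
  for (m in mod_names) lmat[m, paste0("modality", m)] <- 1
  mh_est <- drop(lmat %*% fe)
  mh_se <- sqrt(diag(lmat %*% V %*% t(lmat)))
  mae_hat <- data.frame(modality = all_mods, estimate = mh_est, se = mh_se,
                        lo = mh_est - zq * mh_se, hi = mh_est + zq * mh_se,
                        row.names = NULL, stringsAsFactors = FALSE)
  ltot <- colMeans(lmat)
  tot_est <- sum(ltot * fe)
  tot_se <- sqrt(drop(t(ltot) %*% V %*% ltot))
  list(contrasts = contrasts, mae_hat = mae_hat,
       total_mae = list(estimate = tot_est, se = tot_se,
                        lo = tot_est - zq * tot_se,
                        hi = tot_est + zq * tot_se),
       reference = reference,
       converged = length(msgs) == 0,
       messages = msgs,
       model = fit)
}
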