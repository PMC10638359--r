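#' Build the participants-by-items matrix of brain-PAD
#'
#' Rows are participants; columns ("items") are modality/repetition pairs;
#' cells hold the bias-corrected brain-PAD or `NA`. Dropping rules are
#' applied in order: first participants with fewer than `min_items` observed
#' items, then items missing in more than `max_missing` of the retained rows.
#'
#' @param records scans with `participant_id`, `modality`, `repetition`.
#' @param pad bias-corrected brain-PAD values, one per scan.
#' @param item_grid optional data frame `(modality, repetition)` fixing the
#'   item set and order (e.g. 6 modality-sources x 4 repetitions = 24 items);
#'   default: all pairs observed in the data.
#' @param min_items minimum observed items for a participant to be retained
#'   (default 3).
#' @param max_missing maximum missing fraction for an item to be retained
#'   (default 0.95).
#' @return An object of class `item_matrix`: list with the numeric matrix
#'   `X`, `dropped_rows`, `dropped_items`, `n_rows`, `n_items`.
#' @export
build_item_matrix <- function(records, pad, item_grid = NULL,
                              min_items = 3, max_missing = 0.95) {
  stopifnot(length(pad) == nrow(records))
  if (is.null(item_grid)) {
    item_grid <- unique(data.frame(modality = records$modality,
                                   repetition = records$repetition,
                                   stringsAsFactors = FALSE))
    item_grid <- item_grid[order(item_grid$modality, item_grid$repetition), ]
  }
  items <- paste0(item_grid$modality, "_r", item_grid$repetition)
  key <- paste0(records$modality, "_r", records$repetition)
  keep <- key %in% items
  records <- records[keep, , drop = FALSE]
  pad <- pad[keep]
  key <- key[keep]
  ids <- sort(unique(records$participant_id))
  X <- matrix(NA_real_, nrow = length(ids), ncol = length(items),
              dimnames = list(ids, items))
  X[cbind(match(records$participant_id, ids), match(key, items))] <- pad
  observed <- rowSums(!is.na(X))
  dropped_rows <- rownames(X)[observed < min_items]
  X <- X[observed >= min_items, , drop = FALSE]
  if (nrow(X) == 0)
    stop("empty item matrix: every participant has fewer than ",
         min_items, " items")
  miss_frac <- colMeans(is.na(X))
  dropped_items <- colnames(X)[miss_frac > max_missing]
  X <- X[, miss_frac <= max_missing, drop = FALSE]
  if (ncol(X) == 0) stop("empty item matrix: all items dropped")
  structure(list(X = X, dropped_rows = dropped_rows,
                 dropped_items = dropped_items,
                 n_rows = nrow(X), n_items = ncol(X)),
            class = "item_matrix")
}

#' Cronbach's alpha with an F-based confidence interval
#'
#' Internal consistency over an items matrix:
#' `alpha = k/(k-1) * (1 - trace(C)/sum(C))` with `C` the item covariance
#' matrix computed by pairwise deletion (pair-specific means). The
#' confidence bounds use the inverse survival function of the F
#' distribution with `df1 = n_rows - 1` and `df2 = df1 * n_items`:
#' `lower = 1 - (1 - alpha_c) * F^-1(a/2)`,
#' `upper = 1 - (1 - alpha_c) * F^-1(1 - a/2)`, `a = 1 - ci_level`.
#' Qualitative band: >= 0.95 redundant, >= 0.9 excellent, >= 0.8 acceptable,
#' below that questionable or lower.
#'
#' @param x an [build_item_matrix()] result or a numeric matrix (rows =
#'   participants, columns = items).
#' @param ci_level confidence level (default 0.95).
#' @return An object of class `cronbach_alpha`: list with `alpha`, `ci`,
#'   `band`, `n_rows`, `n_items`, `df1`, `df2`.
#' @export
cronbach_alpha <- function(x, ci_level = 0.95) {
  X <- if (inherits(x, "item_matrix")) x$X else as.matrix(x)
  k <- ncol(X)
  n <- nrow(X)
  stopifnot(k >= 2, n >= 2)
  C <- suppressWarnings(stats::cov(X, use = "pairwise.complete.obs"))
  if (any(is.na(diag(C))))
    stop("an item has fewer than 2 observations; cannot form its variance")
  no_overlap <- sum(is.na(C))
  if (no_overlap > 0) C[is.na(C)] <- 0  # item pairs with no overlap carry no information
  total <- sum(C)
  if (total == 0) {
    warning("sum of the covariance matrix is zero: alpha undefined")
    return(structure(list(alpha = NA_real_, ci = c(NA_real_, NA_real_),
                          band = NA_character_, n_rows = n, n_items = k,
                          df1 = n - 1, df2 = (n - 1) * k),
                     class = "cronbach_alpha"))
  }
  alpha_c <- k / (k - 1) * (1 - sum(diag(C)) / total)
  a <- 1 - ci_level
  df1 <- n - 1
  df2 <- df1 * k
  isf <- function(q) stats::qf(q, df1, df2, lower.tail = FALSE)
  ci <- c(1 - (1 - alpha_c) * isf(a / 2), 1 - (1 - alpha_c) * isf(1 - a / 2))
  band <- if (alpha_c >= 0.95) "redundant (>= 0.95)" else
    if (alpha_c >= 0.9) "excellent (>= 0.9)" else
      if (alpha_c >= 0.8) "acceptable (0.8-0.9)" else
        "questionable or lower (< 0.8)"
  structure(list(alpha = alpha_c, ci = ci, band = band,
                 n_rows = n, n_items = k, df1 = df1, df2 = df2,
                 pairs_without_overlap = no_overlap),
            class = "cronbach_alpha")
}

#' @export
print.cronbach_alpha <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f [%.3f, %.3f] (%s)\n",
              x$alpha, x$ci[1], x$ci[2], x$band))
  cat(sprintf("  %d participants x %d items (df1 = %d, df2 = %d)\n",
              x$n_rows, x$n_items, x$df1, x$df2))
  invisible(x)
}

#' Within-subject mean absolute deviation of brain-PAD
#'
#' For each participant with at least two scans, the mean absolute
#' difference between their brain-PADs and their own average; the statistic
#' is the across-participant mean of these deviations, with a bootstrap
#' percentile CI over participants. Because the deviation is taken about the
#' participant's own mean, any participant-level offset (the subject random
#' effect) cancels; the measure reflects scan-to-scan consistency only.
#'
#' @param records scans with `participant_id`.
#' @param pad bias-corrected brain-PAD values, one per scan.
#' @param boot a [bootstrap_spec()] for the CI.
#' @param exclude_modalities modalities dropped before the computation (e.g.
#'   a failure modality).
#' @return List with `estimate` (years), `ci`, `n_participants`,
#'   `per_participant`.
#' @export
within_subject_mad <- function(records, pad,
                               boot = bootstrap_spec(base_reps = 2000),
                               exclude_modalities = NULL) {
  stopifnot(length(pad) == nrow(records))
  if (!is.null(exclude_modalities)) {
    keep <- !(records$modality %in% exclude_modalities)
    records <- records[keep, , drop = FALSE]
    pad <- pad[keep]
  }
  devs <- vapply(split(pad, records$participant_id), function(p) {
    if (length(p) < 2) return(NA_real_)
    mean(abs(p - mean(p)))
  }, 0)
  devs <- devs[!is.na(devs)]
  if (!length(devs)) {
    warning("no participant with 2+ scans: within-subject MAD undefined")
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                n_participants = 0L, per_participant = devs))
  }
  est <- mean(devs)
  ci <- with_seed(derive_seed(boot$seed, "wsmad"), {
    reps <- vapply(seq_len(boot$base_reps), function(i)
      mean(sample(devs, replace = TRUE)), 0)
    stats::quantile(reps, c(boot$alpha / 2, 1 - boot$alpha / 2), names = FALSE)
  })
  list(estimate = est, ci = ci, n_participants = length(devs),
       per_participant = devs)
}

#' Reliability report as JSON
#'
#' @param alpha_result a [cronbach_alpha()] result.
#' @param mad_result a [within_subject_mad()] result.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_reliability_report <- function(alpha_result, mad_result, path) {
  obj <- list(alpha = alpha_result$alpha,
              ci = alpha_result$ci,
              band = alpha_result$band,
              n_rows = alpha_result$n_rows,
              n_items = alpha_result$n_items,
              within_subject_mad = mad_result$estimate,
              within_subject_mad_ci = mad_result$ci,
              n_participants_mad = mad_result$n_participants)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
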