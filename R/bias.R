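#' Specification of a linear bias model
#'
#' The bias of brain-age predictions is modeled as
#' `brain age = f_beta(chronological age) + error`, with `f_beta` linear in
#' age and optionally moderated by modality or scanner model:
#' \describe{
#'   \item{marginal}{one global intercept and slope (2 coefficients);}
#'   \item{by_modality}{one (intercept, slope) pair per modality;}
#'   \item{by_scanner}{one pair per scanner model.}
#' }
#' Fitting is by ordinary least squares or by weighted least squares with
#' inverse group-frequency weights, so that each modality (or scanner)
#' contributes equally to the fit.
#'
#' @param form one of `"marginal"`, `"by_modality"`, `"by_scanner"`.
#' @param fit_method `"OLS"` or `"WLS"`.
#' @param wls_grouping `"modality"` or `"scanner"`; required iff
#'   `fit_method = "WLS"`.
#' @return An object of class `bias_model_spec`.
#' @export
bias_model_spec <- function(form = c("marginal", "by_modality", "by_scanner"),
                            fit_method = c("OLS", "WLS"),
                            wls_grouping = NULL) {
  form <- match.arg(form)
  fit_method <- match.arg(fit_method)
  if (fit_method == "WLS") {
    if (is.null(wls_grouping) || !wls_grouping %in% c("modality", "scanner"))
      stop("WLS requires wls_grouping = 'modality' or 'scanner'")
  } else if (!is.null(wls_grouping)) {
    stop("wls_grouping is only meaningful with fit_method = 'WLS'")
  }
  structure(list(form = form, fit_method = fit_method,
                 wls_grouping = wls_grouping),
            class = "bias_model_spec")
}

bias_spec_label <- function(spec) {
  paste0(spec$form, "/", spec$fit_method,
         if (!is.null(spec$wls_grouping)) paste0("(", spec$wls_grouping, ")"))
}

#' @export
print.bias_model_spec <- function(x, ...) {
  cat("Bias model:", bias_spec_label(x), "\n")
  invisible(x)
}

level_of <- function(records, form) {
  switch(form,
         marginal = rep("(all)", nrow(records)),
         by_modality = as.character(records$modality),
         by_scanner = as.character(records$scanner))
}

#' Fit a linear bias model of brain age on chronological age
#'
#' Per level of the chosen form (globally for the marginal model),
#' least-squares estimates of the intercept and slope of
#' `predicted_brain_age ~ age`. WLS uses weights equal to the inverse of the
#' observation's group frequency under `wls_grouping`. Levels with fewer than
#' `min_n` scans are flagged unfittable and excluded; a level with zero age
#' variance is a singular fit and raises an error.
#'
#' @param records scans with `predicted_brain_age` and `age` (plus `modality`
#'   / `scanner` as needed).
#' @param spec a [bias_model_spec()].
#' @param min_n minimum scans per level (default 3: two parameters plus one
#'   residual degree of freedom).
#' @return An object of class `bias_model_fit` with elements `spec`,
#'   `coefficients` (data frame `level, intercept, slope, n`),
#'   `dropped_levels` and `coef_count`.
#' @export
fit_bias_model <- function(records, spec, min_n = 3) {
  stopifnot(inherits(spec, "bias_model_spec"),
            all(c("predicted_brain_age", "age") %in% names(records)))
  records <- records[!is.na(records$predicted_brain_age), , drop = FALSE]
  lev <- level_of(records, spec$form)
  w <- NULL
  if (spec$fit_method == "WLS") {
    g <- as.character(records[[spec$wls_grouping]])
    freq <- table(g)
    w <- 1 / as.numeric(freq[g])
  }
  levels_present <- sort(unique(lev))
  coefs <- list()
  dropped <- character()
  for (l in levels_present) {
    idx <- which(lev == l)
    if (length(idx) < min_n) {
      dropped <- c(dropped, l)
      next
    }
    x <- records$age[idx]
    y <- records$predicted_brain_age[idx]
    if (stats::var(x) == 0)
      stop("singular fit: zero age variance within level '", l, "'")
    wi <- if (is.null(w)) rep(1, length(idx)) else w[idx]
    fit <- stats::lm.wfit(cbind(`(Intercept)` = 1, age = x), y, wi)
    coefs[[l]] <- data.frame(level = l,
                             intercept = unname(fit$coefficients[1]),
                             slope = unname(fit$coefficients[2]),
                             n = length(idx), stringsAsFactors = FALSE)
  }
  if (!length(coefs))
    stop("no level had the minimum of ", min_n, " scans; nothing fitted")
  if (length(dropped))
    message("bias model ", bias_spec_label(spec), ": unfittable level(s) ",
            paste(dropped, collapse = ", "), " (fewer than ", min_n, " scans)")
  coefficients <- do.call(rbind, coefs)
  rownames(coefficients) <- NULL
  structure(list(spec = spec, coefficients = coefficients,
                 dropped_levels = dropped,
                 coef_count = 2L * nrow(coefficients)),
            class = "bias_model_fit")
}

#' @export
print.bias_model_fit <- function(x, ...) {
  cat("Fitted bias model:", bias_spec_label(x$spec),
      sprintf("(%d coefficients)\n", x$coef_count))
  print(x$coefficients, row.names = FALSE)
  if (length(x$dropped_levels))
    cat("unfittable levels:", paste(x$dropped_levels, collapse = ", "), "\n")
  invisible(x)
}

#' Age-independent inverse bias correction
#'
#' Inverts the fitted linear bias:
#' `corrected = (brain age - intercept) / slope`, using the coefficients of
#' the record's modality or scanner level (or the single global pair for the
#' marginal model). The correction never reads chronological age, so it
#' cannot inflate the apparent accuracy. For a level absent from the fit
#' (e.g. a modality unseen in the bias-estimation set), the unweighted mean
#' intercept and mean slope across fitted levels are used.
#'
#' @param records scans with `predicted_brain_age` (and `modality`/`scanner`
#'   as required by the fit's form).
#' @param fit a [fit_bias_model()] result; all slopes must be nonzero.
#' @return Numeric vector of corrected brain ages; attribute
#'   `"unseen_levels"` lists levels corrected with averaged coefficients.
#' @export
correct_ages <- function(records, fit) {
  stopifnot(inherits(fit, "bias_model_fit"))
  co <- fit$coefficients
  if (any(!is.finite(co$slope)) || any(co$slope == 0))
    stop("correction error: fitted slope is zero or non-finite")
  lev <- level_of(records, fit$spec$form)
  idx <- match(lev, co$level)
  unseen <- sort(unique(lev[is.na(idx)]))
  intercept <- co$intercept[idx]
  slope <- co$slope[idx]
  if (length(unseen)) {
    intercept[is.na(idx)] <- mean(co$intercept)
    slope[is.na(idx)] <- mean(co$slope)
  }
  out <- (records$predicted_brain_age - intercept) / slope
  attr(out, "unseen_levels") <- unseen
  out
}

#' Naive age-dependent bias correction (diagnostics only)
#'
#' The correction `corrected = age + brain age - f(age)` commonly derived
#' from regressing out age. Because it reads chronological age, it inflates
#' the corrected-age/age correlation -- never below about 0.87 even for
#' predictions carrying no age signal -- and is provided only as the
#' inflation-prone comparator to [correct_ages()].
#'
#' @param records scans with `predicted_brain_age`.
#' @param fit a marginal [fit_bias_model()] result.
#' @param ages chronological ages (defaults to `records$age`).
#' @return Numeric vector of naively corrected brain ages.
#' @export
naive_correct <- function(records, fit, ages = records$age) {
  stopifnot(inherits(fit, "bias_model_fit"))
  if (fit$spec$form != "marginal")
    stop("the naive correction is defined for the marginal bias model")
  co <- fit$coefficients
  ages + records$predicted_brain_age - (co$intercept[1] + co$slope[1] * ages)
}

#' Cross-validated selection of a bias model
#'
#' For each cross-validation iteration, each candidate bias model is fitted
#' on the held-out fold's bias-estimation subset and scored by the
#' bias-corrected mean absolute error on that fold's evaluation subset. The
#' candidate minimizing the across-fold mean MAE is selected; MAEs equal
#' after rounding to one decimal place are treated as ties, broken first by
#' the smaller coefficient count and then by the smaller across-fold MAE
#' standard deviation (the simplest, most stable model). Candidates
#' unfittable in any fold are dropped with a log message.
#'
#' @param records training-set scans with predictions.
#' @param candidates list of [bias_model_spec()] objects.
#' @param folds a [make_cv_folds()] assignment.
#' @return List with `selected` (a `bias_model_spec`), `table` (per-candidate
#'   fold MAEs, mean, sd, coefficient count) and `dropped` (labels of
#'   candidates that failed).
#' @export
select_bias_model_cv <- function(records, candidates, folds) {
  stopifnot(length(candidates) >= 1,
            all(c("participant_id", "fold", "sub") %in% names(folds)))
  fold_ids <- sort(unique(folds$fold))
  labels <- vapply(candidates, bias_spec_label, "")
  mae <- matrix(NA_real_, nrow = length(candidates), ncol = length(fold_ids),
                dimnames = list(labels, paste0("fold", fold_ids)))
  coef_count <- rep(NA_integer_, length(candidates))
  for (j in seq_along(fold_ids)) {
    f <- fold_ids[j]
    bias_ids <- folds$participant_id[folds$fold == f & folds$sub == "bias_sub"]
    eval_ids <- folds$participant_id[folds$fold == f & folds$sub == "eval_sub"]
    bias_recs <- records[records$participant_id %in% bias_ids, , drop = FALSE]
    eval_recs <- records[records$participant_id %in% eval_ids, , drop = FALSE]
    for (i in seq_along(candidates)) {
      res <- tryCatch({
        fit <- fit_bias_model(bias_recs, candidates[[i]])
        corrected <- correct_ages(eval_recs, fit)
        list(mae = mean(abs(corrected - eval_recs$age)),
             coef_count = fit$coef_count)
      }, error = function(e) NULL)
      if (!is.null(res)) {
        mae[i, j] <- res$mae
        coef_count[i] <- max(coef_count[i], res$coef_count, na.rm = TRUE)
      }
    }
  }
  ok <- !apply(mae, 1, anyNA)
  dropped <- labels[!ok]
  if (length(dropped))
    message("candidate(s) dropped (unfittable in some fold): ",
            paste(dropped, collapse = "; "))
  if (!any(ok)) stop("no candidate bias model could be fitted in every fold")
  mean_mae <- rowMeans(mae)
  sd_mae <- apply(mae, 1, stats::sd)
  tab <- data.frame(candidate = labels, coef_count = coef_count,
                    mae, mean_mae = mean_mae, sd_mae = sd_mae,
                    row.names = NULL, check.names = FALSE)
  pool <- which(ok)
  rounded <- round(mean_mae[pool], 1)
  best <- pool[rounded == min(rounded)]
  if (length(best) > 1) best <- best[coef_count[best] == min(coef_count[best])]
  if (length(best) > 1) best <- best[which.min(sd_mae[best])]
  list(selected = candidates[[best[1]]], table = tab, dropped = dropped)
}

#' Write / read a fitted bias model as JSON
#'
#' Layout: `{form, fit_method, wls_grouping, levels: {label: {intercept,
#' slope, n}}}`.
#'
#' @param fit a `bias_model_fit`.
#' @param path file path.
#' @return `read_bias_fit()` returns a `bias_model_fit`.
#' @export
write_bias_fit <- function(fit, path) {
  stopifnot(inherits(fit, "bias_model_fit"))
  levels <- stats::setNames(
    lapply(seq_len(nrow(fit$coefficients)), function(i) {
      r <- fit$coefficients[i, ]
      list(intercept = r$intercept, slope = r$slope, n = r$n)
    }), fit$coefficients$level)
  obj <- list(form = fit$spec$form, fit_method = fit$spec$fit_method,
              wls_grouping = fit$spec$wls_grouping, levels = levels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_bias_fit
#' @export
read_bias_fit <- function(path) {
  obj <- jsonlite::read_json(path)
  spec <- bias_model_spec(obj$form, obj$fit_method,
                          wls_grouping = obj$wls_grouping)
  coefs <- do.call(rbind, lapply(names(obj$levels), function(l) {
    e <- obj$levels[[l]]
    data.frame(level = l, intercept = e$intercept, slope = e$slope,
               n = as.integer(e$n), stringsAsFactors = FALSE)
  }))
  structure(list(spec = spec, coefficients = coefs,
                 dropped_levels = character(),
                 coef_count = 2L * nrow(coefs)),
            class = "bias_model_fit")
}
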