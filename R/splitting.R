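#' Stratification specification for participant-level splits
#'
#' Splits are stratified on the Cartesian product of participant-level
#' variables: sex, a binned chronological age, the participant's set of
#' modalities and set of scanner models. Participants carrying a forced-test
#' modality or scanner are assigned to the test split before stratification,
#' mirroring the exclusion of rare modalities and their scanners from
#' training and bias estimation.
#'
#' @param variables subset of `c("sex", "age_bin", "modality_set",
#'   "scanner_set")` used to form strata.
#' @param age_bin_width width of the age bins in years (default 20).
#' @param forced_test_modalities,forced_test_scanners labels whose carriers
#'   are moved to the test split before stratified allocation.
#' @return An object of class `strata_spec`.
#' @export
strata_spec <- function(variables = c("sex", "age_bin", "modality_set",
                                      "scanner_set"),
                        age_bin_width = 20,
                        forced_test_modalities = character(),
                        forced_test_scanners = character()) {
  stopifnot(age_bin_width > 0,
            all(variables %in% c("sex", "age_bin", "modality_set",
                                 "scanner_set")))
  structure(list(variables = variables,
                 age_bin_width = age_bin_width,
                 forced_test_modalities = forced_test_modalities,
                 forced_test_scanners = forced_test_scanners),
            class = "strata_spec")
}

# One row per participant with the stratification variables.
participant_table <- function(cohort, strata) {
  sp <- split(seq_len(nrow(cohort)), cohort$participant_id)
  ids <- names(sp)
  first <- vapply(sp, `[`, 0L, 1L)
  tab <- data.frame(participant_id = ids,
                    age = cohort$age[first],
                    sex = cohort$sex[first],
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$modality_set <- vapply(sp, function(i)
    paste(sort(unique(cohort$modality[i])), collapse = "+"), "")
  tab$scanner_set <- vapply(sp, function(i)
    paste(sort(unique(cohort$scanner[i])), collapse = "+"), "")
  tab$age_bin <- floor(tab$age / strata$age_bin_width)
  tab$stratum <- do.call(paste, c(tab[strata$variables], sep = "|"))
  tab
}

# Largest-remainder apportionment within each stratum after a seeded
# shuffle: every split receives floor(n_s * p) members, and the leftover
# units go to splits drawn (seeded, without replacement) with probability
# proportional to the fractional remainders. Realized counts are therefore
# within one participant of the stratum's targets, and unbiased globally.
allocate_strata <- function(ids_by_stratum, proportions, seed) {
  labels <- names(proportions)
  assign_list <- list()
  small <- character()
  with_seed(seed, {
    for (s in sort(names(ids_by_stratum))) {
      ids <- sample(ids_by_stratum[[s]])
      n_s <- length(ids)
      if (n_s < sum(proportions > 0)) small <- c(small, s)
      target <- n_s * proportions
      base <- floor(target)
      left <- n_s - sum(base)
      if (left > 0) {
        frac <- target - base
        add <- if (sum(frac > 0) == left) which(frac > 0) else
          sample(seq_along(labels), left, prob = frac)
        base[add] <- base[add] + 1
      }
      assign_list[[s]] <- stats::setNames(rep(labels, base), ids)
    }
  })
  out <- unlist(unname(assign_list))
  attr(out, "small_strata") <- small
  out
}

#' Participant-level stratified split into train / bias-estimation / test
#'
#' Carriers of forced-test modalities or scanners go to the test split first;
#' the remaining participants are shuffled within each stratum and allocated
#' by largest-remainder apportionment so that realized counts match the
#' target proportions as closely as integer counts allow, both per stratum
#' and globally. Strata smaller than the number of splits are allocated
#' best-effort and reported via a warning.
#'
#' @param cohort a cohort data frame (one row per scan).
#' @param proportions named numeric `c(train=, bias_estimation=, test=)`
#'   summing to 1.
#' @param strata a [strata_spec()].
#' @param seed integer seed.
#' @return An object of class `split_assignment`: a data frame
#'   `(participant_id, split)` with attributes `proportions`, `seed`,
#'   `forced_test` and `small_strata`.
#' @export
stratified_split <- function(cohort,
                             proportions = c(train = 0.71,
                                             bias_estimation = 0.12,
                                             test = 0.17),
                             strata = strata_spec(),
                             seed = 1L) {
  stopifnot(nrow(cohort) > 0, abs(sum(proportions) - 1) < 1e-8,
            all(proportions >= 0), inherits(strata, "strata_spec"))
  if (is.null(names(proportions)))
    names(proportions) <- c("train", "bias_estimation", "test")
  ptab <- participant_table(cohort, strata)
  n <- nrow(ptab)

  forced_part <- vapply(split(seq_len(nrow(cohort)), cohort$participant_id),
                        function(i) {
                          any(cohort$modality[i] %in% strata$forced_test_modalities) ||
                            any(cohort$scanner[i] %in% strata$forced_test_scanners)
                        }, logical(1))
  forced_ids <- names(forced_part)[forced_part]
  rest <- ptab[!(ptab$participant_id %in% forced_ids), ]

  # recompute proportions over the remainder: forced participants count
  # toward the global test target
  p_rem <- proportions * n
  p_rem["test"] <- max(0, p_rem["test"] - length(forced_ids))
  p_rem <- p_rem / sum(p_rem)

  assignment <- stats::setNames(rep("test", length(forced_ids)), forced_ids)
  small <- character()
  if (nrow(rest) > 0) {
    ids_by_stratum <- split(rest$participant_id, rest$stratum)
    alloc <- allocate_strata(ids_by_stratum, p_rem, seed)
    small <- attr(alloc, "small_strata")
    assignment <- c(assignment, alloc)
  }
  if (length(small))
    warning(length(small), " strata smaller than the number of splits; ",
            "allocated best-effort")
  out <- data.frame(participant_id = names(assignment),
                    split = unname(assignment),
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id), ]
  rownames(out) <- NULL
  structure(out, class = c("split_assignment", "data.frame"),
            proportions = proportions, seed = seed,
            forced_test = forced_ids, small_strata = small)
}

#' Stratified cross-validation folds with bias/evaluation sub-splits
#'
#' Training participants are allocated to `k` folds with the same stratified
#' apportionment as the main split. Each fold, when held out, is further
#' split at the participant level into a bias-estimation subset and an
#' evaluation subset (63/37 by default).
#'
#' @param train_ids participant ids of the training split.
#' @param cohort the cohort (used for stratification variables).
#' @param k number of folds (>= 2).
#' @param sub_fractions named fractions `c(bias_sub=, eval_sub=)` summing
#'   to 1.
#' @param strata a [strata_spec()].
#' @param seed integer seed.
#' @return Data frame `(participant_id, fold, sub)`; `sub` applies when the
#'   participant's fold is the held-out fold of a cross-validation iteration.
#' @export
make_cv_folds <- function(train_ids, cohort, k = 3,
                          sub_fractions = c(bias_sub = 0.63, eval_sub = 0.37),
                          strata = strata_spec(), seed = 1L) {
  stopifnot(k >= 2, abs(sum(sub_fractions) - 1) < 1e-8)
  if (k > length(train_ids))
    stop("k (", k, ") exceeds the number of training participants (",
         length(train_ids), ")")
  sub_cohort <- cohort[cohort$participant_id %in% train_ids, ]
  ptab <- participant_table(sub_cohort, strata)
  fold_props <- stats::setNames(rep(1 / k, k), as.character(seq_len(k)))
  alloc <- suppressWarnings(
    allocate_strata(split(ptab$participant_id, ptab$stratum), fold_props,
                    derive_seed(seed, "folds")))
  fold <- as.integer(alloc[ptab$participant_id])
  sub <- character(nrow(ptab))
  for (j in seq_len(k)) {
    in_fold <- ptab$participant_id[fold == j]
    stratum_j <- ptab$stratum[fold == j]
    sub_alloc <- suppressWarnings(
      allocate_strata(split(in_fold, stratum_j), sub_fractions,
                      derive_seed(seed, paste0("sub-", j))))
    sub[match(names(sub_alloc), ptab$participant_id)] <- unname(sub_alloc)
  }
  out <- data.frame(participant_id = ptab$participant_id, fold = fold,
                    sub = sub, stringsAsFactors = FALSE)
  out[order(out$participant_id), , drop = FALSE]
}

#' Distribution-equality checks between splits
#'
#' For every pair of splits: a two-sample Kolmogorov-Smirnov test on
#' participant ages, and chi-squared tests on sex (participant level) and on
#' modality and scanner (scan level). Bonferroni correction is applied across
#' the pairwise comparisons within each variable.
#'
#' @param cohort the cohort data frame.
#' @param assignment a data frame with `participant_id` and a label column.
#' @param label_col name of the label column (default `"split"`).
#' @return Data frame with columns `variable, split_a, split_b, statistic,
#'   p_value, p_bonferroni, significant` (at 0.05).
#' @export
check_distributions <- function(cohort, assignment, label_col = "split") {
  lab <- assignment[[label_col]]
  stopifnot(!is.null(lab))
  lab_of <- stats::setNames(as.character(lab), assignment$participant_id)
  cohort$.label <- lab_of[cohort$participant_id]
  cohort <- cohort[!is.na(cohort$.label), ]
  labels <- sort(unique(cohort$.label))
  nonempty <- labels[vapply(labels, function(l) any(cohort$.label == l),
                            logical(1))]
  if (length(nonempty) < 2) {
    message("fewer than two nonempty splits; distribution checks skipped")
    return(data.frame())
  }
  ptab <- cohort[!duplicated(cohort$participant_id),
                 c("participant_id", "age", "sex", ".label")]
  pairs <- utils::combn(nonempty, 2, simplify = FALSE)
  rows <- list()
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    ks <- suppressWarnings(
      stats::ks.test(ptab$age[ptab$.label == a], ptab$age[ptab$.label == b]))
    rows[[length(rows) + 1]] <- data.frame(
      variable = "age", split_a = a, split_b = b,
      statistic = unname(ks$statistic), p_value = ks$p.value)
    for (v in c("sex", "modality", "scanner")) {
      dat <- if (v == "sex") ptab else cohort
      val <- dat[[v]][dat$.label %in% c(a, b)]
      grp <- dat$.label[dat$.label %in% c(a, b)]
      tb <- table(grp, val)
      chi <- if (nrow(tb) < 2 || ncol(tb) < 2) {
        list(statistic = c(X = NA_real_), p.value = NA_real_)
      } else suppressWarnings(stats::chisq.test(tb))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, split_a = a, split_b = b,
        statistic = unname(chi$statistic), p_value = chi$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_pairs <- length(pairs)
  out$p_bonferroni <- pmin(1, out$p_value * n_pairs)
  out$significant <- !is.na(out$p_bonferroni) & out$p_bonferroni < 0.05
  out
}

#' Observation weights per scan
#'
#' Weighting schemes used to counter over-represented participants and
#' strata: `"none"` (all 1), `"inverse_n_mri"` (inverse of the participant's
#' scan count, so each participant contributes total weight 1), and
#' `"inverse_n_mri_age_sex"` (the former additionally divided by the scan
#' prevalence of the participant's age bin and sex).
#'
#' @param cohort the cohort data frame.
#' @param scheme weighting scheme.
#' @param age_bin_width width of age bins for the prevalence weights.
#' @return Numeric weight per scan (same order as `cohort`).
#' @export
compute_observation_weights <- function(cohort,
                                        scheme = c("none", "inverse_n_mri",
                                                   "inverse_n_mri_age_sex"),
                                        age_bin_width = 20) {
  scheme <- match.arg(scheme)
  n <- nrow(cohort)
  if (scheme == "none") return(rep(1, n))
  n_mri <- table(cohort$participant_id)
  w <- 1 / as.numeric(n_mri[cohort$participant_id])
  if (scheme == "inverse_n_mri_age_sex") {
    bin <- floor(cohort$age / age_bin_width)
    bin_prev <- table(bin) / n
    sex_prev <- table(cohort$sex) / n
    if (any(bin_prev == 0)) stop("empty age bin in prevalence weights")
    w <- w / as.numeric(bin_prev[as.character(bin)]) /
      as.numeric(sex_prev[cohort$sex])
  }
  w
}

#' Write a split assignment (and optional folds) as CSV
#'
#' @param split a [stratified_split()] result.
#' @param path file path.
#' @param folds optional [make_cv_folds()] result to merge in.
#' @return `read_split_assignment()` returns the data frame.
#' @export
write_split_assignment <- function(split, path, folds = NULL) {
  out <- as.data.frame(split)
  if (!is.null(folds)) {
    out <- merge(out, folds, by = "participant_id", all.x = TRUE)
  } else {
    out$fold <- NA_integer_
    out$sub <- NA_character_
  }
  utils::write.csv(out[order(out$participant_id), ], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_split_assignment
#' @export
read_split_assignment <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(participant_id = "character"))
}
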