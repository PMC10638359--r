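strata_basic <- strata_spec(variables = c("sex", "age_bin"))

test_that("stratified allocation matches target proportions per stratum", {
  cfg <- small_noisy_config(seed = 12, n = 400)
  co <- generate_predictions(build_cohort(cfg), cfg)
  props <- c(train = 0.71, bias_estimation = 0.12, test = 0.17)
  sp <- suppressWarnings(stratified_split(co, props, strata_basic, seed = 3))
  ptab <- co[!duplicated(co$participant_id), ]
  ptab$split <- sp$split[match(ptab$participant_id, sp$participant_id)]
  ptab$stratum <- paste(ptab$sex, floor(ptab$age / 20))
  for (s in unique(ptab$stratum)) {
    n_s <- sum(ptab$stratum == s)
    for (lab in names(props)) {
      got <- sum(ptab$stratum == s & ptab$split == lab)
      expect_lte(abs(got - n_s * props[[lab]]), 1)
    }
  }
  # global counts track the targets up to per-stratum rounding
  realized <- table(factor(sp$split, names(props)))
  n_strata <- length(unique(ptab$stratum))
  expect_true(all(abs(realized - 400 * props) <= n_strata))
})

test_that("degenerate proportions send everyone to one split", {
  cfg <- noiseless_config(seed = 2, n = 30)
  co <- generate_predictions(build_cohort(cfg), cfg)
  sp <- suppressWarnings(
    stratified_split(co, c(train = 1, bias_estimation = 0, test = 0),
                     strata_spec(variables = "sex"), seed = 1))
  expect_true(all(sp$split == "train"))
})

test_that("splits partition participants with no leakage across seeds", {
  cfg <- small_noisy_config(seed = 6, n = 60)
  co <- generate_predictions(build_cohort(cfg), cfg)
  all_ids <- unique(co$participant_id)
  for (s in 1:20) {
    sp <- suppressWarnings(stratified_split(co, strata = strata_basic, seed = s))
    expect_setequal(sp$participant_id, all_ids)
    expect_false(any(duplicated(sp$participant_id)))
    # every scan inherits its participant's label: label is a function of id
    lab <- sp$split[match(co$participant_id, sp$participant_id)]
    expect_false(any(is.na(lab)))
  }
})

test_that("forced-test rules move carriers to the test split", {
  cfg <- small_noisy_config(seed = 19, n = 150, failure = TRUE)
  co <- generate_predictions(build_cohort(cfg), cfg)
  st <- strata_spec(variables = c("sex", "age_bin"),
                    forced_test_modalities = "T2w")
  sp <- suppressWarnings(stratified_split(co, strata = st, seed = 2))
  carriers <- unique(co$participant_id[co$modality == "T2w"])
  expect_true(all(sp$split[sp$participant_id %in% carriers] == "test"))
})

test_that("cross-validation folds partition the training set at participant level", {
  cfg <- small_noisy_config(seed = 8, n = 300)
  co <- generate_predictions(build_cohort(cfg), cfg)
  sp <- suppressWarnings(stratified_split(co, strata = strata_basic, seed = 4))
  train_ids <- sp$participant_id[sp$split == "train"]
  folds <- suppressWarnings(make_cv_folds(train_ids, co, k = 3,
                                          strata = strata_basic, seed = 4))
  expect_setequal(folds$participant_id, train_ids)
  expect_false(any(duplicated(folds$participant_id)))
  expect_setequal(unique(folds$fold), 1:3)
  # folds of equal size up to stratification rounding
  expect_lt(diff(range(table(folds$fold))), 8)
  # held-fold 63/37 sub-split
  for (j in 1:3) {
    tab <- table(folds$sub[folds$fold == j])
    frac <- tab[["bias_sub"]] / sum(tab)
    expect_lt(abs(frac - 0.63), 0.08)
  }
  expect_error(make_cv_folds(train_ids[1:2], co, k = 3), "exceeds")
})

test_that("distribution checks follow the KS/chi-squared protocol", {
  # two splits with identical ages: KS statistic 0, p = 1
  n <- 40
  co <- data.frame(participant_id = sprintf("P%03d", 1:(2 * n)),
                   age = rep(seq(20, 80, length.out = n), 2),
                   sex = rep(c("F", "M"), n),
                   modality = "T2w", scanner = "Aera", repetition = 1L,
                   predicted_brain_age = 50)
  asg <- data.frame(participant_id = co$participant_id,
                    split = rep(c("a", "b"), each = n))
  res <- check_distributions(co, asg)
  age_row <- res[res$variable == "age", ]
  expect_equal(age_row$statistic, 0)
  expect_equal(age_row$p_value, 1)

  # a +20-year shift is detected by the KS test
  co2 <- co
  co2$age[asg$split == "b"] <- co2$age[asg$split == "b"] + 20
  res2 <- check_distributions(co2, asg)
  expect_true(res2$significant[res2$variable == "age"])

  # splits from one stratified allocation of a large cohort: nothing significant
  cfg <- small_noisy_config(seed = 23, n = 600)
  big <- generate_predictions(build_cohort(cfg), cfg)
  sp <- suppressWarnings(stratified_split(big, strata = strata_spec(), seed = 5))
  res3 <- check_distributions(big, sp)
  expect_false(any(res3$significant, na.rm = TRUE))
  # Bonferroni across the three pairwise comparisons within each variable
  expect_equal(res3$p_bonferroni, pmin(1, res3$p_value * 3))
})

test_that("stratified allocation balances age at least as well as random", {
  cfg <- small_noisy_config(seed = 3, n = 150)
  co <- generate_predictions(build_cohort(cfg), cfg)
  ptab <- co[!duplicated(co$participant_id), ]
  mean_ks <- function(lab) {
    pairs <- combn(unique(lab), 2, simplify = FALSE)
    mean(vapply(pairs, function(pr) {
      suppressWarnings(ks.test(ptab$age[lab == pr[1]],
                               ptab$age[lab == pr[2]])$statistic)
    }, 0))
  }
  props <- c(train = 0.71, bias_estimation = 0.12, test = 0.17)
  ks_strat <- ks_rand <- numeric(100)
  for (s in 1:100) {
    sp <- suppressWarnings(stratified_split(co, props, strata_basic, seed = s))
    lab <- sp$split[match(ptab$participant_id, sp$participant_id)]
    ks_strat[s] <- mean_ks(lab)
    counts <- diff(round(cumsum(c(0, props)) * nrow(ptab)))
    set.seed(s)
    lab_r <- sample(rep(names(props), times = counts))
    ks_rand[s] <- mean_ks(lab_r)
  }
  expect_lte(mean(ks_strat), mean(ks_rand))
})

test_that("observation weights follow their definitions", {
  co <- data.frame(participant_id = c(rep("A", 4), "B", "C", "C"),
                   age = c(20, 20, 20, 20, 50, 80, 80),
                   sex = c(rep("F", 4), "M", "F", "F"),
                   modality = "T2w", scanner = "Aera",
                   repetition = c(1:4, 1, 1, 2),
                   predicted_brain_age = 50)
  expect_equal(compute_observation_weights(co, "none"), rep(1, 7))
  w <- compute_observation_weights(co, "inverse_n_mri")
  expect_equal(w[1:4], rep(0.25, 4))
  # telescoping: inverse-count weights sum to the number of participants
  expect_equal(sum(w), 3)
  w2 <- compute_observation_weights(co, "inverse_n_mri_age_sex")
  # participant A: bin prevalence 4/7, sex prevalence 6/7
  expect_equal(w2[1], 0.25 / (4 / 7) / (6 / 7))
})

test_that("split assignment CSV round-trips", {
  cfg <- small_noisy_config(seed = 14, n = 50)
  co <- generate_predictions(build_cohort(cfg), cfg)
  sp <- suppressWarnings(stratified_split(co, strata = strata_basic, seed = 2))
  folds <- suppressWarnings(
    make_cv_folds(sp$participant_id[sp$split == "train"], co,
                  strata = strata_basic, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_split_assignment(sp, path, folds)
  back <- read_split_assignment(path)
  expect_identical(back$split, sp$split[order(sp$participant_id)])
  expect_setequal(back$participant_id[!is.na(back$fold)],
                  folds$participant_id)
})
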