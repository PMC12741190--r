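# Fixtures here are deliberately small so the penalized fits stay fast;
# the full-scale recovery checks live in the acceptance suite.

clock_fixture <- function(seed = 5, n_info = 5, n_null = 45,
                          beta = 0.03, sigma = 0.2) {
  cfg <- cohort_config(seed = seed, noise_sigma = sigma,
                       zero_inflation = 0)
  specs <- list(trajectory_spec("linear", n = n_info, beta = beta,
                                label = "info"),
                trajectory_spec("null", n = n_null))
  sim <- simulate_cohort(cfg, specs)
  sim$table <- total_sum_normalize(sim$table)
  sim
}

test_that("a perfect age predictor dominates the fitted clock", {
  cfg <- cohort_config(seed = 111, noise_sigma = 0.2, zero_inflation = 0)
  sim <- simulate_cohort(cfg, trajectory_spec("null", n = 99))
  v <- sim$table$values
  # one feature whose log10 abundance equals age exactly
  v <- rbind(v, oracle_age = 10^(sim$meta$age / 50))
  t0 <- feature_table(v)
  clock <- fit_clock(t0, sim$meta, alpha_grid = c(0.3, 0.7),
                     train_fractions = c(0.6, 0.8), seed = 2,
                     log_offset = 1e-12)
  expect_lt(clock$mae_test, 1)
  expect_gt(clock$r_test, 0.99)
  expect_true("oracle_age" %in% names(clock$coefficients))
})

test_that("the clock is deterministic given a seed", {
  sim <- clock_fixture()
  c1 <- fit_clock(sim$table, sim$meta, alpha_grid = c(0.5),
                  train_fractions = c(0.7), seed = 9)
  c2 <- fit_clock(sim$table, sim$meta, alpha_grid = c(0.5),
                  train_fractions = c(0.7), seed = 9)
  expect_identical(c1$coefficients, c2$coefficients)
  expect_identical(c1$predictions, c2$predictions)
})

test_that("stored test MAE equals the recomputed prediction error", {
  sim <- clock_fixture(seed = 6)
  clock <- fit_clock(sim$table, sim$meta, alpha_grid = c(0.5),
                     train_fractions = c(0.7), seed = 3)
  recomputed <- mean(abs(clock$predictions$predicted -
                           clock$predictions$age))
  expect_equal(clock$mae_test, recomputed, tolerance = 1e-10)
})

test_that("null features cannot predict age", {
  cfg <- cohort_config(n_subjects = 150, seed = 17, noise_sigma = 0.3,
                       zero_inflation = 0)
  sim <- simulate_cohort(cfg, trajectory_spec("null", n = 100))
  tn <- total_sum_normalize(sim$table)
  clock <- fit_clock(tn, sim$meta, alpha_grid = c(0.5),
                     train_fractions = c(0.7), seed = 4)
  expect_true(is.na(clock$r_test) || abs(clock$r_test) < 0.3)
})

test_that("broken-stick regression recovers a constructed knot", {
  x <- 2:20
  y <- ifelse(x <= 9, 0.5 + 0.05 * x, 0.5 + 0.05 * 9 + 0.002 * (x - 9))
  bs <- broken_stick(x, y)
  expect_lt(abs(bs$knot - 9), 0.5)
  expect_false(bs$low_confidence)
  # a featureless straight line is flagged low-confidence
  flat <- broken_stick(x, 0.3 + 0.01 * x)
  expect_true(flat$low_confidence)
  expect_error(broken_stick(1:3, 1:3), ">= 4")
})

test_that("reduce_clock finds a breakpoint near the informative count", {
  sim <- clock_fixture(seed = 11, n_info = 5, n_null = 95)
  clock <- fit_clock(sim$table, sim$meta, alpha_grid = c(0.3, 0.7),
                     train_fractions = c(0.7), seed = 5)
  expect_gte(length(clock$coefficients), 4)
  red <- reduce_clock(clock, sim$table, sim$meta,
                      alpha_grid = c(0.3, 0.7), seed = 5,
                      max_features = 15)
  expect_gte(red$breakpoint, 3)
  expect_lte(red$breakpoint, 8)
  ranking <- names(sort(abs(clock$coefficients) *
                          clock$feature_sd[names(clock$coefficients)],
                        decreasing = TRUE))
  expect_identical(red$ranked_features,
                   utils::head(ranking, length(red$ranked_features)))
  expect_s3_class(red$final_model, "ClockModel")
  expect_lte(length(red$final_model$coefficients), red$breakpoint)
})

test_that("predictions are invariant to feature-wise affine rescaling", {
  sim <- clock_fixture(seed = 13)
  c1 <- fit_clock(sim$table, sim$meta, alpha_grid = c(0.5),
                  train_fractions = c(0.7), seed = 7, log_offset = 1e-12)
  scaled <- sim$table
  # multiplying a feature's abundance shifts its log10 by a constant;
  # standardization inside the penalized fit absorbs it
  scaled$values <- sweep(scaled$values, 1,
                         10^(seq_len(nrow(scaled$values)) %% 3), "*")
  scaled$normalization_state <- "raw"
  c2 <- fit_clock(scaled, sim$meta, alpha_grid = c(0.5),
                  train_fractions = c(0.7), seed = 7, log_offset = 1e-12)
  expect_equal(c1$predictions$predicted, c2$predictions$predicted,
               tolerance = 1e-6)
})

test_that("select_panel performs the three-way set algebra", {
  de <- data.frame(feature_id = c("a", "b", "c", "d"),
                   direction = c("up", "up", "down", "ns"),
                   stringsAsFactors = FALSE)
  age_models <- data.frame(feature_id = c("a", "b", "c", "d"),
                           q_age = c(0.01, 0.2, 0.01, 0.01),
                           beta_age = c(1, 1, 1, -1),
                           stringsAsFactors = FALSE)
  clock <- structure(list(coefficients = c(a = 0.5, d = 0.1)),
                     class = "ClockModel")
  sel <- select_panel(de, age_models, clock)
  expect_identical(sel$intersection, "a")
  expect_equal(unname(sel$pairwise), c(1, 1, 1))
  # disjoint sets intersect empty
  clock2 <- structure(list(coefficients = c(zzz = 1)),
                      class = "ClockModel")
  sel2 <- select_panel(de[3, , drop = FALSE], age_models[2, , drop = FALSE],
                       clock2)
  expect_length(sel2$intersection, 0)
  expect_true(all(sel2$pairwise == 0))
})

test_that("ROC AUC equals the pairwise Mann-Whitney statistic with ties", {
  scores <- c(0.9, 0.8, 0.8, 0.7, 0.6, 0.5, 0.5, 0.5, 0.3, 0.2, 0.2, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE,
              FALSE, TRUE, FALSE)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$auc, auc_oracle(scores, labels), tolerance = 1e-12)
  set.seed(123)
  for (i in 1:10) {
    s <- sample(seq(0, 1, 0.1), 14, replace = TRUE)
    l <- sample(c(TRUE, FALSE), 14, replace = TRUE)
    if (!any(l) || all(l)) next
    expect_equal(roc_curve(s, l)$auc, auc_oracle(s, l),
                 tolerance = 1e-12)
  }
})

test_that("separable classes give CV AUC 1 and permutation breaks it", {
  cfg <- cohort_config(seed = 3, noise_sigma = 0.2, zero_inflation = 0)
  specs <- list(trajectory_spec("linear", n = 5, beta = 0.05,
                                label = "sig"),
                trajectory_spec("null", n = 5))
  sim <- simulate_cohort(cfg, specs)
  tn <- total_sum_normalize(sim$table)
  panel <- paste0("sig_000", 1:5)
  pr <- fit_panel_classifier(panel, tn, sim$meta, seed = 2)
  expect_equal(pr$cv_auc_mean, 1)
  # permuted labels: average over three permutations hugs chance level
  aucs <- vapply(1:3, function(i) {
    set.seed(100 + i)
    m2 <- sim$meta
    m2$age <- sample(m2$age)
    fit_panel_classifier(panel, tn, m2, seed = 2)$cv_auc_mean
  }, numeric(1))
  expect_gt(mean(aucs), 0.35)
  expect_lt(mean(aucs), 0.65)
})

test_that("clock JSON export carries the model terms", {
  sim <- clock_fixture(seed = 15)
  clock <- fit_clock(sim$table, sim$meta, alpha_grid = c(0.5),
                     train_fractions = c(0.7), seed = 8)
  f <- file.path(tempdir(), "clock.json")
  write_clock_json(clock, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(parsed$feature_ids, names(clock$coefficients))
  expect_equal(parsed$mae_test, clock$mae_test, tolerance = 1e-12)
})
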