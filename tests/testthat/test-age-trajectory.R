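test_that("linear age model matches the normal-equations closed form", {
  set.seed(12)
  n <- 12
  ids <- sprintf("s%02d", 1:n)
  age <- c(0, 2, 7, 10, 15, 22, 30, 45, 52, 60, 70, 80)
  m <- data.frame(sample_id = ids, age = age,
                  sex = rep(c("F", "M"), 6),
                  group = assign_life_stage(age), stringsAsFactors = FALSE)
  v <- matrix(rexp(8 * n, 0.5) + 0.05, 8, n,
              dimnames = list(sprintf("f%02d", 1:8), ids))
  t0 <- feature_table(v)
  fit <- fit_linear_age(t0, m, log_offset = 1e-12)
  X <- cbind(1, age, as.numeric(m$sex == "M"))
  for (i in 1:8) {
    y <- log10(v[i, ] + 1e-12)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(fit$alpha_hat[i], beta[1], tolerance = 1e-9)
    expect_equal(fit$beta_age[i], beta[2], tolerance = 1e-9)
    expect_equal(fit$beta_sex[i], beta[3], tolerance = 1e-9)
  }
})

test_that("age-term p-values agree with the Type II ANOVA oracle", {
  skip_if_not_installed("car")
  set.seed(23)
  n <- 30
  ids <- sprintf("s%02d", 1:n)
  age <- runif(n, 0, 84)
  m <- data.frame(sample_id = ids, age = age,
                  sex = rep(c("F", "M"), 15),
                  group = assign_life_stage(age), stringsAsFactors = FALSE)
  v <- matrix(rexp(6 * n) + 0.05, 6, n,
              dimnames = list(sprintf("f%02d", 1:6), ids))
  fit <- fit_linear_age(feature_table(v), m, log_offset = 1e-12)
  sex <- factor(m$sex)
  for (i in 1:6) {
    y <- log10(v[i, ] + 1e-12)
    an <- car::Anova(lm(y ~ age + sex), type = 2)
    expect_equal(fit$p_age[i], an["age", "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("a noiseless linear feature is recovered exactly", {
  age <- seq(0, 80, by = 8)
  ids <- sprintf("s%02d", seq_along(age))
  m <- data.frame(sample_id = ids, age = age,
                  sex = rep(c("F", "M"), length.out = length(age)),
                  group = assign_life_stage(age), stringsAsFactors = FALSE)
  v <- matrix(10^(2 + 0.5 * age), 1, length(age),
              dimnames = list("lin", ids))
  fit <- fit_linear_age(feature_table(v), m, log_offset = 1e-12)
  expect_equal(fit$beta_age, 0.5, tolerance = 1e-8)
  expect_equal(fit$alpha_hat, 2, tolerance = 1e-8)
  expect_identical(fit$direction, "increase")
})

test_that("slope recovery is unbiased across the generator's beta grid", {
  betas <- c(-0.02, -0.01, -0.005, 0.005, 0.01, 0.02)
  cfg <- cohort_config(seed = 314, noise_sigma = 0.2, zero_inflation = 0)
  specs <- unlist(lapply(betas, function(b)
    replicate(34, trajectory_spec("linear", beta = b,
                                  label = sprintf("b%+0.3f", b)),
              simplify = FALSE)), recursive = FALSE)
  sim <- simulate_cohort(cfg, specs[1:200])
  # raw table, negligible offset: fitted log10 slope = beta / ln(10)
  fit <- fit_linear_age(sim$table, sim$meta, log_offset = 1e-12)
  true_beta <- sim$truth$beta / log(10)      # generator works in ln units
  err <- fit$beta_age - true_beta
  for (b in unique(true_beta)) {
    sel <- true_beta == b
    expect_lt(abs(mean(err[sel])), 0.1 * abs(b))
  }
})

test_that("LOESS reproduces polynomials and flags constants", {
  age <- seq(0, 80, length.out = 40)
  ids <- sprintf("s%02d", seq_along(age))
  m <- data.frame(sample_id = ids, age = age,
                  sex = rep(c("F", "M"), 20),
                  group = assign_life_stage(age), stringsAsFactors = FALSE)
  v <- rbind(lin = 10^(1 + 0.02 * age), const = rep(3, 40))
  colnames(v) <- ids
  lo <- fit_loess_trajectories(feature_table(v), m, standardize = FALSE,
                               log_offset = 1e-12)
  pred_lin <- lo$raw_curves["lin", ]
  expect_lt(max(abs(pred_lin - (1 + 0.02 * lo$grid))), 1e-6)
  expect_identical(lo$excluded, "const")
  los <- fit_loess_trajectories(feature_table(v), m, standardize = TRUE,
                                log_offset = 1e-12)
  expect_false("const" %in% rownames(los$curves))
})

test_that("LOESS locates a generator peak within tolerance", {
  cfg <- cohort_config(seed = 71, noise_sigma = 0.1, zero_inflation = 0)
  sim <- simulate_cohort(cfg, trajectory_spec("peak", n = 5,
                                              peak_age = 20,
                                              peak_width = 8))
  # span 0.5: wide windows over-smooth and displace a width-8 crest
  lo <- fit_loess_trajectories(sim$table, sim$meta, span = 0.5,
                               standardize = FALSE)
  for (i in 1:5) {
    argmax <- lo$grid[which.max(lo$raw_curves[i, ])]
    expect_lt(abs(argmax - 20), 3)
  }
})

test_that("antithetic archetypes cluster perfectly at k = 2", {
  skip_if_not_installed("mclust")
  cfg <- cohort_config(seed = 83, noise_sigma = 0.1, zero_inflation = 0)
  specs <- list(trajectory_spec("peak", n = 20, peak_age = 20,
                                peak_width = 10, label = "crest"),
                trajectory_spec("linear", n = 20, beta = 0.02,
                                label = "rise"))
  sim <- simulate_cohort(cfg, specs)
  lo <- fit_loess_trajectories(sim$table, sim$meta)
  cl <- cluster_trajectories(lo$curves, k = 2)
  truth <- as.integer(grepl("^crest", names(cl$assignments)))
  ari <- mclust::adjustedRandIndex(cl$assignments, truth)
  expect_equal(ari, 1)
  # assignment is invariant to feature order
  perm <- sample(nrow(lo$curves))
  cl2 <- cluster_trajectories(lo$curves[perm, ], k = 2)
  expect_identical(cl2$assignments[names(cl$assignments)],
                   cl$assignments)
  expect_error(cluster_trajectories(lo$curves[1:3, ], k = 8), "exceeds")
  same <- lo$curves[rep(1, 5), ]
  rownames(same) <- paste0("dup", 1:5)
  expect_error(cluster_trajectories(same, k = 2), "distinct")
})

test_that("DE-SWAN counts equal a brute-force per-center oracle", {
  cfg <- cohort_config(seed = 101, noise_sigma = 0.25, zero_inflation = 0)
  specs <- list(trajectory_spec("step", n = 30, step_age = 40,
                                step_delta = 0.5),
                trajectory_spec("null", n = 70))
  sim <- simulate_cohort(cfg, specs)
  tn <- total_sum_normalize(sim$table)
  centers <- c(25, 40, 55)
  sw <- deswan(tn, sim$meta, centers = centers, window = 20)
  offset <- min(tn$values[tn$values > 0]) / 2
  age <- sim$meta$age
  male <- as.numeric(sim$meta$sex == "M")
  for (j in seq_along(centers)) {
    c0 <- centers[j]
    young <- which(age >= c0 - 10 & age < c0)
    old <- which(age > c0 & age <= c0 + 10)
    sel <- c(young, old)
    stratum <- c(rep(0, length(young)), rep(1, length(old)))
    p <- apply(log10(tn$values[, sel] + offset), 1, function(y) {
      fit <- lm(y ~ stratum + male[sel])
      anova_p <- anova(lm(y ~ male[sel] + stratum))
      anova_p["stratum", "Pr(>F)"]
    })
    expect_equal(sum(p.adjust(p, "BH") < 0.05, na.rm = TRUE),
                 sw$n_sig[j])
  }
})

test_that("step features place the global DE-SWAN peak near the step", {
  cfg <- cohort_config(seed = 103, noise_sigma = 0.2, zero_inflation = 0)
  specs <- list(trajectory_spec("step", n = 50, step_age = 40,
                                step_delta = 0.5),
                trajectory_spec("null", n = 50))
  sim <- simulate_cohort(cfg, specs)
  tn <- total_sum_normalize(sim$table)
  sw <- suppressWarnings(deswan(tn, sim$meta, window = 20))
  global_peak <- sw$centers[which.max(sw$n_sig)]
  expect_lte(abs(global_peak - 40), 5)
  expect_true(any(abs(sw$peaks - 40) <= 5))
  # monotone in signal strength: doubling the step never lowers the crest
  specs2 <- list(trajectory_spec("step", n = 50, step_age = 40,
                                 step_delta = 1),
                 trajectory_spec("null", n = 50))
  sim2 <- simulate_cohort(cfg, specs2)
  sw2 <- suppressWarnings(deswan(total_sum_normalize(sim2$table),
                                 sim2$meta, window = 20))
  expect_gte(max(sw2$n_sig, na.rm = TRUE), max(sw$n_sig, na.rm = TRUE))
})

test_that("samples exactly at a center belong to neither stratum", {
  ages <- c(30, 32, 34, 36, 38, 40, 42, 44, 46, 48, 50)
  ids <- sprintf("s%02d", seq_along(ages))
  m <- data.frame(sample_id = ids, age = ages,
                  sex = rep(c("F", "M"), length.out = length(ages)),
                  group = assign_life_stage(ages),
                  stringsAsFactors = FALSE)
  set.seed(7)
  v <- matrix(rexp(5 * length(ages)) + 0.1, 5, length(ages),
              dimnames = list(paste0("f", 1:5), ids))
  sw <- deswan(feature_table(v), m, centers = 40, window = 20)
  expect_identical(sw$n_young, 5L) # 30..38, not 40
  expect_identical(sw$n_old, 5L)   # 42..50, not 40
})
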