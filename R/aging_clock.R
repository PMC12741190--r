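# Elastic-net chronological-age clocks, broken-stick model reduction, and
# the triple-intersection biomarker panel with cross-validated ROC.

# Assemble the samples x features predictor matrix from one table or a
# list (combined clock): log10 with half-minimum offset per table,
# features prefixed by modality when combined.
clock_design <- function(tables, log_offset = NULL) {
  if (is_feature_table(tables)) tables <- list(tables)
  shared <- Reduce(intersect, lapply(tables, sample_ids))
  if (length(shared) == 0L) stop("tables share no samples")
  blocks <- lapply(tables, function(t) {
    Y <- log_offset_transform(t$values[, shared, drop = FALSE], base = 10,
                              offset = log_offset)
    if (length(tables) > 1L)
      rownames(Y) <- paste(t$modality, rownames(Y), sep = ":")
    base::t(Y)
  })
  X <- do.call(cbind, blocks)
  modality <- unlist(lapply(tables, function(t)
    rep(t$modality, nrow(t$values))))
  attr(X, "modality") <- stats::setNames(modality, colnames(X))
  X
}

# Stratified train/test split by life-stage group; deterministic in seed.
stratified_split <- function(m, train_fraction, seed) {
  set.seed(seed)
  train <- character()
  for (g in unique(as.character(m$group))) {
    ids <- m$sample_id[as.character(m$group) == g]
    n_tr <- round(train_fraction * length(ids))
    n_tr <- min(max(n_tr, 1L), length(ids) - 1L)
    if (length(ids) == 1L) n_tr <- 1L
    train <- c(train, sample(ids, n_tr))
  }
  test <- setdiff(m$sample_id, train)
  if (length(test) == 0L) stop("degenerate split: empty test set")
  list(train = train, test = test)
}

#' Fit an elastic-net aging clock
#'
#' For every combination of elastic-net mixing `alpha` and training
#' fraction: a stratified (by life-stage) train/test split, 10-fold
#' cross-validation of the penalty on the training set, and mean absolute
#' error of the age prediction on the held-out test set. The combination
#' with the smallest test MAE is returned, with coefficients from the
#' training-set fit at the selected lambda. Predictors are standardized
#' inside the penalized fit.
#'
#' @param tables A `FeatureTable` or list of them (metabolite + lipid for
#'   the combined clock).
#' @param m Sample metadata covering the shared samples.
#' @param alpha_grid Elastic-net mixing values; default 0.1-0.9.
#' @param train_fractions Training fractions, all >= 0.5; default
#'   `c(0.5, 0.6, 0.7, 0.8)`.
#' @param seed Integer seed governing splits and CV folds.
#' @param lambda_choice `"lambda.1se"` (parsimonious, default) or
#'   `"lambda.min"`.
#' @param nfolds CV folds for the penalty (default 10).
#' @param log_offset Offset for the log10 transform.
#' @return A `ClockModel` list: nonzero `coefficients` (named),
#'   `intercept`, `alpha`, `lambda`, `train_fraction`, `mae_test`,
#'   `r_test`, `predictions` (test-set frame), `trace` (all combinations),
#'   `feature_sd` (training-set predictor sds, for ranking), `train_ids`,
#'   `test_ids`, `modality`.
#' @export
fit_clock <- function(tables, m, alpha_grid = seq(0.1, 0.9, by = 0.1),
                      train_fractions = c(0.5, 0.6, 0.7, 0.8), seed = 1L,
                      lambda_choice = c("lambda.1se", "lambda.min"),
                      nfolds = 10, log_offset = NULL) {
  lambda_choice <- match.arg(lambda_choice)
  stopifnot(all(alpha_grid > 0 & alpha_grid < 1),
            all(train_fractions >= 0.5 & train_fractions < 1))
  X <- clock_design(tables, log_offset)
  modality <- attr(X, "modality")
  m <- m[match(rownames(X), m$sample_id), , drop = FALSE]
  if (nrow(m) < 30) stop("need >= 30 samples to fit a clock")
  age <- m$age
  best <- NULL
  trace <- list()
  for (frac in train_fractions) {
    split <- stratified_split(m, frac, derive_seed(seed, paste0("split",
                                                                frac)))
    tr <- match(split$train, rownames(X))
    te <- match(split$test, rownames(X))
    set.seed(derive_seed(seed, paste0("folds", frac)))
    foldid <- sample(rep(seq_len(nfolds), length.out = length(tr)))
    for (alpha in alpha_grid) {
      cv <- glmnet::cv.glmnet(X[tr, , drop = FALSE], age[tr],
                              alpha = alpha, foldid = foldid,
                              standardize = TRUE)
      lam <- cv[[lambda_choice]]
      pred <- as.numeric(stats::predict(cv, X[te, , drop = FALSE],
                                        s = lam))
      mae <- mean(abs(pred - age[te]))
      trace[[length(trace) + 1L]] <-
        data.frame(alpha = alpha, train_fraction = frac, lambda = lam,
                   mae = mae)
      if (is.null(best) || mae < best$mae) {
        best <- list(cv = cv, alpha = alpha, frac = frac, lambda = lam,
                     mae = mae, tr = tr, te = te, pred = pred,
                     split = split)
      }
    }
  }
  cf <- as.matrix(stats::coef(best$cv, s = best$lambda))
  nz <- cf[-1, 1][cf[-1, 1] != 0]
  pred_df <- data.frame(sample_id = rownames(X)[best$te],
                        age = age[best$te], predicted = best$pred,
                        stringsAsFactors = FALSE)
  r_test <- if (stats::sd(best$pred) == 0) NA_real_
            else stats::cor(best$pred, age[best$te])
  structure(list(
    coefficients = nz, intercept = cf[1, 1], alpha = best$alpha,
    lambda = best$lambda, train_fraction = best$frac,
    mae_test = best$mae, r_test = r_test, predictions = pred_df,
    trace = do.call(rbind, trace),
    feature_sd = apply(X[best$tr, , drop = FALSE], 2, stats::sd),
    train_ids = best$split$train, test_ids = best$split$test,
    modality = modality, lambda_choice = lambda_choice, seed = seed),
    class = "ClockModel")
}

#' @export
print.ClockModel <- function(x, ...) {
  cat(sprintf(paste0("ClockModel: %d nonzero features, alpha = %.2f, ",
                     "train fraction = %.2f\n  test MAE = %.2f years, ",
                     "test r = %.3f\n"),
              length(x$coefficients), x$alpha, x$train_fraction,
              x$mae_test, x$r_test))
  invisible(x)
}

#' Two-segment broken-stick regression
#'
#' Fits `y ~ a + b x + c (x - k)+` by exhaustive search over candidate
#' knots (ordinary least squares at each), returning the least-squares
#' knot. A low-confidence flag is raised when the two segments' slopes are
#' nearly equal (no identifiable break).
#'
#' @param x,y Numeric vectors (>= 4 points).
#' @param knot_grid Candidate knots; default a 0.1-step grid spanning the
#'   interior of `x`.
#' @return List: `knot`, `coefficients` (a, b, c), `fitted`, `sse`,
#'   `low_confidence`.
#' @export
broken_stick <- function(x, y, knot_grid = NULL) {
  if (length(x) < 4) stop("broken-stick fit needs >= 4 points")
  if (is.null(knot_grid)) {
    xs <- sort(unique(x))
    knot_grid <- seq(xs[2], xs[length(xs) - 1], by = 0.1)
  }
  best <- NULL
  for (k in knot_grid) {
    Xk <- cbind(1, x, pmax(x - k, 0))
    fit <- stats::lm.fit(Xk, y)
    sse <- sum(fit$residuals^2)
    if (is.null(best) || sse < best$sse)
      best <- list(knot = k, coefficients = fit$coefficients,
                   fitted = fit$fitted.values, sse = sse)
  }
  b <- best$coefficients
  scale_y <- max(stats::sd(y), .Machine$double.eps)
  span_x <- diff(range(x))
  # slope change small relative to the curve's overall variation
  best$low_confidence <- is.na(b[3]) ||
    abs(b[3]) * span_x < 0.1 * scale_y
  best
}

#' Reduce a clock by ranked refits and broken-stick breakpoint
#'
#' Ranks the clock's nonzero features by standardized coefficient
#' magnitude, refits elastic-net clocks on the top 2, 3, 4, ... features
#' (80% training split, alpha grid, CV lambda), records test accuracy
#' (Pearson r of predicted vs chronological age by default), locates the
#' breakpoint of the accuracy-vs-size curve by two-segment broken-stick
#' regression, and refits the final model at the breakpoint size.
#'
#' @param model A fitted [fit_clock()] `ClockModel` with >= 3 nonzero
#'   coefficients.
#' @param tables,m As in [fit_clock()].
#' @param alpha_grid Elastic-net mixing values for the refits.
#' @param seed Integer seed.
#' @param metric `"r"` (default) or `"mae"` for the accuracy curve.
#' @param train_fraction Training fraction for the refits (default 0.8).
#' @param max_features Cap on the curve length (default all ranked
#'   features).
#' @param log_offset Offset for the log10 transform.
#' @return A `ReducedClock` list: `ranked_features`, `accuracy_curve`
#'   (`n_features`, `accuracy`), `breakpoint`, `low_confidence`,
#'   `final_model`.
#' @export
reduce_clock <- function(model, tables, m,
                         alpha_grid = seq(0.1, 0.9, by = 0.1), seed = 1L,
                         metric = c("r", "mae"), train_fraction = 0.8,
                         max_features = NULL, log_offset = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "ClockModel"))
  if (length(model$coefficients) < 3)
    stop("reduced clock needs >= 3 nonzero coefficients")
  std_coef <- abs(model$coefficients) *
    model$feature_sd[names(model$coefficients)]
  ranked <- names(sort(std_coef, decreasing = TRUE))
  J <- length(ranked)
  if (!is.null(max_features)) J <- min(J, max_features)
  if (J < 4) stop("accuracy curve would have fewer than 4 points")
  X <- clock_design(tables, log_offset)
  m <- m[match(rownames(X), m$sample_id), , drop = FALSE]
  age <- m$age
  split <- stratified_split(m, train_fraction,
                            derive_seed(seed, "reduce_split"))
  tr <- match(split$train, rownames(X))
  te <- match(split$test, rownames(X))
  set.seed(derive_seed(seed, "reduce_folds"))
  foldid <- sample(rep(seq_len(10), length.out = length(tr)))
  fit_top <- function(j) {
    Xj <- X[, ranked[seq_len(j)], drop = FALSE]
    best <- NULL
    for (alpha in alpha_grid) {
      cv <- glmnet::cv.glmnet(Xj[tr, , drop = FALSE], age[tr],
                              alpha = alpha, foldid = foldid,
                              standardize = TRUE)
      pred <- as.numeric(stats::predict(cv, Xj[te, , drop = FALSE],
                                        s = cv$lambda.min))
      mae <- mean(abs(pred - age[te]))
      if (is.null(best) || mae < best$mae)
        best <- list(cv = cv, pred = pred, mae = mae, alpha = alpha)
    }
    best
  }
  acc <- numeric(J - 1)
  fits <- vector("list", J - 1)
  for (j in 2:J) {
    f <- fit_top(j)
    fits[[j - 1]] <- f
    acc[j - 1] <- if (metric == "mae") f$mae else {
      if (stats::sd(f$pred) == 0) 0 else stats::cor(f$pred, age[te])
    }
  }
  curve <- data.frame(n_features = 2:J, accuracy = acc)
  bs <- broken_stick(curve$n_features, curve$accuracy)
  breakpoint <- min(max(round(bs$knot), 2L), J)
  final_f <- fits[[breakpoint - 1]]
  cf <- as.matrix(stats::coef(final_f$cv, s = final_f$cv$lambda.min))
  nz <- cf[-1, 1][cf[-1, 1] != 0]
  final_model <- structure(list(
    coefficients = nz, intercept = cf[1, 1], alpha = final_f$alpha,
    lambda = final_f$cv$lambda.min, train_fraction = train_fraction,
    mae_test = final_f$mae,
    r_test = if (stats::sd(final_f$pred) == 0) NA_real_
             else stats::cor(final_f$pred, age[te]),
    predictions = data.frame(sample_id = rownames(X)[te], age = age[te],
                             predicted = final_f$pred,
                             stringsAsFactors = FALSE),
    trace = NULL, feature_sd = model$feature_sd,
    train_ids = split$train, test_ids = split$test,
    modality = model$modality, lambda_choice = "lambda.min",
    seed = seed), class = "ClockModel")
  structure(list(ranked_features = ranked[seq_len(J)],
                 accuracy_curve = curve, metric = metric,
                 breakpoint = breakpoint,
                 low_confidence = bs$low_confidence,
                 broken_stick = bs, final_model = final_model),
            class = "ReducedClock")
}

#' Triple-intersection biomarker selection
#'
#' Intersects (1) features significantly up in the elderly-vs-young
#' contrast, (2) features with a significant positive linear age slope,
#' and (3) features carrying nonzero clock coefficients.
#'
#' @param de_elderly [de_elderly_vs_young()] (or compatible) result frame.
#' @param age_models [fit_linear_age()] result frame.
#' @param clock A `ClockModel`.
#' @param q_thresh Significance threshold for sets 1 and 2.
#' @return List: `sets` (the three feature-id vectors), `intersection`
#'   (triple), `pairwise` (named counts), `counts`.
#' @export
select_panel <- function(de_elderly, age_models, clock, q_thresh = 0.05) {
  clock_feats <- names(clock$coefficients)
  # strip modality prefixes from a combined clock
  clock_feats <- sub("^(metabolite|lipid):", "", clock_feats)
  universe <- union(de_elderly$feature_id, age_models$feature_id)
  if (length(universe) == 0L) stop("empty feature universe")
  set1 <- de_elderly$feature_id[de_elderly$direction == "up"]
  set2 <- age_models$feature_id[!is.na(age_models$q_age) &
                                  age_models$q_age < q_thresh &
                                  age_models$beta_age > 0]
  set3 <- clock_feats
  triple <- Reduce(intersect, list(set1, set2, set3))
  pairwise <- c(elderly_linear = length(intersect(set1, set2)),
                elderly_clock = length(intersect(set1, set3)),
                linear_clock = length(intersect(set2, set3)))
  list(sets = list(elderly_up = set1, linear_increase = set2,
                   clock = set3),
       intersection = triple, pairwise = pairwise,
       counts = c(elderly_up = length(set1),
                  linear_increase = length(set2), clock = length(set3),
                  triple = length(triple)))
}

#' ROC curve and AUC from scores
#'
#' Builds the empirical ROC by sweeping thresholds over the unique scores
#' and integrates by the trapezoid rule (equivalently, the tie-corrected
#' rank statistic of the two-sample comparison).
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Logical or 0/1 vector of true classes.
#' @return List with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels))
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  tpr <- c(0, vapply(thr, function(s) sum(scores >= s & labels) / n_pos,
                     numeric(1)))
  fpr <- c(0, vapply(thr, function(s) sum(scores >= s & !labels) / n_neg,
                     numeric(1)))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr,
                           threshold = c(Inf, thr)), auc = auc)
}

#' Cross-validated elderly-vs-young panel classifier
#'
#' Penalized logistic regression (elastic net) on the selected panel
#' features, discriminating elderly (age >= `elderly_cut`) from young
#' (age < `young_cut`) samples; middle-aged samples are excluded.
#' Performance is the mean ROC AUC over stratified k-fold
#' cross-validation; the fold count is reduced with a warning when a class
#' is smaller than `k_folds`.
#'
#' @param features Character vector of panel feature ids.
#' @param t A normalized `FeatureTable` containing them.
#' @param m Sample metadata.
#' @param k_folds Cross-validation folds (default 10).
#' @param seed Integer seed.
#' @param elderly_cut,young_cut Age cut-offs (65 / 40 years).
#' @param alpha Elastic-net mixing for the logistic fit (default 0.5).
#' @param log_offset Offset for the log10 transform.
#' @return A `PanelResult` list: `selected_features`, `cv_auc_mean`,
#'   `fold_auc`, `roc_points` (per fold), `coefficients` (full-data fit),
#'   `n_elderly`, `n_young`, `k_folds`.
#' @export
fit_panel_classifier <- function(features, t, m, k_folds = 10, seed = 1L,
                                 elderly_cut = 65, young_cut = 40,
                                 alpha = 0.5, log_offset = NULL) {
  miss <- setdiff(features, feature_ids(t))
  if (length(miss))
    stop("panel feature(s) missing from table: ",
         paste(miss, collapse = ", "))
  m <- validate_sample_meta(m, t)
  m <- m[match(sample_ids(t), m$sample_id), , drop = FALSE]
  keep <- m$age >= elderly_cut | m$age < young_cut
  X <- base::t(log_offset_transform(
    t$values[features, keep, drop = FALSE], base = 10,
    offset = log_offset))
  y <- as.numeric(m$age[keep] >= elderly_cut)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos < 2 || n_neg < 2) stop("need >= 2 samples in each class")
  k <- k_folds
  if (min(n_pos, n_neg) < k) {
    k <- max(2L, min(n_pos, n_neg))
    warning("class smaller than k_folds; using ", k, " folds")
  }
  set.seed(derive_seed(seed, "panel_folds"))
  fold <- integer(length(y))
  fold[y == 1] <- sample(rep(seq_len(k), length.out = n_pos))
  fold[y == 0] <- sample(rep(seq_len(k), length.out = n_neg))
  fold_auc <- numeric(k)
  roc_points <- list()
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = alpha,
                          standardize = TRUE)
    lam <- min(fit$lambda) # near-unpenalized end of the path
    sc <- as.numeric(stats::predict(fit, X[te, , drop = FALSE], s = lam,
                                    type = "link"))
    if (length(unique(y[te])) < 2) {
      fold_auc[f] <- NA_real_
      next
    }
    roc <- roc_curve(sc, y[te] == 1)
    fold_auc[f] <- roc$auc
    roc$points$fold <- f
    roc_points[[f]] <- roc$points
  }
  full_fit <- glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                             standardize = TRUE)
  cf <- as.matrix(stats::coef(full_fit, s = min(full_fit$lambda)))
  structure(list(selected_features = features,
                 cv_auc_mean = mean(fold_auc, na.rm = TRUE),
                 fold_auc = fold_auc,
                 roc_points = do.call(rbind, roc_points),
                 coefficients = stats::setNames(cf[, 1], rownames(cf)),
                 n_elderly = n_pos, n_young = n_neg, k_folds = k,
                 alpha = alpha), class = "PanelResult")
}

#' Export a clock model as JSON
#' @param model A `ClockModel`.
#' @param path Output `.json` path.
#' @export
write_clock_json <- function(model, path) {
  obj <- list(feature_ids = names(model$coefficients),
              coefficients = unname(model$coefficients),
              intercept = model$intercept, alpha = model$alpha,
              lambda = model$lambda,
              train_fraction = model$train_fraction,
              mae_test = model$mae_test, r_test = model$r_test)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
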