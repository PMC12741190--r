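# Per-feature linear age models with a sex covariate, LOESS trajectory
# fitting/clustering, and sliding-window differential expression (DE-SWAN).

# Fast per-feature OLS over a shared design: Y is features x samples.
# Returns coefficients and the partial F-test p for one term obtained by
# comparing against the design with that term removed (Type II sums of
# squares in an additive model).
ols_partial_f <- function(Y, X, term) {
  stopifnot(term %in% colnames(X))
  n <- ncol(Y); p_full <- ncol(X)
  qr_full <- qr(X)
  X0 <- X[, setdiff(colnames(X), term), drop = FALSE]
  qr_red <- qr(X0)
  Yt <- t(Y) # samples x features
  beta <- qr.coef(qr_full, Yt)
  res_full <- qr.resid(qr_full, Yt)
  res_red <- qr.resid(qr_red, Yt)
  rss1 <- colSums(res_full^2)
  rss0 <- colSums(res_red^2)
  df2 <- n - p_full
  f <- (rss0 - rss1) / (rss1 / df2)
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  list(coef = t(beta), f = f, p = p, rss = rss1, df2 = df2)
}

#' Per-feature linear age model with a sex covariate
#'
#' Fits `log10(abundance + offset) ~ intercept + age + sex` by ordinary
#' least squares for every feature, tests the age term with a Type II
#' partial F-test, and BH-adjusts across features. Zero-variance features
#' are flagged and excluded from the BH family.
#'
#' @param t A normalized `FeatureTable`.
#' @param m Sample metadata (>= 3 distinct ages; both sexes present when
#'   `use_sex`).
#' @param use_sex Include the sex indicator (default TRUE).
#' @param q_thresh Threshold for the `increase`/`decrease` call.
#' @param log_offset Offset for the log10 transform (`NULL` = half-minimum).
#' @return Data frame per feature: `feature_id`, `alpha_hat`, `beta_age`,
#'   `beta_sex`, `p_age`, `q_age`, `direction`
#'   (`increase`/`decrease`/`ns`), `degenerate`.
#' @export
fit_linear_age <- function(t, m, use_sex = TRUE, q_thresh = 0.05,
                           log_offset = NULL) {
  m <- validate_sample_meta(m, t)
  m <- m[match(sample_ids(t), m$sample_id), , drop = FALSE]
  if (length(unique(m$age)) < 3) stop("need >= 3 distinct ages")
  if (use_sex && length(unique(m$sex)) < 2)
    stop("both sexes must be present for the sex covariate")
  Y <- log_offset_transform(t$values, base = 10, offset = log_offset)
  X <- cbind(intercept = 1, age = m$age)
  if (use_sex) X <- cbind(X, sex = as.numeric(m$sex == "M"))
  degenerate <- apply(Y, 1, stats::sd) == 0
  fit <- ols_partial_f(Y, X, "age")
  p_age <- fit$p
  p_age[degenerate] <- NA_real_
  q_age <- bh_adjust(p_age)
  beta_age <- fit$coef[, "age"]
  direction <- rep("ns", nrow(Y))
  sig <- !is.na(q_age) & q_age < q_thresh
  direction[sig & beta_age > 0] <- "increase"
  direction[sig & beta_age < 0] <- "decrease"
  data.frame(feature_id = feature_ids(t),
             alpha_hat = fit$coef[, "intercept"],
             beta_age = beta_age,
             beta_sex = if (use_sex) fit$coef[, "sex"] else NA_real_,
             p_age = p_age, q_age = q_age, direction = direction,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' LOESS age trajectories on a common grid
#'
#' Per feature, a locally weighted quadratic regression (tricube weights)
#' of log10 abundance on age, evaluated on an age grid and optionally
#' z-standardized over the grid for clustering. Constant fitted curves
#' cannot be standardized and are excluded with a flag.
#'
#' @param t A normalized `FeatureTable`.
#' @param m Sample metadata.
#' @param span LOESS span in (0, 1]; default 0.75.
#' @param degree Local polynomial degree; default 2.
#' @param grid Age grid (within the observed range); default 50 points.
#' @param standardize Z-score each curve over the grid (default TRUE).
#' @param log_offset Offset for the log10 transform.
#' @return List with `curves` (features x grid matrix, standardized if
#'   requested), `raw_curves`, `grid`, and `excluded` (flagged ids).
#' @export
fit_loess_trajectories <- function(t, m, span = 0.75, degree = 2,
                                   grid = NULL, standardize = TRUE,
                                   log_offset = NULL) {
  stopifnot(span > 0, span <= 1)
  m <- validate_sample_meta(m, t)
  m <- m[match(sample_ids(t), m$sample_id), , drop = FALSE]
  age <- m$age
  if (is.null(grid)) grid <- seq(min(age), max(age), length.out = 50)
  if (min(grid) < min(age) || max(grid) > max(age))
    stop("grid must lie within the observed age range")
  if (span * length(age) < degree + 1)
    stop("too few points in the local window; increase span")
  Y <- log_offset_transform(t$values, base = 10, offset = log_offset)
  raw <- t(apply(Y, 1, function(y) {
    fit <- stats::loess(y ~ age, span = span, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    stats::predict(fit, newdata = data.frame(age = grid))
  }))
  colnames(raw) <- signif(grid, 6)
  sds <- apply(raw, 1, stats::sd)
  # numerically flat curves cannot be z-scored
  flat <- sds <= 1e-10 * pmax(abs(rowMeans(raw)), 1)
  excluded <- feature_ids(t)[flat | !is.finite(sds)]
  curves <- raw
  if (standardize) {
    keep <- !(feature_ids(t) %in% excluded)
    curves <- raw[keep, , drop = FALSE]
    curves <- t(scale(t(curves)))
  }
  list(curves = curves, raw_curves = raw, grid = grid, excluded = excluded)
}

#' Hierarchical clustering of standardized trajectories
#'
#' Agglomerative clustering (Euclidean distance, complete linkage by
#' default) of the standardized LOESS curves, with the tree cut into `k`
#' clusters; the study convention is k = 8.
#'
#' @param curves Features x grid matrix (standardized), as from
#'   [fit_loess_trajectories()].
#' @param k Number of clusters (default 8).
#' @param linkage `hclust` method: `"complete"`, `"ward.D2"`, `"average"`.
#' @return List with `assignments` (named integer vector), `mean_curves`
#'   (k x grid matrix of member averages) and `tree` (the `hclust`).
#' @export
cluster_trajectories <- function(curves, k = 8,
                                 linkage = c("complete", "ward.D2",
                                             "average")) {
  linkage <- match.arg(linkage)
  if (nrow(curves) < k)
    stop("k = ", k, " exceeds the ", nrow(curves), " available curves")
  if (nrow(unique(curves)) < k)
    stop("only ", nrow(unique(curves)), " distinct curves for k = ", k)
  ord <- order(rownames(curves)) # order-invariant clustering input
  tree <- stats::hclust(stats::dist(curves[ord, , drop = FALSE]),
                        method = linkage)
  cl <- stats::cutree(tree, k = k)
  assignments <- cl[rownames(curves)]
  mean_curves <- t(vapply(seq_len(k), function(i)
    colMeans(curves[assignments == i, , drop = FALSE]),
    numeric(ncol(curves))))
  rownames(mean_curves) <- paste0("cluster_", seq_len(k))
  list(assignments = assignments, mean_curves = mean_curves, tree = tree)
}

#' Sliding-window differential expression across age (DE-SWAN)
#'
#' For each center `c` on the age axis, samples with age in
#' `[c - window/2, c)` form the young stratum and `(c, c + window/2]` the
#' old stratum (samples exactly at the center belong to neither). Per
#' feature, log10 abundance is regressed on the stratum indicator plus a
#' sex covariate; the stratum term's partial F-test p-values are
#' BH-adjusted across features within the center, and `n_sig` counts
#' `q < q_thresh`. Centers with fewer than 3 samples on either side are
#' skipped and recorded.
#'
#' The headline analysis walks 1-year centers with a 20-year total window;
#' a 5-year window reproduces the narrow-window variant.
#'
#' @param t A normalized `FeatureTable`.
#' @param m Sample metadata.
#' @param centers Age grid of window centers; default every year from
#'   `min(age) + window/2` to `max(age) - window/2`.
#' @param window Total window width in years (default 20).
#' @param q_thresh Significance threshold (default 0.05).
#' @param use_sex Include the sex covariate (default TRUE).
#' @param log_offset Offset for the log10 transform.
#' @return A `SwanCurve` list: `centers`, `n_sig`, `n_young`, `n_old`,
#'   `skipped`, `window`, `peaks`, plus the per-feature `p_matrix` and
#'   `q_matrix` (features x centers).
#' @export
deswan <- function(t, m, centers = NULL, window = 20, q_thresh = 0.05,
                   use_sex = TRUE, log_offset = NULL) {
  stopifnot(window > 0)
  m <- validate_sample_meta(m, t)
  m <- m[match(sample_ids(t), m$sample_id), , drop = FALSE]
  age <- m$age
  if (is.null(centers)) {
    lo <- ceiling(min(age) + window / 2)
    hi <- floor(max(age) - window / 2)
    if (hi < lo) stop("window wider than the observed age range")
    centers <- seq(lo, hi, by = 1)
  }
  Y <- log_offset_transform(t$values, base = 10, offset = log_offset)
  male <- as.numeric(m$sex == "M")
  n_feat <- nrow(Y)
  n_sig <- rep(NA_real_, length(centers))
  n_young <- n_old <- integer(length(centers))
  q_matrix <- p_matrix <- matrix(NA_real_, n_feat, length(centers),
                                 dimnames = list(feature_ids(t),
                                                 as.character(centers)))
  for (i in seq_along(centers)) {
    c0 <- centers[i]
    young <- which(age >= c0 - window / 2 & age < c0)
    old <- which(age > c0 & age <= c0 + window / 2)
    n_young[i] <- length(young); n_old[i] <- length(old)
    if (length(young) < 3 || length(old) < 3) next
    sel <- c(young, old)
    X <- cbind(intercept = 1,
               stratum = c(rep(0, length(young)), rep(1, length(old))))
    if (use_sex && length(unique(male[sel])) > 1)
      X <- cbind(X, sex = male[sel])
    fit <- ols_partial_f(Y[, sel, drop = FALSE], X, "stratum")
    p <- fit$p
    p[!is.finite(p)] <- NA_real_
    q <- bh_adjust(p)
    p_matrix[, i] <- p
    q_matrix[, i] <- q
    n_sig[i] <- sum(q < q_thresh, na.rm = TRUE)
  }
  skipped <- centers[is.na(n_sig)]
  if (length(skipped))
    warning("center(s) skipped for underpopulated strata: ",
            paste(skipped, collapse = ", "))
  peaks <- find_swan_peaks(centers, n_sig)
  structure(list(centers = centers, n_sig = n_sig, n_young = n_young,
                 n_old = n_old, skipped = skipped, window = window,
                 q_thresh = q_thresh, peaks = peaks, q_matrix = q_matrix,
                 p_matrix = p_matrix),
            class = "SwanCurve")
}

#' Deterministic peak calling on a DE-SWAN count curve
#'
#' A center is a peak iff its significant-feature count is maximal within
#' `+/- neighborhood` years and exceeds the curve median by at least
#' `mad_mult` raw median absolute deviations. Runs of tied neighboring
#' candidates are collapsed to their middle center.
#'
#' @param centers Age grid.
#' @param n_sig Significant-feature counts (NA for skipped centers).
#' @param neighborhood Half-width of the local-maximum test, years.
#' @param mad_mult Required prominence in raw MADs above the median.
#' @return Numeric vector of peak center ages (possibly empty).
#' @export
find_swan_peaks <- function(centers, n_sig, neighborhood = 5,
                            mad_mult = 2) {
  ok <- !is.na(n_sig)
  if (!any(ok)) return(numeric())
  med <- stats::median(n_sig[ok])
  madv <- stats::mad(n_sig[ok], constant = 1)
  thresh <- med + mad_mult * madv
  cand <- logical(length(centers))
  for (i in which(ok)) {
    near <- ok & abs(centers - centers[i]) <= neighborhood
    cand[i] <- n_sig[i] == max(n_sig[near]) & n_sig[i] > thresh
  }
  if (!any(cand)) return(numeric())
  # collapse consecutive tied candidates to the middle center of each run
  idx <- which(cand)
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  unname(vapply(runs, function(r) centers[r[ceiling(length(r) / 2)]],
                numeric(1)))
}
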