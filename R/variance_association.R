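# PCA, principal variance component analysis (PVCA), and Spearman
# correlation networks between metabolites and lipids.

#' PCA sample scores on the log2 abundance matrix
#'
#' Features are log2-transformed (half-minimum offset), centered, and the
#' samples projected onto principal components. Constant features are
#' dropped with a warning.
#'
#' @param t A normalized `FeatureTable`.
#' @param n_components Number of PCs to return (default all).
#' @param scale. Also scale features to unit variance (default FALSE).
#' @param log_offset Offset for the log2 transform.
#' @return List with `scores` (samples x PCs), `explained` (variance
#'   fractions, non-increasing), `sdev` and the `prcomp` object.
#' @export
pca_scores <- function(t, n_components = NULL, scale. = FALSE,
                       log_offset = NULL) {
  if (ncol(t$values) < 2) stop("PCA needs more than one sample")
  Y <- log_offset_transform(t$values, base = 2, offset = log_offset)
  constant <- apply(Y, 1, stats::sd) == 0
  if (any(constant)) {
    warning(sum(constant), " constant feature(s) dropped before PCA")
    Y <- Y[!constant, , drop = FALSE]
  }
  pc <- stats::prcomp(base::t(Y), center = TRUE, scale. = scale.)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (is.null(n_components)) length(explained)
       else min(n_components, length(explained))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = explained[seq_len(k)], sdev = pc$sdev, prcomp = pc)
}

# Random-effects variance components of one PC score vector over the
# factors; REML via lme4 with a method-of-moments fallback.
pc_variance_components <- function(score, fac_list) {
  df <- data.frame(score = score, fac_list)
  terms <- paste(sprintf("(1 | %s)", names(fac_list)), collapse = " + ")
  form <- stats::as.formula(paste("score ~ 1 +", terms))
  fit <- tryCatch(
    lme4::lmer(form, data = df, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    vars <- stats::setNames(vc$vcov, vc$grp)
    out <- c(vars[names(fac_list)], residual = vars[["Residual"]])
    names(out) <- c(names(fac_list), "residual")
    out[is.na(out)] <- 0
    return(out)
  }
  # method-of-moments fallback: between-level variance of level means,
  # truncated at zero, residual as the remainder
  message("REML failed for one component; method-of-moments fallback used")
  total <- stats::var(score)
  comps <- vapply(fac_list, function(f) {
    mom <- stats::var(tapply(score, f, mean))
    max(0, mom)
  }, numeric(1))
  resid <- max(total - sum(comps), 0)
  c(comps, residual = resid)
}

#' Principal variance component analysis
#'
#' Projects the log2 abundance matrix onto the top principal components
#' (retaining the smallest set covering at least `variance_kept` of the
#' variance), decomposes each retained PC's score variance into random
#' effects for age (the seven life-stage groups), sex, and their
#' interaction, averages the per-PC fractions with eigenvalue weights, and
#' normalizes to sum 1. Age enters as the categorical life-stage factor: a
#' classical variance-component decomposition needs grouping levels, and
#' the seven-stage design is the study's own stratification.
#'
#' @param t A normalized `FeatureTable`.
#' @param m Sample metadata.
#' @param variance_kept Cumulative explained-variance target in (0, 1];
#'   default 0.6.
#' @param log_offset Offset for the log2 transform.
#' @return Data frame with `factor` in
#'   `c("age", "sex", "age_sex", "residual")` and `fraction` (sums to 1);
#'   the per-PC decomposition is attached as attribute `per_pc`.
#' @export
pvca <- function(t, m, variance_kept = 0.6, log_offset = NULL) {
  stopifnot(variance_kept > 0, variance_kept <= 1)
  m <- validate_sample_meta(m, t)
  m <- m[match(sample_ids(t), m$sample_id), , drop = FALSE]
  pc <- pca_scores(t, log_offset = log_offset)
  k <- which(cumsum(pc$explained) >= variance_kept)[1]
  if (is.na(k)) k <- length(pc$explained)
  k <- max(k, 1L)
  fac_list <- list(age = factor(as.character(m$group)),
                   sex = factor(as.character(m$sex)),
                   age_sex = interaction(m$group, m$sex, drop = TRUE))
  single <- vapply(fac_list, function(f) nlevels(f) < 2, logical(1))
  if (any(single)) {
    warning("single-level factor(s) get zero fraction: ",
            paste(names(fac_list)[single], collapse = ", "))
    fac_list <- fac_list[!single]
  }
  per_pc <- vapply(seq_len(k), function(i) {
    v <- pc_variance_components(pc$scores[, i], fac_list)
    v / sum(v)
  }, numeric(length(fac_list) + 1))
  weights <- pc$explained[seq_len(k)] / sum(pc$explained[seq_len(k)])
  avg <- as.numeric(per_pc %*% weights)
  names(avg) <- rownames(per_pc)
  full <- stats::setNames(numeric(4),
                          c("age", "sex", "age_sex", "residual"))
  full[names(avg)] <- avg
  full <- full / sum(full)
  out <- data.frame(factor = names(full), fraction = as.numeric(full),
                    stringsAsFactors = FALSE)
  attr(out, "per_pc") <- per_pc
  attr(out, "n_components") <- k
  out
}

# Spearman correlation with average ranks and a t-approximation p-value.
spearman_pair <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  if (is.na(rho) || abs(rho) == 1) {
    p <- if (is.na(rho)) NA_real_ else 0
  } else {
    stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(stat), n - 2, lower.tail = FALSE)
  }
  c(rho = rho, p = p)
}

#' Metabolite-lipid Spearman correlation network
#'
#' Ranks each table's features by `|beta_age|` among those significant in
#' the linear age model (`q_age < q_thresh`, optionally restricted to one
#' direction), takes the top `top_n` per side, scores all cross-pairs by
#' Spearman correlation, and retains edges with `|rho| > rho_thresh` and
#' `p < p_thresh`, annotated with both endpoints' age slopes.
#'
#' @param metab,lipid `FeatureTable`s sharing a sample set.
#' @param metab_age,lipid_age Matching [fit_linear_age()] result frames.
#' @param top_n Features kept per side (default 50).
#' @param rho_thresh Absolute-correlation threshold (default 0.5).
#' @param p_thresh Correlation p-value threshold (default 0.05).
#' @param direction Restrict endpoints to `"increase"`, `"decrease"`, or
#'   `"any"` significant age trend (default `"increase"`).
#' @return Data frame of retained edges: `feature_a` (metabolite),
#'   `feature_b` (lipid), `rho`, `p`, `beta_a`, `beta_b`. The full rho
#'   matrix is attached as attribute `rho_matrix`.
#' @export
spearman_network <- function(metab, lipid, metab_age, lipid_age,
                             top_n = 50, rho_thresh = 0.5,
                             p_thresh = 0.05,
                             direction = c("increase", "decrease", "any")) {
  direction <- match.arg(direction)
  shared <- intersect(sample_ids(metab), sample_ids(lipid))
  if (length(shared) == 0L) stop("sample sets are disjoint")
  pick <- function(age_res, ids) {
    sel <- age_res[!is.na(age_res$q_age) & age_res$q_age < 0.05 &
                     age_res$feature_id %in% ids, , drop = FALSE]
    if (direction != "any")
      sel <- sel[sel$direction == direction, , drop = FALSE]
    sel <- sel[order(-abs(sel$beta_age)), , drop = FALSE]
    utils::head(sel, top_n)
  }
  top_m <- pick(metab_age, feature_ids(metab))
  top_l <- pick(lipid_age, feature_ids(lipid))
  if (nrow(top_m) == 0L || nrow(top_l) == 0L)
    stop("no significant age-trending features on one side")
  Xm <- metab$values[top_m$feature_id, shared, drop = FALSE]
  Xl <- lipid$values[top_l$feature_id, shared, drop = FALSE]
  rho_mat <- matrix(NA_real_, nrow(Xm), nrow(Xl),
                    dimnames = list(rownames(Xm), rownames(Xl)))
  edges <- list()
  for (i in seq_len(nrow(Xm))) for (j in seq_len(nrow(Xl))) {
    sp <- spearman_pair(Xm[i, ], Xl[j, ])
    rho_mat[i, j] <- sp["rho"]
    if (!is.na(sp["rho"]) && abs(sp["rho"]) > rho_thresh &&
        !is.na(sp["p"]) && sp["p"] < p_thresh) {
      edges[[length(edges) + 1L]] <- data.frame(
        feature_a = rownames(Xm)[i], feature_b = rownames(Xl)[j],
        rho = sp[["rho"]], p = sp[["p"]],
        beta_a = top_m$beta_age[i], beta_b = top_l$beta_age[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(edges)) do.call(rbind, edges)
         else data.frame(feature_a = character(), feature_b = character(),
                         rho = numeric(), p = numeric(),
                         beta_a = numeric(), beta_b = numeric(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "rho_matrix") <- rho_mat
  out
}

#' Export a correlation network as GraphML
#'
#' Writes a Cytoscape-loadable GraphML file with `rho`, `p` edge
#' attributes and `beta_age`, `side` node attributes.
#'
#' @param edges Edge frame from [spearman_network()].
#' @param path Output `.graphml` path.
#' @export
write_network_graphml <- function(edges, path) {
  nodes <- unique(data.frame(
    id = c(edges$feature_a, edges$feature_b),
    side = rep(c("metabolite", "lipid"),
               c(nrow(edges), nrow(edges))),
    beta = c(edges$beta_a, edges$beta_b), stringsAsFactors = FALSE))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
    "<key id=\"side\" for=\"node\" attr.name=\"side\" attr.type=\"string\"/>",
    "<key id=\"beta\" for=\"node\" attr.name=\"beta_age\" attr.type=\"double\"/>",
    "<key id=\"rho\" for=\"edge\" attr.name=\"rho\" attr.type=\"double\"/>",
    "<key id=\"p\" for=\"edge\" attr.name=\"p\" attr.type=\"double\"/>",
    "<graph edgedefault=\"undirected\">"), con)
  for (i in seq_len(nrow(nodes)))
    writeLines(sprintf(
      "  <node id=\"%s\"><data key=\"side\">%s</data><data key=\"beta\">%.12g</data></node>",
      esc(nodes$id[i]), nodes$side[i], nodes$beta[i]), con)
  for (i in seq_len(nrow(edges)))
    writeLines(sprintf(
      "  <edge source=\"%s\" target=\"%s\"><data key=\"rho\">%.12g</data><data key=\"p\">%.12g</data></edge>",
      esc(edges$feature_a[i]), esc(edges$feature_b[i]), edges$rho[i],
      edges$p[i]), con)
  writeLines(c("</graph>", "</graphml>"), con)
  invisible(path)
}
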