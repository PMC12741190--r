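# Group-wise differential expression, BH correction, marker discovery,
# class-level change scores, and pathway over-representation.

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in [0, 1] (NAs passed through).
#' @return Adjusted q-values (order-preserving, capped at 1).
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# log10 with the table-wide half-minimum offset unless one is supplied.
de_log_matrix <- function(t, log_offset = NULL) {
  log_offset_transform(t$values, base = 10, offset = log_offset)
}

welch_row <- function(xa, xb, var_equal = FALSE) {
  if (stats::sd(xa) == 0 && stats::sd(xb) == 0)
    return(c(t = NA_real_, p = NA_real_))
  tt <- stats::t.test(xa, xb, var.equal = var_equal)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Two-group differential expression
#'
#' Per feature, a two-sided t-test (Welch by default) on log10-transformed
#' abundances, BH-adjusted across all features of the comparison. The
#' log2 fold change is group `a` over group `b` on the (offset) raw scale.
#' Features with zero variance in both groups are flagged degenerate
#' (`p = NA`, direction `ns`) and excluded from the BH family.
#'
#' @param t A `FeatureTable` (normalized).
#' @param m Sample metadata.
#' @param a,b Life-stage labels to compare (a vs b).
#' @param q_thresh Significance threshold on the BH-adjusted p.
#' @param log_offset Offset for the log10 transform (`NULL` for the
#'   half-minimum default).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Data frame with one row per feature: `feature_id`, `group_a`,
#'   `group_b`, `log2fc`, `t_stat`, `p`, `q`, `direction`
#'   (`up`/`down`/`ns`), `degenerate`.
#' @export
de_two_groups <- function(t, m, a, b, q_thresh = 0.05, log_offset = NULL,
                          var_equal = FALSE) {
  m <- validate_sample_meta(m, t)
  grp <- as.character(m$group[match(sample_ids(t), m$sample_id)])
  ia <- which(grp == a); ib <- which(grp == b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("each group needs >= 2 samples (", a, ": ", length(ia), ", ",
         b, ": ", length(ib), ")")
  offset <- if (is.null(log_offset)) smallest_positive(t$values) / 2
            else log_offset
  lx <- log_offset_transform(t$values, base = 10, offset = offset)
  stats_mat <- t(apply(lx, 1, function(y) welch_row(y[ia], y[ib],
                                                    var_equal)))
  mean_a <- rowMeans(t$values[, ia, drop = FALSE]) + offset
  mean_b <- rowMeans(t$values[, ib, drop = FALSE]) + offset
  p <- stats_mat[, "p"]
  q <- bh_adjust(p)
  direction <- rep("ns", nrow(lx))
  sig <- !is.na(q) & q < q_thresh
  direction[sig & mean_a > mean_b] <- "up"
  direction[sig & mean_a < mean_b] <- "down"
  data.frame(feature_id = feature_ids(t), group_a = a, group_b = b,
             log2fc = log2(mean_a / mean_b), t_stat = stats_mat[, "t"],
             p = p, q = q, direction = direction, degenerate = is.na(p),
             stringsAsFactors = FALSE)
}

#' Newborn-versus-each-group contrasts with intersection counts
#'
#' Runs the newborn group (A) against each of the six later life stages
#' and tabulates upset-style intersection counts of the significant
#' feature sets.
#'
#' @inheritParams de_two_groups
#' @return List with `results` (named list of [de_two_groups()] frames),
#'   `membership` (features x comparisons logical matrix of significance)
#'   and `intersections` (data frame `pattern`, `degree`, `count`; the
#'   pattern names the comparisons a feature is significant in).
#' @export
newborn_contrasts <- function(t, m, q_thresh = 0.05, log_offset = NULL) {
  m <- validate_sample_meta(m, t)
  if (!any(as.character(m$group) == "A_newborn"))
    stop("newborn group is empty")
  others <- setdiff(LIFE_STAGE_LEVELS, "A_newborn")
  others <- others[others %in% as.character(m$group)]
  results <- lapply(others, function(g)
    de_two_groups(t, m, "A_newborn", g, q_thresh, log_offset))
  names(results) <- others
  membership <- vapply(results, function(r) r$direction != "ns",
                       logical(nrow(results[[1]])))
  rownames(membership) <- feature_ids(t)
  pattern <- apply(membership, 1, function(z)
    paste(others[z], collapse = "&"))
  counts <- table(pattern[pattern != ""])
  intersections <- data.frame(
    pattern = names(counts),
    degree = lengths(strsplit(names(counts), "&", fixed = TRUE)),
    count = as.integer(counts), stringsAsFactors = FALSE)
  intersections <- intersections[order(-intersections$degree,
                                       intersections$pattern), ,
                                 drop = FALSE]
  rownames(intersections) <- NULL
  list(results = results, membership = membership,
       intersections = intersections)
}

#' Per-group marker features
#'
#' A feature is a marker of group `g` iff it is significantly up
#' (BH q < `q_thresh`) in `g` versus the pooled remaining samples, and its
#' maximal group mean is attained in `g` (specificity condition).
#'
#' @inheritParams de_two_groups
#' @return Named list (per group) of marker feature-id vectors; the full
#'   per-group DE frames are attached as attribute `de`.
#' @export
group_markers <- function(t, m, q_thresh = 0.05, log_offset = NULL) {
  m <- validate_sample_meta(m, t)
  grp <- as.character(m$group[match(sample_ids(t), m$sample_id)])
  groups <- LIFE_STAGE_LEVELS[LIFE_STAGE_LEVELS %in% grp]
  if (length(groups) < 2) stop("need >= 2 groups")
  group_mean <- vapply(groups, function(g)
    rowMeans(t$values[, grp == g, drop = FALSE]), numeric(nrow(t$values)))
  group_mean <- matrix(group_mean, nrow = nrow(t$values),
                       dimnames = list(feature_ids(t), groups))
  argmax <- groups[max.col(group_mean, ties.method = "first")]
  lx <- de_log_matrix(t, log_offset)
  de_list <- list(); markers <- list()
  for (g in groups) {
    ia <- which(grp == g); ib <- which(grp != g)
    stats_mat <- t(apply(lx, 1, function(y) welch_row(y[ia], y[ib])))
    q <- bh_adjust(stats_mat[, "p"])
    mean_g <- rowMeans(t$values[, ia, drop = FALSE])
    mean_rest <- rowMeans(t$values[, ib, drop = FALSE])
    up <- !is.na(q) & q < q_thresh & mean_g > mean_rest
    de_list[[g]] <- data.frame(feature_id = feature_ids(t),
                               group = g, t_stat = stats_mat[, "t"],
                               p = stats_mat[, "p"], q = q, up = up,
                               stringsAsFactors = FALSE)
    markers[[g]] <- feature_ids(t)[up & argmax == g]
  }
  attr(markers, "de") <- de_list
  markers
}

#' Signed per-class change score
#'
#' For each feature class, `(n_up - n_down) / n_class` using the DE
#' directions at the comparison's q threshold; bounded in [-1, 1]. This
#' summary is this package's own definition of a class-level change score.
#'
#' @param de A [de_two_groups()] result frame.
#' @param class_map Named character vector mapping feature id to class.
#' @return Data frame per class: `class`, `score`, `n_class`, `n_up`,
#'   `n_down`; empty classes are omitted with a warning.
#' @export
change_score <- function(de, class_map) {
  miss <- setdiff(de$feature_id, names(class_map))
  if (length(miss))
    stop("class_map missing feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  cls <- class_map[de$feature_id]
  rows <- lapply(unique(cls), function(cl) {
    d <- de[cls == cl, , drop = FALSE]
    if (nrow(d) == 0L) return(NULL)
    data.frame(class = cl,
               score = (sum(d$direction == "up") -
                          sum(d$direction == "down")) / nrow(d),
               n_class = nrow(d),
               n_up = sum(d$direction == "up"),
               n_down = sum(d$direction == "down"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read a GMT pathway file
#'
#' @param path GMT file (tab-separated: id, description, members...).
#' @return Named list of member character vectors; descriptions in
#'   attribute `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  desc <- vapply(parts, function(z) if (length(z) >= 2) z[2] else "",
                 character(1))
  sets <- lapply(parts, function(z) unique(z[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(desc, ids)
  sets
}

#' Pathway over-representation (one-sided hypergeometric)
#'
#' For each pathway of size >= `min_size` (after restriction to the
#' universe), the upper-tail hypergeometric probability of observing at
#' least the seen overlap, BH-adjusted across tested pathways. Pathway
#' members outside the universe are dropped with a warning.
#'
#' @param hits Character vector of significant feature ids (subset of
#'   `universe`).
#' @param universe Character vector of all tested feature ids.
#' @param pathways Named list of pathway member vectors ([read_gmt()]).
#' @param min_size Minimum in-universe pathway size to test; default 2.
#' @return Data frame per tested pathway: `pathway_id`, `overlap`,
#'   `pathway_size`, `hits`, `universe`, `p`, `q`.
#' @export
enrich <- function(hits, universe, pathways, min_size = 2) {
  universe <- unique(universe)
  hits <- unique(hits)
  if (!all(hits %in% universe))
    stop("hits must be a subset of the universe")
  restricted <- lapply(pathways, function(mem) intersect(mem, universe))
  n_outside <- sum(lengths(pathways)) - sum(lengths(restricted))
  if (n_outside > 0)
    warning(n_outside, " pathway member(s) outside the universe dropped")
  keep <- lengths(restricted) >= min_size
  restricted <- restricted[keep]
  if (length(restricted) == 0L)
    return(data.frame(pathway_id = character(), overlap = integer(),
                      pathway_size = integer(), hits = integer(),
                      universe = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  N <- length(universe); K <- length(hits)
  rows <- lapply(names(restricted), function(id) {
    mem <- restricted[[id]]
    ov <- length(intersect(mem, hits))
    p <- stats::phyper(ov - 1, length(mem), N - length(mem), K,
                       lower.tail = FALSE)
    data.frame(pathway_id = id, overlap = ov, pathway_size = length(mem),
               hits = K, universe = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Differential expression between elderly and young samples
#'
#' Convenience contrast for the biomarker-panel workflow: elderly
#' (age >= `elderly_cut`) versus young (age < `young_cut`), middle-aged
#' samples excluded.
#'
#' @inheritParams de_two_groups
#' @param elderly_cut,young_cut Age cut-offs in years (defaults 65 / 40).
#' @return A [de_two_groups()]-shaped frame with `group_a = "elderly"`,
#'   `group_b = "young"`.
#' @export
de_elderly_vs_young <- function(t, m, elderly_cut = 65, young_cut = 40,
                                q_thresh = 0.05, log_offset = NULL) {
  m <- validate_sample_meta(m, t)
  age <- m$age[match(sample_ids(t), m$sample_id)]
  ia <- which(age >= elderly_cut); ib <- which(age < young_cut)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 elderly and >= 2 young samples")
  lx <- de_log_matrix(t, log_offset)
  stats_mat <- t(apply(lx, 1, function(y) welch_row(y[ia], y[ib])))
  mean_a <- rowMeans(t$values[, ia, drop = FALSE])
  mean_b <- rowMeans(t$values[, ib, drop = FALSE])
  p <- stats_mat[, "p"]
  q <- bh_adjust(p)
  direction <- rep("ns", nrow(lx))
  sig <- !is.na(q) & q < q_thresh
  direction[sig & mean_a > mean_b] <- "up"
  direction[sig & mean_a < mean_b] <- "down"
  data.frame(feature_id = feature_ids(t), group_a = "elderly",
             group_b = "young",
             log2fc = log2((mean_a + 1e-300) / (mean_b + 1e-300)),
             t_stat = stats_mat[, "t"], p = p, q = q,
             direction = direction, degenerate = is.na(p),
             stringsAsFactors = FALSE)
}
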