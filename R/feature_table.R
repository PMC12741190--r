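# Core data model: abundance matrices with sample metadata, plus the
# normalization and filtering steps every downstream stage consumes.

LIFE_STAGE_LEVELS <- c("A_newborn", "B_early_childhood", "C_middle_childhood",
                       "D_adolescence", "E_early_adulthood",
                       "F_middle_adulthood", "G_late_adulthood")

#' Construct a FeatureTable
#'
#' A FeatureTable holds a nonnegative abundance matrix (rows = features,
#' columns = samples) together with its modality and normalization state.
#' Feature and sample identifiers live in the matrix dimnames and must be
#' unique.
#'
#' @param values Numeric matrix, features x samples, finite and >= 0, with
#'   unique rownames (feature ids) and colnames (sample ids).
#' @param modality `"metabolite"` or `"lipid"`.
#' @param normalization_state One of `"raw"`, `"total_sum"`, `"median_ratio"`.
#' @return An object of class `FeatureTable`.
#' @export
feature_table <- function(values, modality = c("metabolite", "lipid"),
                          normalization_state = "raw") {
  modality <- match.arg(modality)
  obj <- structure(list(values = values, modality = modality,
                        normalization_state = normalization_state),
                   class = "FeatureTable")
  validate_feature_table(obj)
  obj
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat(sprintf("FeatureTable: %d features x %d samples (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$modality,
              x$normalization_state))
  invisible(x)
}

validate_feature_table <- function(t) {
  stopifnot(inherits(t, "FeatureTable"))
  v <- t$values
  if (!is.matrix(v) || !is.numeric(v)) stop("values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    stop("values must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(v)))
    stop("duplicate feature id(s): ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", "))
  if (any(!is.finite(v))) stop("values must all be finite")
  if (any(v < 0)) stop("values must be nonnegative")
  if (!t$normalization_state %in% c("raw", "total_sum", "median_ratio"))
    stop("unknown normalization_state: ", t$normalization_state)
  if (t$normalization_state == "total_sum" &&
      any(abs(colSums(v) - 1) > 1e-9))
    stop("total_sum state but columns do not sum to 1")
  invisible(t)
}

#' @rdname feature_table
#' @param t Object to test.
#' @export
is_feature_table <- function(t) inherits(t, "FeatureTable")

#' Feature and sample identifiers of a FeatureTable
#' @param t A `FeatureTable`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(t) rownames(t$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(t) colnames(t$values)

#' Validate a sample metadata table
#'
#' Metadata carries one row per sample with columns `sample_id`, `age`
#' (years, >= 0), `sex` (`F`/`M`) and `group` (one of the seven ordered
#' life-stage labels, newborn through late adulthood).
#'
#' @param m Data frame of sample metadata.
#' @param t Optional paired `FeatureTable`; if given, the sample sets must
#'   match exactly.
#' @return `m`, invisibly, with `sex` and `group` as factors.
#' @export
validate_sample_meta <- function(m, t = NULL) {
  need <- c("sample_id", "age", "sex", "group")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample id(s) in metadata: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  if (any(!is.finite(m$age)) || any(m$age < 0))
    stop("age must be finite and >= 0")
  if (!all(as.character(m$sex) %in% c("F", "M")))
    stop("sex must be F or M")
  if (!all(as.character(m$group) %in% LIFE_STAGE_LEVELS))
    stop("unknown life-stage label(s): ",
         paste(setdiff(unique(as.character(m$group)), LIFE_STAGE_LEVELS),
               collapse = ", "))
  m$sex <- factor(as.character(m$sex), levels = c("F", "M"))
  m$group <- factor(as.character(m$group), levels = LIFE_STAGE_LEVELS,
                    ordered = TRUE)
  if (!is.null(t)) {
    miss <- setdiff(sample_ids(t), m$sample_id)
    extra <- setdiff(m$sample_id, sample_ids(t))
    if (length(miss) || length(extra))
      stop("sample sets differ; missing from metadata: [",
           paste(miss, collapse = ", "), "]; missing from table: [",
           paste(extra, collapse = ", "), "]")
  }
  invisible(m)
}

#' Default life-stage group boundaries
#'
#' Newborns (group A) are cord-blood samples at age exactly 0; the elderly
#' cut-off is 65 years and the young cut-off 40, with intermediate
#' boundaries at 6, 12 and 19 years. Boundaries are half-open on the right
#' except group A (a point) and G (unbounded above).
#'
#' @return Data frame with columns `group`, `min_age`, `max_age`.
#' @export
default_group_boundaries <- function() {
  data.frame(group = LIFE_STAGE_LEVELS,
             min_age = c(0, 0, 6, 12, 19, 40, 65),
             max_age = c(0, 6, 12, 19, 40, 65, Inf),
             stringsAsFactors = FALSE)
}

#' Assign life-stage groups from ages
#' @param age Numeric vector of ages in years.
#' @param boundaries Boundary table as from [default_group_boundaries()].
#' @return Character vector of life-stage labels.
#' @export
assign_life_stage <- function(age, boundaries = default_group_boundaries()) {
  vapply(age, function(a) {
    if (a == 0) return(boundaries$group[1])
    i <- which(a >= boundaries$min_age & a < boundaries$max_age &
                 boundaries$group != boundaries$group[1])
    if (length(i) != 1L) stop("age ", a, " matches no group")
    boundaries$group[i]
  }, character(1))
}

# --- readers / writers -----------------------------------------------------

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "\"", comment.char = "")
}

#' Read a feature table and its sample metadata
#'
#' The abundance file is CSV or TSV with features as rows: first column
#' feature ids, header row of sample ids, numeric body. The metadata file
#' has columns `sample_id`, `age`, `sex`, `group`. The two sample sets must
#' match exactly.
#'
#' @param path Abundance table file.
#' @param meta_path Metadata file.
#' @param modality `"metabolite"` or `"lipid"`.
#' @return List with elements `table` (a raw-state `FeatureTable`) and
#'   `meta` (validated metadata, ordered as the table's columns).
#' @export
read_feature_table <- function(path, meta_path,
                               modality = c("metabolite", "lipid")) {
  modality <- match.arg(modality)
  df <- read_delim_auto(path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad))
      stop("non-numeric cell at row ", bad[1], " (feature ", ids[bad[1]],
           "), column ", names(body)[j])
    body[[j]] <- v
  }
  values <- as.matrix(body)
  rownames(values) <- ids
  t <- feature_table(values, modality = modality)
  meta <- read_sample_meta(meta_path)
  meta <- validate_sample_meta(meta, t)
  meta <- meta[match(sample_ids(t), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(table = t, meta = meta)
}

#' @rdname read_feature_table
#' @export
read_sample_meta <- function(meta_path) {
  m <- read_delim_auto(meta_path)
  # a lone "F" sex level would otherwise be read as logical
  m$sex <- as.character(m$sex)
  m$sex[m$sex == "FALSE"] <- "F"
  m$group <- as.character(m$group)
  m$age <- as.numeric(m$age)
  validate_sample_meta(m)
  m$sex <- factor(as.character(m$sex), levels = c("F", "M"))
  m$group <- factor(as.character(m$group), levels = LIFE_STAGE_LEVELS,
                    ordered = TRUE)
  m
}

#' Write a feature table / metadata to delimited text
#'
#' Values are written at full precision (`digits = 17`) so a write/read
#' round-trip is exact.
#'
#' @param t A `FeatureTable`.
#' @param path Output file; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @export
write_feature_table <- function(t, path) {
  validate_feature_table(t)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(feature_id = feature_ids(t),
                   apply(t$values, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("feature_id", sample_ids(t))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param m Sample metadata data frame.
#' @export
write_sample_meta <- function(m, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- m
  out$age <- sprintf("%.17g", out$age)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- normalization ---------------------------------------------------------

#' Total-sum normalization
#'
#' Divides each sample column by its sum so columns sum to 1. Requires a raw
#' table with strictly positive column sums.
#'
#' @param t A raw-state `FeatureTable`.
#' @return A `FeatureTable` in `total_sum` state.
#' @export
total_sum_normalize <- function(t) {
  validate_feature_table(t)
  if (t$normalization_state != "raw")
    stop("total_sum_normalize expects a raw table, got ",
         t$normalization_state)
  cs <- colSums(t$values)
  if (any(cs <= 0))
    stop("all-zero sample column(s): ",
         paste(sample_ids(t)[cs <= 0], collapse = ", "))
  t$values <- sweep(t$values, 2, cs, "/")
  t$normalization_state <- "total_sum"
  t
}

#' Median-ratio normalization
#'
#' Divides each sample column by its median over all values (zeros
#' included); when that median is 0 — common under zero inflation — the
#' median of the nonzero values is used instead. After normalization the
#' effective median of each column is 1.
#'
#' @param t A raw-state `FeatureTable`.
#' @return A `FeatureTable` in `median_ratio` state.
#' @export
median_ratio_normalize <- function(t) {
  validate_feature_table(t)
  if (t$normalization_state != "raw")
    stop("median_ratio_normalize expects a raw table, got ",
         t$normalization_state)
  med <- apply(t$values, 2, function(x) {
    m <- stats::median(x)
    if (m == 0) m <- stats::median(x[x > 0])
    m
  })
  if (any(!is.finite(med) | med <= 0))
    stop("zero or undefined median for sample(s): ",
         paste(sample_ids(t)[!is.finite(med) | med <= 0], collapse = ", "))
  t$values <- sweep(t$values, 2, med, "/")
  t$normalization_state <- "median_ratio"
  t
}

# --- filtering -------------------------------------------------------------

#' Access the drop report attached by a filter
#' @param t A filtered `FeatureTable`.
#' @return Data frame with columns `feature_id`, `reason` (possibly empty).
#' @export
drop_report <- function(t) {
  rep <- attr(t, "drop_report")
  if (is.null(rep))
    rep <- data.frame(feature_id = character(), reason = character(),
                      stringsAsFactors = FALSE)
  rep
}

attach_drop_report <- function(t, dropped, reason, report_path = NULL) {
  rep <- rbind(drop_report(t),
               data.frame(feature_id = dropped,
                          reason = rep(reason, length(dropped)),
                          stringsAsFactors = FALSE))
  attr(t, "drop_report") <- rep
  if (!is.null(report_path)) write_tsv_stable(rep, report_path)
  t
}

#' Filter features by per-group nonzero fraction
#'
#' Retains features whose nonzero fraction exceeds `min_frac` (strictly) in
#' at least one life-stage group; a feature nonzero in exactly half of every
#' group is dropped.
#'
#' @param t A `FeatureTable`.
#' @param m Paired sample metadata.
#' @param min_frac Required nonzero fraction, in (0, 1]; default 0.5.
#' @param report_path Optional TSV path for the drop report.
#' @return Filtered `FeatureTable` carrying a [drop_report()].
#' @export
filter_nonzero_by_group <- function(t, m, min_frac = 0.5,
                                    report_path = NULL) {
  stopifnot(min_frac > 0, min_frac <= 1)
  m <- validate_sample_meta(m, t)
  grp <- m$group[match(sample_ids(t), m$sample_id)]
  keep <- rep(FALSE, nrow(t$values))
  for (g in levels(droplevels(grp))) {
    cols <- which(grp == g)
    if (!length(cols)) next
    frac <- rowMeans(t$values[, cols, drop = FALSE] > 0)
    keep <- keep | (frac > min_frac)
  }
  dropped <- feature_ids(t)[!keep]
  t$values <- t$values[keep, , drop = FALSE]
  if (nrow(t$values) == 0L)
    warning("all features dropped by the nonzero-fraction filter")
  attach_drop_report(t, dropped,
                     sprintf("nonzero fraction <= %g in every group",
                             min_frac),
                     report_path)
}

#' Coefficient of variation over QC replicate columns
#'
#' @param t A `FeatureTable` whose columns include the QC injections.
#' @param qc_samples Character vector of QC column ids.
#' @return Data frame (`feature_id`, `cv`, `flagged`); `cv` is `NA` and
#'   `flagged` `TRUE` where the QC mean is 0.
#' @export
qc_profile <- function(t, qc_samples) {
  missing_qc <- setdiff(qc_samples, sample_ids(t))
  if (length(missing_qc))
    stop("QC sample(s) not in table: ", paste(missing_qc, collapse = ", "))
  q <- t$values[, qc_samples, drop = FALSE]
  mu <- rowMeans(q)
  sdv <- apply(q, 1, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, sdv / mu)
  data.frame(feature_id = feature_ids(t), cv = cv, flagged = mu == 0,
             stringsAsFactors = FALSE)
}

#' Filter features by QC coefficient of variation
#'
#' Retains features with `cv < max_cv` (strict, so cv exactly at the
#' threshold is dropped). Flagged features (undefined cv) are dropped.
#'
#' @param t A `FeatureTable`.
#' @param qc QC profile as from [qc_profile()].
#' @param max_cv CV threshold; default 0.3.
#' @param report_path Optional TSV path for the drop report.
#' @return Filtered `FeatureTable`; the retained proportion is attached as
#'   attribute `qc_retained_fraction`.
#' @export
filter_by_qc_cv <- function(t, qc, max_cv = 0.3, report_path = NULL) {
  miss <- setdiff(feature_ids(t), qc$feature_id)
  if (length(miss))
    stop("QC profile missing feature(s): ", paste(miss, collapse = ", "))
  cv <- qc$cv[match(feature_ids(t), qc$feature_id)]
  keep <- !is.na(cv) & cv < max_cv
  dropped <- feature_ids(t)[!keep]
  retained_fraction <- mean(keep)
  t$values <- t$values[keep, , drop = FALSE]
  t <- attach_drop_report(t, dropped, sprintf("QC cv >= %g or undefined",
                                              max_cv), report_path)
  attr(t, "qc_retained_fraction") <- retained_fraction
  t
}

#' Hook for externally batch-corrected tables
#'
#' Batch correction (e.g. QC-based support-vector regression) happens
#' outside this package; this hook has the signature a corrected table
#' would flow through and returns its input unchanged, so an externally
#' corrected matrix can be injected in its place.
#'
#' @param t A `FeatureTable`.
#' @param qc_samples Ignored; present for signature compatibility.
#' @return `t`, unchanged.
#' @export
batch_correct_hook <- function(t, qc_samples = NULL) {
  t
}

#' Subset a FeatureTable
#' @param t A `FeatureTable`.
#' @param features,samples Character ids or index vectors (NULL keeps all).
#' @return The subsetted `FeatureTable`.
#' @export
subset_feature_table <- function(t, features = NULL, samples = NULL) {
  v <- t$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  t$values <- v
  validate_feature_table(t)
  t
}
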