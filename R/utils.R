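# Internal helpers shared across modules.

#' Derive a reproducible child seed from a master seed and a label
#'
#' Stage- and feature-level random streams are derived from one master seed
#' so that toggling a stage (or appending features) never perturbs the
#' randomness of the others. The derivation is a plain 31-bit polynomial
#' hash of the label folded into the master seed; it is stable across
#' platforms and R versions.
#'
#' @param seed Master integer seed.
#' @param label Character label naming the stream (e.g. a stage name).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact-double range
  h <- 0
  for (code in utf8ToInt(paste(label, collapse = "|"))) {
    h <- (h * 31 + code) %% m
  }
  as.integer((abs(seed) %% m + h) %% m)
}

# Smallest positive value in a matrix; used to pick the default log offset.
smallest_positive <- function(x) {
  pos <- x[x > 0]
  if (length(pos) == 0L) stop("matrix has no positive values")
  min(pos)
}

#' Log-transform an abundance matrix with a half-minimum offset
#'
#' Zeros are carried through normalization untouched; the log transform used
#' by the statistical stages adds `offset` first. The default offset is half
#' the smallest positive value in the table, a standard choice for
#' zero-inflated metabolomics intensities.
#'
#' @param x Numeric matrix of nonnegative abundances.
#' @param base Logarithm base (10 for the regression stages, 2 for PCA/PVCA).
#' @param offset Positive offset added before the log; `NULL` for the
#'   half-minimum default.
#' @return Matrix of the same shape, log-transformed.
#' @export
log_offset_transform <- function(x, base = 10, offset = NULL) {
  if (is.null(offset)) offset <- smallest_positive(x) / 2
  stopifnot(offset > 0)
  log(x + offset, base = base)
}

#' Write a data frame as TSV with stable numeric formatting
#'
#' Numbers are written with 12 significant digits so repeated runs diff
#' cleanly.
#'
#' @param df Data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_tsv_stable <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA",
                         sprintf("%.12g", out[[j]]))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a numeric matrix as a wide TSV
#'
#' First column holds the row ids, remaining columns the matrix columns,
#' with the same 12-digit formatting as [write_tsv_stable()].
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output TSV path.
#' @param id_col Name for the row-id column.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_stable(df, path)
}
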