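# Lipid shorthand parsing ("TG(16:0/18:1/18:2)", "SPH(d18:0)") and
# chain-length x saturation analytics.

#' Parse one lipid shorthand name
#'
#' Accepts `CLASS(C1:D1/.../Cn:Dn)` with an optional sphingoid base prefix
#' (`d`/`t`) per chain and optional whitespace. Saturation is classified on
#' the total double-bond count: S (0), MU (1), PU (>= 2). Unparseable names
#' return a typed failure object instead of raising.
#'
#' @param name Lipid shorthand string.
#' @return A `LipidAnnotation` list (`feature_id`, `lipid_class`, `chains`
#'   data frame with `carbons`/`double_bonds`/`prefix`, `total_carbons`,
#'   `total_db`, `saturation`) or an object of class `lipid_parse_failure`.
#' @export
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  fail <- function(msg) structure(list(feature_id = name, message = msg),
                                  class = "lipid_parse_failure")
  pat <- "^\\s*([A-Za-z][A-Za-z0-9]*)\\s*\\(\\s*([^()]*?)\\s*\\)\\s*$"
  if (!grepl(pat, name)) return(fail("not of the form CLASS(...)"))
  cls <- sub(pat, "\\1", name)
  body <- sub(pat, "\\2", name)
  parts <- strsplit(body, "/", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  chain_pat <- "^([dt]?)(\\d+):(\\d+)$"
  if (length(parts) == 0L || !all(grepl(chain_pat, parts)))
    return(fail("chain list is not C:D pairs"))
  chains <- data.frame(
    prefix = sub(chain_pat, "\\1", parts),
    carbons = as.integer(sub(chain_pat, "\\2", parts)),
    double_bonds = as.integer(sub(chain_pat, "\\3", parts)),
    stringsAsFactors = FALSE)
  total_db <- sum(chains$double_bonds)
  structure(list(feature_id = name, lipid_class = cls, chains = chains,
                 total_carbons = sum(chains$carbons), total_db = total_db,
                 saturation = saturation_class(total_db)),
            class = "LipidAnnotation")
}

#' Classify saturation from a double-bond count
#' @param db Nonnegative integer double-bond count(s).
#' @return `"S"` (0 double bonds), `"MU"` (1) or `"PU"` (>= 2).
#' @export
saturation_class <- function(db) {
  stopifnot(all(db >= 0))
  ifelse(db == 0, "S", ifelse(db == 1, "MU", "PU"))
}

#' Format a LipidAnnotation back to shorthand
#' @param ann A `LipidAnnotation`.
#' @return The canonical shorthand string.
#' @export
format_lipid_name <- function(ann) {
  stopifnot(inherits(ann, "LipidAnnotation"))
  chains <- sprintf("%s%d:%d", ann$chains$prefix, ann$chains$carbons,
                    ann$chains$double_bonds)
  sprintf("%s(%s)", ann$lipid_class, paste(chains, collapse = "/"))
}

#' Parse many lipid names into an annotation table
#'
#' @param names Character vector of shorthand names.
#' @return Data frame with one row per name: `feature_id`, `ok`,
#'   `lipid_class`, `n_chains`, `chains` (compact `C:D` string),
#'   `total_carbons`, `total_db`, `saturation` (`NA` columns on failures).
#' @export
parse_lipid_annotations <- function(names) {
  rows <- lapply(names, function(nm) {
    p <- parse_lipid_name(nm)
    if (inherits(p, "lipid_parse_failure")) {
      data.frame(feature_id = nm, ok = FALSE, lipid_class = NA_character_,
                 n_chains = NA_integer_, chains = NA_character_,
                 total_carbons = NA_integer_, total_db = NA_integer_,
                 saturation = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(feature_id = nm, ok = TRUE, lipid_class = p$lipid_class,
                 n_chains = nrow(p$chains),
                 chains = paste(sprintf("%s%d:%d", p$chains$prefix,
                                        p$chains$carbons,
                                        p$chains$double_bonds),
                                collapse = "/"),
                 total_carbons = p$total_carbons, total_db = p$total_db,
                 saturation = p$saturation, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Expand an annotation table back into per-chain rows.
annotation_chains <- function(ann) {
  ann <- ann[ann$ok, , drop = FALSE]
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    parts <- strsplit(ann$chains[i], "/", fixed = TRUE)[[1]]
    pat <- "^([dt]?)(\\d+):(\\d+)$"
    data.frame(feature_id = ann$feature_id[i],
               carbons = as.integer(sub(pat, "\\2", parts)),
               double_bonds = as.integer(sub(pat, "\\3", parts)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Chain-length by saturation intensity matrix for one lipid class
#'
#' For a life-stage group, sums the normalized intensities of the class's
#' species into cells indexed by carbon chain length (rows) and saturation
#' class (columns S/MU/PU). Two attribution conventions are offered:
#' `per_chain` credits a species to each of its distinct chain lengths,
#' classified by that chain's own double-bond count; `per_species`
#' classifies by the species' total double bonds and credits each distinct
#' chain length once.
#'
#' @param t Lipid `FeatureTable`.
#' @param ann Annotation table from [parse_lipid_annotations()].
#' @param lipid_class Class code, e.g. `"SPH"`.
#' @param m Sample metadata.
#' @param group Life-stage label to summarise.
#' @param mode `"per_chain"` or `"per_species"`.
#' @return Numeric matrix, chain lengths x c("S","MU","PU").
#' @export
chain_saturation_matrix <- function(t, ann, lipid_class, m, group,
                                    mode = c("per_chain", "per_species")) {
  mode <- match.arg(mode)
  m <- validate_sample_meta(m, t)
  cls <- ann[ann$ok & ann$lipid_class == lipid_class, , drop = FALSE]
  cls <- cls[cls$feature_id %in% feature_ids(t), , drop = FALSE]
  if (nrow(cls) == 0L) {
    warning("no annotated features of class ", lipid_class)
    return(matrix(0, 0, 3, dimnames = list(NULL, c("S", "MU", "PU"))))
  }
  cols <- m$sample_id[as.character(m$group) == group]
  intensity <- rowSums(t$values[cls$feature_id, cols, drop = FALSE])
  chains <- annotation_chains(cls)
  if (mode == "per_species") {
    chains <- unique(chains[, c("feature_id", "carbons")])
    chains$sat <- cls$saturation[match(chains$feature_id, cls$feature_id)]
  } else {
    chains$sat <- saturation_class(chains$double_bonds)
    chains <- unique(chains[, c("feature_id", "carbons", "sat")])
  }
  lens <- sort(unique(chains$carbons))
  out <- matrix(0, length(lens), 3,
                dimnames = list(as.character(lens), c("S", "MU", "PU")))
  for (i in seq_len(nrow(chains))) {
    out[as.character(chains$carbons[i]), chains$sat[i]] <-
      out[as.character(chains$carbons[i]), chains$sat[i]] +
      intensity[[chains$feature_id[i]]]
  }
  out
}

#' Polyunsaturated-to-saturated intensity ratio per life-stage group
#'
#' For each sample the ratio of summed PU-species intensity to summed
#' S-species intensity is computed (after removing `exclude_classes`), then
#' averaged within group (mean and SEM over samples, matching per-replicate
#' reporting). Samples with zero saturated total yield an infinite ratio
#' and are flagged.
#'
#' @param t Lipid `FeatureTable`.
#' @param ann Annotation table from [parse_lipid_annotations()].
#' @param m Sample metadata.
#' @param exclude_classes Class codes removed before the ratio (e.g.
#'   `"SPH"`).
#' @return Data frame per group: `group`, `ratio_mean`, `ratio_sem`, `n`,
#'   `n_infinite`.
#' @export
pu_s_ratio <- function(t, ann, m, exclude_classes = character()) {
  m <- validate_sample_meta(m, t)
  keep <- ann[ann$ok & !(ann$lipid_class %in% exclude_classes), ,
              drop = FALSE]
  keep <- keep[keep$feature_id %in% feature_ids(t), , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("no lipid species remain after exclusion")
  pu <- keep$feature_id[keep$saturation == "PU"]
  s <- keep$feature_id[keep$saturation == "S"]
  if (length(s) == 0L) stop("no saturated species remain after exclusion")
  pu_tot <- colSums(t$values[pu, , drop = FALSE])
  s_tot <- colSums(t$values[s, , drop = FALSE])
  ratio <- ifelse(s_tot == 0, Inf, pu_tot / s_tot)
  grp <- m$group[match(sample_ids(t), m$sample_id)]
  res <- lapply(levels(droplevels(grp)), function(g) {
    r <- ratio[grp == g]
    fin <- r[is.finite(r)]
    data.frame(group = g,
               ratio_mean = mean(fin),
               ratio_sem = stats::sd(fin) / sqrt(length(fin)),
               n = length(r), n_infinite = sum(!is.finite(r)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Write an annotation table as TSV
#' @param ann Annotation table from [parse_lipid_annotations()].
#' @param path Output TSV path.
#' @export
write_lipid_annotations <- function(ann, path) {
  write_tsv_stable(ann, path)
}
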