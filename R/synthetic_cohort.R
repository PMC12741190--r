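# Synthetic cohort generator: age/sex-annotated abundance tables with known
# ground-truth trajectory structure, emulating a cross-sectional plasma
# cohort of ~136 subjects aged 0-84 across seven life-stage groups.

#' Specify a ground-truth age trajectory for simulated features
#'
#' Trajectories act on the natural-log scale of abundance:
#' \describe{
#'   \item{null}{flat (no age or group effect).}
#'   \item{linear}{`beta` log-units per year.}
#'   \item{peak}{Gaussian bump of height `peak_height` centred at
#'     `peak_age` with sd `peak_width` years.}
#'   \item{step}{shift of `step_delta` log-units for ages >= `step_age`.}
#'   \item{group_marker}{shift of `marker_delta` log-units in one
#'     life-stage group.}
#' }
#' Every kind may additionally carry a `sex_delta` shift applied to males
#' and a positive `base_level` scale.
#'
#' @param kind Trajectory kind (see above).
#' @param n Number of features drawn with this spec.
#' @param beta Linear slope per year (log scale).
#' @param peak_age,peak_width,peak_height Gaussian bump parameters (years,
#'   years, log-units).
#' @param step_age,step_delta Step location (years) and size (log-units).
#' @param marker_group,marker_delta Life-stage label and shift (log-units).
#' @param sex_delta Log-scale shift added for males (0 = no sex effect).
#' @param base_level Positive abundance scale.
#' @param label Optional id stem for the generated features.
#' @return A `TrajectorySpec` object.
#' @export
trajectory_spec <- function(kind = c("null", "linear", "peak", "step",
                                     "group_marker"),
                            n = 1L, beta = NULL, peak_age = NULL,
                            peak_width = NULL, peak_height = 1,
                            step_age = NULL, step_delta = NULL,
                            marker_group = NULL, marker_delta = NULL,
                            sex_delta = 0, base_level = 1, label = NULL) {
  kind <- match.arg(kind)
  need <- switch(kind,
                 null = character(),
                 linear = "beta",
                 peak = c("peak_age", "peak_width"),
                 step = c("step_age", "step_delta"),
                 group_marker = c("marker_group", "marker_delta"))
  args <- list(beta = beta, peak_age = peak_age, peak_width = peak_width,
               step_age = step_age, step_delta = step_delta,
               marker_group = marker_group, marker_delta = marker_delta)
  for (nm in need)
    if (is.null(args[[nm]])) stop(kind, " trajectory requires ", nm)
  for (nm in setdiff(names(args), need))
    if (!is.null(args[[nm]]))
      stop(nm, " is not a parameter of a ", kind, " trajectory")
  if (!is.null(peak_width) && peak_width <= 0) stop("peak_width must be > 0")
  if (!is.null(marker_group) &&
      !marker_group %in% LIFE_STAGE_LEVELS)
    stop("unknown marker_group: ", marker_group)
  stopifnot(base_level > 0, n >= 1)
  structure(list(kind = kind, n = as.integer(n), beta = beta,
                 peak_age = peak_age, peak_width = peak_width,
                 peak_height = peak_height, step_age = step_age,
                 step_delta = step_delta, marker_group = marker_group,
                 marker_delta = marker_delta, sex_delta = sex_delta,
                 base_level = base_level,
                 label = if (is.null(label)) kind else label),
            class = "TrajectorySpec")
}

#' Cohort simulation configuration
#'
#' Defaults emulate the study cohort: 136 subjects aged 0-84 in seven
#' life-stage groups, multiplicative log-normal noise, a small sex effect
#' per feature spec, and light zero inflation.
#'
#' @param n_subjects Total cohort size.
#' @param group_sizes Named integer vector over the seven life-stage
#'   labels; must sum to `n_subjects`.
#' @param age_max Upper age bound (years) for the oldest group.
#' @param noise_sigma Log-scale noise sd.
#' @param zero_inflation Proportion of cells forced to 0, in [0, 1).
#' @param seed Master integer seed.
#' @return A `CohortConfig` object.
#' @export
cohort_config <- function(n_subjects = 136,
                          group_sizes = NULL,
                          age_max = 85,
                          noise_sigma = 0.3,
                          zero_inflation = 0.05,
                          seed = 1L) {
  if (is.null(group_sizes)) {
    base <- n_subjects %/% 7
    group_sizes <- stats::setNames(rep(base, 7), LIFE_STAGE_LEVELS)
    extra <- n_subjects - base * 7
    if (extra > 0)
      group_sizes[seq_len(extra)] <- group_sizes[seq_len(extra)] + 1
  }
  if (!identical(sort(names(group_sizes)), sort(LIFE_STAGE_LEVELS)))
    stop("group_sizes must be named with the seven life-stage labels")
  group_sizes <- group_sizes[LIFE_STAGE_LEVELS]
  if (sum(group_sizes) != n_subjects)
    stop("group_sizes sum (", sum(group_sizes), ") != n_subjects (",
         n_subjects, ")")
  if (any(group_sizes < 0)) stop("group sizes must be nonnegative")
  stopifnot(zero_inflation >= 0, zero_inflation < 1, noise_sigma >= 0,
            age_max > 65)
  structure(list(n_subjects = n_subjects, group_sizes = group_sizes,
                 age_max = age_max, noise_sigma = noise_sigma,
                 zero_inflation = zero_inflation, seed = as.integer(seed)),
            class = "CohortConfig")
}

# Trajectory value (log scale) at given ages/groups.
trajectory_value <- function(spec, age, group) {
  switch(spec$kind,
         null = rep(0, length(age)),
         linear = spec$beta * age,
         peak = spec$peak_height *
           exp(-(age - spec$peak_age)^2 / (2 * spec$peak_width^2)),
         step = spec$step_delta * as.numeric(age >= spec$step_age),
         group_marker = spec$marker_delta *
           as.numeric(as.character(group) == spec$marker_group))
}

simulate_subjects <- function(cfg) {
  bounds <- default_group_boundaries()
  set.seed(derive_seed(cfg$seed, "subjects"))
  rows <- lapply(seq_along(LIFE_STAGE_LEVELS), function(i) {
    g <- LIFE_STAGE_LEVELS[i]
    n <- cfg$group_sizes[[g]]
    if (n == 0) return(NULL)
    if (g == "A_newborn") {
      age <- rep(0, n)
    } else {
      hi <- min(bounds$max_age[i], cfg$age_max)
      age <- stats::runif(n, bounds$min_age[i], hi)
    }
    sex <- sample(c("F", "M"), n, replace = TRUE)
    data.frame(sample_id = sprintf("S%s%02d", substr(g, 1, 1), seq_len(n)),
               age = age, sex = sex, group = g, stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  validate_sample_meta(m)
  m$sex <- factor(m$sex, levels = c("F", "M"))
  m$group <- factor(m$group, levels = LIFE_STAGE_LEVELS, ordered = TRUE)
  m
}

truth_row <- function(id, spec) {
  data.frame(feature_id = id, kind = spec$kind,
             beta = spec$beta %||% NA_real_,
             peak_age = spec$peak_age %||% NA_real_,
             peak_width = spec$peak_width %||% NA_real_,
             peak_height = if (spec$kind == "peak") spec$peak_height
                           else NA_real_,
             step_age = spec$step_age %||% NA_real_,
             step_delta = spec$step_delta %||% NA_real_,
             marker_group = spec$marker_group %||% NA_character_,
             marker_delta = spec$marker_delta %||% NA_real_,
             sex_delta = spec$sex_delta, base_level = spec$base_level,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort feature table with known trajectory truth
#'
#' Abundance is `base_level * exp(trajectory(age) + sex_delta * I(male) +
#' N(0, noise_sigma))`, with zeros injected uniformly at the configured
#' zero-inflation rate. Each feature uses its own seed derived from the
#' master seed, so appending specs never perturbs earlier features.
#'
#' @param cfg A [cohort_config()].
#' @param specs A single [trajectory_spec()] or list of them; each spec
#'   contributes `spec$n` features.
#' @param modality Modality tag of the generated table.
#' @return List with `table` (raw `FeatureTable`), `meta` (sample
#'   metadata) and `truth` (one row per feature with kind and parameters).
#' @export
simulate_cohort <- function(cfg, specs, modality = "metabolite") {
  stopifnot(inherits(cfg, "CohortConfig"))
  if (inherits(specs, "TrajectorySpec")) specs <- list(specs)
  meta <- simulate_subjects(cfg)
  n <- nrow(meta)
  male <- as.numeric(meta$sex == "M")
  rows <- list(); truth <- list()
  idx <- 0L
  for (spec in specs) {
    stopifnot(inherits(spec, "TrajectorySpec"))
    for (r in seq_len(spec$n)) {
      idx <- idx + 1L
      id <- sprintf("%s_%04d", spec$label, idx)
      set.seed(derive_seed(cfg$seed, paste0("feature_", idx)))
      mu <- log(spec$base_level) + trajectory_value(spec, meta$age,
                                                    meta$group) +
        spec$sex_delta * male
      x <- exp(mu + stats::rnorm(n, 0, cfg$noise_sigma))
      if (cfg$zero_inflation > 0)
        x[stats::runif(n) < cfg$zero_inflation] <- 0
      rows[[id]] <- x
      truth[[id]] <- truth_row(id, spec)
    }
  }
  values <- do.call(rbind, rows)
  colnames(values) <- meta$sample_id
  list(table = feature_table(values, modality = modality),
       meta = meta,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Default lipid shorthand grid across the detected classes
#'
#' Builds parseable shorthand names across the 27 lipid classes reported
#' for human plasma, with class-appropriate chain counts and a sphingoid
#' d-prefix for sphingolipid backbones.
#'
#' @param chain_lengths Carbon counts sampled for chains.
#' @param double_bonds Double-bond counts sampled for chains.
#' @return Character vector of lipid shorthand names.
#' @export
default_lipid_grid <- function(chain_lengths = c(16, 18, 20, 22),
                               double_bonds = c(0, 1, 2, 4)) {
  classes <- list(
    # class = c(n_chains, sphingoid?)
    Cer = c(2, 1), CerG2GNAc = c(2, 1), CL = c(4, 0), Co = c(1, 0),
    DG = c(2, 0), FA = c(1, 0), FE = c(1, 0), GSL = c(2, 1),
    Hex1SPH = c(1, 1), HexCer = c(2, 1), LPC = c(1, 0), LPE = c(1, 0),
    LPG = c(1, 0), LPI = c(1, 0), LSM = c(1, 1), MG = c(1, 0),
    PA = c(2, 0), PC = c(2, 0), PE = c(2, 0), PG = c(2, 0), PI = c(2, 0),
    PS = c(2, 0), SGalCer = c(2, 1), SM = c(2, 1), SPH = c(1, 1),
    ST = c(1, 0), TG = c(3, 0))
  out <- character()
  for (cls in names(classes)) {
    n_chain <- classes[[cls]][1]
    sphingo <- classes[[cls]][2] == 1
    for (len in chain_lengths) for (db in double_bonds) {
      chains <- sprintf("%d:%d", len, db)
      if (n_chain > 1) {
        # remaining chains fixed to a common backbone to keep the grid small
        extra <- rep("18:1", n_chain - 1)
        chains <- paste(c(chains, extra), collapse = "/")
      }
      if (sphingo) chains <- paste0("d", chains)
      out <- c(out, sprintf("%s(%s)", cls, chains))
    }
  }
  unique(out)
}

#' Simulate a lipid panel with parseable shorthand names
#'
#' Generates one feature per grid entry. By default all species are null
#' trajectories; saturated SPH species receive a newborn group-marker
#' shift (`sph_newborn_delta` log-units), emulating the elevated saturated
#' sphingosine profile of cord blood, so saturation analytics have a known
#' truth to recover.
#'
#' @param cfg A [cohort_config()].
#' @param class_grid Character vector of lipid shorthand names; default
#'   [default_lipid_grid()].
#' @param sph_newborn_delta Log-scale newborn shift for saturated SPH
#'   species (0 disables the marker).
#' @param tg_pu_beta Linear age slope (log-units per year) given to
#'   polyunsaturated TG species, emulating their age-associated rise
#'   (0 disables the trend).
#' @param sex_delta Log-scale sex shift applied to every species.
#' @return As [simulate_cohort()]; the truth table additionally carries the
#'   parsed lipid annotation columns.
#' @export
simulate_lipid_panel <- function(cfg, class_grid = default_lipid_grid(),
                                 sph_newborn_delta = 1.5,
                                 tg_pu_beta = 0.02, sex_delta = 0) {
  ann <- parse_lipid_annotations(class_grid)
  bad <- ann$feature_id[!ann$ok]
  if (length(bad))
    stop("malformed grid entr(ies): ", paste(bad, collapse = ", "))
  specs <- lapply(seq_len(nrow(ann)), function(i) {
    nm <- ann$feature_id[i]
    marked <- ann$lipid_class[i] == "SPH" && ann$saturation[i] == "S" &&
      sph_newborn_delta != 0
    trending <- ann$lipid_class[i] == "TG" && ann$saturation[i] == "PU" &&
      tg_pu_beta != 0
    if (marked) {
      trajectory_spec("group_marker", marker_group = "A_newborn",
                      marker_delta = sph_newborn_delta,
                      sex_delta = sex_delta, label = nm)
    } else if (trending) {
      trajectory_spec("linear", beta = tg_pu_beta, sex_delta = sex_delta,
                      label = nm)
    } else {
      trajectory_spec("null", sex_delta = sex_delta, label = nm)
    }
  })
  sim <- simulate_cohort(cfg, specs, modality = "lipid")
  # generated ids are "<label>_<idx>"; restore the bare shorthand names
  rownames(sim$table$values) <- ann$feature_id
  sim$truth$feature_id <- ann$feature_id
  sim$truth <- cbind(sim$truth,
                     ann[, c("lipid_class", "total_carbons", "total_db",
                             "saturation")])
  sim
}

#' Write a simulation's truth table as TSV
#' @param sim Result of [simulate_cohort()] or [simulate_lipid_panel()].
#' @param path Output TSV path.
#' @export
write_truth_table <- function(sim, path) {
  write_tsv_stable(sim$truth, path)
}
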