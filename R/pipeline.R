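# End-to-end orchestration: one config, deterministic stage seeding, TSV
# outputs with a manifest.

#' Build a pipeline run configuration
#'
#' Defaults mirror the study conditions: BH q threshold 0.05, Spearman
#' threshold 0.5, QC CV 0.3, nonzero fraction 0.5, DE-SWAN 20-year window,
#' eight trajectory clusters, elastic-net alpha grid 0.1-0.9, elderly/young
#' cut-offs 65/40 years. Either supply input paths (`table_path`,
#' `meta_path`) or leave them NULL to simulate the default synthetic
#' cohort.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Output directory (created if missing).
#' @param table_path,meta_path Optional delimited-text inputs; NULL
#'   simulates.
#' @param stages Named logical vector toggling stages; unnamed stages
#'   default on. Stage names: simulate, normalize, de, trajectories,
#'   deswan, lipids, pvca, network, clock, panel.
#' @param n_metabolite_null,n_metabolite_linear,n_metabolite_peak,n_metabolite_step,n_metabolite_marker
#'   Simulated metabolite feature counts per trajectory kind.
#' @param q_thresh,rho_thresh,cv_thresh,nonzero_frac,window,k_clusters,alpha_grid,train_fractions,elderly_cut,young_cut
#'   Analysis thresholds (documented defaults above).
#' @param noise_sigma,zero_inflation Cohort generator noise settings.
#' @return A `RunConfig` list.
#' @export
run_config <- function(seed = 1L, out_dir = "results",
                       table_path = NULL, meta_path = NULL,
                       stages = character(),
                       n_metabolite_null = 60, n_metabolite_linear = 60,
                       n_metabolite_peak = 30, n_metabolite_step = 30,
                       n_metabolite_marker = 20,
                       q_thresh = 0.05, rho_thresh = 0.5, cv_thresh = 0.3,
                       nonzero_frac = 0.5, window = 20, k_clusters = 8,
                       alpha_grid = seq(0.1, 0.9, by = 0.1),
                       train_fractions = c(0.5, 0.6, 0.7, 0.8),
                       elderly_cut = 65, young_cut = 40,
                       noise_sigma = 0.3, zero_inflation = 0.05) {
  all_stages <- c("simulate", "normalize", "de", "trajectories", "deswan",
                  "lipids", "pvca", "network", "clock", "panel")
  on <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  if (length(stages)) {
    bad <- setdiff(names(stages), all_stages)
    if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
    on[names(stages)] <- stages
  }
  stopifnot(q_thresh > 0, q_thresh < 1, rho_thresh >= 0, rho_thresh <= 1,
            cv_thresh > 0, nonzero_frac > 0, nonzero_frac <= 1,
            window > 0, k_clusters >= 2,
            all(alpha_grid > 0 & alpha_grid < 1),
            all(train_fractions >= 0.5), elderly_cut > young_cut)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 table_path = table_path, meta_path = meta_path,
                 stages = on,
                 n_metabolite = c(null = n_metabolite_null,
                                  linear = n_metabolite_linear,
                                  peak = n_metabolite_peak,
                                  step = n_metabolite_step,
                                  marker = n_metabolite_marker),
                 q_thresh = q_thresh, rho_thresh = rho_thresh,
                 cv_thresh = cv_thresh, nonzero_frac = nonzero_frac,
                 window = window, k_clusters = k_clusters,
                 alpha_grid = alpha_grid,
                 train_fractions = train_fractions,
                 elderly_cut = elderly_cut, young_cut = young_cut,
                 noise_sigma = noise_sigma,
                 zero_inflation = zero_inflation),
            class = "RunConfig")
}

default_metabolite_specs <- function(cfg) {
  n <- cfg$n_metabolite
  set.seed(derive_seed(cfg$seed, "spec_draw"))
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  if (n[["null"]] > 0) add(trajectory_spec("null", n = n[["null"]]))
  if (n[["linear"]] > 0) {
    betas <- sample(c(-0.02, -0.01, -0.005, 0.005, 0.01, 0.02),
                    n[["linear"]], replace = TRUE)
    for (b in betas)
      add(trajectory_spec("linear", beta = b, sex_delta = 0.05))
  }
  if (n[["peak"]] > 0) {
    ages <- sample(c(7, 20, 40, 60), n[["peak"]], replace = TRUE)
    for (a in ages)
      add(trajectory_spec("peak", peak_age = a, peak_width = 8))
  }
  if (n[["step"]] > 0) {
    steps <- sample(c(40, 65), n[["step"]], replace = TRUE)
    for (s in steps)
      add(trajectory_spec("step", step_age = s, step_delta = 0.6))
  }
  if (n[["marker"]] > 0) {
    grps <- rep(LIFE_STAGE_LEVELS,
                length.out = n[["marker"]])
    for (g in grps)
      add(trajectory_spec("group_marker", marker_group = g,
                          marker_delta = 1.2))
  }
  specs
}

pipeline_log <- function(state, ...) {
  msg <- paste0(...)
  state$log <- c(state$log, msg)
  message("[pipeline] ", msg)
  state
}

manifest_add <- function(state, stage, files) {
  files <- files[file.exists(files)]
  state$manifest[[stage]] <- list(
    stage = stage,
    seed = derive_seed(state$cfg$seed, stage),
    version = as.character(utils::packageVersion("lifespanomics")),
    outputs = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  state
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (simulate/load, normalize +
#' filter, differential expression, trajectories, DE-SWAN, lipid
#' analytics, PVCA, correlation network, aging clock, biomarker panel),
#' writing every stage's tables under `cfg$out_dir` together with a
#' manifest (stage, output hashes, derived seed, package version). All
#' randomness derives from `cfg$seed`, so a re-run is byte-identical.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the run state: `results` (per-stage objects),
#'   `manifest`, `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  state <- list(cfg = cfg, results = list(), manifest = list(),
                log = character())
  run_stage <- function(state, stage, fun) {
    if (!cfg$stages[[stage]]) {
      return(pipeline_log(state, "stage ", stage, " toggled off"))
    }
    state <- pipeline_log(state, "running stage: ", stage)
    state <- tryCatch(fun(state), error = function(e) {
      write_manifest(state)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    state
  }
  write_manifest <- function(state) {
    jsonlite::write_json(state$manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  state <- run_stage(state, "simulate", function(state) {
    if (!is.null(cfg$table_path)) {
      pair <- read_feature_table(cfg$table_path, cfg$meta_path)
      state$results$raw <- pair$table
      state$results$meta <- pair$meta
      state$results$truth <- NULL
      state <- pipeline_log(state, "loaded ", nrow(pair$table$values),
                            " features from ", cfg$table_path)
    } else {
      ccfg <- cohort_config(seed = derive_seed(cfg$seed, "cohort"),
                            noise_sigma = cfg$noise_sigma,
                            zero_inflation = cfg$zero_inflation)
      sim <- simulate_cohort(ccfg, default_metabolite_specs(cfg))
      lip <- simulate_lipid_panel(
        cohort_config(seed = derive_seed(cfg$seed, "cohort"),
                      noise_sigma = cfg$noise_sigma,
                      zero_inflation = cfg$zero_inflation))
      state$results$raw <- sim$table
      state$results$meta <- sim$meta
      state$results$truth <- sim$truth
      state$results$lipid_raw <- lip$table
      state$results$lipid_truth <- lip$truth
      write_feature_table(sim$table, out("metabolite_raw.tsv"))
      write_feature_table(lip$table, out("lipid_raw.tsv"))
      write_sample_meta(sim$meta, out("sample_meta.tsv"))
      write_truth_table(sim, out("metabolite_truth.tsv"))
      write_truth_table(lip, out("lipid_truth.tsv"))
      state <- pipeline_log(state, "simulated cohort: ",
                            nrow(sim$meta), " subjects, ",
                            nrow(sim$table$values), " metabolites, ",
                            nrow(lip$table$values), " lipid species")
    }
    manifest_add(state, "simulate",
                 out(c("metabolite_raw.tsv", "lipid_raw.tsv",
                       "sample_meta.tsv", "metabolite_truth.tsv",
                       "lipid_truth.tsv")))
  })

  state <- run_stage(state, "normalize", function(state) {
    raw <- state$results$raw
    if (is.null(raw)) stop("normalize requires the simulate/load stage")
    filt <- filter_nonzero_by_group(raw, state$results$meta,
                                    cfg$nonzero_frac,
                                    out("metabolite_drop_report.tsv"))
    norm <- total_sum_normalize(filt)
    state$results$norm <- norm
    write_feature_table(norm, out("metabolite_normalized.tsv"))
    if (!is.null(state$results$lipid_raw)) {
      lfilt <- filter_nonzero_by_group(state$results$lipid_raw,
                                       state$results$meta,
                                       cfg$nonzero_frac,
                                       out("lipid_drop_report.tsv"))
      state$results$lipid_norm <- total_sum_normalize(lfilt)
      write_feature_table(state$results$lipid_norm,
                          out("lipid_normalized.tsv"))
    }
    state <- pipeline_log(state, "retained ", nrow(norm$values),
                          " metabolites after the nonzero filter")
    manifest_add(state, "normalize",
                 out(c("metabolite_normalized.tsv",
                       "lipid_normalized.tsv",
                       "metabolite_drop_report.tsv",
                       "lipid_drop_report.tsv")))
  })

  state <- run_stage(state, "de", function(state) {
    norm <- state$results$norm
    if (is.null(norm)) stop("de requires the normalize stage")
    nb <- newborn_contrasts(norm, state$results$meta, cfg$q_thresh)
    state$results$newborn <- nb
    for (g in names(nb$results))
      write_tsv_stable(nb$results[[g]],
                       out(sprintf("de_newborn_vs_%s.tsv", g)))
    write_tsv_stable(nb$intersections, out("de_newborn_intersections.tsv"))
    markers <- group_markers(norm, state$results$meta, cfg$q_thresh)
    state$results$markers <- markers
    write_tsv_stable(
      data.frame(group = rep(names(markers), lengths(markers)),
                 feature_id = unlist(markers, use.names = FALSE),
                 stringsAsFactors = FALSE),
      out("group_markers.tsv"))
    state <- pipeline_log(state, "newborn contrasts done; ",
                          sum(lengths(markers)), " group markers")
    manifest_add(state, "de",
                 out(c(sprintf("de_newborn_vs_%s.tsv", names(nb$results)),
                       "de_newborn_intersections.tsv",
                       "group_markers.tsv")))
  })

  state <- run_stage(state, "trajectories", function(state) {
    norm <- state$results$norm
    if (is.null(norm)) stop("trajectories requires the normalize stage")
    age_fit <- fit_linear_age(norm, state$results$meta,
                              q_thresh = cfg$q_thresh)
    state$results$age_models <- age_fit
    write_tsv_stable(age_fit, out("linear_age_models.tsv"))
    lo <- fit_loess_trajectories(norm, state$results$meta)
    state$results$loess <- lo
    cl <- cluster_trajectories(lo$curves, k = cfg$k_clusters)
    state$results$clusters <- cl
    write_matrix_tsv(lo$curves, out("loess_curves.tsv"))
    write_tsv_stable(
      data.frame(feature_id = names(cl$assignments),
                 cluster = as.integer(cl$assignments),
                 stringsAsFactors = FALSE),
      out("trajectory_clusters.tsv"))
    state <- pipeline_log(state, sum(age_fit$direction != "ns"),
                          " features with a significant linear age trend")
    manifest_add(state, "trajectories",
                 out(c("linear_age_models.tsv", "loess_curves.tsv",
                       "trajectory_clusters.tsv")))
  })

  state <- run_stage(state, "deswan", function(state) {
    norm <- state$results$norm
    if (is.null(norm)) stop("deswan requires the normalize stage")
    sw <- suppressWarnings(deswan(norm, state$results$meta,
                                  window = cfg$window,
                                  q_thresh = cfg$q_thresh))
    state$results$swan <- sw
    write_tsv_stable(
      data.frame(center = sw$centers, n_sig = sw$n_sig,
                 n_young = sw$n_young, n_old = sw$n_old),
      out("deswan_curve.tsv"))
    write_tsv_stable(data.frame(peak_age = sw$peaks),
                     out("deswan_peaks.tsv"))
    state <- pipeline_log(state, "DE-SWAN peaks at: ",
                          paste(sw$peaks, collapse = ", "))
    manifest_add(state, "deswan",
                 out(c("deswan_curve.tsv", "deswan_peaks.tsv")))
  })

  state <- run_stage(state, "lipids", function(state) {
    lip <- state$results$lipid_norm
    if (is.null(lip)) stop("lipids requires a lipid table (simulate mode)")
    ann <- parse_lipid_annotations(feature_ids(lip))
    state$results$lipid_ann <- ann
    write_lipid_annotations(ann, out("lipid_annotations.tsv"))
    ratios <- pu_s_ratio(lip, ann, state$results$meta)
    ratios_nosph <- pu_s_ratio(lip, ann, state$results$meta,
                               exclude_classes = "SPH")
    state$results$pu_s <- ratios
    state$results$pu_s_nosph <- ratios_nosph
    write_tsv_stable(ratios, out("pu_s_ratio.tsv"))
    write_tsv_stable(ratios_nosph, out("pu_s_ratio_excl_sph.tsv"))
    sat <- chain_saturation_matrix(lip, ann, "SPH", state$results$meta,
                                   "A_newborn")
    write_matrix_tsv(sat, out("sph_chain_saturation_newborn.tsv"),
                     id_col = "chain_length")
    state <- pipeline_log(state, "PU:S ratio by group written")
    manifest_add(state, "lipids",
                 out(c("lipid_annotations.tsv", "pu_s_ratio.tsv",
                       "pu_s_ratio_excl_sph.tsv",
                       "sph_chain_saturation_newborn.tsv")))
  })

  state <- run_stage(state, "pvca", function(state) {
    norm <- state$results$norm
    if (is.null(norm)) stop("pvca requires the normalize stage")
    pv <- pvca(norm, state$results$meta)
    state$results$pvca <- pv
    write_tsv_stable(pv, out("pvca_fractions.tsv"))
    state <- pipeline_log(state, "PVCA age fraction: ",
                          signif(pv$fraction[pv$factor == "age"], 4))
    manifest_add(state, "pvca", out("pvca_fractions.tsv"))
  })

  state <- run_stage(state, "network", function(state) {
    norm <- state$results$norm
    lip <- state$results$lipid_norm
    if (is.null(state$results$age_models))
      stop("network requires the trajectories stage")
    if (is.null(lip)) stop("network requires a lipid table")
    lip_age <- fit_linear_age(lip, state$results$meta,
                              q_thresh = cfg$q_thresh)
    state$results$lipid_age_models <- lip_age
    edges <- tryCatch(
      spearman_network(norm, lip, state$results$age_models, lip_age,
                       rho_thresh = cfg$rho_thresh, direction = "any"),
      error = function(e) {
        message("network skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(edges)) {
      state$results$network <- edges
      write_tsv_stable(edges, out("network_edges.tsv"))
      if (nrow(edges) > 0)
        write_network_graphml(edges, out("network.graphml"))
      state <- pipeline_log(state, nrow(edges), " network edges retained")
    }
    manifest_add(state, "network",
                 out(c("network_edges.tsv", "network.graphml")))
  })

  state <- run_stage(state, "clock", function(state) {
    norm <- state$results$norm
    if (is.null(norm)) stop("clock requires the normalize stage")
    clock <- fit_clock(norm, state$results$meta,
                       alpha_grid = cfg$alpha_grid,
                       train_fractions = cfg$train_fractions,
                       seed = derive_seed(cfg$seed, "clock"))
    state$results$clock <- clock
    write_clock_json(clock, out("clock_model.json"))
    write_tsv_stable(clock$predictions, out("clock_predictions.tsv"))
    write_tsv_stable(clock$trace, out("clock_trace.tsv"))
    if (length(clock$coefficients) >= 4) {
      red <- reduce_clock(clock, norm, state$results$meta,
                          alpha_grid = cfg$alpha_grid,
                          seed = derive_seed(cfg$seed, "reduce"),
                          max_features = 30)
      state$results$reduced <- red
      write_tsv_stable(red$accuracy_curve, out("reduced_accuracy.tsv"))
      write_clock_json(red$final_model, out("reduced_clock_model.json"))
    }
    state <- pipeline_log(state, "clock test MAE = ",
                          signif(clock$mae_test, 4), " years (",
                          length(clock$coefficients), " features)")
    manifest_add(state, "clock",
                 out(c("clock_model.json", "clock_predictions.tsv",
                       "clock_trace.tsv", "reduced_accuracy.tsv",
                       "reduced_clock_model.json")))
  })

  state <- run_stage(state, "panel", function(state) {
    norm <- state$results$norm
    if (is.null(state$results$clock))
      stop("panel requires the clock stage")
    if (is.null(state$results$age_models))
      stop("panel requires the trajectories stage")
    de_old <- de_elderly_vs_young(norm, state$results$meta,
                                  cfg$elderly_cut, cfg$young_cut,
                                  cfg$q_thresh)
    sel <- select_panel(de_old, state$results$age_models,
                        state$results$clock, cfg$q_thresh)
    state$results$panel_selection <- sel
    write_tsv_stable(
      data.frame(feature_id = sel$intersection, stringsAsFactors = FALSE),
      out("panel_features.tsv"))
    if (length(sel$intersection) >= 2) {
      pr <- fit_panel_classifier(sel$intersection, norm,
                                 state$results$meta,
                                 seed = derive_seed(cfg$seed, "panel"),
                                 elderly_cut = cfg$elderly_cut,
                                 young_cut = cfg$young_cut)
      state$results$panel <- pr
      write_tsv_stable(pr$roc_points, out("panel_roc.tsv"))
      state <- pipeline_log(state, "panel CV AUC = ",
                            signif(pr$cv_auc_mean, 4))
    } else {
      state <- pipeline_log(state,
                            "panel intersection too small; classifier ",
                            "skipped")
    }
    manifest_add(state, "panel",
                 out(c("panel_features.tsv", "panel_roc.tsv")))
  })

  write_manifest(state)
  writeLines(state$log, out("run_log.txt"))
  invisible(state)
}
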