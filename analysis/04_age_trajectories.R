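#!/usr/bin/env Rscript
# Step 4 — linear and nonlinear age trajectories.
#
# Per-feature OLS of log10 abundance on age with a sex covariate (Type II
# F-test for age, BH across features), then LOESS curves on a common age
# grid, z-scored and hierarchically clustered into eight trajectory
# groups.

source("analysis/00_common.R")

pair <- read_feature_table(load_stage("metabolite_normalized.tsv"),
                           load_stage("sample_meta.tsv"))
norm <- pair$table; meta <- pair$meta
truth <- read.delim(load_stage("metabolite_truth.tsv"))

age_fit <- fit_linear_age(norm, meta)
write_tsv_stable(age_fit, res_path("linear_age_models.tsv"))
message(sprintf("linear trends: %d increase, %d decrease, %d ns",
                sum(age_fit$direction == "increase"),
                sum(age_fit$direction == "decrease"),
                sum(age_fit$direction == "ns")))
message(sprintf("true linear features called: %d of %d",
                sum(age_fit$direction != "ns" &
                      truth$kind[match(age_fit$feature_id,
                                       truth$feature_id)] == "linear"),
                sum(truth$kind == "linear")))

lo <- fit_loess_trajectories(norm, meta)
cl <- cluster_trajectories(lo$curves, k = 8)
write_matrix_tsv(lo$curves, res_path("loess_curves.tsv"))
write_tsv_stable(
  data.frame(feature_id = names(cl$assignments),
             cluster = as.integer(cl$assignments)),
  res_path("trajectory_clusters.tsv"))
message("cluster sizes: ",
        paste(table(cl$assignments), collapse = " "))
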