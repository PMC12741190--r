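#!/usr/bin/env Rscript
# Step 8 — aging clocks, model reduction, and the biomarker panel.
#
# Elastic-net clocks on the metabolite table, the lipid table, and their
# combination (alpha 0.1-0.9, training fractions 0.5-0.8, 10-fold CV
# lambda; the alpha/fraction pair with the smallest held-out MAE wins).
# The combined clock is then reduced by ranked refits and broken-stick
# regression, and the triple-intersection biomarker panel (up in the
# elderly, linear increase, clock-selected) is scored by 10-fold CV ROC
# on the elderly (>= 65) vs young (< 40) task.

source("analysis/00_common.R")

metab <- read_feature_table(load_stage("metabolite_normalized.tsv"),
                            load_stage("sample_meta.tsv"))
lip <- read_feature_table(load_stage("lipid_normalized.tsv"),
                          load_stage("sample_meta.tsv"),
                          modality = "lipid")
meta <- metab$meta

clocks <- list(
  metabolite = fit_clock(metab$table, meta,
                         seed = derive_seed(SEED, "clock_m")),
  lipid = fit_clock(lip$table, meta,
                    seed = derive_seed(SEED, "clock_l")),
  combined = fit_clock(list(metab$table, lip$table), meta,
                       seed = derive_seed(SEED, "clock_c")))
for (nm in names(clocks)) {
  cl <- clocks[[nm]]
  write_clock_json(cl, res_path(sprintf("clock_%s.json", nm)))
  write_tsv_stable(cl$predictions,
                   res_path(sprintf("clock_%s_predictions.tsv", nm)))
  message(sprintf(
    "%s clock: %d features, test MAE %.2f y, r %.3f (alpha %.1f)",
    nm, length(cl$coefficients), cl$mae_test, cl$r_test, cl$alpha))
}

red <- reduce_clock(clocks$metabolite, metab$table, meta,
                    seed = derive_seed(SEED, "reduce"),
                    max_features = 30)
write_tsv_stable(red$accuracy_curve, res_path("reduced_accuracy.tsv"))
write_clock_json(red$final_model, res_path("reduced_clock.json"))
message(sprintf("reduced clock: breakpoint at %d features (r = %.3f)",
                red$breakpoint, red$final_model$r_test))

de_old <- de_elderly_vs_young(metab$table, meta)
age_fit <- fit_linear_age(metab$table, meta)
sel <- select_panel(de_old, age_fit, clocks$metabolite)
write_tsv_stable(data.frame(feature_id = sel$intersection),
                 res_path("panel_features.tsv"))
message(sprintf("panel: %d elderly-up, %d linear-increase, %d in clock, %d in all three",
                sel$counts["elderly_up"], sel$counts["linear_increase"],
                sel$counts["clock"], sel$counts["triple"]))

if (length(sel$intersection) >= 2) {
  pr <- fit_panel_classifier(sel$intersection, metab$table, meta,
                             seed = derive_seed(SEED, "panel"))
  write_tsv_stable(pr$roc_points, res_path("panel_roc.tsv"))
  message(sprintf("panel classifier: mean 10-fold CV AUC = %.3f",
                  pr$cv_auc_mean))
}
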