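#!/usr/bin/env Rscript
# Step 2 — filtering and normalization.
#
# Features must exceed 50% nonzero values in at least one life-stage
# group; surviving features are total-sum normalized (each sample column
# sums to 1). Median-ratio normalization of the metabolites is written as
# well so downstream robustness checks can compare the two.

source("analysis/00_common.R")

metab <- read_feature_table(load_stage("metabolite_raw.tsv"),
                            load_stage("sample_meta.tsv"))
lip <- read_feature_table(load_stage("lipid_raw.tsv"),
                          load_stage("sample_meta.tsv"),
                          modality = "lipid")

filt <- filter_nonzero_by_group(metab$table, metab$meta, 0.5,
                                res_path("metabolite_drop_report.tsv"))
norm <- total_sum_normalize(filt)
write_feature_table(norm, res_path("metabolite_normalized.tsv"))
write_feature_table(median_ratio_normalize(filt),
                    res_path("metabolite_median_ratio.tsv"))

lfilt <- filter_nonzero_by_group(lip$table, lip$meta, 0.5,
                                 res_path("lipid_drop_report.tsv"))
write_feature_table(total_sum_normalize(lfilt),
                    res_path("lipid_normalized.tsv"))

message(sprintf("metabolites: %d kept, %d dropped by the nonzero filter",
                nrow(norm$values), nrow(drop_report(filt))))
message(sprintf("lipids: %d kept, %d dropped", nrow(lfilt$values),
                nrow(drop_report(lfilt))))
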