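#!/usr/bin/env Rscript
# Step 7 — variance decomposition and the metabolite-lipid network.
#
# PCA on the log2 matrix, PVCA decomposing the top PCs' variance into
# age / sex / age-sex / residual (age as the seven-group factor), and a
# Spearman network between the top age-trending metabolites and lipids
# (|rho| > 0.5, p < 0.05).

source("analysis/00_common.R")

metab <- read_feature_table(load_stage("metabolite_normalized.tsv"),
                            load_stage("sample_meta.tsv"))
lip <- read_feature_table(load_stage("lipid_normalized.tsv"),
                          load_stage("sample_meta.tsv"),
                          modality = "lipid")

pc <- pca_scores(metab$table, n_components = 5)
write_matrix_tsv(pc$scores, res_path("pca_scores.tsv"),
                 id_col = "sample_id")
message(sprintf("PC1/PC2 explain %.1f%% / %.1f%%",
                100 * pc$explained[1], 100 * pc$explained[2]))

pv <- pvca(metab$table, metab$meta)
write_tsv_stable(pv, res_path("pvca_fractions.tsv"))
message("PVCA fractions: ",
        paste(sprintf("%s=%.3f", pv$factor, pv$fraction),
              collapse = " "))

m_age <- fit_linear_age(metab$table, metab$meta)
l_age <- fit_linear_age(lip$table, lip$meta)
edges <- spearman_network(metab$table, lip$table, m_age, l_age,
                          direction = "increase")
write_tsv_stable(edges, res_path("network_edges.tsv"))
if (nrow(edges) > 0)
  write_network_graphml(edges, res_path("network.graphml"))
message(sprintf("network: %d edges over %d metabolites and %d lipids",
                nrow(edges), length(unique(edges$feature_a)),
                length(unique(edges$feature_b))))
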