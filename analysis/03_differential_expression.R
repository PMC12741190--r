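#!/usr/bin/env Rscript
# Step 3 — group differential expression.
#
# Newborns against each later life stage (Welch t on log10 abundance, BH
# within each comparison), upset-style intersection counts, per-group
# marker discovery against the pooled rest, class-level change scores,
# and a trajectory-kind over-representation check of the newborn DEMs
# against the generator's truth (the synthetic stand-in for a pathway
# analysis: kinds play the role of pathways, so the enrichment has a
# known right answer).

source("analysis/00_common.R")

pair <- read_feature_table(load_stage("metabolite_normalized.tsv"),
                           load_stage("sample_meta.tsv"))
norm <- pair$table; meta <- pair$meta
truth <- read.delim(load_stage("metabolite_truth.tsv"))

nb <- newborn_contrasts(norm, meta)
for (g in names(nb$results))
  write_tsv_stable(nb$results[[g]],
                   res_path(sprintf("de_newborn_vs_%s.tsv", g)))
write_tsv_stable(nb$intersections,
                 res_path("de_newborn_intersections.tsv"))
all6 <- nb$intersections
message(sprintf("newborn DEMs significant against all six groups: %d",
                sum(all6$count[all6$degree == 6])))

markers <- group_markers(norm, meta)
write_tsv_stable(
  data.frame(group = rep(names(markers), lengths(markers)),
             feature_id = unlist(markers, use.names = FALSE)),
  res_path("group_markers.tsv"))
message("markers per group: ",
        paste(sprintf("%s=%d", substr(names(markers), 1, 1),
                      lengths(markers)), collapse = " "))

# change scores by trajectory kind (the class annotation of this cohort)
kind_map <- setNames(truth$kind, truth$feature_id)
cs <- change_score(nb$results$G_late_adulthood, kind_map)
write_tsv_stable(cs, res_path("change_scores_newborn_vs_G.tsv"))

# trajectory kinds as pathway sets: newborn markers should enrich the
# group_marker "pathway"
gmt_path <- res_path("trajectory_kinds.gmt")
kinds <- split(truth$feature_id, truth$kind)
writeLines(vapply(names(kinds), function(k)
  paste(c(k, paste("features with a", k, "age trajectory"),
          kinds[[k]]), collapse = "\t"), character(1)), gmt_path)
hits <- rownames(nb$membership)[rowSums(nb$membership) == 6]
enr <- suppressWarnings(
  enrich(hits, feature_ids(norm), read_gmt(gmt_path)))
write_tsv_stable(enr, res_path("newborn_dem_enrichment.tsv"))
message("most enriched kind among all-six DEMs: ", enr$pathway_id[1],
        sprintf(" (q = %.3g)", enr$q[1]))
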