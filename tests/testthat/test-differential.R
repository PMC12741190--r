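test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(17)
  for (i in 1:20) {
    p <- runif(sample(5:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("two-group DE is symmetric and flags degenerate features", {
  fx <- two_group_fixture(n_feat = 12, delta = 0.5)
  # inject a feature constant in both groups
  fx$table$values[1, ] <- 2
  ab <- de_two_groups(fx$table, fx$meta, "A_newborn", "G_late_adulthood")
  ba <- de_two_groups(fx$table, fx$meta, "G_late_adulthood", "A_newborn")
  expect_true(ab$degenerate[1])
  expect_identical(ab$direction[1], "ns")
  expect_equal(ab$log2fc[-1], -ba$log2fc[-1], tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  keep <- fx$meta$sample_id[-(1:5)] # one newborn left
  small_t <- subset_feature_table(fx$table, samples = keep)
  expect_error(de_two_groups(small_t, fx$meta[-(1:5), ], "A_newborn",
                             "G_late_adulthood"), ">= 2")
})

test_that("strong group markers are recovered as upregulated", {
  cfg <- cohort_config(seed = 31, noise_sigma = 0.1, zero_inflation = 0)
  specs <- list(trajectory_spec("group_marker", n = 5,
                                marker_group = "C_middle_childhood",
                                marker_delta = 2, label = "mark"),
                trajectory_spec("null", n = 40))
  sim <- simulate_cohort(cfg, specs)
  tn <- total_sum_normalize(sim$table)
  de <- de_two_groups(tn, sim$meta, "C_middle_childhood", "A_newborn")
  marked <- grepl("^mark", de$feature_id)
  expect_true(all(de$direction[marked] == "up"))
  expect_true(all(de$q[marked] < 0.05))
})

test_that("label permutation on null features yields no discoveries", {
  cfg <- cohort_config(seed = 37, zero_inflation = 0)
  sim <- simulate_cohort(cfg, trajectory_spec("null", n = 200))
  tn <- total_sum_normalize(sim$table)
  set.seed(99)
  m2 <- sim$meta
  m2$group <- sample(m2$group)
  de <- de_two_groups(tn, m2, "A_newborn", "G_late_adulthood")
  expect_lte(sum(de$q < 0.05, na.rm = TRUE), 2)
})

test_that("newborn contrasts build six comparisons with intersections", {
  cfg <- cohort_config(seed = 41, noise_sigma = 0.15, zero_inflation = 0)
  specs <- list(trajectory_spec("group_marker", n = 3,
                                marker_group = "A_newborn",
                                marker_delta = 2.5, label = "nbmark"),
                trajectory_spec("null", n = 30))
  sim <- simulate_cohort(cfg, specs)
  tn <- total_sum_normalize(sim$table)
  nb <- newborn_contrasts(tn, sim$meta)
  expect_length(nb$results, 6)
  # features shifted in newborns are significant against all six groups
  all6 <- nb$intersections[nb$intersections$degree == 6, , drop = FALSE]
  expect_gte(sum(all6$count), 3)
  marked <- grepl("^nbmark", rownames(nb$membership))
  expect_true(all(rowSums(nb$membership[marked, ]) == 6))
})

test_that("strong newborn markers agree across normalizations", {
  cfg <- cohort_config(seed = 43, noise_sigma = 0.15, zero_inflation = 0)
  specs <- list(trajectory_spec("group_marker", n = 10,
                                marker_group = "A_newborn",
                                marker_delta = 2.5, label = "nbmark"),
                trajectory_spec("null", n = 60))
  sim <- simulate_cohort(cfg, specs)
  de_ts <- de_two_groups(total_sum_normalize(sim$table), sim$meta,
                         "A_newborn", "E_early_adulthood")
  de_mr <- de_two_groups(median_ratio_normalize(sim$table), sim$meta,
                         "A_newborn", "E_early_adulthood")
  # newborn-enriched sets: markers are up in newborns; the up-set is
  # robust to the composition shift the two normalizations induce
  sig_ts <- de_ts$feature_id[de_ts$direction == "up"]
  sig_mr <- de_mr$feature_id[de_mr$direction == "up"]
  overlap <- length(intersect(sig_ts, sig_mr)) /
    max(length(union(sig_ts, sig_mr)), 1)
  expect_gte(overlap, 0.9)
})

test_that("group markers recover the generator's per-group truth", {
  cfg <- cohort_config(seed = 47, noise_sigma = 0.1, zero_inflation = 0)
  grps <- lifespanomics:::LIFE_STAGE_LEVELS
  specs <- c(lapply(grps, function(g)
    trajectory_spec("group_marker", marker_group = g, marker_delta = 2,
                    label = paste0("mk_", substr(g, 1, 1)))),
    list(trajectory_spec("null", n = 100)))
  sim <- simulate_cohort(cfg, specs)
  tn <- total_sum_normalize(sim$table)
  mk <- group_markers(tn, sim$meta)
  extras <- 0
  for (g in grps) {
    expected <- sim$truth$feature_id[!is.na(sim$truth$marker_group) &
                                       sim$truth$marker_group == g]
    expect_true(all(expected %in% mk[[g]]))
    extras <- extras + length(setdiff(mk[[g]], expected))
  }
  # BH controls FDR at 5%, it does not forbid individual false calls
  expect_lte(extras, 2)
  # null-only table gives empty marker lists
  sim0 <- simulate_cohort(cohort_config(seed = 53, zero_inflation = 0),
                          trajectory_spec("null", n = 50))
  mk0 <- group_markers(total_sum_normalize(sim0$table), sim0$meta)
  expect_lte(sum(lengths(mk0)), 1)
})

test_that("change score counts signed directions per class", {
  de <- data.frame(
    feature_id = sprintf("f%02d", 1:14),
    direction = c(rep("up", 4), rep("up", 3), "down", rep("ns", 6)),
    stringsAsFactors = FALSE)
  class_map <- setNames(c(rep("all_up", 4), rep("mixed", 10)),
                        de$feature_id)
  cs <- change_score(de, class_map)
  expect_equal(cs$score[cs$class == "all_up"], 1)
  expect_equal(cs$score[cs$class == "mixed"], (3 - 1) / 10)
  de$direction[1:4] <- c("up", "up", "down", "down")
  expect_equal(change_score(de, class_map)$score[1], 0)
  expect_error(change_score(de, class_map[-1]), "f01")
})

test_that("enrichment p equals the exhaustive hypergeometric tail", {
  universe <- sprintf("u%03d", 1:100)
  hits <- universe[1:10]
  pathways <- list(pw = universe[c(1:3, 50, 51)],
                   whole = universe,
                   tiny = universe[1])
  res <- suppressWarnings(enrich(hits, universe, pathways))
  expect_false("tiny" %in% res$pathway_id) # below min_size
  expect_equal(res$p[res$pathway_id == "whole"], 1)
  # brute-force tail: P(overlap >= 3) for K=5-member pathway, k=10 hits
  tail_p <- sum(vapply(3:5, function(x)
    choose(5, x) * choose(95, 10 - x) / choose(100, 10), numeric(1)))
  expect_equal(res$p[res$pathway_id == "pw"], tail_p, tolerance = 1e-12)
  # relabeling invariance
  relab <- setNames(sprintf("v%03d", 1:100), universe)
  res2 <- suppressWarnings(
    enrich(relab[hits], relab, lapply(pathways, function(z) relab[z])))
  expect_equal(res2$p[res2$pathway_id == "pw"],
               res$p[res$pathway_id == "pw"], tolerance = 1e-15)
  # zero overlap: the over-representation tail P(X >= 0) is exactly 1
  res3 <- enrich(universe[1:2], universe,
                 list(pw2 = universe[99:100]))
  expect_equal(res3$p, 1)
})

test_that("GMT files round-trip through read_gmt", {
  gmt <- file.path(tempdir(), "p.gmt")
  writeLines(c("path1\tdesc one\tA\tB\tC", "path2\t\tB\tD"), gmt)
  sets <- read_gmt(gmt)
  expect_identical(sets$path1, c("A", "B", "C"))
  expect_identical(sets$path2, c("B", "D"))
  expect_identical(unname(attr(sets, "description")["path1"]), "desc one")
})
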