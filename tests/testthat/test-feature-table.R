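test_that("write/read round-trip preserves values and ids exactly", {
  set.seed(1)
  values <- matrix(rexp(50 * 6), nrow = 50,
                   dimnames = list(sprintf("feat_%02d", 1:50),
                                   sprintf("s%02d", 1:6)))
  t0 <- feature_table(values)
  m0 <- meta_for(sample_ids(t0))
  tf <- file.path(tempdir(), "tbl.csv")
  mf <- file.path(tempdir(), "meta.csv")
  write_feature_table(t0, tf)
  write_sample_meta(m0, mf)
  pair <- read_feature_table(tf, mf)
  expect_identical(feature_ids(pair$table), feature_ids(t0))
  expect_identical(sample_ids(pair$table), sample_ids(t0))
  expect_equal(pair$table$values, t0$values, tolerance = 0)
  expect_equal(pair$meta$age, m0$age, tolerance = 0)
})

test_that("reader rejects mismatched samples, duplicates and bad cells", {
  t0 <- tiny_table()
  m0 <- meta_for(sample_ids(t0))
  tf <- file.path(tempdir(), "t.csv"); mf <- file.path(tempdir(), "m.csv")
  write_feature_table(t0, tf)
  write_sample_meta(m0[1, , drop = FALSE], mf)
  expect_error(read_feature_table(tf, mf), "s2")
  writeLines(c("feature_id,s1,s2", "f1,1,2", "f1,3,4"), tf)
  write_sample_meta(m0, mf)
  expect_error(read_feature_table(tf, mf), "f1")
  writeLines(c("feature_id,s1,s2", "f1,1,2", "f2,x,4"), tf)
  expect_error(read_feature_table(tf, mf), "s1")
})

test_that("total-sum normalization matches its definition and contracts", {
  t0 <- tiny_table(matrix(c(2, 3, 5, 7, 0, 0), nrow = 3,
                          dimnames = list(paste0("f", 1:3),
                                          c("s1", "s2"))))
  tn <- total_sum_normalize(t0)
  expect_equal(tn$values[, "s1"], c(f1 = 0.2, f2 = 0.3, f3 = 0.5))
  expect_equal(unname(tn$values[, "s2"]), c(1, 0, 0)) # single nonzero
  expect_identical(tn$normalization_state, "total_sum")
  expect_error(total_sum_normalize(tn), "raw")
  # random matrix: columns sum to 1; reordering features commutes
  set.seed(3)
  v <- matrix(rexp(500), 50, 10,
              dimnames = list(sprintf("f%02d", 1:50), sprintf("s%02d", 1:10)))
  tn2 <- total_sum_normalize(feature_table(v))
  expect_true(all(abs(colSums(tn2$values) - 1) < 1e-9))
  perm <- sample(1:50)
  tn3 <- total_sum_normalize(feature_table(v[perm, ]))
  expect_equal(tn3$values, tn2$values[perm, ], tolerance = 1e-15)
  # all-zero column errors with the sample name
  v0 <- v; v0[, 3] <- 0
  expect_error(total_sum_normalize(feature_table(v0)), "s03")
})

test_that("median-ratio normalization divides by the column median", {
  t0 <- tiny_table(matrix(c(1, 2, 3, 4, 4, 4), nrow = 3,
                          dimnames = list(paste0("f", 1:3),
                                          c("s1", "s2"))))
  tn <- median_ratio_normalize(t0)
  expect_equal(unname(tn$values[, "s1"]), c(0.5, 1, 1.5))
  expect_equal(unname(tn$values[, "s2"]), c(1, 1, 1)) # constant column
  # zero median falls back to the nonzero median
  t1 <- tiny_table(matrix(c(0, 0, 4, 1, 2, 3), nrow = 3,
                          dimnames = list(paste0("f", 1:3),
                                          c("s1", "s2"))))
  tn1 <- median_ratio_normalize(t1)
  expect_equal(unname(tn1$values[, "s1"]), c(0, 0, 1))
})

test_that("the two normalizations differ by the sum-to-median ratio", {
  set.seed(11)
  v <- matrix(rexp(20 * 12, rate = 0.2), 20, 12,
              dimnames = list(sprintf("f%02d", 1:20),
                              sprintf("s%02d", 1:12)))
  ts <- total_sum_normalize(feature_table(v))
  md <- median_ratio_normalize(feature_table(v))
  ratio <- apply(v, 2, median) / colSums(v)
  for (j in 1:12)
    expect_equal(ts$values[, j], md$values[, j] * ratio[j],
                 tolerance = 1e-12)
})

test_that("nonzero-by-group filter uses strict > and reports drops", {
  ids <- sprintf("s%02d", 1:8)
  m <- data.frame(sample_id = ids, age = c(0, 0, 0, 0, 70, 71, 72, 73),
                  sex = rep(c("F", "M"), 4),
                  group = rep(c("A_newborn", "G_late_adulthood"),
                              each = 4), stringsAsFactors = FALSE)
  v <- matrix(1, 3, 8, dimnames = list(paste0("f", 1:3), ids))
  v[1, 4:8] <- 0          # 3/4 nonzero in A -> retained
  v[2, c(1, 2, 5, 6)] <- 0 # exactly 50% in both groups -> dropped
  v[3, ] <- 0             # all zero -> dropped
  filt <- suppressWarnings(
    filter_nonzero_by_group(feature_table(v), m, 0.5))
  expect_identical(feature_ids(filt), "f1")
  expect_setequal(drop_report(filt)$feature_id, c("f2", "f3"))
})

test_that("nonzero filter retains the engineered survivors", {
  # 10 features over 2 groups of 4; two engineered to fail everywhere
  ids <- sprintf("s%02d", 1:8)
  m <- data.frame(sample_id = ids, age = c(rep(0, 4), 66:69),
                  sex = rep(c("F", "M"), 4),
                  group = rep(c("A_newborn", "G_late_adulthood"),
                              each = 4), stringsAsFactors = FALSE)
  set.seed(5)
  v <- matrix(rexp(80) + 0.1, 10, 8,
              dimnames = list(sprintf("f%02d", 1:10), ids))
  v[4, ] <- c(1, 1, 0, 0, 1, 1, 0, 0) # 50% in each group
  v[9, ] <- c(1, 0, 0, 0, 0, 1, 0, 0) # 25% in each group
  filt <- filter_nonzero_by_group(feature_table(v), m, 0.5)
  expect_equal(nrow(filt$values), 8)
  expect_setequal(drop_report(filt)$feature_id, c("f04", "f09"))
})

test_that("QC CV matches sd/mean and the filter uses strict <", {
  ids <- c("qc1", "qc2", "qc3", "s1")
  v <- rbind(f1 = c(10, 12, 14, 1), f2 = c(5, 5, 5, 2),
             f3 = c(0, 0, 0, 3))
  colnames(v) <- ids
  t0 <- feature_table(v)
  qc <- qc_profile(t0, c("qc1", "qc2", "qc3"))
  expect_equal(qc$cv[1], sd(c(10, 12, 14)) / mean(c(10, 12, 14)),
               tolerance = 1e-12)
  expect_equal(qc$cv[2], 0) # identical replicates
  expect_true(qc$flagged[3])
  # boundary: cv exactly at the threshold drops, just below retains
  qc2 <- data.frame(feature_id = c("f1", "f2", "f3"),
                    cv = c(0.29, 0.30, 0.10), flagged = FALSE)
  filt <- filter_by_qc_cv(t0, qc2, 0.3)
  expect_setequal(feature_ids(filt), c("f1", "f3"))
  expect_equal(attr(filt, "qc_retained_fraction"), 2 / 3)
  expect_error(filter_by_qc_cv(t0, qc2[1:2, ], 0.3), "f3")
})

test_that("nonzero and CV filters commute", {
  ids <- sprintf("s%02d", 1:8)
  m <- data.frame(sample_id = ids, age = c(rep(0, 4), 66:69),
                  sex = rep(c("F", "M"), 4),
                  group = rep(c("A_newborn", "G_late_adulthood"),
                              each = 4), stringsAsFactors = FALSE)
  set.seed(8)
  v <- matrix(rexp(160) * rbinom(160, 1, 0.7), 20, 8,
              dimnames = list(sprintf("f%02d", 1:20), ids))
  t0 <- feature_table(v)
  qc <- data.frame(feature_id = feature_ids(t0),
                   cv = runif(20, 0, 0.6), flagged = FALSE)
  a <- suppressWarnings(filter_by_qc_cv(
    filter_nonzero_by_group(t0, m, 0.5), qc, 0.3))
  b <- suppressWarnings(filter_nonzero_by_group(
    filter_by_qc_cv(t0, qc, 0.3), m, 0.5))
  expect_identical(feature_ids(a), feature_ids(b))
  expect_equal(a$values, b$values, tolerance = 0)
})

test_that("life-stage assignment respects the configured boundaries", {
  expect_identical(assign_life_stage(c(0, 3, 6, 12, 19, 40, 65, 80)),
                   c("A_newborn", "B_early_childhood",
                     "C_middle_childhood", "D_adolescence",
                     "E_early_adulthood", "F_middle_adulthood",
                     "G_late_adulthood", "G_late_adulthood"))
})
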