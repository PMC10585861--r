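test_that("batch split keeps batches and patient pairs intact", {
  sheet <- as_sample_sheet(toy_sheet(20, per_batch = 2))  # 10 batches
  plan <- stratified_batch_split(sheet, 0.6, seed = 1)
  expect_setequal(c(plan$train_batches, plan$test_batches),
                  unique(sheet$batch))
  expect_length(intersect(plan$train_samples, plan$test_samples), 0)
  expect_setequal(c(plan$train_samples, plan$test_samples), sheet$sample_id)
  # both samples of every patient on the same side (leakage guard)
  side <- ifelse(sheet$sample_id %in% plan$train_samples, "train", "test")
  expect_true(all(vapply(split(side, sheet$patient_id),
                         function(x) length(unique(x)) == 1L, TRUE)))
  # achieved fraction within the 10% tolerance
  expect_lt(abs(plan$train_fraction_achieved - 0.6), 0.1 + 1e-9)
  # determinism
  plan2 <- stratified_batch_split(sheet, 0.6, seed = 1)
  expect_identical(plan[names(plan) != "lesion_ratio"],
                   plan2[names(plan2) != "lesion_ratio"])
  expect_error(stratified_batch_split(as_sample_sheet(toy_sheet(4, 4)), 0.5),
               "2 batches")
})

test_that("split stratifies the lesion ratio towards the cohort ratio", {
  co <- small_cohort(seed = 51, n_patients = 30, n_batches = 6)
  plan <- stratified_batch_split(co$sheet, 0.6, seed = 2)
  expect_lt(abs(plan$lesion_ratio[["train"]] - plan$lesion_ratio[["cohort"]]),
            0.15)
})

test_that("top-k selection orders by q, then Simes p, then region id", {
  tab <- data.frame(region_id = c("A", "B", "C"),
                    simes_p = c(0.05, 0.0005, 0.005),
                    q = c(0.1, 0.001, 0.01))
  expect_equal(select_top_panel(tab, 2), c("B", "C"))
  expect_equal(select_top_panel(tab, 3), c("B", "C", "A"))
  ties <- data.frame(region_id = c("Z", "Y"), simes_p = 0.01, q = 0.02)
  expect_equal(select_top_panel(ties, 2), c("Y", "Z"))
  expect_error(select_top_panel(tab, 4), "eligible")
  expect_equal(select_top_panel(tab, 1, eligible = c("A", "C")), "C")
})

test_that("panel score is the unweighted mean with missing regions dropped", {
  lv <- structure(list(
    levels = matrix(c(0.2, 0.4, 0.6, 0.1, NA, 0.3), nrow = 3,
                    dimnames = list(c("R1", "R2", "R3"), c("S1", "S2"))),
    totals = matrix(10, 3, 2), samples = c("S1", "S2")),
    class = "RegionLevelMatrix")
  sc <- panel_score(lv, c("R1", "R2"))
  expect_equal(sc$score, c(0.3, 0.1))
  expect_equal(sc$n_missing, c(0L, 1L))     # R2 missing for S2 -> dropped
  sc3 <- panel_score(lv, c("R1", "R2", "R3"))
  expect_equal(sc3$score[2], mean(c(0.1, 0.3)))
  expect_equal(panel_score(lv, "R3")$score, c(0.6, 0.3))  # single-region panel
  lv$levels["R1", "S2"] <- NA; lv$levels["R2", "S2"] <- NA
  expect_error(panel_score(lv, c("R1", "R2")), "S2")
  expect_error(panel_score(lv, c("R1", "R9")), "R9")
})

test_that("cutoff optimisation picks the separating midpoint", {
  scores <- c(0.01, 0.05, 0.6, 0.9)
  labels <- c("NM", "NM", "tumor", "tumor")
  for (m in c("F1", "YoudenJ", "Kappa")) {
    opt <- optimize_cutoff(scores, labels, m)
    expect_equal(opt$cutoff, (0.05 + 0.6) / 2)
    expect_equal(opt$value, 1)
  }
  # degenerate candidate set: all scores equal -> sentinel, all called tumor
  opt1 <- optimize_cutoff(rep(0.3, 4), c("NM", "NM", "tumor", "tumor"))
  expect_equal(opt1$cutoff, 0.3)
  expect_true(all(classify_samples(rep(0.3, 4), opt1$cutoff)$labels == "tumor"))
  expect_error(optimize_cutoff(1:3, rep("tumor", 3)), "both classes")
})

test_that("the optimal labelling is invariant under monotone score transforms", {
  set.seed(23)
  scores <- runif(20)
  labels <- ifelse(scores + rnorm(20, 0, 0.3) > 0.5, "tumor", "NM")
  if (length(unique(labels)) < 2) labels[1:2] <- c("NM", "tumor")
  base <- optimize_cutoff(scores, labels)
  for (f in list(function(x) 3 * x + 1, function(x) x^3, plogis)) {
    tr <- optimize_cutoff(f(scores), labels)
    expect_equal(tr$value, base$value, tolerance = 1e-12)
    expect_identical(classify_samples(f(scores), tr$cutoff)$labels,
                     classify_samples(scores, base$cutoff)$labels)
  }
})

test_that("classification is inclusive at the cutoff", {
  cls <- classify_samples(c(0.5, 0.4999), 0.5)
  expect_equal(cls$labels, c("tumor", "NM"))
  truth <- c("tumor", "tumor", "tumor", "tumor", "tumor", "NM")
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.1, 0.05)
  out <- classify_samples(sc, 0.5, truth)
  expect_equal(unname(out$confusion), c(4L, 0L, 1L, 1L))  # TP FP TN FN
  expect_equal(out$sensitivity, 4 / 5)
})

test_that("ROC sweep matches the Mann-Whitney pair count, with ties", {
  r <- roc_curve_auc(c(0.9, 0.8, 0.2, 0.1), c("tumor", "tumor", "NM", "NM"))
  expect_equal(r$auc, 1)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1); expect_equal(r$tpr[length(r$tpr)], 1)
  expect_equal(roc_curve_auc(c(0.9, 0.8, 0.2, 0.1),
                             c("NM", "NM", "tumor", "tumor"))$auc, 0)
  expect_equal(roc_curve_auc(c(0.8, 0.3, 0.5, 0.1),
                             c("tumor", "tumor", "NM", "NM"))$auc, 0.75)
  set.seed(29)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(truth) || !any(truth)) next
    expect_equal(roc_curve_auc(sc, truth)$auc, oracle_auc(sc, truth),
                 tolerance = 1e-12)
  }
})

test_that("ROC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(31)
  sc <- rnorm(60)
  truth <- rbinom(60, 1, 0.5) == 1
  if (all(truth) || !any(truth)) truth[1:2] <- c(TRUE, FALSE)
  ref <- suppressMessages(pROC::auc(pROC::roc(truth, sc, quiet = TRUE)))
  expect_equal(roc_curve_auc(sc, truth)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("random panels are reproducible and degenerate pools collapse", {
  co <- small_cohort(seed = 61)
  counts <- filter_coverage(co$counts, 7)
  lv <- region_meth_levels(counts, co$regions)
  labels <- co$sheet$tissue[match(lv$samples, co$sheet$sample_id)]
  pool <- co$regions$region_id[co$regions$truth_class == "biomarker"]
  a <- random_panel_aucs(pool, 5, 20, lv, labels, seed = 3)
  b <- random_panel_aucs(pool, 5, 20, lv, labels, seed = 3)
  expect_identical(a$aucs, b$aucs)
  expect_length(a$aucs, 20)
  forced <- random_panel_aucs(pool[1:5], 5, 10, lv, labels, seed = 3)
  expect_equal(var(forced$aucs), 0)          # pool size == k -> same panel
  expect_error(random_panel_aucs(pool[1:3], 5, 10, lv, labels), "pool")
})

test_that("MDS embeds 3 samples exactly and collapses duplicated samples", {
  set.seed(37)
  x <- matrix(runif(30), nrow = 10,
              dimnames = list(paste0("R", 1:10), c("a", "b", "c")))
  emb <- mds_embedding(x, top_n = 10)
  d_in <- emb$dist
  d_out <- as.matrix(dist(emb$coords))
  expect_equal(unname(d_out), unname(d_in), tolerance = 1e-8)

  x4 <- cbind(x, d = x[, "c"])               # duplicated sample
  emb4 <- mds_embedding(x4, top_n = 10)
  expect_equal(emb4$dist["c", "d"], 0)
  expect_equal(emb4$coords["c", ], emb4$coords["d", ], tolerance = 1e-8)
})

test_that("first MDS dimension separates tumor from NM in a planted cohort", {
  co <- small_cohort(seed = 71, n_patients = 12)
  lv <- region_meth_levels(filter_coverage(co$counts, 7), co$regions)
  emb <- mds_embedding(asin_transform(lv), top_n = 20)
  tum <- co$sheet$tissue[match(rownames(emb$coords), co$sheet$sample_id)] == "tumor"
  d1 <- emb$coords[, 1]
  # mean silhouette on dimension 1 > 0: tissues form separated clusters
  sil <- vapply(seq_along(d1), function(i) {
    own <- mean(abs(d1[i] - d1[setdiff(which(tum == tum[i]), i)]))
    oth <- mean(abs(d1[i] - d1[tum != tum[i]]))
    (oth - own) / max(own, oth)
  }, 0)
  expect_gt(mean(sil, na.rm = TRUE), 0)
})
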