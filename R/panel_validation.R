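# Batch-stratified train/test splitting, top-k panel selection, panel
# scoring, cutpoint optimisation, ROC/AUC, random-panel baselines, and
# classical MDS on pairwise leading distances.

#' Batch-stratified train/test split
#'
#' Assigns whole batches to the training or test side (so no batch — and
#' hence no patient — is split across sides). Among all batch subsets whose
#' training patient fraction is within 0.1 of `train_fraction`, the subset
#' whose training-side cADN:SSL composition is closest to the cohort's is
#' chosen; exact ties are broken by a seeded random draw. If no subset
#' meets the tolerance, the closest achievable fraction is used.
#'
#' @param sheet a `SampleSheet` with at least two batches.
#' @param train_fraction target fraction of patients on the training side.
#' @param seed seed for tie-breaking.
#' @return a `SplitPlan` list: `train_batches`, `test_batches`,
#'   `train_patients`, `test_patients`, `train_samples`, `test_samples`,
#'   `train_fraction_achieved`, `lesion_ratio` (cADN fraction per side).
#' @export
stratified_batch_split <- function(sheet, train_fraction = 0.6, seed = 1) {
  sheet <- as_sample_sheet(sheet)
  stopifnot(train_fraction > 0, train_fraction < 1)
  pat <- unique(sheet[, c("patient_id", "batch", "lesion_type")])
  batches <- sort(unique(pat$batch))
  nb <- length(batches)
  if (nb < 2) stop("a leakage-free split needs at least 2 batches")
  n_pat <- nrow(pat)
  cohort_ratio <- mean(pat$lesion_type == "cADN")
  per_batch_n <- table(factor(pat$batch, levels = batches))
  per_batch_cadn <- tapply(pat$lesion_type == "cADN",
                           factor(pat$batch, levels = batches), sum)
  if (nb <= 20) {
    subsets <- lapply(seq_len(2^nb - 2), function(code) {
      which(bitwAnd(code, bitwShiftL(1L, seq_len(nb) - 1L)) != 0L)
    })
  } else {
    subsets <- with_seed(seed, unique(lapply(seq_len(100000), function(i) {
      sort(sample(nb, sample(nb - 1, 1)))
    })))
  }
  frac <- vapply(subsets, function(s) sum(per_batch_n[s]) / n_pat, 0)
  ratio_dev <- vapply(subsets, function(s) {
    abs(sum(per_batch_cadn[s]) / sum(per_batch_n[s]) - cohort_ratio)
  }, 0)
  eligible <- abs(frac - train_fraction) <= 0.1
  if (any(eligible)) {
    cand <- which(eligible)
    best <- cand[ratio_dev[cand] == min(ratio_dev[cand])]
  } else {
    dev <- abs(frac - train_fraction)
    cand <- which(dev == min(dev))
    best <- cand[ratio_dev[cand] == min(ratio_dev[cand])]
  }
  pick <- if (length(best) > 1) with_seed(seed, sample(best, 1)) else best
  train_batches <- batches[subsets[[pick]]]
  test_batches <- setdiff(batches, train_batches)
  train_pat <- pat$patient_id[pat$batch %in% train_batches]
  test_pat <- pat$patient_id[pat$batch %in% test_batches]
  plan <- list(
    train_batches = train_batches, test_batches = test_batches,
    train_patients = train_pat, test_patients = test_pat,
    train_samples = sheet$sample_id[sheet$patient_id %in% train_pat],
    test_samples = sheet$sample_id[sheet$patient_id %in% test_pat],
    train_fraction_achieved = length(train_pat) / n_pat,
    lesion_ratio = c(
      cohort = cohort_ratio,
      train = mean(pat$lesion_type[pat$patient_id %in% train_pat] == "cADN"),
      test = mean(pat$lesion_type[pat$patient_id %in% test_pat] == "cADN")))
  class(plan) <- "SplitPlan"
  plan
}

#' Select the top-k marker panel by region q-value
#'
#' Orders eligible regions by ascending q, then ascending Simes p, then
#' lexicographic region id, and returns the first `k`.
#'
#' @param region_tab per-region test summaries (columns `region_id`,
#'   `simes_p`, `q`).
#' @param k panel size (default 30).
#' @param eligible optional character vector restricting the candidate
#'   pool (e.g. the candidate-biomarker regions).
#' @return character vector of `k` region ids, best first.
#' @export
select_top_panel <- function(region_tab, k = 30, eligible = NULL) {
  tab <- region_tab[!is.na(region_tab$q), , drop = FALSE]
  if (!is.null(eligible)) tab <- tab[tab$region_id %in% eligible, , drop = FALSE]
  if (k > nrow(tab)) {
    stop("k = ", k, " exceeds the ", nrow(tab), " eligible regions")
  }
  o <- order(tab$q, tab$simes_p, tab$region_id, method = "radix")
  tab$region_id[o][seq_len(k)]
}

#' Per-sample panel score
#'
#' The unweighted mean methylation level across the panel regions; regions
#' with a missing level for a sample are dropped from that sample's mean.
#'
#' @param levels a `RegionLevelMatrix`.
#' @param panel character vector of region ids.
#' @return data.frame with `sample_id`, `score`, `n_missing`.
#' @export
panel_score <- function(levels, panel) {
  stopifnot(inherits(levels, "RegionLevelMatrix"))
  miss <- setdiff(panel, rownames(levels$levels))
  if (length(miss)) stop("panel region(s) absent from level matrix: ",
                         paste(miss, collapse = ", "))
  sub <- levels$levels[panel, , drop = FALSE]
  n_missing <- colSums(is.na(sub))
  if (any(n_missing == length(panel))) {
    stop("sample(s) missing every panel region: ",
         paste(colnames(sub)[n_missing == length(panel)], collapse = ", "))
  }
  data.frame(sample_id = colnames(sub),
             score = colMeans(sub, na.rm = TRUE),
             n_missing = n_missing, row.names = NULL)
}

confusion_counts <- function(pred_tumor, truth_tumor) {
  c(TP = sum(pred_tumor & truth_tumor), FP = sum(pred_tumor & !truth_tumor),
    TN = sum(!pred_tumor & !truth_tumor), FN = sum(!pred_tumor & truth_tumor))
}

cutoff_metric <- function(cc, metric, n) {
  TP <- cc["TP"]; FP <- cc["FP"]; TN <- cc["TN"]; FN <- cc["FN"]
  unname(switch(metric,
    F1 = if (2 * TP + FP + FN == 0) 0 else 2 * TP / (2 * TP + FP + FN),
    YoudenJ = TP / (TP + FN) - FP / (FP + TN),
    Kappa = {
      po <- (TP + TN) / n
      pe <- ((TP + FP) * (TP + FN) + (FN + TN) * (FP + TN)) / n^2
      if (pe == 1) 0 else (po - pe) / (1 - pe)
    }))
}

#' Optimise the panel-score cutoff on labelled samples
#'
#' Candidate cutoffs are the midpoints of consecutive distinct sorted
#' scores plus a sentinel at the minimum score (which, with the inclusive
#' decision rule, calls every sample a tumor). A sample is called tumor
#' iff `score >= cutoff`; the candidate maximising the chosen metric is
#' returned, ties resolved towards the smallest cutoff (higher
#' sensitivity).
#'
#' @param scores numeric panel scores.
#' @param labels tissue labels, `"NM"` or `"tumor"` (tumor = positive).
#' @param metric one of `"F1"`, `"YoudenJ"`, `"Kappa"`.
#' @return list with `cutoff`, `metric`, `value`, and the evaluated
#'   `candidates` data.frame.
#' @export
optimize_cutoff <- function(scores, labels, metric = c("F1", "YoudenJ", "Kappa")) {
  metric <- match.arg(metric)
  stopifnot(length(scores) == length(labels),
            all(labels %in% TISSUE_LEVELS))
  truth <- labels == "tumor"
  if (all(truth) || !any(truth)) stop("both classes must be present")
  s <- sort(unique(scores))
  candidates <- c(s[1], if (length(s) > 1) (s[-length(s)] + s[-1]) / 2)
  vals <- vapply(candidates, function(ct) {
    cutoff_metric(confusion_counts(scores >= ct, truth), metric, length(scores))
  }, 0)
  best <- which.max(vals)  # which.max returns the first (smallest) maximiser
  list(cutoff = candidates[best], metric = metric, value = vals[best],
       candidates = data.frame(cutoff = candidates, value = vals))
}

#' Classify samples by panel score
#'
#' A sample is called tumor iff its score is greater than or equal to the
#' cutoff (inclusive).
#'
#' @param scores numeric panel scores.
#' @param cutoff finite decision threshold.
#' @param truth optional true labels (`"NM"`/`"tumor"`) for confusion
#'   counts.
#' @return list with `labels` and, when truth is given, `confusion`
#'   (TP/FP/TN/FN), `sensitivity`, `specificity`, `accuracy`.
#' @export
classify_samples <- function(scores, cutoff, truth = NULL) {
  stopifnot(is.finite(cutoff))
  labels <- ifelse(scores >= cutoff, "tumor", "NM")
  out <- list(labels = labels)
  if (!is.null(truth)) {
    cc <- confusion_counts(labels == "tumor", truth == "tumor")
    out$confusion <- cc
    out$sensitivity <- unname(cc["TP"] / (cc["TP"] + cc["FN"]))
    out$specificity <- unname(cc["TN"] / (cc["TN"] + cc["FP"]))
    out$accuracy <- unname((cc["TP"] + cc["TN"]) / length(scores))
  }
  out
}

#' ROC curve and AUC
#'
#' Sweeps the distinct scores in descending order (tied scores grouped),
#' emitting (FPR, TPR) points from (0, 0) to (1, 1); the AUC is the
#' trapezoidal area, which equals the Mann-Whitney concordance
#' probability (ties counted 1/2).
#'
#' @param scores numeric scores (higher = more tumor-like).
#' @param labels `"NM"`/`"tumor"` labels, or a logical vector of tumor
#'   status.
#' @return a `RocResult` list: `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_curve_auc <- function(scores, labels) {
  truth <- if (is.logical(labels)) labels else labels == "tumor"
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & truth), 0)
  fp <- vapply(thr, function(t) sum(scores >= t & !truth), 0)
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr, auc = auc),
            class = "RocResult")
}

#' AUCs of randomly drawn panels
#'
#' Draws `n_sets` panels of size `k` without replacement from the eligible
#' pool (independently across sets), scores each with [panel_score()], and
#' computes each panel's AUC.
#'
#' @param pool character vector of eligible region ids.
#' @param k panel size.
#' @param n_sets number of random panels.
#' @param levels a `RegionLevelMatrix` for the evaluation samples.
#' @param labels tissue labels aligned with the level matrix columns.
#' @param seed seed for panel drawing.
#' @return list with `aucs` (length `n_sets`) and `mean_auc`.
#' @export
random_panel_aucs <- function(pool, k, n_sets, levels, labels, seed = 1) {
  stopifnot(n_sets >= 1)
  if (k > length(pool)) stop("k exceeds the pool size")
  panels <- with_seed(seed, lapply(seq_len(n_sets), function(i) sample(pool, k)))
  aucs <- vapply(panels, function(pn) {
    roc_curve_auc(panel_score(levels, pn)$score, labels)$auc
  }, 0)
  list(aucs = aucs, mean_auc = mean(aucs))
}

#' Classical MDS embedding on pairwise leading distances
#'
#' The distance between two samples is the root-mean-square of the
#' `top_n` largest absolute differences of their (arcsine-transformed)
#' per-region levels — the region subset is chosen per pair. Classical
#' (Torgerson) scaling of the squared distances yields 2-D coordinates;
#' each dimension's sign is fixed so its first nonzero loading is
#' positive.
#'
#' @param x numeric matrix, regions x samples (e.g. [asin_transform()] of
#'   a level matrix).
#' @param top_n regions used per pair (default 100); pairs with fewer
#'   complete regions use all available, with a warning.
#' @return list with `coords` (samples x 2) and `dist` (the pairwise
#'   distance matrix).
#' @export
mds_embedding <- function(x, top_n = 100) {
  stopifnot(ncol(x) >= 3)
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  short <- FALSE
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      v <- abs(x[, a] - x[, b])
      v <- v[!is.na(v)]
      if (length(v) == 0) stop("no shared regions between samples ",
                               colnames(x)[a], " and ", colnames(x)[b])
      if (length(v) < top_n) short <- TRUE
      v <- sort(v, decreasing = TRUE)[seq_len(min(top_n, length(v)))]
      d[a, b] <- d[b, a] <- sqrt(mean(v^2))
    }
  }
  if (short) warning("some pairs had fewer than top_n shared regions; used all available")
  fit <- stats::cmdscale(stats::as.dist(d), k = 2, eig = TRUE)
  coords <- fit$points
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- c("dim1", "dim2")
  list(coords = coords, dist = d)
}
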