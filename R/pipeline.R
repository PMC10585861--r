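# End-to-end orchestration: simulate (or load) -> coverage filter ->
# split -> differential methylation test -> inclusion criteria -> panel
# selection -> cutoff training -> test-set classification and ROC.

#' Pipeline run configuration
#'
#' Every analysis threshold defaults to the validated study constants:
#' coverage of at least 7 reads in all samples; DMR runs of at least 3
#' consecutive same-direction DM cytosines separated by at most 50 bp;
#' inclusion criteria of at least 80 bp length, methylation difference of
#' at least 0.5, and q below 0.05; a panel of 30 regions; 100 random
#' baseline panels.
#'
#' @param sim a [sim_config()] describing the cohort to simulate.
#' @param min_reads coverage filter threshold.
#' @param alpha_cpg per-CpG significance level used in DMR run calling.
#' @param max_gap,min_run DMR run definition.
#' @param min_len,min_delta,max_q formal inclusion criteria.
#' @param k panel size.
#' @param n_random_sets number of random baseline panels.
#' @param train_fraction target training patient fraction.
#' @param cutoff_metric cutoff optimisation metric (`"F1"`, `"YoudenJ"`,
#'   `"Kappa"`).
#' @param mds_top_n regions per sample pair for the MDS distances.
#' @param seed global seed; stage seeds are forked from it by fixed
#'   offsets so changing one stage's workload does not perturb another.
#' @return a `RunConfig` list.
#' @export
run_config <- function(sim = sim_config(),
                       min_reads = 7,
                       alpha_cpg = 0.05,
                       max_gap = 50,
                       min_run = 3,
                       min_len = 80,
                       min_delta = 0.5,
                       max_q = 0.05,
                       k = 30,
                       n_random_sets = 100,
                       train_fraction = 0.6,
                       cutoff_metric = "F1",
                       mds_top_n = 100,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_reads >= 0, cfg$k >= 1, cfg$n_random_sets >= 1,
            cfg$train_fraction > 0, cfg$train_fraction < 1,
            cfg$cutoff_metric %in% c("F1", "YoudenJ", "Kappa"))
  cfg$sim$seed <- cfg$seed  # one global seed drives every stage
  structure(cfg, class = "RunConfig")
}

#' Write / read a RunConfig as YAML
#'
#' The configuration round-trips exactly through its file form.
#'
#' @param config a `RunConfig`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sim <- do.call(sim_config, x$sim[setdiff(names(x$sim), "nm_cap")])
  do.call(run_config, x)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Stages, in order: simulate the cohort; filter CpGs covered by at least
#' `min_reads` reads in all samples; split patients by batch into training
#' and test sides; run the paired differential methylation test on the
#' training samples; evaluate the formal inclusion criteria on the target
#' regions; select the top-k panel among candidate-biomarker regions by
#' training q-value; train the score cutoff on the training samples;
#' classify the test samples and compute ROC/AUC plus the random-panel
#' baseline on the test side; embed all samples with MDS. With `outdir`
#' set, every intermediate table is written as TSV and the summary as
#' JSON. Identical config implies identical output.
#'
#' @param config a [run_config()].
#' @param outdir optional output directory for the intermediate tables,
#'   summary JSON, and run log.
#' @param cohort optional pre-built cohort (as from [simulate_cohort()]);
#'   when supplied the simulation stage is skipped.
#' @return invisibly, a list with the cohort, filtered counts, split plan,
#'   `DMResult`, criteria table, panel, scores, cutoff, classification,
#'   ROC results, random-panel AUCs, MDS coordinates, and a `summary`
#'   list of the headline numbers.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  log_lines <- character()
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, msg)
    message("[methpanel] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  if (is.null(cohort)) {
    say("simulate: %d patients, seed %d", config$sim$n_patients, config$seed)
    cohort <- stage("simulate", simulate_cohort(config$sim))
  }
  n_sites_raw <- nrow(cohort$counts$sites)
  counts <- stage("filter", filter_coverage(cohort$counts, config$min_reads))
  say("filter: %d/%d CpGs covered by >= %d reads in all samples",
      nrow(counts$sites), n_sites_raw, config$min_reads)

  plan <- stage("split", stratified_batch_split(cohort$sheet,
                                                config$train_fraction,
                                                seed = config$seed + 1L))
  say("split: %d train / %d test patients (%d / %d batches)",
      length(plan$train_patients), length(plan$test_patients),
      length(plan$train_batches), length(plan$test_batches))

  train_sheet <- as_sample_sheet(
    cohort$sheet[cohort$sheet$sample_id %in% plan$train_samples, ])
  dmres <- stage("dmtest", dm_test(counts, train_sheet, cohort$regions))
  say("dmtest: prior df %.3g, prior variance %.3g", dmres$df_prior,
      dmres$s2_prior)

  criteria <- stage("criteria", apply_inclusion_criteria(
    region_dmr_table(dmres, cohort$regions), cohort$islands,
    min_len = config$min_len, min_delta = config$min_delta,
    max_q = config$max_q))
  pass_by_class <- tapply(criteria$pass, criteria$truth_class, mean)
  say("criteria: %.1f%% of biomarker regions pass all four",
      100 * (pass_by_class[["biomarker"]] %||% NA))

  pool <- cohort$regions$region_id[cohort$regions$truth_class == "biomarker"]
  if (!length(pool)) pool <- cohort$regions$region_id
  panel <- stage("panel", select_top_panel(dmres$region, k = config$k,
                                           eligible = pool))

  levels_all <- stage("levels", region_meth_levels(counts, cohort$regions))
  scores <- stage("score", panel_score(levels_all, panel))
  idx_train <- match(plan$train_samples, scores$sample_id)
  idx_test <- match(plan$test_samples, scores$sample_id)
  lab <- cohort$sheet$tissue[match(scores$sample_id, cohort$sheet$sample_id)]

  cut <- stage("cutoff", optimize_cutoff(scores$score[idx_train],
                                         lab[idx_train],
                                         metric = config$cutoff_metric))
  say("cutoff: %.4f (%s = %.3f)", cut$cutoff, cut$metric, cut$value)

  cls_test <- classify_samples(scores$score[idx_test], cut$cutoff,
                               truth = lab[idx_test])
  cls_all <- classify_samples(scores$score, cut$cutoff, truth = lab)
  roc_test <- roc_curve_auc(scores$score[idx_test], lab[idx_test])
  roc_train <- roc_curve_auc(scores$score[idx_train], lab[idx_train])
  say("test AUC %.4f; test sensitivity %.3f", roc_test$auc,
      cls_test$sensitivity)

  rnd <- stage("random_panels", random_panel_aucs(
    pool, k = config$k, n_sets = config$n_random_sets,
    levels = region_level_subset(levels_all, plan$test_samples),
    labels = lab[idx_test], seed = config$seed + 2L))
  say("random panels: mean test AUC %.4f over %d sets", rnd$mean_auc,
      config$n_random_sets)

  mds <- stage("mds", mds_embedding(asin_transform(levels_all),
                                    top_n = config$mds_top_n))

  summary <- list(
    n_patients = length(unique(cohort$sheet$patient_id)),
    n_samples = nrow(cohort$sheet),
    n_cpgs_raw = n_sites_raw,
    n_cpgs_covered = nrow(counts$sites),
    train_patients = length(plan$train_patients),
    test_patients = length(plan$test_patients),
    df_prior = dmres$df_prior,
    panel = panel,
    cutoff = cut$cutoff,
    cutoff_metric = cut$metric,
    train_auc = roc_train$auc,
    test_auc = roc_test$auc,
    test_confusion = as.list(cls_test$confusion),
    test_sensitivity = cls_test$sensitivity,
    test_specificity = cls_test$specificity,
    overall_sensitivity = cls_all$sensitivity,
    overall_specificity = cls_all$specificity,
    random_panel_mean_auc = rnd$mean_auc,
    pass_fraction_by_class = as.list(pass_by_class))

  result <- list(cohort = cohort, counts = counts, plan = plan, dmres = dmres,
                 criteria = criteria, panel = panel, levels = levels_all,
                 scores = scores, cutoff = cut, classification_test = cls_test,
                 classification_all = cls_all, roc_test = roc_test,
                 roc_train = roc_train, random_panels = rnd, mds = mds,
                 summary = summary, config = config, log = log_lines)

  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  invisible(result)
}

# subset a RegionLevelMatrix by sample id
region_level_subset <- function(levels, samples) {
  j <- match(samples, levels$samples)
  structure(list(levels = levels$levels[, j, drop = FALSE],
                 totals = levels$totals[, j, drop = FALSE],
                 samples = samples),
            class = "RegionLevelMatrix")
}

write_tsv_prov <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# methpanel %s; seed=%d; min_reads=%d; max_gap=%d; min_run=%d; min_len=%d; min_delta=%g; max_q=%g; k=%d",
                     as.character(utils::packageVersion("methpanel")),
                     config$seed, config$min_reads, config$max_gap,
                     config$min_run, config$min_len, config$min_delta,
                     config$max_q, config$k), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  write_tsv_prov(result$dmres$cpg, file.path(outdir, "per_cpg.tsv"), cfg)
  write_tsv_prov(result$dmres$region, file.path(outdir, "per_region.tsv"), cfg)
  write_tsv_prov(result$criteria, file.path(outdir, "inclusion_criteria.tsv"), cfg)
  write_tsv_prov(result$scores, file.path(outdir, "panel_scores.tsv"), cfg)
  lv <- data.frame(region_id = rownames(result$levels$levels),
                   result$levels$levels, check.names = FALSE)
  write_tsv_prov(lv, file.path(outdir, "region_levels.tsv"), cfg)
  write_tsv_prov(data.frame(threshold = result$roc_test$thresholds,
                            fpr = result$roc_test$fpr,
                            tpr = result$roc_test$tpr),
                 file.path(outdir, "roc_test.tsv"), cfg)
  write_tsv_prov(data.frame(set = seq_along(result$random_panels$aucs),
                            auc = result$random_panels$aucs),
                 file.path(outdir, "random_panel_aucs.tsv"), cfg)
  write_tsv_prov(data.frame(sample_id = rownames(result$mds$coords),
                            result$mds$coords),
                 file.path(outdir, "mds_coordinates.tsv"), cfg)
  jsonlite::write_json(result$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_config(cfg, file.path(outdir, "config.yaml"))
  writeLines(c(paste0("methpanel ", as.character(utils::packageVersion("methpanel")),
                      " / R ", getRversion()),
               result$log), file.path(outdir, "run.log"))
  invisible(outdir)
}
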