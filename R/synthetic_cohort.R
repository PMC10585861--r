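# Synthetic targeted-bisulfite cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# paired tumor/normal-mucosa (NM) design across measurement batches, target
# regions in five truth classes, beta-binomial read-count noise over
# negative-binomial coverage, mild batch effects on the logit scale, and
# age-dependent methylation at aging-specific regions.

#' Simulation configuration
#'
#' Defaults describe the emulated study: 59 patients (41 conventional
#' adenomas, 18 sessile serrated lesions), 990 candidate biomarker regions
#' hypermethylated in tumors of both lesion types with a methylation
#' difference of at least 0.5, 17 cADN-only and 22 SSL-only regions, 47
#' negative-control regions methylated in both tissues, 20 aging-specific
#' regions whose methylation rises with donor age in both tissues, and 10
#' measurement batches.
#'
#' @param n_patients number of patients (each contributes one NM and one
#'   tumor sample).
#' @param lesion_ratio fraction of tumors that are conventional adenomas
#'   (cADN); the rest are sessile serrated lesions (SSL).
#' @param n_batches number of measurement batches; patients are spread
#'   round-robin so lesion types mix within batches.
#' @param n_biomarker,n_cadn_only,n_ssl_only,n_negative_control,n_aging_specific
#'   region counts per truth class.
#' @param cpgs_per_region inclusive integer range of CpGs per region.
#' @param cpg_spacing inclusive integer range (bp) between consecutive CpGs
#'   within a region.
#' @param mean_coverage mean per-CpG read coverage.
#' @param coverage_size negative-binomial size (dispersion) of coverage;
#'   the default 4 gives a coefficient of variation of about 0.5 at 100x.
#' @param nm_baseline_mean,nm_baseline_precision beta mean and precision of
#'   the NM methylation baseline at biomarker/lesion-specific regions.
#' @param delta_range tumor-minus-NM methylation difference at biomarker
#'   regions, drawn uniformly per region from this range.
#' @param lesion_delta_range like `delta_range` but for the cADN-only /
#'   SSL-only classes (applied only in the matching lesion type).
#' @param negative_control_mean,negative_control_precision beta mean and
#'   precision of the (shared) methylation level at negative controls.
#' @param aging_slope methylation increase per year of donor age at
#'   aging-specific regions (both tissues).
#' @param age_range donor age range (years), sampled uniformly.
#' @param rho beta-binomial overdispersion in [0, 1).
#' @param batch_sd standard deviation of the per-batch logit shift.
#' @param seed integer seed; a fixed seed makes the cohort byte-identical.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_patients = 59,
                       lesion_ratio = 41 / 59,
                       n_batches = 10,
                       n_biomarker = 990,
                       n_cadn_only = 17,
                       n_ssl_only = 22,
                       n_negative_control = 47,
                       n_aging_specific = 20,
                       cpgs_per_region = c(5, 25),
                       cpg_spacing = c(5, 50),
                       mean_coverage = 100,
                       coverage_size = 4,
                       nm_baseline_mean = 0.05,
                       nm_baseline_precision = 30,
                       delta_range = c(0.5, 0.75),
                       lesion_delta_range = c(0.3, 0.6),
                       negative_control_mean = 0.7,
                       negative_control_precision = 50,
                       aging_slope = 0.004,
                       age_range = c(40, 80),
                       rho = 0.05,
                       batch_sd = 0.1,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 2,
            cfg$lesion_ratio >= 0, cfg$lesion_ratio <= 1,
            cfg$n_batches >= 1,
            cfg$rho >= 0, cfg$rho < 1,
            cfg$nm_baseline_mean > 0, cfg$nm_baseline_mean < 1,
            cfg$negative_control_mean > 0, cfg$negative_control_mean < 1,
            length(cfg$delta_range) == 2, diff(cfg$delta_range) >= 0,
            cfg$delta_range[1] >= 0,
            cfg$mean_coverage > 0, cfg$coverage_size > 0,
            cfg$batch_sd >= 0, cfg$aging_slope >= 0)
  # NM draws at effect regions are capped at nm_cap so tumor = NM + delta
  # stays inside [0, 1].
  cfg$nm_cap <- 0.2
  if (cfg$delta_range[2] > 1 - cfg$nm_cap) {
    stop("delta_range must lie within [0, ", 1 - cfg$nm_cap, "]")
  }
  structure(cfg, class = "SimConfig")
}

# Beta draw parameterised by mean and precision (a+b), vectorised.
rbeta_mean_prec <- function(n, mean, precision) {
  stats::rbeta(n, shape1 = mean * precision, shape2 = (1 - mean) * precision)
}

#' Draw beta-binomial counts
#'
#' `rho = 0` reduces to the binomial; for `rho > 0` the per-draw success
#' probability is beta-distributed with `alpha = p(1-rho)/rho`,
#' `beta = (1-p)(1-rho)/rho`, giving variance
#' `n p (1-p) (1 + (n-1) rho)`.
#'
#' @param n vector of trial counts (non-negative).
#' @param p vector of mean methylation probabilities in [0, 1].
#' @param rho overdispersion in [0, 1).
#' @return integer counts in `[0, n]`, recycled to the common length.
#' @export
sample_beta_binomial <- function(n, p, rho = 0) {
  if (any(n < 0)) stop("trial counts must be non-negative")
  stopifnot(all(p >= 0), all(p <= 1), rho >= 0, rho < 1)
  m <- max(length(n), length(p))
  n <- rep_len(as.integer(n), m)
  p <- rep_len(p, m)
  if (rho == 0) return(stats::rbinom(m, n, p))
  out <- integer(m)
  inner <- (p > 0 & p < 1)
  if (any(inner)) {
    a <- p[inner] * (1 - rho) / rho
    b <- (1 - p[inner]) * (1 - rho) / rho
    pp <- stats::rbeta(sum(inner), a, b)
    out[inner] <- stats::rbinom(sum(inner), n[inner], pp)
  }
  out[p == 1] <- n[p == 1]
  out
}

#' Simulate a paired, batched targeted-bisulfite cohort
#'
#' Produces per-CpG methylated/total read counts for every sample, the
#' paired sample sheet, the target regions with truth-class labels, CpG
#' islands covering the targets, and a truth manifest with the per-patient
#' true methylation levels.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `counts` (`MethCountMatrix`), `sheet`
#'   (`SampleSheet`), `regions` (`RegionSet`), `islands` (`RegionSet`),
#'   `truth` (list: `regions` data.frame of per-region class and delta;
#'   `levels` data.frame of per (region, patient) true NM/tumor levels),
#'   and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$n_patients < 2) stop("paired testing needs at least 2 patients")
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_pat <- cfg$n_patients
  pat_ids <- sprintf("P%03d", seq_len(n_pat))
  n_cadn <- round(cfg$lesion_ratio * n_pat)
  lesion <- rep(c("cADN", "SSL"), c(n_cadn, n_pat - n_cadn))
  age <- round(stats::runif(n_pat, cfg$age_range[1], cfg$age_range[2]), 1)
  # round-robin over lesion-sorted patients mixes lesion types within batches
  batch <- sprintf("B%02d", rep_len(seq_len(cfg$n_batches), n_pat))

  sheet <- as_sample_sheet(data.frame(
    sample_id = c(rbind(paste0(pat_ids, "_NM"), paste0(pat_ids, "_T"))),
    patient_id = rep(pat_ids, each = 2),
    tissue = rep(c("NM", "tumor"), n_pat),
    lesion_type = rep(lesion, each = 2),
    batch = rep(batch, each = 2),
    age = rep(age, each = 2)))

  classes <- rep(c("biomarker", "cadn_only", "ssl_only", "negative_control",
                   "aging_specific"),
                 c(cfg$n_biomarker, cfg$n_cadn_only, cfg$n_ssl_only,
                   cfg$n_negative_control, cfg$n_aging_specific))
  n_reg <- length(classes)
  if (n_reg < 1) stop("at least one region is required")
  n_cpg <- sample(seq(cfg$cpgs_per_region[1], cfg$cpgs_per_region[2]),
                  n_reg, replace = TRUE)

  # lay regions on synthetic chromosomes, 22 per round, 1 kb gaps
  chrom <- sprintf("chr%02d", rep_len(seq_len(22), n_reg))
  pos_list <- vector("list", n_reg)
  offset <- stats::setNames(rep(1000L, 22), sprintf("chr%02d", 1:22))
  start <- integer(n_reg); end <- integer(n_reg)
  for (r in seq_len(n_reg)) {
    gaps <- sample(seq(cfg$cpg_spacing[1], cfg$cpg_spacing[2]),
                   n_cpg[r] - 1L, replace = TRUE)
    p0 <- offset[[chrom[r]]]
    pos <- p0 + c(0L, cumsum(gaps))
    pos_list[[r]] <- pos
    start[r] <- pos[1]
    end[r] <- pos[n_cpg[r]] + 2L  # cover the final CpG dinucleotide
    offset[[chrom[r]]] <- end[r] + 1000L
  }
  region_id <- sprintf("R%04d", seq_len(n_reg))
  regions <- as_region_set(data.frame(region_id = region_id, chrom = chrom,
                                      start = start, end = end,
                                      truth_class = classes))
  islands <- as_region_set(data.frame(
    region_id = paste0("CGI_", region_id), chrom = chrom,
    start = pmax(start - 25L, 0L), end = end + 25L,
    truth_class = "unknown"))

  # per-region effect sizes and per (region, patient) true levels
  delta_region <- numeric(n_reg)
  delta_region[classes == "biomarker"] <-
    stats::runif(sum(classes == "biomarker"), cfg$delta_range[1], cfg$delta_range[2])
  one_sided <- classes %in% c("cadn_only", "ssl_only")
  delta_region[one_sided] <-
    stats::runif(sum(one_sided), cfg$lesion_delta_range[1], cfg$lesion_delta_range[2])

  nm_level <- matrix(0, n_reg, n_pat)     # regions x patients
  tumor_level <- matrix(0, n_reg, n_pat)
  base_classes <- classes %in% c("biomarker", "cadn_only", "ssl_only")
  nb <- sum(base_classes)
  if (nb) {
    nm <- pmin(rbeta_mean_prec(nb * n_pat, cfg$nm_baseline_mean,
                               cfg$nm_baseline_precision), cfg$nm_cap)
    nm_level[base_classes, ] <- nm
    affected <- matrix(TRUE, nb, n_pat)
    sub_cls <- classes[base_classes]
    if (any(sub_cls == "cadn_only")) {
      affected[sub_cls == "cadn_only", ] <-
        matrix(lesion == "cADN", sum(sub_cls == "cadn_only"), n_pat, byrow = TRUE)
    }
    if (any(sub_cls == "ssl_only")) {
      affected[sub_cls == "ssl_only", ] <-
        matrix(lesion == "SSL", sum(sub_cls == "ssl_only"), n_pat, byrow = TRUE)
    }
    tl <- nm_level[base_classes, , drop = FALSE] +
      affected * delta_region[base_classes]
    tumor_level[base_classes, ] <- tl
  }
  is_nc <- classes == "negative_control"
  if (any(is_nc)) {
    lv <- rbeta_mean_prec(sum(is_nc) * n_pat, cfg$negative_control_mean,
                          cfg$negative_control_precision)
    nm_level[is_nc, ] <- lv
    tumor_level[is_nc, ] <- lv
  }
  is_ag <- classes == "aging_specific"
  if (any(is_ag)) {
    lv <- outer(rep(1, sum(is_ag)),
                clamp(cfg$nm_baseline_mean +
                        cfg$aging_slope * (age - cfg$age_range[1]), 0, 0.95))
    nm_level[is_ag, ] <- lv
    tumor_level[is_ag, ] <- lv
  }

  truth <- list(
    regions = data.frame(region_id = region_id, truth_class = classes,
                         delta = delta_region),
    levels = data.frame(
      region_id = rep(region_id, n_pat),
      patient_id = rep(pat_ids, each = n_reg),
      nm_level = as.vector(nm_level),
      tumor_level = as.vector(tumor_level),
      delta = as.vector(tumor_level - nm_level)))

  # expand to site x sample true probabilities
  site_region <- rep.int(seq_len(n_reg), n_cpg)
  sites <- data.frame(chrom = chrom[site_region],
                      pos = unlist(pos_list),
                      strand = "+")
  n_site <- nrow(sites)
  n_smp <- nrow(sheet)
  pat_idx <- match(sheet$patient_id, pat_ids)
  is_tumor <- sheet$tissue == "tumor"
  p <- matrix(0, n_site, n_smp)
  for (j in seq_len(n_smp)) {
    lev <- if (is_tumor[j]) tumor_level[, pat_idx[j]] else nm_level[, pat_idx[j]]
    p[, j] <- lev[site_region]
  }
  shift <- stats::rnorm(cfg$n_batches, 0, cfg$batch_sd)
  names(shift) <- sprintf("B%02d", seq_len(cfg$n_batches))
  p_adj <- stats::plogis(stats::qlogis(clamp(p, 1e-4, 1 - 1e-4)) +
                           rep(shift[sheet$batch], each = n_site))

  coverage <- matrix(stats::rnbinom(n_site * n_smp, mu = cfg$mean_coverage,
                                    size = cfg$coverage_size),
                     n_site, n_smp)
  meth <- matrix(sample_beta_binomial(as.vector(coverage), as.vector(p_adj),
                                      cfg$rho),
                 n_site, n_smp)
  counts <- meth_count_matrix(sites, meth, coverage, sheet$sample_id)

  list(counts = counts, sheet = sheet, regions = regions, islands = islands,
       truth = truth, config = cfg)
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits one Bismark-style cytosine report per sample, the region and island
#' BED files, the sample sheet TSV, and a truth-manifest TSV.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_along(cohort$counts$samples)) {
    s <- cohort$counts$samples[j]
    rec <- data.frame(cohort$counts$sites,
                      meth = cohort$counts$meth[, j],
                      total = cohort$counts$total[, j])
    write_cytosine_report(rec, file.path(dir, paste0(s, ".CpG_report.txt")))
  }
  write_regions_bed(cohort$regions, file.path(dir, "regions.bed"))
  write_regions_bed(cohort$islands, file.path(dir, "cpg_islands.bed"))
  write_sample_sheet(cohort$sheet, file.path(dir, "samples.tsv"))
  utils::write.table(cohort$truth$levels, file.path(dir, "truth_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
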