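# Shared fixtures and independent brute-force oracles.

# hand-built 5-site x 2-sample count matrix
toy_counts <- function() {
  sites <- data.frame(chrom = "chr1",
                      pos = c(100L, 130L, 160L, 300L, 350L),
                      strand = "+")
  total <- matrix(c(10L, 7L, 6L, 0L, 8L,
                    10L, 7L, 9L, 50L, 8L), ncol = 2)
  meth <- matrix(c(3L, 7L, 2L, 0L, 4L,
                   7L, 0L, 3L, 25L, 4L), ncol = 2)
  meth_count_matrix(sites, meth, total, c("S1", "S2"))
}

# minimal paired sheet: n patients, alternating lesion types, one batch
# per `per_batch` patients
toy_sheet <- function(n_patients = 2, per_batch = 1) {
  pid <- sprintf("P%02d", seq_len(n_patients))
  data.frame(
    sample_id = c(rbind(paste0(pid, "_NM"), paste0(pid, "_T"))),
    patient_id = rep(pid, each = 2),
    tissue = rep(c("NM", "tumor"), n_patients),
    lesion_type = rep(rep(c("cADN", "SSL"), length.out = n_patients), each = 2),
    batch = rep(sprintf("B%02d", ceiling(seq_len(n_patients) / per_batch)),
                each = 2))
}

small_cohort <- function(seed = 42, ...) {
  args <- list(n_patients = 10, n_biomarker = 12, n_cadn_only = 2,
               n_ssl_only = 2, n_negative_control = 4, n_aging_specific = 2,
               n_batches = 3, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  simulate_cohort(do.call(sim_config, args))
}

# --- independent oracles -------------------------------------------------

# Simes by explicit loop over the sorted vector
oracle_simes <- function(p) {
  ps <- p[order(p)]
  m <- length(ps)
  best <- 1
  for (i in seq_len(m)) best <- min(best, m * ps[i] / i)
  best
}

# BH step-up with explicit backwards cumulative minimum
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- min(1, running)
  }
  q
}

# AUC as the Mann-Whitney pair count (ties worth 1/2)
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  conc <- 0
  for (a in pos) for (b in neg) {
    conc <- conc + (a > b) + 0.5 * (a == b)
  }
  conc / (length(pos) * length(neg))
}
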