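# Rule-based DMR calling and the formal inclusion criteria.
#
# A DMR is a run of at least `min_run` consecutive differentially
# methylated cytosines with directionally identical changes, successive
# positions at most `max_gap` bp apart. Candidate calls are then screened
# by the formal inclusion criteria: CpG-island overlap, minimum length,
# minimum methylation difference, and a q-value threshold.

#' Call candidate DMRs from per-CpG test results
#'
#' A CpG is differentially methylated (DM) iff its BH-adjusted per-CpG
#' p-value is below `alpha_cpg`. Maximal runs of DM CpGs sharing
#' `sign(beta)` with successive gaps `<= max_gap` and at least `min_run`
#' members become calls spanning first to last member CpG (end exclusive
#' at last position + 1). Each call gets a Simes p over its member CpG
#' p-values and a BH q across calls; when `counts` and `sheet` are
#' supplied, the call's methylation difference `delta` is the pooled
#' (coverage-weighted) tumor-minus-NM level over the call interval.
#'
#' @param cpg per-CpG results (columns `chrom`, `pos`, `beta`, `p`,
#'   `p_adj`), sorted by (chrom, pos); the `cpg` element of a `DMResult`.
#' @param alpha_cpg per-CpG significance level on the adjusted p (0.05).
#' @param max_gap maximum distance (bp) between successive DM CpGs (50).
#' @param min_run minimum number of member CpGs (3).
#' @param counts,sheet optional `MethCountMatrix` and `SampleSheet` used to
#'   compute per-call `delta`.
#' @return data.frame of calls: `chrom`, `start`, `end`, `n_cpgs`,
#'   `direction`, `delta`, `simes_p`, `q`.
#' @export
call_candidate_dmrs <- function(cpg, alpha_cpg = 0.05, max_gap = 50,
                                min_run = 3, counts = NULL, sheet = NULL) {
  if (!is_sorted_sites(cpg$chrom, cpg$pos)) {
    stop("per-CpG results must be sorted by (chrom, pos)")
  }
  dm <- cpg[cpg$p_adj < alpha_cpg, , drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_cpgs = integer(), direction = character(),
                      delta = numeric(), simes_p = numeric(), q = numeric())
  if (nrow(dm) == 0) return(empty)
  sgn <- sign(dm$beta)
  new_run <- c(TRUE,
               dm$chrom[-1] != dm$chrom[-nrow(dm)] |
                 dm$pos[-1] - dm$pos[-nrow(dm)] > max_gap |
                 sgn[-1] != sgn[-nrow(dm)])
  run_id <- cumsum(new_run)
  keep <- as.vector(table(run_id)) >= min_run
  runs <- split(seq_len(nrow(dm)), run_id)[keep]
  if (length(runs) == 0) return(empty)
  calls <- do.call(rbind, lapply(runs, function(idx) {
    data.frame(chrom = dm$chrom[idx[1]],
               start = dm$pos[idx[1]],
               end = dm$pos[idx[length(idx)]] + 1L,
               n_cpgs = length(idx),
               direction = if (sgn[idx[1]] > 0) "hyper" else "hypo",
               simes_p = simes_aggregate(dm$p[idx]))
  }))
  rownames(calls) <- NULL
  calls$q <- bh_adjust(calls$simes_p)
  calls$delta <- NA_real_
  if (!is.null(counts) && !is.null(sheet)) {
    sheet <- as_sample_sheet(sheet)
    counts <- subset_counts(counts, samples = sheet$sample_id)
    reg <- as_region_set(data.frame(region_id = sprintf("call%04d", seq_len(nrow(calls))),
                                    chrom = calls$chrom, start = calls$start,
                                    end = calls$end))
    hits <- GenomicRanges::findOverlaps(sites_to_granges(counts$sites),
                                        regions_to_granges(reg))
    si <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
    pool <- function(tissue) {
      j <- which(sheet$tissue == tissue)
      msum <- rep(0, nrow(reg)); tsum <- rep(0, nrow(reg))
      if (length(si)) {
        ms <- rowsum(rowSums(counts$meth[si, j, drop = FALSE]), ri)
        ts <- rowsum(rowSums(counts$total[si, j, drop = FALSE]), ri)
        rows <- as.integer(rownames(ms))
        msum[rows] <- ms[, 1]
        tsum[rows] <- ts[, 1]
      }
      ifelse(tsum > 0, msum / tsum, NA_real_)
    }
    calls$delta <- pool("tumor") - pool("NM")
  }
  calls[, c("chrom", "start", "end", "n_cpgs", "direction", "delta",
            "simes_p", "q")]
}

#' Apply the formal inclusion criteria to DMR calls
#'
#' A call passes iff it overlaps at least one CpG-island interval by at
#' least 1 bp, spans at least `min_len` bp, is hypermethylated with a
#' methylation difference `delta >= min_delta`, and has `q < max_q`. All
#' four flags are reported for every call, passing or not.
#'
#' @param calls data.frame of calls (from [call_candidate_dmrs()] or
#'   [region_dmr_table()]); needs `chrom`, `start`, `end`, `direction`,
#'   `delta`, `q`.
#' @param islands CpG islands as a `RegionSet` (or data.frame with `chrom`,
#'   `start`, `end` on the 0-based half-open scale).
#' @param min_len minimum call length in bp (default 80).
#' @param min_delta minimum tumor-minus-NM methylation difference (0.5).
#' @param max_q q-value threshold (0.05, strict).
#' @return the calls with logical columns `cpg_island_overlap`,
#'   `min_length`, `min_delta`, `max_q`, and `pass`.
#' @export
apply_inclusion_criteria <- function(calls, islands, min_len = 80,
                                     min_delta = 0.5, max_q = 0.05) {
  islands <- as_region_set(islands)
  if (nrow(calls) == 0) {
    calls$cpg_island_overlap <- logical()
    calls$min_length <- logical()
    calls$min_delta <- logical()
    calls$max_q <- logical()
    calls$pass <- logical()
    return(calls)
  }
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start + 1L, calls$end))
  ov <- GenomicRanges::countOverlaps(gr, regions_to_granges(islands),
                                     minoverlap = 1L)
  calls$cpg_island_overlap <- ov > 0
  calls$min_length <- (calls$end - calls$start) >= min_len
  calls$min_delta <- calls$direction == "hyper" &
    !is.na(calls$delta) & calls$delta >= min_delta
  calls$max_q <- !is.na(calls$q) & calls$q < max_q
  calls$pass <- calls$cpg_island_overlap & calls$min_length &
    calls$min_delta & calls$max_q
  calls
}

#' Per-region DMR table for validation mode
#'
#' Treats each predefined target region as a candidate call so the formal
#' inclusion criteria can be evaluated on a fixed region catalogue:
#' coordinates come from the region set, direction from the sign of the
#' mean log-fold-change, and `delta`/`q` from the per-region test
#' summaries.
#'
#' @param dmres a `DMResult` computed with `regions`.
#' @param regions the same `RegionSet`.
#' @return data.frame in the call format accepted by
#'   [apply_inclusion_criteria()], plus `region_id` and `truth_class`.
#' @export
region_dmr_table <- function(dmres, regions) {
  stopifnot(inherits(dmres, "DMResult"), !is.null(dmres$region))
  regions <- as_region_set(regions)
  tab <- dmres$region
  idx <- match(regions$region_id, tab$region_id)
  data.frame(region_id = regions$region_id,
             truth_class = regions$truth_class,
             chrom = regions$chrom, start = regions$start, end = regions$end,
             n_cpgs = tab$n_cpgs[idx],
             direction = ifelse(!is.na(tab$mean_lfc[idx]) & tab$mean_lfc[idx] >= 0,
                                "hyper", "hypo"),
             delta = tab$delta[idx],
             simes_p = tab$simes_p[idx],
             q = tab$q[idx])
}
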