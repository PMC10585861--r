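# Coverage filtering, per-region methylation levels, and the transforms
# used by testing (log2CPM) and visualisation (arcsine square root).

#' Filter CpG sites by minimum coverage in every sample
#'
#' Retains exactly the sites whose total read count is at least `min_reads`
#' in all samples (conjunction across samples); site order is preserved.
#'
#' @param x a `MethCountMatrix`.
#' @param min_reads minimum total reads required in every sample (default 7).
#' @return a filtered `MethCountMatrix`.
#' @export
filter_coverage <- function(x, min_reads = 7) {
  stopifnot(inherits(x, "MethCountMatrix"), min_reads >= 0)
  keep <- rowSums(x$total >= min_reads) == ncol(x$total)
  if (!any(keep)) warning("no CpG sites pass the coverage filter")
  subset_counts(x, sites = which(keep))
}

#' Per-region methylation levels
#'
#' For each (region, sample), the level is the fraction of methylated over
#' all reads pooled across the region's CpGs — i.e. the coverage-weighted
#' mean of per-CpG levels. Cells with zero supporting reads are `NA`.
#'
#' @param x a `MethCountMatrix` (sites sorted).
#' @param regions a `RegionSet` (non-overlapping); membership is evaluated
#'   on the 0-based half-open interval `[start, end)`.
#' @return an object of class `RegionLevelMatrix`: list with `levels` and
#'   `totals` matrices (regions x samples, rownames = region ids) and
#'   `samples`.
#' @export
region_meth_levels <- function(x, regions) {
  stopifnot(inherits(x, "MethCountMatrix"))
  regions <- as_region_set(regions)
  hits <- GenomicRanges::findOverlaps(sites_to_granges(x$sites),
                                      regions_to_granges(regions))
  si <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  n_reg <- nrow(regions)
  meth <- matrix(0, n_reg, length(x$samples))
  total <- matrix(0, n_reg, length(x$samples))
  if (length(si)) {
    ms <- rowsum(x$meth[si, , drop = FALSE], ri)
    ts <- rowsum(x$total[si, , drop = FALSE], ri)
    rows <- as.integer(rownames(ms))
    meth[rows, ] <- ms
    total[rows, ] <- ts
  }
  empty <- setdiff(seq_len(n_reg), unique(ri))
  if (length(empty)) {
    message(length(empty), " region(s) contain no probed CpGs; levels set to NA")
  }
  levels <- ifelse(total > 0, meth / total, NA_real_)
  dimnames(levels) <- dimnames(total) <- list(regions$region_id, x$samples)
  structure(list(levels = levels, totals = total, samples = x$samples),
            class = "RegionLevelMatrix")
}

#' Arcsine square-root transform of methylation levels
#'
#' The variance-stabilising transform for proportions, `x -> asin(sqrt(x))`;
#' `NA` propagates.
#'
#' @param x numeric matrix/vector of levels in [0, 1], or a
#'   `RegionLevelMatrix`.
#' @return transformed numeric object of the same shape.
#' @export
asin_transform <- function(x) {
  if (inherits(x, "RegionLevelMatrix")) x <- x$levels
  v <- x[!is.na(x)]
  if (any(v < 0 | v > 1)) stop("methylation levels must lie in [0, 1]")
  asin(sqrt(x))
}

#' log2 counts-per-million transform
#'
#' `log2((c + prior) / (L + 2 * prior) * 1e6)` where `L` is the library
#' size (column sum) of each observation column.
#'
#' @param counts non-negative count matrix; columns are observations.
#' @param prior pseudo-count (default 0.5).
#' @param lib optional explicit library sizes, one per column, overriding
#'   the column sums (used for two-level methylation counts, where both of
#'   a sample's observation columns share the sample's total library so
#'   that normalisation is absorbed by the sample effects).
#' @return real matrix of the same dimensions.
#' @export
log2cpm <- function(counts, prior = 0.5, lib = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(lib)) lib <- colSums(counts)
  stopifnot(length(lib) == ncol(counts))
  if (any(lib == 0)) {
    bad <- which(lib == 0)[1L]
    nm <- colnames(counts)[bad] %||% as.character(bad)
    stop("all-zero observation column: ", nm)
  }
  log2(sweep(counts + prior, 2, lib + 2 * prior, "/") * 1e6)
}
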