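# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library calls never perturb a user's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

site_key <- function(chrom, pos, strand) paste(chrom, pos, strand, sep = ":")

# Deterministic ordering of sites by (chrom, pos, strand).
order_sites <- function(chrom, pos, strand) order(chrom, pos, strand, method = "radix")

is_sorted_sites <- function(chrom, pos) {
  !is.unsorted(order(chrom, pos, method = "radix")) &&
    identical(order(chrom, pos, method = "radix"), seq_along(chrom))
}

# GRanges view of internal 0-based half-open intervals (1-based closed inside GRanges).
regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos + 1L, width = 1L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
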