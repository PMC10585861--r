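# Readers and writers for the file formats the pipeline touches.
#
# Coordinate conventions: everything internal is 0-based half-open
# (BED-native). Bismark cytosine reports are 1-based and converted at the
# I/O boundary; positions are written back out as 1-based.

TRUTH_CLASSES <- c("biomarker", "cadn_only", "ssl_only", "negative_control",
                   "aging_specific", "unknown")
TISSUE_LEVELS <- c("NM", "tumor")
LESION_LEVELS <- c("cADN", "SSL", "none")

#' Construct and validate a per-CpG methylation count matrix
#'
#' The central count container: an ordered table of CpG sites with one
#' methylated-count and one total-count matrix (sites x samples).
#'
#' @param sites data.frame with columns `chrom`, `pos` (0-based cytosine
#'   position), `strand` (`"+"` or `"-"`).
#' @param meth,total integer matrices, sites x samples, with
#'   `0 <= meth <= total` elementwise.
#' @param samples character vector of sample ids, one per column.
#' @return An object of class `MethCountMatrix`: a list with elements
#'   `sites`, `meth`, `total`, `samples`.
#' @export
meth_count_matrix <- function(sites, meth, total, samples) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "strand") %in% names(sites)))
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  samples <- as.character(samples)
  if (nrow(meth) != nrow(sites) || nrow(total) != nrow(sites) ||
      ncol(meth) != length(samples) || ncol(total) != length(samples)) {
    stop("matrix dimensions must be sites x samples")
  }
  if (any(sites$pos < 0)) stop("positions must be >= 0")
  if (!all(sites$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(site_key(sites$chrom, sites$pos, sites$strand))) {
    stop("sites must be unique by (chrom, pos, strand)")
  }
  o <- order_sites(sites$chrom, sites$pos, sites$strand)
  if (!identical(o, seq_len(nrow(sites)))) {
    sites <- sites[o, , drop = FALSE]
    meth <- meth[o, , drop = FALSE]
    total <- total[o, , drop = FALSE]
  }
  if (any(meth < 0) || any(meth > total)) {
    stop("counts must satisfy 0 <= meth <= total elementwise")
  }
  storage.mode(meth) <- "integer"
  storage.mode(total) <- "integer"
  rownames(meth) <- rownames(total) <- NULL
  colnames(meth) <- colnames(total) <- samples
  rownames(sites) <- NULL
  structure(list(sites = sites, meth = meth, total = total, samples = samples),
            class = "MethCountMatrix")
}

#' @export
print.MethCountMatrix <- function(x, ...) {
  cat(sprintf("MethCountMatrix: %d CpG sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Subset a MethCountMatrix by site index and/or sample id
#' @param x a `MethCountMatrix`.
#' @param sites integer or logical index over sites (optional).
#' @param samples character vector of sample ids to keep (optional).
#' @export
subset_counts <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "MethCountMatrix"))
  si <- if (is.null(sites)) seq_len(nrow(x$sites)) else sites
  sj <- if (is.null(samples)) x$samples else samples
  j <- match(sj, x$samples)
  if (anyNA(j)) stop("unknown sample id(s): ", paste(sj[is.na(j)], collapse = ", "))
  meth_count_matrix(x$sites[si, , drop = FALSE],
                    x$meth[si, j, drop = FALSE],
                    x$total[si, j, drop = FALSE], sj)
}

#' Read a Bismark-style per-cytosine report
#'
#' Parses the 7-column tab-separated cytosine report (chromosome, 1-based
#' position, strand, methylated count, unmethylated count, context,
#' trinucleotide) and returns 0-based per-site records.
#'
#' @param path path to the report.
#' @param min_context retain only rows whose context equals this string
#'   (default `"CpG"`); `NULL` keeps all contexts.
#' @return data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `meth`, `total`.
#' @export
read_cytosine_report <- function(path, min_context = "CpG") {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty cytosine report: ", path)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), meth = integer(),
                      total = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop(sprintf("malformed cytosine report at line %d: expected >= 6 tab-separated fields",
                 which(nf < 6L)[1L]))
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  chrom <- get(1L)
  pos1 <- suppressWarnings(as.integer(get(2L)))
  strand <- get(3L)
  cm <- suppressWarnings(as.integer(get(4L)))
  cu <- suppressWarnings(as.integer(get(5L)))
  context <- get(6L)
  bad <- which(is.na(pos1) | pos1 < 1L | is.na(cm) | is.na(cu) |
                 cm < 0L | cu < 0L | !(strand %in% c("+", "-")))
  if (length(bad)) {
    stop(sprintf("malformed cytosine report at line %d: %s", bad[1L],
                 lines[bad[1L]]))
  }
  keep <- if (is.null(min_context)) rep(TRUE, length(chrom)) else context == min_context
  data.frame(chrom = chrom[keep], pos = pos1[keep] - 1L, strand = strand[keep],
             meth = cm[keep], total = cm[keep] + cu[keep])
}

#' Write per-site records as a Bismark-style cytosine report
#'
#' Positions are converted back to 1-based. Context is written as `CpG`.
#'
#' @param records data.frame as returned by [read_cytosine_report()].
#' @param path output path.
#' @export
write_cytosine_report <- function(records, path) {
  out <- data.frame(records$chrom, records$pos + 1L, records$strand,
                    records$meth, records$total - records$meth,
                    "CpG", "CGN")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Assemble per-sample site records into a MethCountMatrix
#'
#' Takes the union of sites across samples; a site absent from a sample is
#' filled with `meth = total = 0`. Sites are sorted by (chrom, pos).
#'
#' @param records named list of per-sample data.frames (columns `chrom`,
#'   `pos`, `strand`, `meth`, `total`).
#' @param samples sample ids; defaults to `names(records)`.
#' @return a `MethCountMatrix`.
#' @export
assemble_matrix <- function(records, samples = names(records)) {
  stopifnot(length(records) >= 1L, length(samples) == length(records))
  for (s in seq_along(records)) {
    r <- records[[s]]
    if (anyDuplicated(site_key(r$chrom, r$pos, r$strand))) {
      stop("duplicate site records in sample ", samples[s])
    }
  }
  all_sites <- unique(do.call(rbind, lapply(records, function(r) {
    r[, c("chrom", "pos", "strand")]
  })))
  o <- order_sites(all_sites$chrom, all_sites$pos, all_sites$strand)
  all_sites <- all_sites[o, , drop = FALSE]
  keys <- site_key(all_sites$chrom, all_sites$pos, all_sites$strand)
  n <- nrow(all_sites)
  meth <- matrix(0L, n, length(samples))
  total <- matrix(0L, n, length(samples))
  for (s in seq_along(records)) {
    r <- records[[s]]
    idx <- match(site_key(r$chrom, r$pos, r$strand), keys)
    meth[idx, s] <- as.integer(r$meth)
    total[idx, s] <- as.integer(r$total)
  }
  meth_count_matrix(all_sites, meth, total, samples)
}

#' Validate a region table
#'
#' Regions are 0-based half-open intervals with unique ids, non-overlapping
#' within the set, and a truth-class label (unknown strings map to
#' `"unknown"`).
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, optional
#'   `region_id` and `truth_class`.
#' @return a validated `RegionSet` data.frame with columns `region_id`,
#'   `chrom`, `start`, `end`, `truth_class`.
#' @export
as_region_set <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (is.null(df$region_id)) {
    df$region_id <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  }
  df$region_id <- as.character(df$region_id)
  if (is.null(df$truth_class)) df$truth_class <- "unknown"
  df$truth_class <- ifelse(df$truth_class %in% TRUTH_CLASSES,
                           df$truth_class, "unknown")
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop("regions with start >= end: ",
         paste(df$region_id[bad], collapse = ", "))
  }
  if (anyDuplicated(df$region_id)) stop("region ids must be unique")
  o <- order(df$chrom, df$start, method = "radix")
  ds <- df[o, , drop = FALSE]
  same_chrom <- ds$chrom[-1] == ds$chrom[-nrow(ds)]
  ovl <- which(same_chrom & ds$start[-1] < ds$end[-nrow(ds)])
  if (length(ovl)) {
    stop("overlapping regions: ",
         paste(sprintf("%s/%s", ds$region_id[ovl], ds$region_id[ovl + 1L]),
               collapse = ", "))
  }
  out <- df[, c("region_id", "chrom", "start", "end", "truth_class")]
  rownames(out) <- NULL
  class(out) <- c("RegionSet", "data.frame")
  out
}

#' Read a BED file of regions
#'
#' BED3 plus optional name (column 4) and truth-class (column 5) columns.
#' Intervals are kept verbatim on the 0-based half-open BED scale. Rows
#' without a name get a deterministic `chrom:start-end` id.
#'
#' @param path BED file path.
#' @return a `RegionSet`.
#' @export
read_regions_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "region_id"
  if (ncol(df) >= 5L) names(df)[5L] <- "truth_class"
  as_region_set(df)
}

#' Write a RegionSet as BED5 (name in column 4, truth class in column 5)
#' @param regions a `RegionSet`.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end", "region_id",
                                 "truth_class")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#'
#' Enforces the paired design: every patient contributes exactly one normal
#' mucosa (`NM`) and one `tumor` sample. The lesion type of an NM sample is
#' inherited from its patient's tumor so the two samples stratify together.
#'
#' @param df data.frame with columns `sample_id`, `patient_id`, `tissue`,
#'   `lesion_type`, `batch`, optional `age`.
#' @return a validated `SampleSheet` data.frame.
#' @export
as_sample_sheet <- function(df) {
  df <- as.data.frame(df)
  req <- c("sample_id", "patient_id", "tissue", "lesion_type", "batch")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  bad_tissue <- setdiff(unique(df$tissue), TISSUE_LEVELS)
  if (length(bad_tissue)) {
    stop("unknown tissue label(s) ", paste(sQuote(bad_tissue), collapse = ", "),
         "; expected one of {NM, tumor}")
  }
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  tab <- table(df$patient_id, factor(df$tissue, levels = TISSUE_LEVELS))
  bad <- rownames(tab)[tab[, "NM"] != 1L | tab[, "tumor"] != 1L]
  if (length(bad)) {
    stop("pairing error: patient(s) without exactly one NM and one tumor sample: ",
         paste(bad, collapse = ", "))
  }
  tumor_rows <- df[df$tissue == "tumor", ]
  lesion_of <- stats::setNames(as.character(tumor_rows$lesion_type),
                               tumor_rows$patient_id)
  bad_lesion <- setdiff(unique(lesion_of), LESION_LEVELS)
  if (length(bad_lesion)) {
    stop("unknown lesion_type label(s): ", paste(bad_lesion, collapse = ", "))
  }
  df$lesion_type <- unname(lesion_of[as.character(df$patient_id)])
  pb <- unique(df[, c("patient_id", "batch")])
  if (anyDuplicated(pb$patient_id)) {
    stop("both samples of a patient must share a batch")
  }
  if (is.null(df$age)) df$age <- NA_real_
  out <- df[, c("sample_id", "patient_id", "tissue", "lesion_type", "batch", "age")]
  out$sample_id <- as.character(out$sample_id)
  out$patient_id <- as.character(out$patient_id)
  out$batch <- as.character(out$batch)
  rownames(out) <- NULL
  class(out) <- c("SampleSheet", "data.frame")
  out
}

#' Read a tab-separated sample sheet
#' @param path TSV with header; columns `sample_id`, `patient_id`, `tissue`,
#'   `lesion_type`, `batch`, optional `age`.
#' @return a `SampleSheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  as_sample_sheet(df)
}

#' Write a SampleSheet as TSV
#' @param sheet a `SampleSheet`.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
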