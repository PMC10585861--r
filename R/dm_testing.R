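# Per-CpG differential methylation testing in a paired design on the
# two-level count structure (one methylated and one unmethylated
# observation per sample), empirical-Bayes variance moderation, Simes
# aggregation per region, and Benjamini-Hochberg correction.

#' Build the expanded design matrix for two-level methylation counts
#'
#' Each sample contributes two observation rows (methylated counts first,
#' then unmethylated counts). The design has one indicator column per
#' sample, plus a treatment block applied to methylated rows only:
#' intercept, patient indicators (reference = first patient), and the
#' tested tumor-vs-NM tissue indicator.
#'
#' @param sheet a `SampleSheet` (paired; at least 2 patients).
#' @return a `MethDesign` list: `X` (2N x (N + P + 1) matrix), `coef`
#'   (name of the tested coefficient), `samples` (sample order), and
#'   `df_residual` = `2N - (N + P + 1)`.
#' @export
build_meth_design <- function(sheet) {
  sheet <- as_sample_sheet(sheet)
  n <- nrow(sheet)
  patients <- unique(sheet$patient_id)
  P <- length(patients)
  if (P < 2) stop("paired testing needs at least 2 patients")
  m <- rep(c(1, 0), n)                       # methylated-row indicator
  row_sample <- rep(seq_len(n), each = 2)
  Xs <- matrix(0, 2 * n, n, dimnames = list(NULL, sheet$sample_id))
  Xs[cbind(seq_len(2 * n), row_sample)] <- 1
  pat <- factor(sheet$patient_id, levels = patients)[row_sample]
  Xp <- sapply(patients[-1], function(p) m * (pat == p))
  if (P == 2) Xp <- matrix(Xp, ncol = 1)
  colnames(Xp) <- paste0("patient", patients[-1])
  tissue <- m * (sheet$tissue[row_sample] == "tumor")
  X <- cbind(Xs, `(Intercept)` = m, Xp, tissuetumor = tissue)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient methylation design; check the pairing structure")
  }
  structure(list(X = X, coef = "tissuetumor", samples = sheet$sample_id,
                 df_residual = 2 * n - ncol(X)),
            class = "MethDesign")
}

#' Expand a MethCountMatrix into observation columns
#'
#' Produces the 2N-column count matrix aligned with the rows of
#' [build_meth_design()]: for each sample, one methylated-count column
#' followed by one unmethylated-count column.
#'
#' @param x a `MethCountMatrix`.
#' @param samples sample order (default: the matrix's order).
#' @return integer matrix, CpGs x 2N observations.
#' @export
expand_meth_counts <- function(x, samples = x$samples) {
  stopifnot(inherits(x, "MethCountMatrix"))
  j <- match(samples, x$samples)
  if (anyNA(j)) stop("unknown sample id(s)")
  n <- length(j)
  out <- matrix(0L, nrow(x$sites), 2 * n)
  out[, seq(1, 2 * n, by = 2)] <- x$meth[, j, drop = FALSE]
  out[, seq(2, 2 * n, by = 2)] <- x$total[, j, drop = FALSE] - x$meth[, j, drop = FALSE]
  colnames(out) <- paste(rep(samples, each = 2), c("meth", "unmeth"), sep = ".")
  out
}

#' Ordinary least-squares fit per CpG
#'
#' Fits every CpG's log2CPM observation vector against the expanded design
#' and extracts the tested (tissue) coefficient.
#'
#' @param y numeric matrix, CpGs x observations, columns aligned with the
#'   design rows.
#' @param design a `MethDesign`.
#' @return list with per-CpG `beta` (tested coefficient), `s2` (residual
#'   variance RSS/df), `df` (residual degrees of freedom), and scalar
#'   `v` (unscaled variance of the tested coefficient).
#' @export
fit_per_cpg <- function(y, design) {
  stopifnot(inherits(design, "MethDesign"))
  y <- as.matrix(y)
  X <- design$X
  if (ncol(y) != nrow(X)) stop("observation columns must align with design rows")
  d <- nrow(X) - qr(X)$rank
  if (d <= 0) stop("non-positive residual df; more samples are required")
  qx <- qr(X)
  B <- qr.coef(qx, t(y))
  res <- t(y) - X %*% B
  s2 <- colSums(res^2) / d
  xtxi <- chol2inv(chol(crossprod(X)))
  j <- match(design$coef, colnames(X))
  list(beta = unname(B[j, ]), s2 = unname(s2),
       df = rep(d, ncol(B)), v = xtxi[j, j])
}

# Newton solve of trigamma(y) = x, vectorised, monotone convergent.
trigamma_inverse <- function(x) {
  out <- x
  big <- x > 1e7
  out[big] <- 1 / sqrt(x[big])
  small <- x < 1e-6
  out[small] <- 1 / x[small]
  mid <- !big & !small
  if (any(mid)) {
    y <- 0.5 + 1 / x[mid]
    for (i in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / x[mid]) / psigamma(y, deriv = 2)
      y <- y + dif
      if (max(-dif / y) < 1e-8) break
    }
    out[mid] <- y
  }
  out
}

#' Empirical-Bayes moderation of per-CpG variances
#'
#' Fits a scaled-F hyperprior to the per-CpG residual variances by moment
#' matching on the log scale: with `e_g = log s_g^2 - digamma(d_g/2) +
#' log(d_g/2)`, the prior df `d0` solves `trigamma(d0/2) =
#' var(e) - mean(trigamma(d_g/2))` (infinite when the right-hand side is
#' non-positive) and the prior variance is `s0^2 = exp(mean(e) +
#' digamma(d0/2) - log(d0/2))` (the plain mean of the variances when `d0`
#' is infinite). Posterior variances shrink towards the prior:
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)`; the moderated t statistic is
#' `beta / sqrt(s~^2 v)` on `d0 + d` degrees of freedom.
#'
#' @param s2 per-CpG residual variances.
#' @param df per-CpG residual degrees of freedom (scalar or vector).
#' @param beta per-CpG tested coefficients (optional; needed for t and p).
#' @param v unscaled variance of the tested coefficient.
#' @param winsor optional two-sided winsorization fraction applied to the
#'   log-variance residuals before moment matching (default 0 = off), a
#'   simple guard against variance outliers.
#' @return list with `df_prior`, `s2_prior`, `s2_post`, and (when `beta`
#'   is supplied) `t` and two-sided `p`.
#' @export
ebayes_moderate <- function(s2, df, beta = NULL, v = NULL, winsor = 0) {
  stopifnot(length(s2) >= 1, winsor >= 0, winsor < 0.5)
  df <- rep_len(df, length(s2))
  if (all(s2 == 0)) stop("all residual variances are zero; cannot moderate")
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 10) stop("need at least 10 CpGs with positive residual variance")
  e <- log(s2[ok]) - digamma(df[ok] / 2) + log(df[ok] / 2)
  if (winsor > 0) {
    q <- stats::quantile(e, c(winsor, 1 - winsor))
    e <- clamp(e, q[1], q[2])
  }
  n <- length(e)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (n - 1)
  rhs <- evar - mean(trigamma(df[ok] / 2))
  if (rhs > 0) {
    df_prior <- 2 * trigamma_inverse(rhs)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- mean(s2[ok])
  }
  s2_post <- if (is.infinite(df_prior)) {
    rep(s2_prior, length(s2))
  } else {
    (df_prior * s2_prior + df * s2) / (df_prior + df)
  }
  out <- list(df_prior = df_prior, s2_prior = s2_prior, s2_post = s2_post)
  if (!is.null(beta)) {
    stopifnot(!is.null(v))
    out$t <- beta / sqrt(s2_post * v)
    out$p <- 2 * stats::pt(-abs(out$t), df = df_prior + df)
  }
  out
}

#' Simes combination of per-CpG p-values for one region
#'
#' `p_region = min_i (m * p_(i) / i)` over the sorted p-values, capped at 1.
#' Valid under positive dependence of the member tests.
#'
#' @param p vector of p-values in [0, 1] (length >= 1).
#' @return a single combined p-value.
#' @export
simes_aggregate <- function(p) {
  if (length(p) == 0) stop("cannot aggregate an empty p-value vector")
  stopifnot(all(p >= 0), all(p <= 1))
  m <- length(p)
  min(1, min(m * sort(p) / seq_len(m)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, `q_(i) = min(1, min_{j >= i} m p_(j) / j)`,
#' mapped back to input order (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values in [0, 1].
#' @return vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0, na.rm = TRUE), all(p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Differential methylation test: per CpG and per region
#'
#' Runs the full testing stage on a count matrix: expanded two-level
#' design, log2CPM transform, per-CpG OLS, empirical-Bayes moderation,
#' per-CpG BH adjustment, then Simes aggregation of the member CpG
#' p-values per region and BH across regions. Per-region summaries include
#' the mean log-fold-change of member CpGs and the pooled tumor-minus-NM
#' methylation-level difference.
#'
#' @param counts a `MethCountMatrix` (already coverage-filtered).
#' @param sheet the matching `SampleSheet`; the test uses exactly these
#'   samples.
#' @param regions a `RegionSet` for the per-region summaries (optional).
#' @param prior log2CPM pseudo-count.
#' @param winsor passed to [ebayes_moderate()].
#' @return a `DMResult` list: `cpg` (chrom, pos, strand, beta, s2, df,
#'   s2_post, t, p, p_adj), `region` (region_id, n_cpgs, mean_lfc, delta,
#'   simes_p, q), `df_prior`, `s2_prior`, `design`.
#' @export
dm_test <- function(counts, sheet, regions = NULL, prior = 0.5, winsor = 0) {
  sheet <- as_sample_sheet(sheet)
  counts <- subset_counts(counts, samples = sheet$sample_id)
  design <- build_meth_design(sheet)
  # both observation columns of a sample share the sample's total library,
  # so per-sample normalisation is absorbed by the sample-indicator columns
  # and composition shifts in the methylated fraction cannot masquerade as
  # tissue effects
  lib <- rep(colSums(counts$total[, design$samples, drop = FALSE]), each = 2)
  y <- log2cpm(expand_meth_counts(counts, design$samples), prior = prior,
               lib = lib)
  fit <- fit_per_cpg(y, design)
  mod <- ebayes_moderate(fit$s2, fit$df, beta = fit$beta, v = fit$v,
                         winsor = winsor)
  cpg <- data.frame(counts$sites,
                    beta = fit$beta, s2 = fit$s2, df = fit$df,
                    s2_post = mod$s2_post, t = mod$t, p = mod$p,
                    p_adj = bh_adjust(mod$p))
  out <- list(cpg = cpg, df_prior = mod$df_prior, s2_prior = mod$s2_prior,
              design = design)
  if (!is.null(regions)) {
    regions <- as_region_set(regions)
    hits <- GenomicRanges::findOverlaps(sites_to_granges(counts$sites),
                                        regions_to_granges(regions))
    si <- S4Vectors::queryHits(hits)
    ri <- S4Vectors::subjectHits(hits)
    simes_p <- rep(NA_real_, nrow(regions))
    n_cpgs <- integer(nrow(regions))
    mean_lfc <- rep(NA_real_, nrow(regions))
    members <- split(si, ri)
    for (nm in names(members)) {
      r <- as.integer(nm)
      idx <- members[[nm]]
      simes_p[r] <- simes_aggregate(cpg$p[idx])
      n_cpgs[r] <- length(idx)
      mean_lfc[r] <- mean(cpg$beta[idx])
    }
    # pooled per-tissue levels: sum counts over samples of each tissue
    pool <- function(tissue) {
      j <- which(sheet$tissue == tissue)
      msum <- rep(0, nrow(regions)); tsum <- rep(0, nrow(regions))
      if (length(si)) {
        ms <- rowsum(rowSums(counts$meth[si, j, drop = FALSE]), ri)
        ts <- rowsum(rowSums(counts$total[si, j, drop = FALSE]), ri)
        rows <- as.integer(rownames(ms))
        msum[rows] <- ms[, 1]
        tsum[rows] <- ts[, 1]
      }
      ifelse(tsum > 0, msum / tsum, NA_real_)
    }
    delta <- pool("tumor") - pool("NM")
    region_tab <- data.frame(region_id = regions$region_id,
                             truth_class = regions$truth_class,
                             n_cpgs = n_cpgs, mean_lfc = mean_lfc,
                             delta = delta, simes_p = simes_p)
    region_tab$q <- NA_real_
    tested <- !is.na(region_tab$simes_p)
    region_tab$q[tested] <- bh_adjust(region_tab$simes_p[tested])
    out$region <- region_tab
  }
  class(out) <- "DMResult"
  out
}

#' @export
print.DMResult <- function(x, ...) {
  cat(sprintf("DMResult: %d CpGs tested (prior df %.3g, prior variance %.3g)\n",
              nrow(x$cpg), x$df_prior, x$s2_prior))
  if (!is.null(x$region)) {
    cat(sprintf("  %d regions summarised; %d with q < 0.05\n",
                nrow(x$region), sum(x$region$q < 0.05, na.rm = TRUE)))
  }
  invisible(x)
}
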