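test_that("expanded design has the documented shape and zero unmethylated rows", {
  d <- build_meth_design(toy_sheet(2))
  expect_equal(dim(d$X), c(8L, 7L))   # 4 sample cols + intercept + 1 patient + tissue
  # unmethylated rows (even rows) carry no treatment columns
  treat <- d$X[, 5:7]
  expect_true(all(treat[seq(2, 8, by = 2), ] == 0))
  # each sample column has exactly two 1s
  expect_true(all(colSums(d$X[, 1:4]) == 2))
  # residual df = 2N - (N + P + 1)
  expect_equal(d$df_residual, 8L - 7L)
  d35 <- build_meth_design(toy_sheet(35))
  expect_equal(d35$df_residual, 2 * 70 - (70 + 35 + 1))  # 34
})

test_that("expanded design matches edgeR's two-level construction", {
  skip_if_not_installed("edgeR")
  sheet <- as_sample_sheet(toy_sheet(4))
  d <- build_meth_design(sheet)
  mm <- stats::model.matrix(~ patient_id + tissue, data = sheet)
  ref <- edgeR::modelMatrixMeth(mm)
  expect_equal(unname(d$X), unname(ref))
})

test_that("per-CpG OLS recovers exact and random effects", {
  sheet <- toy_sheet(4)
  d <- build_meth_design(sheet)
  n_obs <- nrow(d$X)
  # no effect: identical response on tumor and NM methylated rows
  y0 <- matrix(rep(5, n_obs), nrow = 1)
  f0 <- fit_per_cpg(y0, d)
  expect_equal(f0$beta, 0)
  # planted tissue effect +2, zero noise -> exact interpolation
  y2 <- matrix(as.vector(d$X %*% c(rep(1, 8), 0.5, 0, 0, 0, 2)), nrow = 1)
  f2 <- fit_per_cpg(y2, d)
  expect_equal(f2$beta, 2)
  expect_equal(f2$s2, 0)
  # random responses match a brute-force normal-equations solve
  set.seed(1)
  y <- matrix(rnorm(3 * n_obs), nrow = 3)
  f <- fit_per_cpg(y, d)
  for (g in 1:3) {
    b <- solve(crossprod(d$X), crossprod(d$X, y[g, ]))
    expect_equal(f$beta[g], unname(b[nrow(b), 1]), tolerance = 1e-8)
    res <- y[g, ] - d$X %*% b
    expect_equal(f$s2[g], sum(res^2) / f$df[g], tolerance = 1e-8)
  }
})

test_that("a patient missing one tissue is rejected as rank-deficient", {
  sheet <- toy_sheet(3)
  sheet$tissue[2] <- "NM"  # patient P01 now has two NM samples
  expect_error(build_meth_design(sheet), "pairing|rank")
})

test_that("variance moderation shrinks towards the prior and handles the limits", {
  # all variances identical -> infinite prior df and s~2 = s2
  m <- ebayes_moderate(rep(2, 50), df = 10, beta = rep(1, 50), v = 0.5)
  expect_identical(m$df_prior, Inf)
  expect_equal(m$s2_post, rep(2, 50))
  # infinite prior df -> normal-tail p-values
  expect_equal(m$p, rep(2 * pnorm(-abs(1 / sqrt(2 * 0.5))), 50),
               tolerance = 1e-12)
  # posterior variance lies between the observed and the prior
  set.seed(7)
  s2 <- exp(rnorm(200, 0, 1))
  mm <- ebayes_moderate(s2, df = 8)
  expect_true(all(mm$s2_post >= pmin(s2, mm$s2_prior) - 1e-12))
  expect_true(all(mm$s2_post <= pmax(s2, mm$s2_prior) + 1e-12))
  expect_error(ebayes_moderate(rep(0, 20), df = 5), "zero")
})

test_that("moderation matches limma's squeezeVar and eBayes", {
  skip_if_not_installed("limma")
  set.seed(11)
  s2 <- rchisq(500, 6) / 6 * exp(rnorm(500, 0, 0.7))
  df <- 12
  mine <- ebayes_moderate(s2, df)
  ref <- limma::squeezeVar(s2, df)
  expect_equal(mine$df_prior, ref$df.prior, tolerance = 1e-8)
  expect_equal(mine$s2_prior, ref$var.prior, tolerance = 1e-8)
  expect_equal(mine$s2_post, ref$var.post, tolerance = 1e-8)
})

test_that("prior df is recovered from scaled-F simulated variances", {
  set.seed(3)
  d0 <- 4; d <- 34; s02 <- 2
  s2 <- s02 * (rchisq(5000, d) / d) / (rchisq(5000, d0) / d0)
  m <- ebayes_moderate(s2, d)
  expect_lt(abs(m$df_prior - d0) / d0, 0.25)
})

test_that("Simes aggregation follows the order-statistic formula", {
  expect_equal(simes_aggregate(0.03), 0.03)
  expect_equal(simes_aggregate(c(0.01, 0.02, 0.5)), 0.03)
  expect_equal(simes_aggregate(rep(0.2, 7)), 0.2)
  expect_equal(simes_aggregate(c(1, 1, 1)), 1)
  expect_error(simes_aggregate(numeric()), "empty")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
  }
})

test_that("dm_test separates planted biomarker regions from negative controls", {
  co <- small_cohort(seed = 31, n_patients = 12)
  counts <- filter_coverage(co$counts, 7)
  dm <- dm_test(counts, co$sheet, co$regions)
  reg <- dm$region
  expect_true(all(reg$q[reg$truth_class == "biomarker"] < 1e-4))
  expect_true(all(reg$q[reg$truth_class == "negative_control"] > 0.05))
  expect_true(all(reg$delta[reg$truth_class == "biomarker"] > 0.4))
  expect_true(all(reg$mean_lfc[reg$truth_class == "biomarker"] > 0))
  # per-CpG p-values are proper probabilities
  expect_true(all(dm$cpg$p >= 0 & dm$cpg$p <= 1))
})

test_that("moderated t approaches the ordinary t as the prior df vanishes", {
  set.seed(13)
  beta <- rnorm(50); s2 <- exp(rnorm(50)); df <- 10; v <- 0.4
  # d0 -> 0 limit: s2_post -> s2, so t -> beta / sqrt(s2 * v)
  s2_post <- (1e-9 * 1 + df * s2) / (1e-9 + df)
  t_mod <- beta / sqrt(s2_post * v)
  t_ord <- beta / sqrt(s2 * v)
  expect_equal(t_mod, t_ord, tolerance = 1e-8)
})
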