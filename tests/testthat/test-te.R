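test_that("median-of-ratios size factors behave and match DESeq2", {
  m <- matrix(rpois(400, 50), ncol = 2)
  expect_equal(size_factors(cbind(m[, 1], m[, 1])), c(1, 1))

  m2 <- cbind(m[, 1], 2L * m[, 1])
  sf <- size_factors(m2)
  expect_equal(sf[2] / sf[1], 2)
  expect_equal(exp(mean(log(sf))), 1)

  cx <- simulate_count_experiment(2000, 3, dispersion = 0.05,
                                  seed = 51, depth_sdlog = 0.2)
  sf_hat <- size_factors(cx$rna)
  truth <- cx$truth$depth[colnames(cx$rna)]
  truth <- truth / exp(mean(log(truth)))
  expect_equal(unname(sf_hat), unname(truth), tolerance = 0.05)

  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(cx$rna)
  expect_equal(unname(sf_hat / sf_hat[1]), unname(ref / ref[1]),
               tolerance = 1e-6)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "no gene")
})

test_that("NB LRT reduces to the brute-force Poisson LRT as dispersion -> 0", {
  set.seed(61)
  n <- 10
  counts <- matrix(rpois(n * 6, lambda = rep(c(40, 80), each = 3)),
                   nrow = n, byrow = TRUE)
  cond <- factor(rep(c("a", "b"), each = 3))
  full <- model.matrix(~cond)
  red <- full[, 1, drop = FALSE]
  sf <- rep(1, 6)
  res <- nb_lrt(counts, full, red, sf = sf,
                dispersions = rep(1e-8, n))
  # independent oracle: per-gene Poisson GLM deviance difference
  for (g in seq_len(n)) {
    y <- counts[g, ]
    f1 <- stats::glm(y ~ cond, family = stats::poisson())
    f0 <- stats::glm(y ~ 1, family = stats::poisson())
    expect_equal(res$stat[g], f0$deviance - f1$deviance, tolerance = 1e-3)
    expect_equal(res$p[g],
                 pchisq(f0$deviance - f1$deviance, 1, lower.tail = FALSE),
                 tolerance = 1e-3)
  }
  expect_true(all(res$df == 1))
  expect_error(nb_lrt(counts, red, full, sf = sf), "not nested")
})

test_that("NB LRT recovers simulated expression effects", {
  cx <- simulate_count_experiment(1000, 3, dispersion = 0.01,
                                  rna_effect = c(rep(2, 100), rep(0, 900)),
                                  seed = 63, depth_sdlog = 0)
  de <- differential_expression(cx$rna, cx$condition)
  err <- de$log2fc[1:100] - 2
  expect_lt(abs(mean(err)), 0.08)
  expect_lt(stats::median(abs(err)), 0.2)
  expect_gte(sum(de$call[1:100] == "up"), 95)
  # BH monotonicity: padj non-decreasing in p rank
  ord <- order(de$p)
  expect_true(all(diff(de$padj[ord]) >= -1e-12))
  # linear-scale threshold: nothing below |FC| 1.5 is ever called
  called <- de$call != "ns"
  expect_true(all(abs(de$log2fc[called]) >= log2(1.5)))
})

test_that("all-null differential expression controls false calls", {
  cx <- simulate_count_experiment(1000, 3, dispersion = 0.05, seed = 64)
  de <- differential_expression(cx$rna, cx$condition)
  expect_lte(sum(de$call != "ns"), 0.05 * 1000)
  expect_error(differential_expression(cx$rna[, 1:3],
                                       cx$condition[1:3]), "two conditions")
})

test_that("TE is the ratio of normalized means with flagged undefined genes", {
  m <- matrix(rpois(600, 100), ncol = 6,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  cond <- factor(rep(c("WT", "mutant"), each = 3),
                 levels = c("WT", "mutant"))
  te <- compute_te(m, m, cond)      # RPF = RNA -> TE 1 everywhere
  expect_equal(te$te_WT, rep(1, 100))
  expect_equal(te$te_mutant, rep(1, 100))

  m0 <- m; m0[1, ] <- 0L            # zero RNA -> TE undefined, flagged
  te0 <- compute_te(m, m0, cond)
  expect_true(is.na(te0$te_WT[1]))

  # per-gene TE halving is read off against the unaffected background
  eff <- c(rep(-1, 50), rep(0, 450))
  cx <- simulate_count_experiment(500, 3, dispersion = 0.05,
                                  te_effect = eff, seed = 65)
  tec <- compute_te(cx$rpf, cx$rna, cx$condition)
  lr <- log(tec$te_mutant / tec$te_WT)
  contrast <- exp(mean(lr[1:50], na.rm = TRUE) -
                    mean(lr[51:500], na.rm = TRUE))
  expect_equal(contrast, 0.5, tolerance = 0.1)
})

test_that("TE eCDF comparison detects shifts and respects flags", {
  set.seed(71)
  te_wt <- rlnorm(1000)
  ec <- te_ecdf(te_wt, te_wt)
  expect_equal(ec$D, 0)
  # halving TE shifts the log2 eCDF left by exactly 1
  ec2 <- te_ecdf(te_wt, te_wt * 0.5)
  grid <- seq(-2, 2, by = 0.1)
  expect_equal(ec2$ecdf_b(grid - 1), ec2$ecdf_a(grid))
  # undefined TE never enters the eCDF
  ec3 <- te_ecdf(c(te_wt, NA, 0), c(te_wt * 0.5, 1, 1))
  expect_equal(environment(ec3$ecdf_a)$nobs, 1000)
  expect_error(te_ecdf(rlnorm(10), rlnorm(10)), ">= 50 genes")

  # a global 30% TE reduction is detected by the KS test at 1,000 genes
  set.seed(70)
  te_base <- rlnorm(1000, sdlog = 0.4)
  te_mut2 <- te_base * 0.7 * rlnorm(1000, sdlog = 0.15)
  ks <- te_ecdf(te_base, te_mut2)
  expect_lt(ks$p, 0.01)
  # and the mutant curve is left-shifted (stochastically dominated)
  grid <- seq(-1.5, 1.5, by = 0.25)
  expect_true(all(ks$ecdf_b(grid) >= ks$ecdf_a(grid)))
})

test_that("nine-quadrant classes follow the legend and exhaust all genes", {
  # the 3x3 legend mapping, fold-change axes only
  cases <- expand.grid(m = c(-1, 0, 1), r = c(-1, 0, 1))
  got <- nine_quadrant(cases$m, cases$r, fc_threshold = 1.5)
  want <- c("S1", "S2", "S3",   # RPF up   : mRNA down/unch/up
            "S4", "S5", "S6",   # RPF unch
            "S7", "S8", "S9")   # RPF down
  key <- paste(cases$m, cases$r)
  map <- setNames(as.character(got), key)
  expect_equal(unname(map[c("-1 1", "0 1", "1 1",
                            "-1 0", "0 0", "1 0",
                            "-1 -1", "0 -1", "1 -1")]), want)
  # boundary |FC| exactly 1.5 counts as changed
  expect_equal(as.character(nine_quadrant(log2(1.5), 0)), "S6")
  expect_equal(as.character(nine_quadrant(-log2(1.5), 0)), "S4")
  expect_true(is.na(nine_quadrant(NA, 0)))
  # totality on simulated data
  set.seed(73)
  cls <- nine_quadrant(rnorm(500), rnorm(500))
  expect_equal(sum(table(cls)), 500)
})

test_that("differential TE is calibrated under the null and finds DTEGs", {
  cx <- simulate_count_experiment(800, 3, dispersion = 0.05,
                                  te_effect = 0, seed = 81)
  res <- differential_te(cx$rpf, cx$rna, cx$condition)
  t1 <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(t1, 0.02); expect_lt(t1, 0.09)
  # interaction identity: log2FC_TE = log2FC_RPF - log2FC_mRNA exactly
  ok <- !is.na(res$log2fc_te)
  expect_equal(res$log2fc_te[ok],
               (res$log2fc_rpf - res$log2fc_mrna)[ok], tolerance = 1e-9)
  # equal RNA and RPF shifts are never DTEGs
  cx2 <- simulate_count_experiment(300, 3, dispersion = 0.05,
                                   te_effect = 0, rna_effect = 2,
                                   seed = 82)
  res2 <- differential_te(cx2$rpf, cx2$rna, cx2$condition)
  expect_equal(mean(res2$log2fc_te, na.rm = TRUE), 0, tolerance = 0.05)
  expect_lte(sum(res2$dteg), 0.05 * 300)
  expect_error(differential_te(cx$rpf[, 1:3], cx$rna[, 1:3],
                               cx$condition[1:3]), "two conditions")
})
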