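test_that("rank normalization orders genes in the requested direction", {
  expect_equal(normalize_ranks(c(3, 1, 2), "descending"),
               c(1 / 3, 1, 2 / 3))
  expect_equal(normalize_ranks(c(3, 1, 2), "ascending"),
               c(1, 1 / 3, 2 / 3))
  expect_equal(normalize_ranks(rep(2, 4)), rep(0.625, 4))  # avg rank 2.5 / 4
  expect_equal(normalize_ranks(5), 1)
  expect_error(normalize_ranks(numeric(0)), "empty")
  expect_error(normalize_ranks(c(1, Inf)), "finite")
})

test_that("RRA rho matches closed-form Beta order-statistic probabilities", {
  expect_equal(rra_rho(0.3)$rho, 0.3)  # Beta(1,1) CDF is the identity
  # closed forms: P(Beta(1,3)<=x) = 1-(1-x)^3; P(Beta(2,2)<=x) = 3x^2-2x^3;
  # P(Beta(3,1)<=x) = x^3
  r <- c(0.1, 0.2, 0.9)
  expected <- min(1 - (1 - 0.1)^3, 3 * 0.2^2 - 2 * 0.2^3, 0.9^3)
  expect_equal(rra_rho(r)$rho, expected, tolerance = 1e-12)
  expect_equal(rra_rho(r)$rho, 0.104, tolerance = 1e-3)
  expect_equal(rra_rho(rep(1, 5))$rho, 1)
  expect_equal(rra_rho(r, n_genes = 1000)$corrected_p,
               min(1, expected * 1000))
  expect_error(rra_rho(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("improving any rank never increases rho", {
  set.seed(61)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    r <- runif(k)
    j <- sample(k, 1)
    better <- r
    better[j] <- runif(1, 0, r[j])
    expect_lte(rra_rho(better)$rho, rra_rho(r)$rho + 1e-12)
  }
})

test_that("RRA corrected p-values are conservative under the null", {
  set.seed(71)
  n_genes <- 2000
  rho <- replicate(n_genes, rra_rho(runif(6))$rho)
  corrected <- pmin(1, rho * n_genes)
  rate <- mean(corrected < 0.05)
  mc_err <- sqrt(0.05 * 0.95 / n_genes)
  expect_lte(rate, 0.05 + 2 * mc_err)
})

test_that("DerSimonian-Laird pooling reproduces hand calculations", {
  r <- pool_fold_changes(c(0.5, 0.7), c(0.04, 0.04))
  expect_equal(r$tau2, 0)            # Q = 0.5 < df
  expect_equal(r$meta_lfc, 0.6)
  expect_equal(r$pooled_var, 0.02)

  r2 <- pool_fold_changes(c(0, 1), c(0.04, 0.04))
  expect_equal(r2$q, 12.5)
  expect_equal(r2$tau2, 0.46)        # (12.5 - 1) / 25
  expect_equal(r2$meta_lfc, 0.5)

  r3 <- pool_fold_changes(0.8, 0.1)  # single-study reduction
  expect_equal(r3$meta_lfc, 0.8)
  expect_equal(r3$tau2, 0)
  expect_equal(r3$pooled_var, 0.1)

  expect_error(pool_fold_changes(numeric(0), numeric(0)), "at least one")
  expect_error(pool_fold_changes(c(1, 2), c(0.1, 0)), "positive")
})

test_that("DL pooling agrees with metafor's implementation", {
  skip_if_not_installed("metafor")
  set.seed(81)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    y <- rnorm(k, 0.4, 0.5)
    v <- runif(k, 0.01, 0.3)
    ours <- pool_fold_changes(y, v)
    ref <- metafor::rma(yi = y, vi = v, method = "DL")
    expect_equal(ours$meta_lfc, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
  }
})

test_that("fixed-effect reduction: zero heterogeneity equals inverse-variance mean", {
  set.seed(91)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    y <- rnorm(k, 0.3, 0.02)  # tight effects keep Q below its df
    v <- runif(k, 0.05, 0.4)
    r <- pool_fold_changes(y, v)
    if (r$tau2 == 0) {
      expect_equal(r$meta_lfc, sum(y / v) / sum(1 / v), tolerance = 1e-12)
    }
  }
})

test_that("Fisher's combined probability matches the chi-square closed form", {
  r <- fisher_combined(c(1, 1, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$combined_p, 1)

  r2 <- fisher_combined(c(0.05, 0.05))
  expect_equal(r2$statistic, -4 * log(0.05), tolerance = 1e-10)
  expect_equal(r2$statistic, 11.9829, tolerance = 1e-4)
  expect_equal(r2$df, 4)
  # chi-square_4 survival has closed form exp(-x/2) (1 + x/2)
  x <- r2$statistic
  expect_equal(r2$combined_p, exp(-x / 2) * (1 + x / 2), tolerance = 1e-12)
  expect_equal(r2$combined_p, 0.01748, tolerance = 1e-3)

  expect_equal(fisher_combined(0.2)$combined_p, 0.2, tolerance = 1e-12)
  expect_error(fisher_combined(c(0.5, 0)), "\\(0, 1\\]")

  # combining m identical p-values is increasing in p
  ps <- seq(0.01, 0.99, length.out = 20)
  combined <- vapply(ps, function(p) fisher_combined(rep(p, 4))$combined_p, 0)
  expect_true(all(diff(combined) > 0))
})

test_that("candidate filtering applies the fold and p rules strictly", {
  empty <- filter_candidates(data.frame(gene = character(),
                                        n_studies_present = integer(),
                                        meta_lfc = numeric(),
                                        fisher_p = numeric()))
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)

  meta <- data.frame(gene = c("a", "b", "c", "d"),
                     n_studies_present = c(6, 6, 6, 5),
                     meta_lfc = c(log2(1.19), log2(1.2), -log2(1.5),
                                  log2(2)),
                     fisher_p = c(0.001, 0.001, 0.001, 0.001))
  got <- filter_candidates(meta, n_studies_total = 6)
  expect_equal(got$up, "b")      # 1.19-fold excluded, boundary 1.2 kept
  expect_equal(got$down, "c")    # d excluded: absent from one study
})

test_that("meta-analysis recovers planted genes from synthetic studies", {
  md <- generate_meta_studies(meta_study_spec(n_studies = 6, n_genes = 500,
                                              n_per_group = 20,
                                              de_fraction = 0.1,
                                              planted_lfc = 1,
                                              heterogeneity_sd = 0.2,
                                              seed = 17L))
  meta <- meta_analyze(md$studies)
  cand <- filter_candidates(meta)
  hits <- c(cand$up, cand$down)
  planted <- names(which(md$de_mask))
  recall <- mean(planted %in% hits)
  fpr <- mean(setdiff(meta$gene, planted) %in% hits)
  expect_gte(recall, 0.8)
  expect_lte(fpr, 0.05)
  # direction consistent with the pooled fold change
  expect_true(all((meta$meta_lfc >= 0) == (meta$direction == "up")))
  # rho scores of planted genes dominate nulls on average
  null_rho <- meta$rra_rho[!md$de_mask[meta$gene]]
  planted_rho <- meta$rra_rho[md$de_mask[meta$gene]]
  expect_gt(mean(planted_rho < stats::quantile(null_rho, 0.1)), 0.5)
})
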