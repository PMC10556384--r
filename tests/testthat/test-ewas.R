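test_that("beta to M transform and clipping", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(1, eps = 1e-6), log2((1 - 1e-6) / 1e-6))
  expect_error(beta_to_m(0.5, eps = 0.7))
})

test_that("site models equal a textbook OLS oracle probe by probe", {
  set.seed(6)
  n <- 24
  sheet <- data.frame(sample_id = sprintf("S%02d", 1:n),
                      group = rep(c("case", "control"), each = n / 2),
                      age = runif(n, 10, 40))
  design <- ewas_design(sheet, "age")
  beta <- matrix(runif(50 * n, 0.05, 0.95), 50, n,
                 dimnames = list(sprintf("cg%02d", 1:50), sheet$sample_id))
  beta[3, 5] <- NA  # exercise the incomplete-row path
  res <- fit_site_models(beta, design)
  m <- beta_to_m(beta)
  for (i in c(1, 3, 17, 50)) {
    ok <- !is.na(m[i, ])
    fit <- lm(m[i, ok] ~ design[ok, -1])
    sm <- summary(fit)$coefficients
    expect_equal(res$effect[i], unname(sm["design[ok, -1]group", 1]),
                 tolerance = 1e-10)
    expect_equal(res$se[i], unname(sm["design[ok, -1]group", 2]),
                 tolerance = 1e-10)
    expect_equal(res$t_stat[i], unname(sm["design[ok, -1]group", 3]),
                 tolerance = 1e-10)
    expect_equal(res$p_raw[i], unname(sm["design[ok, -1]group", 4]),
                 tolerance = 1e-10)
  }
  expect_equal(res$n_used[3], n - 1)
})

test_that("with no covariates the group t equals the pooled two-sample t", {
  set.seed(12)
  n <- 20
  sheet <- data.frame(sample_id = sprintf("S%d", 1:n),
                      group = rep(c("case", "control"), each = n / 2))
  design <- ewas_design(sheet)
  beta <- matrix(runif(5 * n, 0.2, 0.8), 5, n)
  res <- fit_site_models(beta, design)
  m <- beta_to_m(beta)
  for (i in 1:5) {
    tt <- t.test(m[i, 1:10], m[i, 11:20], var.equal = TRUE)
    expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p_raw[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("null cohorts give nominal type-I error at alpha = 0.05", {
  cfg <- sim_config(n_probes = 2000, n_cases = 30, n_controls = 30,
                    dmp_fraction = 0, sem_rate_control = 0,
                    epivar_per_case = 0, deletion_runs = 0,
                    batch_shift_sd = 0, seed = 33)
  co <- generate_cohort(cfg)
  design <- ewas_design(co$sheet, "age")
  res <- fit_site_models(co$beta, design)
  frac <- mean(res$p_raw < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("strong injected group effects are recovered by p-value rank", {
  cfg <- sim_config(n_probes = 2000, n_cases = 30, n_controls = 30,
                    dmp_fraction = 0.02, dmp_effect = 0.15,
                    sem_rate_control = 0, epivar_per_case = 0,
                    deletion_runs = 0, seed = 41)
  co <- generate_cohort(cfg)
  res <- fit_site_models(co$beta, ewas_design(co$sheet, "age"))
  n_dmp <- length(co$truth$dmp_probe_ids)
  top <- res$probe_id[order(res$p_raw)][seq_len(n_dmp)]
  expect_gte(mean(co$truth$dmp_probe_ids %in% top), 0.9)
})

test_that("results are invariant to a joint permutation of samples", {
  set.seed(14)
  n <- 16
  sheet <- data.frame(sample_id = sprintf("S%d", 1:n),
                      group = sample(rep(c("case", "control"), each = n / 2)),
                      age = runif(n, 5, 50))
  design <- ewas_design(sheet, "age")
  beta <- matrix(runif(30 * n, 0.1, 0.9), 30, n)
  perm <- sample(n)
  r1 <- fit_site_models(beta, design)
  r2 <- fit_site_models(beta[, perm], design[perm, ])
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("rank-deficient designs fail naming the collinear column", {
  sheet <- data.frame(sample_id = sprintf("S%d", 1:10),
                      group = rep(c("case", "control"), 5),
                      dup = rep(c(1, 0), 5))
  design <- ewas_design(sheet, "dup")  # dup duplicates the group column
  beta <- matrix(runif(30), 3, 10)
  expect_error(fit_site_models(beta, design), "dup")
})

test_that("moderated variances shrink toward the pooled value", {
  set.seed(15)
  n <- 12
  sheet <- data.frame(sample_id = sprintf("S%d", 1:n),
                      group = rep(c("case", "control"), each = n / 2))
  design <- ewas_design(sheet)
  beta <- matrix(runif(100 * n, 0.1, 0.9), 100, n)
  plain <- fit_site_models(beta, design, moderate = FALSE)
  mod <- fit_site_models(beta, design, moderate = TRUE)
  expect_equal(mod$effect, plain$effect)  # coefficients untouched
  # shrinkage pulls each residual variance toward the pooled value: the
  # smallest-variance probe gains SE, the largest-variance probe loses SE
  i_lo <- which.min(plain$se)
  i_hi <- which.max(plain$se)
  expect_gt(mod$se[i_lo], plain$se[i_lo])
  expect_lt(mod$se[i_hi], plain$se[i_hi])
})

test_that("region combination follows the signed Stouffer rule", {
  site <- data.frame(probe_id = c("a", "b", "c", "d"),
                     effect = c(1, 1, 1, -1),
                     p_raw = c(0.01, 0.05, 0.05, 0.05))
  ann <- data.frame(probe_id = c("a", "b", "c", "d"),
                    chrom = "chr1", pos = 1:4,
                    gene = c("G1", "G2", "G2", "G3"))
  res <- fit_region_models(site, ann)
  expect_equal(res$p[res$region == "G1"], 0.01, tolerance = 1e-12)
  z <- qnorm(1 - 0.05 / 2)
  expect_equal(res$z[res$region == "G2"], 2 * z / sqrt(2), tolerance = 1e-12)
  expect_equal(res$p[res$region == "G2"], 2 * pnorm(-2 * z / sqrt(2)),
               tolerance = 1e-12)
  # opposite equal Z cancels
  res2 <- fit_region_models(site, ann, region_map = list(R = c("c", "d")))
  expect_equal(res2$z, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-12)
  expect_warning(fit_region_models(site, ann, region_map = list(E = "zz")),
                 "no analyzed probes")
})

test_that("BH and Bonferroni adjustments match hand and oracle computations", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.04, "bh"), 0.04)
  expect_equal(adjust_pvalues(0.04, "bonferroni"), 0.04)
  expect_equal(adjust_pvalues(c(0.5, 0.5), "bonferroni"), c(1, 1))
  expect_error(adjust_pvalues(c(0.2, 1.3), "bh"), "0,1")
  set.seed(16)
  for (len in c(1, 2, 5, 8, 12)) {
    p <- round(runif(len), 3)
    expect_equal(adjust_pvalues(p, "bh"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("volcano data pairs delta-beta with -log10 p", {
  set.seed(18)
  beta <- matrix(runif(40, 0.3, 0.7), 4, 10,
                 dimnames = list(sprintf("cg%d", 1:4), sprintf("S%d", 1:10)))
  group <- rep(c("case", "control"), each = 5)
  site <- fit_site_models(beta, ewas_design(data.frame(
    sample_id = colnames(beta), group = group)))
  v <- volcano_data(beta, group, site)
  expect_equal(v$delta_beta,
               unname(rowMeans(beta[, 1:5]) - rowMeans(beta[, 6:10])))
  expect_equal(v$neg_log10_p, -log10(site$p_raw))
})
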