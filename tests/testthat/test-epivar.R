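test_that("window p-values match enumeration and hand-counted cases", {
  expect_equal(window_pvalue(10, 5, 5, 0), 1)
  expect_equal(window_pvalue(10, 5, 5, 5), 1 / choose(10, 5), tolerance = 1e-15)
  expect_equal(window_pvalue(1000, 10, 11, 3), oracle_hyper_tail(1000, 10, 11, 3),
               tolerance = 1e-12)
  set.seed(46)
  for (rep in 1:30) {
    N <- sample(5:200, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(window_pvalue(N, K, n, k), oracle_hyper_tail(N, K, n, k),
                 tolerance = 1e-12)
  }
  expect_error(window_pvalue(10, 11, 5, 2), "K <= N")
  expect_error(window_pvalue(10, 5, 5, 6), "min\\(n, K\\)")
})

test_that("window p-values are monotone non-increasing in k", {
  for (N in c(20, 57)) for (K in c(3, 9)) for (n in c(5, 11)) {
    ks <- 0:min(n, K)
    p <- window_pvalue(rep(N, length(ks)), K, n, ks)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("the scan enumerates single-site-sliding windows per chromosome", {
  ann <- tiny_annotation(20, nchr = 1)
  cs0 <- fake_callset("s1", character(0), character(0), 20, ann)
  t0 <- scan_sample(cs0, ann, n_window = 11)
  expect_equal(nrow(t0), 0)
  expect_equal(attr(t0, "n_windows_total"), 10)  # L - n + 1
  cs1 <- fake_callset("s1", ann$probe_id[c(3, 15)], c("hyper", "hyper"), 20, ann)
  t1 <- scan_sample(cs1, ann, n_window = 11)
  # window count per SEM position, k computed by brute force
  for (i in seq_len(nrow(t1))) {
    probes <- t1$start_index[i]:t1$end_index[i]
    expect_equal(t1$k_sem[i], sum(c(3, 15) %in% probes))
    expect_equal(t1$p_hyper[i],
                 oracle_hyper_tail(20, 2, 11, t1$k_sem[i]), tolerance = 1e-12)
  }
  expect_true(all(t1$k_sem >= 1))
  # short chromosomes are skipped with a warning
  ann2 <- tiny_annotation(20, nchr = 1)
  ann2$chrom[14:20] <- "chr2"  # 13 + 7 probes
  cs2 <- fake_callset("s1", ann2$probe_id[1], "hyper", 20, ann2)
  expect_warning(t2 <- scan_sample(cs2, ann2, n_window = 11), "fewer than")
  expect_equal(attr(t2, "n_windows_total"), 3)  # 13 - 11 + 1
})

test_that("a full-window SEM run attains the minimal attainable p", {
  ann <- tiny_annotation(60, nchr = 1)
  hit <- ann$probe_id[20:30]
  cs <- fake_callset("s1", c(hit, ann$probe_id[50]), rep("hyper", 12), 60, ann)
  tests <- scan_sample(cs, ann, n_window = 11)
  best <- min(tests$p_hyper)
  expect_equal(best, window_pvalue(60, 12, 11, 11), tolerance = 1e-15)
  covering <- tests[tests$start_index == 20 & tests$end_index == 30, ]
  expect_equal(covering$p_hyper, best, tolerance = 1e-15)
})

test_that("region calling merges adjacent significant windows and is idempotent", {
  ann <- tiny_annotation(200, nchr = 1)
  run <- ann$probe_id[100:110]
  cs <- fake_callset("s1", run, rep("hypo", 11), 200, ann)
  tests <- scan_sample(cs, ann, n_window = 11)
  reg <- call_regions(tests, ann, alpha = 0.05, callset = cs)
  expect_equal(nrow(reg), 1)
  # expected merged span derived independently: enumerate all windows, keep
  # those with oracle tail p <= alpha / n_windows, merge by hand
  thr <- 0.05 / 190
  k_of <- function(s) max(0, min(s + 10, 110) - max(s, 100) + 1)
  sig <- Filter(function(s) k_of(s) >= 1 &&
                  oracle_hyper_tail(200, 11, 11, k_of(s)) <= thr, 1:190)
  expect_equal(reg$start_index, min(sig))
  expect_equal(reg$end_index, max(sig) + 10)
  expect_equal(reg$n_sems, 11)
  expect_equal(reg$n_hypo, 11)
  expect_equal(reg$n_hyper, 0)
  # idempotence: feeding the merged region back as a window is a fixed point
  again <- call_regions(
    data.frame(sample_id = reg$sample_id, chrom = reg$chrom,
               start_index = reg$start_index, end_index = reg$end_index,
               p_hyper = reg$min_window_p),
    ann, alpha = 0.05, callset = cs, n_windows_total = 1)
  expect_equal(again$start_index, reg$start_index)
  expect_equal(again$end_index, reg$end_index)
  # no significant window -> no region
  weak <- fake_callset("s1", ann$probe_id[5], "hyper", 200, ann)
  t2 <- scan_sample(weak, ann, n_window = 11)
  expect_equal(nrow(call_regions(t2, ann)), 0)
})

test_that("region calls are invariant to shifting all positions", {
  ann <- tiny_annotation(100, nchr = 1)
  cs <- fake_callset("s1", ann$probe_id[40:50], rep("hyper", 11), 100, ann)
  r1 <- call_regions(scan_sample(cs, ann), ann, callset = cs)
  ann2 <- ann
  ann2$pos <- ann$pos + 10000L
  r2 <- call_regions(scan_sample(cs, ann2), ann2, callset = cs)
  expect_equal(r1$start_index, r2$start_index)
  expect_equal(r1$end_index, r2$end_index)
  expect_equal(r2$start_pos, r1$start_pos + 10000L)
})

test_that("two disjoint injected epivariations give two matching regions", {
  cfg <- sim_config(n_probes = 3000, n_cases = 1, n_controls = 30,
                    sem_rate_control = 0, epivar_per_case = 2,
                    dmp_fraction = 0, deletion_runs = 0, seed = 47)
  co <- generate_cohort(cfg)
  ref <- build_reference(co$beta[, co$sheet$group == "control"])
  cs <- call_sems_matrix(co$beta, ref)
  case_id <- co$sheet$sample_id[co$sheet$group == "case"]
  reg <- scan_cohort(cs[case_id], co$annotation)
  truth <- co$truth$epivar_regions[order(co$truth$epivar_regions$start_index), ]
  reg <- reg[order(reg$start_index), ]
  expect_equal(nrow(reg), 2)
  # called regions cover the injected intervals (window context may widen them)
  expect_true(all(reg$start_index <= truth$start_index))
  expect_true(all(reg$end_index >= truth$end_index))
  expect_lte(max(truth$start_index - reg$start_index), 10)
})

test_that("cross-study overlap isolates case-unique and shared genes", {
  mk_regions <- function(sample_id, genes) data.frame(
    sample_id = sample_id, chrom = "chr1", start_index = 1L, end_index = 2L,
    start_pos = 1L, end_pos = 2L, n_probes = 2L, n_sems = 2L,
    min_window_p = 1e-8, n_hyper = 2L, n_hypo = 0L,
    genes = genes, stringsAsFactors = FALSE)
  sheets <- list(
    s1 = data.frame(sample_id = c("a1", "a2", "a3"),
                    group = c("case", "case", "control")),
    s2 = data.frame(sample_id = c("b1", "b2"), group = c("case", "control")),
    s3 = data.frame(sample_id = c("c1", "c2"), group = c("case", "control")))
  regions <- list(
    s1 = rbind(mk_regions("a1", "GENEX"), mk_regions("a2", "GENEX;OTHER1"),
               mk_regions("a3", "CTRLGENE")),
    s2 = rbind(mk_regions("b1", "GENEX"), mk_regions("b2", "CTRLGENE")),
    s3 = mk_regions("c1", "GENEX;PRIV"))
  ov <- cross_overlap(regions, sheets)
  expect_setequal(ov$case_unique_by_study$s1, c("GENEX", "OTHER1"))
  expect_false("CTRLGENE" %in% rownames(ov$membership))
  expect_true("GENEX" %in% ov$shared_genes)
  expect_false("PRIV" %in% ov$shared_genes)
  expect_equal(unname(ov$n_case_samples["GENEX"]), 4L)
  expect_equal(ov$recurrent_genes, "GENEX")
  all3 <- ov$upset[ov$upset$studies == "s1&s2&s3", ]
  expect_equal(all3$genes, "GENEX")
  # all regions in controls -> empty case-unique sets
  ov0 <- cross_overlap(list(s1 = mk_regions("a3", "CTRLGENE")),
                       sheets["s1"])
  expect_equal(length(ov0$case_unique_by_study$s1), 0)
  expect_equal(nrow(ov0$membership), 0)
})
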