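test_that("reference quartiles follow hand linear-interpolation arithmetic", {
  beta <- matrix(c(0.1, 0.2, 0.3, 0.4), 1, 4, dimnames = list("cg1", NULL))
  ref <- build_reference(beta, k = 3, n_min = 4)
  expect_equal(ref$q1, 0.175, tolerance = 1e-12)
  expect_equal(ref$q3, 0.325, tolerance = 1e-12)
  expect_equal(ref$iqr, 0.15, tolerance = 1e-12)
  expect_equal(ref$lower, 0.175 - 0.45, tolerance = 1e-12)
  expect_equal(ref$upper, 0.325 + 0.45, tolerance = 1e-12)
  # k = 0 collapses the bounds onto the quartiles
  ref0 <- build_reference(beta, k = 0, n_min = 4)
  expect_equal(ref0$lower, ref0$q1)
  expect_equal(ref0$upper, ref0$q3)
})

test_that("degenerate and under-sampled probes are non-callable", {
  beta <- rbind(cg1 = rep(0.5, 12), cg2 = runif(12, 0.2, 0.8))
  ref <- build_reference(beta, n_min = 10)
  expect_false(ref$callable[1])   # zero IQR
  expect_true(ref$callable[2])
  beta[2, 1:5] <- NA              # fewer than n_min observed
  ref2 <- build_reference(beta, n_min = 10)
  expect_false(ref2$callable[2])
  expect_error(build_reference(beta[, 1:5], n_min = 10), "at least 10")
})

test_that("reference construction ignores control ordering", {
  set.seed(35)
  beta <- matrix(runif(300, 0.1, 0.9), 10, 30)
  rownames(beta) <- sprintf("cg%d", 1:10)
  r1 <- build_reference(beta)
  r2 <- build_reference(beta[, sample(30)])
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("single-sample calling hits only boundary crossings", {
  set.seed(36)
  beta <- matrix(runif(200, 0.3, 0.7), 10, 20)
  rownames(beta) <- sprintf("cg%d", 1:10)
  ref <- build_reference(beta)
  s <- ref$median
  names(s) <- ref$probe_id
  cs <- call_sems(s, ref, sample_id = "mid")
  expect_equal(cs$burden, 0)
  expect_equal(cs$log_burden, 0)
  s["cg4"] <- ref$upper[4] + 0.01
  cs2 <- call_sems(s, ref)
  expect_equal(cs2$burden, 1)
  expect_equal(cs2$calls$direction, "hyper")
  expect_equal(cs2$calls$probe_id, "cg4")
  expect_equal(cs2$log_burden, log10(2))
  # excluded probes are skipped
  cs3 <- call_sems(s, ref, exclude_probes = "cg4")
  expect_equal(cs3$burden, 0)
})

test_that("burden is monotone non-increasing in k", {
  set.seed(37)
  beta <- matrix(runif(600, 0.05, 0.95), 20, 30)
  rownames(beta) <- sprintf("cg%d", 1:20)
  sample_v <- setNames(runif(20, 0, 1), rownames(beta))
  burdens <- sapply(c(0.5, 1, 2, 3, 4), function(k)
    call_sems(sample_v, build_reference(beta, k = k))$burden)
  expect_true(all(diff(burdens) <= 0))
})

test_that("injected SEMs are recovered with high recall and precision", {
  cfg <- sim_config(n_probes = 5000, n_cases = 40, n_controls = 40,
                    sem_rate_control = 5e-4, sem_rate_ratio = 2.5,
                    dmp_fraction = 0, epivar_per_case = 0,
                    deletion_runs = 0, seed = 43)
  co <- generate_cohort(cfg)
  ref <- build_reference(co$beta[, co$sheet$group == "control"])
  cs <- call_sems_matrix(co$beta, ref)
  calls <- do.call(rbind, lapply(cs, function(x)
    if (nrow(x$calls)) data.frame(sample_id = x$sample_id,
                                  probe_id = x$calls$probe_id)))
  key_t <- paste(co$truth$sem_positions$sample_id,
                 co$truth$sem_positions$probe_id)
  key_c <- paste(calls$sample_id, calls$probe_id)
  expect_gte(mean(key_t %in% key_c), 0.95)
  expect_gte(mean(key_c %in% key_t), 0.90)
})

test_that("call directions and truth directions agree", {
  cfg <- sim_config(n_probes = 1000, n_cases = 10, n_controls = 20,
                    sem_rate_control = 2e-3, epivar_per_case = 0,
                    dmp_fraction = 0, deletion_runs = 0, seed = 44)
  co <- generate_cohort(cfg)
  ref <- build_reference(co$beta[, co$sheet$group == "control"], n_min = 10)
  cs <- call_sems_matrix(co$beta, ref)
  truth <- co$truth$sem_positions
  for (j in sample(seq_along(cs), 5)) {
    x <- cs[[j]]
    t_j <- truth[truth$sample_id == x$sample_id, ]
    shared <- intersect(t_j$probe_id, x$calls$probe_id)
    expect_equal(x$calls$direction[match(shared, x$calls$probe_id)],
                 t_j$direction[match(shared, t_j$probe_id)])
    # every call strictly outside the crossed bound
    idx <- match(x$calls$probe_id, ref$probe_id)
    hyper <- x$calls$direction == "hyper"
    expect_true(all(x$calls$beta[hyper] > ref$upper[idx][hyper]))
    expect_true(all(x$calls$beta[!hyper] < ref$lower[idx][!hyper]))
  }
})

test_that("the drift model recovers an elevated burden and flags degeneracies", {
  cfg <- sim_config(n_probes = 8000, n_cases = 40, n_controls = 40,
                    sem_rate_control = 1e-3, sem_rate_ratio = 2,
                    dmp_fraction = 0, epivar_per_case = 0,
                    deletion_runs = 0, seed = 45)
  co <- generate_cohort(cfg)
  ref <- build_reference(co$beta[, co$sheet$group == "control"])
  cs <- call_sems_matrix(co$beta, ref)
  fit <- fit_burden_model(cs, co$sheet, covariates = "age")
  expect_gt(fit$odds_ratio, 1)
  expect_gt(fit$ci_low, 1)
  expect_false(fit$separation)
  # constant burden is rejected
  bt <- burden_table(cs)
  bt$log_burden <- 1
  expect_error(fit_burden_model(bt, co$sheet), "constant")
  # perfect separation: plain ML flags it with an infinite CI ...
  bt2 <- burden_table(cs)
  bt2$log_burden <- as.numeric(co$sheet$group == "case")
  fit2 <- fit_burden_model(bt2, co$sheet, firth = FALSE)
  expect_true(fit2$separation)
  expect_equal(fit2$ci_high, Inf)
  # ... while the penalized fit stays finite and still finds the effect
  fit3 <- fit_burden_model(bt2, co$sheet)
  expect_false(fit3$separation)
  expect_true(is.finite(fit3$log_or))
  expect_gt(fit3$ci_low, 1)
})

test_that("the penalized fit agrees with ML when the data are well separated from degeneracy", {
  set.seed(55)
  n <- 400
  lb <- rnorm(n, 1, 0.3)
  pr <- 1 / (1 + exp(-(-1 + 1 * lb)))
  sheet <- data.frame(sample_id = sprintf("S%d", 1:n),
                      group = ifelse(runif(n) < pr, "case", "control"))
  bt <- data.frame(sample_id = sheet$sample_id, burden = 1,
                   log_burden = lb, n_hyper = 0, n_hypo = 0, n_callable = 1)
  f_firth <- fit_burden_model(bt, sheet)
  f_ml <- fit_burden_model(bt, sheet, firth = FALSE)
  expect_equal(f_firth$log_or, f_ml$log_or, tolerance = 0.05)
  expect_equal(f_firth$se, f_ml$se, tolerance = 0.05)
})
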