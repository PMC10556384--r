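#' Sample-size weighted-Z meta-analysis of per-study p-values
#'
#' The classic scheme popularized by METAL for p-value input: each study
#' contributes z_i = sign_i * qnorm(1 - p_i / 2) with weight w_i =
#' sqrt(n_i); the combined statistic is Z = sum(w_i z_i) / sqrt(sum w_i^2)
#' and the combined p-value is the two-sided normal tail.
#'
#' @param p per-study two-sided p-values (>= 2 studies, non-missing).
#' @param direction per-study effect signs (+1/-1, or any signed numbers).
#' @param n per-study sample sizes.
#' @return list with `z_combined`, `p_combined`, `direction` (sign
#'   pattern string, e.g. `"+-+"`), `n_studies`.
#' @export
weighted_z_meta <- function(p, direction, n) {
  keep <- !is.na(p)
  p <- p[keep]; direction <- direction[keep]; n <- n[keep]
  if (length(p) < 2L)
    stop("weighted_z_meta: need >= 2 studies with non-missing p", call. = FALSE)
  stopifnot(length(direction) == length(p), length(n) == length(p), all(n > 0))
  if (any(p <= 0)) {
    warning("weighted_z_meta: p = 0 clipped to smallest positive double")
    p <- pmax(p, .Machine$double.xmin)
  }
  z <- sign(direction) * qnorm(p / 2, lower.tail = FALSE)
  w <- sqrt(n)
  zc <- sum(w * z) / sqrt(sum(w^2))
  list(z_combined = zc, p_combined = 2 * pnorm(-abs(zc)),
       direction = paste(ifelse(direction >= 0, "+", "-"), collapse = ""),
       n_studies = length(p))
}

#' Weighted-Z meta-analysis across a table of per-study site results
#'
#' Applies [weighted_z_meta()] probe-by-probe over a list of per-study
#' EWAS tables, keeping probes analyzed in at least two studies.
#'
#' @param study_results named list of data.frames from
#'   [fit_site_models()].
#' @param study_n named numeric vector of per-study sample sizes (same
#'   names/order as `study_results`).
#' @return data.frame `probe_id`, `z_combined`, `p_combined`, `p_bh`,
#'   `p_bonf`, `direction`, `n_studies`.
#' @export
meta_sites <- function(study_results, study_n) {
  stopifnot(length(study_results) >= 2L,
            length(study_n) == length(study_results))
  ids <- unique(unlist(lapply(study_results, `[[`, "probe_id")))
  ns <- length(study_results)
  pm <- dm <- matrix(NA_real_, length(ids), ns)
  for (s in seq_len(ns)) {
    idx <- match(study_results[[s]]$probe_id, ids)
    pm[idx, s] <- study_results[[s]]$p_raw
    dm[idx, s] <- sign(study_results[[s]]$effect)
  }
  k <- rowSums(!is.na(pm))
  keep <- which(k >= 2L)
  ## vectorized over probes: combined Z with per-probe study availability
  w <- sqrt(study_n)
  zmat <- sign(dm) * qnorm(pmax(pm, .Machine$double.xmin) / 2, lower.tail = FALSE)
  wmat <- matrix(w, length(ids), ns, byrow = TRUE)
  wmat[is.na(zmat)] <- NA
  zc <- rowSums(wmat * zmat, na.rm = TRUE) / sqrt(rowSums(wmat^2, na.rm = TRUE))
  dirstr <- apply(dm, 1, function(d)
    paste(ifelse(is.na(d), "?", ifelse(d >= 0, "+", "-")), collapse = ""))
  p_comb <- 2 * pnorm(-abs(zc))
  out <- data.frame(probe_id = ids, z_combined = zc, p_combined = p_comb,
                    direction = dirstr, n_studies = k, stringsAsFactors = FALSE)[keep, ]
  out$p_bh <- adjust_pvalues(out$p_combined, "bh")
  out$p_bonf <- adjust_pvalues(out$p_combined, "bonferroni")
  rownames(out) <- NULL
  out
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance: with fixed-effect weights
#' w_i = 1/se_i^2 and fixed-effect pooled estimate, Q = sum w_i (e_i -
#' pooled)^2, tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w)), then
#' random-effects weights 1/(se_i^2 + tau2) give the pooled effect, its
#' SE and 95% normal CI. I2 = max(0, (Q - df)/Q) * 100.
#'
#' @param effects per-study effect sizes (>= 2).
#' @param ses per-study standard errors (> 0).
#' @return list with `pooled_effect`, `se`, `ci_low`, `ci_high`, `z`, `p`,
#'   `Q`, `Q_p`, `I2`, `tau2`, `weights` (random-effects weights,
#'   normalized to sum 1).
#' @export
random_effects_meta <- function(effects, ses) {
  stopifnot(length(effects) == length(ses))
  if (length(effects) < 2L)
    stop("random_effects_meta: need >= 2 studies", call. = FALSE)
  if (any(is.na(effects)) || any(is.na(ses)) || any(ses <= 0))
    stop("random_effects_meta: standard errors must be positive and non-missing",
         call. = FALSE)
  w <- 1 / ses^2
  fixed <- sum(w * effects) / sum(w)
  df <- length(effects) - 1L
  Q <- sum(w * (effects - fixed)^2)
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (ses^2 + tau2)
  pooled <- sum(wr * effects) / sum(wr)
  se <- sqrt(1 / sum(wr))
  z <- pooled / se
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(pooled_effect = pooled, se = se,
       ci_low = pooled - qnorm(0.975) * se,
       ci_high = pooled + qnorm(0.975) * se,
       z = z, p = 2 * pnorm(-abs(z)),
       Q = Q, Q_p = pchisq(Q, df, lower.tail = FALSE),
       I2 = I2, tau2 = tau2, weights = wr / sum(wr))
}

#' Forest-plot data table
#'
#' The numbers a forest plot renders: per-study effect, 95% CI and
#' relative random-effects weight (normalized to sum 1), plus a pooled
#' summary row.
#'
#' @param effects,ses per-study effects and standard errors.
#' @param labels optional study labels.
#' @param exp_scale report effects/CIs on the exponential scale (odds
#'   ratios) rather than the linear scale.
#' @return data.frame `study`, `effect`, `ci_low`, `ci_high`, `weight`;
#'   the last row is the pooled estimate with weight `NA`.
#' @export
forest_data <- function(effects, ses, labels = NULL, exp_scale = FALSE) {
  meta <- random_effects_meta(effects, ses)
  if (is.null(labels)) labels <- sprintf("study%d", seq_along(effects))
  tr <- if (exp_scale) exp else identity
  out <- data.frame(
    study = c(labels, "pooled"),
    effect = tr(c(effects, meta$pooled_effect)),
    ci_low = tr(c(effects - qnorm(0.975) * ses, meta$ci_low)),
    ci_high = tr(c(effects + qnorm(0.975) * ses, meta$ci_high)),
    weight = c(meta$weights, NA),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
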