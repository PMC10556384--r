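#' Convert beta values to M-values
#'
#' M = log2(b / (1 - b)) after clipping b into \[eps, 1 - eps\]. Linear
#' models behave better on the M scale because variance is more nearly
#' constant across the methylation range.
#'
#' @param beta numeric vector/matrix of beta values.
#' @param eps clipping bound in (0, 0.5), default 1e-6.
#' @return M-values with the same shape.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  stopifnot(eps > 0, eps < 0.5)
  logit2(pmin(pmax(beta, eps), 1 - eps))
}

#' Build an EWAS design matrix from a sample sheet
#'
#' Intercept + binary group indicator (1 = case) first, then any covariate
#' columns; character/factor covariates are expanded to treatment
#' contrasts.
#'
#' @param sheet sample sheet data.frame with a `group` column.
#' @param covariates character vector of sheet column names (may be empty).
#' @param case_label level treated as case (default `"case"`).
#' @param extra optional numeric matrix of additional per-sample columns
#'   (e.g. PLS scores), rows aligned with `sheet`.
#' @return numeric design matrix, one row per sample; the group column is
#'   named `group`.
#' @export
ewas_design <- function(sheet, covariates = character(0), case_label = "case",
                        extra = NULL) {
  stopifnot("group" %in% names(sheet))
  x <- data.frame(group = as.numeric(sheet$group == case_label))
  for (cv in covariates) {
    if (!cv %in% names(sheet))
      stop("ewas_design: covariate '", cv, "' not in sample sheet", call. = FALSE)
    v <- sheet[[cv]]
    if (is.numeric(v)) x[[cv]] <- v
    else {
      f <- factor(v)
      if (nlevels(f) > 1L) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(f)[-1])
        x <- cbind(x, as.data.frame(mm))
      }
    }
  }
  out <- cbind(`(Intercept)` = 1, as.matrix(x))
  if (!is.null(extra)) {
    stopifnot(nrow(extra) == nrow(sheet))
    out <- cbind(out, as.matrix(extra))
  }
  rownames(out) <- sheet$sample_id
  out
}

#' Per-probe linear models of methylation on group and covariates
#'
#' Ordinary least squares per probe on M-values: the group coefficient,
#' its standard error, t statistic and two-sided p-value from the t
#' distribution. With `moderate = TRUE`, residual variances are shrunk
#' toward their cross-probe harmonic pooled value with a fixed prior
#' weight of `prior_df` degrees of freedom before computing t and p
#' (a fixed-prior variant of variance moderation; the full empirical-Bayes
#' prior fit is intentionally not performed, and moderation is off by
#' default so results match plain OLS exactly).
#'
#' Probes with fewer than `ncol(design) + 2` complete observations are
#' returned with missing statistics.
#'
#' @param beta probes x samples beta matrix (`NA` allowed).
#' @param design numeric design matrix from [ewas_design()] (full rank),
#'   containing a column named `group`.
#' @param moderate logical; apply fixed-prior variance moderation.
#' @param prior_df prior degrees of freedom for moderation (default 4).
#' @param eps clipping for the M transform.
#' @return data.frame with columns `probe_id`, `effect` (group coefficient
#'   on the M scale), `se`, `t_stat`, `p_raw`, `p_bh`, `p_bonf`, `n_used`.
#' @export
fit_site_models <- function(beta, design, moderate = FALSE, prior_df = 4,
                            eps = 1e-6) {
  stopifnot(is.matrix(design), ncol(beta) == nrow(design))
  if (!"group" %in% colnames(design))
    stop("fit_site_models: design must contain a 'group' column", call. = FALSE)
  qrx <- qr(design)
  if (qrx$rank < ncol(design)) {
    bad <- colnames(design)[qrx$pivot[(qrx$rank + 1L):ncol(design)]]
    stop("fit_site_models: design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  m <- beta_to_m(beta, eps)
  n <- ncol(m)
  k <- ncol(design)
  gi <- match("group", colnames(design))
  min_obs <- k + 2L

  probe_id <- rownames(beta)
  if (is.null(probe_id)) probe_id <- sprintf("p%d", seq_len(nrow(beta)))
  eff <- se <- s2 <- rep(NA_real_, nrow(m))
  df <- n_used <- rep(NA_real_, nrow(m))

  complete <- rowSums(is.na(m)) == 0L
  if (any(complete)) {
    xtxi <- chol2inv(chol(crossprod(design)))
    bhat <- m[complete, , drop = FALSE] %*% design %*% xtxi  # probes x k
    res <- m[complete, , drop = FALSE] - bhat %*% t(design)
    rdf <- n - k
    s2c <- rowSums(res^2) / rdf
    eff[complete] <- bhat[, gi]
    s2[complete] <- s2c
    df[complete] <- rdf
    se[complete] <- sqrt(s2c * xtxi[gi, gi])
    n_used[complete] <- n
  }
  for (i in which(!complete)) {
    ok <- !is.na(m[i, ])
    if (sum(ok) < min_obs) next
    xi <- design[ok, , drop = FALSE]
    if (qr(xi)$rank < k) next
    fit <- stats::lm.fit(xi, m[i, ok])
    rdf <- sum(ok) - k
    s2i <- sum(fit$residuals^2) / rdf
    xtxi_i <- chol2inv(chol(crossprod(xi)))
    eff[i] <- fit$coefficients[gi]
    s2[i] <- s2i
    df[i] <- rdf
    se[i] <- sqrt(s2i * xtxi_i[gi, gi])
    n_used[i] <- sum(ok)
  }

  if (moderate) {
    ok <- !is.na(s2) & s2 > 0
    s0 <- 1 / mean(1 / s2[ok])  # harmonic pooled residual variance
    s2_post <- (prior_df * s0 + df * s2) / (prior_df + df)
    scale_f <- sqrt(s2_post / s2)
    se <- se * scale_f
    df <- df + prior_df
  }
  t_stat <- eff / se
  p_raw <- 2 * pt(-abs(t_stat), df)
  data.frame(probe_id = probe_id, effect = eff, se = se, t_stat = t_stat,
             p_raw = p_raw,
             p_bh = adjust_pvalues(p_raw, "bh"),
             p_bonf = adjust_pvalues(p_raw, "bonferroni"),
             n_used = n_used, stringsAsFactors = FALSE)
}

#' Gene/region-level combination of per-probe statistics
#'
#' Unweighted Stouffer combination of signed per-probe Z-scores within
#' each region (by default, probes sharing a gene symbol): Z_region =
#' sum(z_i) / sqrt(m), two-sided p from the normal tail. Signs come from
#' the probe effect direction.
#'
#' @param site_results data.frame from [fit_site_models()].
#' @param annotation probe annotation; `gene` column defines regions
#'   unless `region_map` is given.
#' @param region_map optional named list region -> probe_id vector.
#' @param exclude_probes optional probe ids to drop (e.g. inside a
#'   sample-level deletion region) before combining.
#' @return data.frame `region`, `n_probes`, `z`, `p`.
#' @export
fit_region_models <- function(site_results, annotation, region_map = NULL,
                              exclude_probes = NULL) {
  sr <- site_results[!is.na(site_results$p_raw), ]
  if (!is.null(exclude_probes)) sr <- sr[!sr$probe_id %in% exclude_probes, ]
  z <- qnorm(pmax(sr$p_raw, 1e-300) / 2, lower.tail = FALSE) * sign(sr$effect)
  if (is.null(region_map)) {
    gene <- annotation$gene[match(sr$probe_id, annotation$probe_id)]
    keep <- !is.na(gene) & gene != ""
    region_map <- split(sr$probe_id[keep], gene[keep])
  }
  rows <- lapply(names(region_map), function(r) {
    ids <- intersect(region_map[[r]], sr$probe_id)
    if (!length(ids)) {
      warning("fit_region_models: region '", r, "' has no analyzed probes; skipped")
      return(NULL)
    }
    zi <- z[match(ids, sr$probe_id)]
    zc <- sum(zi) / sqrt(length(zi))
    data.frame(region = r, n_probes = length(zi), z = zc,
               p = 2 * pnorm(-abs(zc)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region = character(0), n_probes = integer(0),
                      z = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Multiple-testing adjustment (Benjamini-Hochberg or Bonferroni)
#'
#' Wraps [stats::p.adjust()]; missing values are excluded from the number
#' of tests and returned as missing.
#'
#' @param p numeric vector of p-values in \[0,1\] (`NA` allowed).
#' @param method `"bh"` or `"bonferroni"`.
#' @return adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("adjust_pvalues: p-values must lie in [0,1]", call. = FALSE)
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Volcano-plot data table
#'
#' Mean beta difference between groups (case minus control) on the x axis
#' and -log10 of the uncorrected p-value on the y axis, one row per probe.
#'
#' @param beta probes x samples beta matrix.
#' @param group per-sample labels; `case_label` defines cases.
#' @param site_results data.frame from [fit_site_models()].
#' @param case_label default `"case"`.
#' @return data.frame `probe_id`, `delta_beta`, `neg_log10_p`.
#' @export
volcano_data <- function(beta, group, site_results, case_label = "case") {
  stopifnot(ncol(beta) == length(group))
  d <- rowMeans(beta[, group == case_label, drop = FALSE], na.rm = TRUE) -
    rowMeans(beta[, group != case_label, drop = FALSE], na.rm = TRUE)
  idx <- match(site_results$probe_id, rownames(beta))
  data.frame(probe_id = site_results$probe_id, delta_beta = d[idx],
             neg_log10_p = -log10(site_results$p_raw), stringsAsFactors = FALSE)
}
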