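#' Per-probe reference methylation ranges from a control population
#'
#' For every probe, the first and third quartiles of the non-missing
#' control beta values (linear-interpolation, type-7 quantiles) define
#' the outlier bounds
#' \deqn{lower = Q1 - k \cdot IQR, \quad upper = Q3 + k \cdot IQR}
#' with IQR = Q3 - Q1 and k = 3 by default. A probe is `callable` only
#' when its control IQR is at least `iqr_floor` (a probe with no spread
#' among controls would be infinitely sensitive) and at least `n_min`
#' controls were observed. Bounds are reported unclipped; beta values
#' cannot leave \[0,1\], so clipping would only corrupt the recorded
#' range.
#'
#' @param beta_controls probes x control-samples beta matrix (`NA`
#'   allowed). Cases must not be included: the reference population is
#'   the study's controls.
#' @param k IQR multiplier (default 3).
#' @param iqr_floor minimum control IQR for a callable probe.
#' @param n_min minimum number of observed controls per probe, and the
#'   minimum number of control samples overall.
#' @return data.frame with columns `probe_id`, `q1`, `median`, `q3`,
#'   `iqr`, `lower`, `upper`, `n_ref`, `callable`; attribute `k`.
#' @export
build_reference <- function(beta_controls, k = 3, iqr_floor = 1e-6, n_min = 10L) {
  stopifnot(is.matrix(beta_controls), k >= 0)
  if (ncol(beta_controls) < n_min)
    stop("build_reference: need at least ", n_min, " control samples",
         call. = FALSE)
  qs <- row_quantiles(beta_controls, c(0.25, 0.5, 0.75))
  iqr <- qs[, 3] - qs[, 1]
  n_ref <- rowSums(!is.na(beta_controls))
  probe_id <- rownames(beta_controls)
  if (is.null(probe_id)) probe_id <- sprintf("p%d", seq_len(nrow(beta_controls)))
  out <- data.frame(
    probe_id = probe_id,
    q1 = qs[, 1], median = qs[, 2], q3 = qs[, 3], iqr = iqr,
    lower = qs[, 1] - k * iqr, upper = qs[, 3] + k * iqr,
    n_ref = n_ref,
    callable = !is.na(iqr) & iqr >= iqr_floor & n_ref >= n_min,
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "k") <- k
  out
}

#' Call stochastic epigenetic mutations for one sample
#'
#' A SEM is a beta value falling outside the control-derived reference
#' range: value > upper gives a hyper-methylated call, value < lower a
#' hypo-methylated call (directions relative to the controls' probe
#' median). Non-callable probes, missing values and probes inside the
#' sample's flagged deletion regions are skipped. The burden is the call
#' count; `log_burden` is log10(burden + 1) so zero-burden samples stay
#' in downstream models.
#'
#' @param beta_sample named numeric vector of beta values, aligned to
#'   `reference$probe_id` (names used to align if present).
#' @param reference data.frame from [build_reference()].
#' @param exclude_probes optional probe ids to skip (e.g. from
#'   [flag_deletion_regions()] for this sample).
#' @param sample_id identifier stored in the result.
#' @return list of class `sem_callset`: `sample_id`, `calls` (data.frame
#'   `probe_id`, `direction`, `beta`), `burden`, `log_burden`,
#'   `n_callable`.
#' @export
call_sems <- function(beta_sample, reference, exclude_probes = NULL,
                      sample_id = "sample") {
  if (!is.null(names(beta_sample))) {
    idx <- match(reference$probe_id, names(beta_sample))
    if (any(is.na(idx)))
      stop("call_sems: sample is missing reference probes", call. = FALSE)
    beta_sample <- beta_sample[idx]
  } else if (length(beta_sample) != nrow(reference)) {
    stop("call_sems: sample length differs from reference", call. = FALSE)
  }
  usable <- reference$callable & !is.na(beta_sample)
  if (!is.null(exclude_probes))
    usable <- usable & !reference$probe_id %in% exclude_probes
  hyper <- usable & beta_sample > reference$upper
  hypo <- usable & beta_sample < reference$lower
  hit <- hyper | hypo
  direction <- rep.int("hypo", sum(hit))
  direction[hyper[hit]] <- "hyper"
  calls <- data.frame(
    probe_id = reference$probe_id[hit],
    direction = direction,
    beta = unname(beta_sample[hit]),
    stringsAsFactors = FALSE)
  burden <- nrow(calls)
  structure(list(sample_id = sample_id, calls = calls, burden = burden,
                 log_burden = log10(burden + 1), n_callable = sum(usable)),
            class = "sem_callset")
}

#' Call SEMs for every sample of a beta matrix
#'
#' @param beta probes x samples beta matrix.
#' @param reference data.frame from [build_reference()].
#' @param deletion_regions optional data.frame from
#'   [flag_deletion_regions()]; each sample's flagged probes are skipped
#'   for that sample only.
#' @param annotation required with `deletion_regions` to map region
#'   indices to probe ids.
#' @return named list of `sem_callset` objects, one per sample.
#' @export
call_sems_matrix <- function(beta, reference, deletion_regions = NULL,
                             annotation = NULL) {
  samples <- colnames(beta) %||% sprintf("S%d", seq_len(ncol(beta)))
  excl <- vector("list", ncol(beta))
  if (!is.null(deletion_regions) && nrow(deletion_regions)) {
    stopifnot(!is.null(annotation))
    for (i in seq_len(nrow(deletion_regions))) {
      j <- match(deletion_regions$sample_id[i], samples)
      if (is.na(j)) next
      ids <- annotation$probe_id[deletion_regions$start_index[i]:deletion_regions$end_index[i]]
      excl[[j]] <- c(excl[[j]], ids)
    }
  }
  out <- lapply(seq_len(ncol(beta)), function(j)
    call_sems(setNames(beta[, j], rownames(beta)), reference,
              exclude_probes = excl[[j]], sample_id = samples[j]))
  names(out) <- samples
  out
}

#' Per-sample SEM burden summary table
#'
#' @param callsets list of `sem_callset` objects.
#' @return data.frame `sample_id`, `burden`, `log_burden`, `n_hyper`,
#'   `n_hypo`, `n_callable`.
#' @export
burden_table <- function(callsets) {
  do.call(rbind, lapply(callsets, function(cs) data.frame(
    sample_id = cs$sample_id, burden = cs$burden, log_burden = cs$log_burden,
    n_hyper = sum(cs$calls$direction == "hyper"),
    n_hypo = sum(cs$calls$direction == "hypo"),
    n_callable = cs$n_callable,
    stringsAsFactors = FALSE, row.names = NULL)))
}

## Firth bias-reduced logistic regression: Newton iterations on the
## Jeffreys-penalized likelihood. Estimates stay finite under complete
## separation, where plain ML diverges.
.firth_logistic <- function(x, y, max_iter = 100, tol = 1e-8) {
  b <- rep(0, ncol(x))
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% b)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    xw <- x * sqrt(w)
    info <- crossprod(xw)
    inv <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(inv)) return(list(converged = FALSE))
    h <- rowSums((xw %*% inv) * xw)
    score <- drop(crossprod(x, y - p + h * (0.5 - p)))
    step <- drop(inv %*% score)
    ## dampen oversized Newton steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    b <- b + step
    if (max(abs(step)) < tol) {
      se <- sqrt(diag(inv))
      return(list(coef = b, se = se, converged = TRUE, iter = it))
    }
  }
  list(coef = b, se = sqrt(diag(chol2inv(chol(info)))), converged = FALSE)
}

#' Logistic drift model: SEM burden vs case/control status
#'
#' Logistic regression of the case indicator on log10(burden + 1) plus
#' covariates (the same set used in the EWAS step). The group difference
#' is reported as the odds ratio per unit log-burden with its Wald 95%
#' CI. By default the model is fitted by Firth's bias-reduced IRLS
#' (Jeffreys-prior penalized likelihood), which keeps estimates finite
#' when the burdens of the two groups separate completely -- a real
#' possibility when the drift effect is strong. With `firth = FALSE`
#' plain maximum likelihood via [stats::glm()] is used and diverging
#' coefficients (perfect separation) are flagged with an infinite CI
#' rather than failing silently.
#'
#' @param callsets list of `sem_callset` objects (or a [burden_table()]).
#' @param sheet sample sheet with `sample_id` and `group` columns.
#' @param covariates sheet column names to adjust for.
#' @param extra optional numeric matrix of extra covariates (e.g. PLS
#'   scores), rows aligned with `sheet`.
#' @param case_label default `"case"`.
#' @param firth use Firth's penalized likelihood (default TRUE).
#' @return list `odds_ratio`, `ci_low`, `ci_high`, `log_or`, `se`, `p`,
#'   `separation`, `covariate_effects` (coefficient table), `n`,
#'   `method`.
#' @export
fit_burden_model <- function(callsets, sheet, covariates = character(0),
                             extra = NULL, case_label = "case", firth = TRUE) {
  bt <- if (is.data.frame(callsets)) callsets else burden_table(callsets)
  idx <- match(sheet$sample_id, bt$sample_id)
  if (any(is.na(idx)))
    stop("fit_burden_model: sheet samples missing from callsets", call. = FALSE)
  dat <- data.frame(y = as.numeric(sheet$group == case_label),
                    log_burden = bt$log_burden[idx])
  if (length(unique(dat$y)) < 2L)
    stop("fit_burden_model: both groups must be present", call. = FALSE)
  if (sd(dat$log_burden) < 1e-12)
    stop("fit_burden_model: log burden is constant (collinear with intercept)",
         call. = FALSE)
  for (cv in covariates) {
    v <- sheet[[cv]]
    if (is.null(v)) stop("fit_burden_model: covariate '", cv, "' not in sheet",
                         call. = FALSE)
    dat[[cv]] <- if (is.numeric(v)) v else factor(v)
  }
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    stopifnot(nrow(extra) == nrow(sheet))
    colnames(extra) <- colnames(extra) %||% sprintf("x%d", seq_len(ncol(extra)))
    dat <- cbind(dat, as.data.frame(extra))
  }
  mm <- stats::model.matrix(y ~ ., data = dat)
  if (qr(mm)$rank < ncol(mm))
    stop("fit_burden_model: design is rank deficient", call. = FALSE)
  gi <- match("log_burden", colnames(mm))
  if (firth) {
    fit <- .firth_logistic(mm, dat$y)
    if (!isTRUE(fit$converged))
      stop("fit_burden_model: penalized IRLS failed to converge", call. = FALSE)
    b <- fit$coef[gi]
    se <- fit$se[gi]
    separation <- FALSE
    z <- fit$coef / fit$se
    co <- cbind(Estimate = fit$coef, `Std. Error` = fit$se, `z value` = z,
                `Pr(>|z|)` = 2 * pnorm(-abs(z)))
    rownames(co) <- colnames(mm)
  } else {
    fitg <- suppressWarnings(glm(y ~ ., data = dat, family = binomial()))
    co <- coef(summary(fitg))
    b <- co["log_burden", "Estimate"]
    se <- co["log_burden", "Std. Error"]
    ## diverging coefficients show up as exploding Wald SEs; a large but
    ## precisely estimated coefficient is a real effect, not separation
    separation <- !fitg$converged || se > 100 ||
      (is.finite(b) && se > 10 * max(1, abs(b)))
  }
  ci <- if (separation) c(0, Inf) else exp(b + c(-1, 1) * qnorm(0.975) * se)
  list(odds_ratio = exp(b), ci_low = ci[1], ci_high = ci[2],
       log_or = b, se = se, p = 2 * pnorm(-abs(b / se)),
       separation = separation,
       covariate_effects = co[setdiff(rownames(co), c("(Intercept)", "log_burden")), ,
                              drop = FALSE],
       n = nrow(dat), method = if (firth) "firth" else "ml")
}
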