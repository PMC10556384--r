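#' Construct a linear epigenetic clock model
#'
#' A clock is an intercept plus a sparse linear combination of probe beta
#' values, optionally followed by the piecewise age transform used by
#' first-generation pan-tissue clocks. Published coefficient sets
#' (Horvath, Hannum, GrimAge, ...) are supplied by the user; none are
#' shipped.
#'
#' @param name clock name.
#' @param intercept numeric intercept.
#' @param coefficients named numeric vector: probe_id -> weight.
#' @param age_transform `"identity"` or `"horvath"` (the log-linear
#'   anti-transform: predictor x <= 0 maps to 21*exp(x) - 1, x > 0 to
#'   21*x + 20, the inverse of F(age) = log(age + 1) - log(21)).
#' @return object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coefficients,
                        age_transform = c("identity", "horvath")) {
  age_transform <- match.arg(age_transform)
  if (length(coefficients) < 1L)
    stop("clock_model: need at least one coefficient", call. = FALSE)
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients)))
    stop("clock_model: coefficients must have unique probe-id names", call. = FALSE)
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients, age_transform = age_transform),
            class = "clock_model")
}

#' Read a clock model from a coefficient CSV plus JSON sidecar
#'
#' The CSV holds columns `probe_id`, `weight`; the sidecar holds `name`,
#' `intercept` and `age_transform`.
#'
#' @param csv_path path to the coefficient CSV.
#' @param json_path path to the JSON sidecar (default: csv path with
#'   `.json` extension).
#' @return a [clock_model()].
#' @export
read_clock <- function(csv_path, json_path = sub("\\.csv$", ".json", csv_path)) {
  co <- read.csv(csv_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  clock_model(meta$name, meta$intercept, setNames(co$weight, co$probe_id),
              meta$age_transform)
}

.horvath_anti <- function(x) ifelse(x <= 0, 21 * exp(x) - 1, 21 * x + 20)

#' Apply an epigenetic clock to a beta matrix
#'
#' Linear predictor intercept + sum(w_j * beta_j) over the clock probes
#' present in the matrix; missing clock probes are imputed with the
#' cohort mean of that probe (and with 0.5 if a probe is absent
#' entirely). Samples with fewer than `min_present` of the clock probes
#' observed are flagged low-confidence but still reported.
#'
#' @param beta probes x samples beta matrix.
#' @param clock a [clock_model()].
#' @param min_present minimum fraction of clock probes required per
#'   sample before flagging (default 0.8).
#' @return data.frame `sample_id`, `dnam_age`, `prop_probes_present`,
#'   `low_confidence`.
#' @export
apply_clock <- function(beta, clock, min_present = 0.8) {
  stopifnot(inherits(clock, "clock_model"))
  ids <- names(clock$coefficients)
  present <- ids %in% rownames(beta)
  if (!any(present))
    warning("apply_clock: no clock probes found in the matrix")
  sub <- matrix(NA_real_, length(ids), ncol(beta),
                dimnames = list(ids, colnames(beta)))
  if (any(present)) sub[ids[present], ] <- beta[ids[present], , drop = FALSE]
  probe_mean <- rowMeans(sub, na.rm = TRUE)
  probe_mean[is.nan(probe_mean)] <- 0.5
  prop_present <- colMeans(!is.na(sub))
  imput <- is.na(sub)
  if (any(imput)) sub[imput] <- probe_mean[row(sub)[imput]]
  pred <- clock$intercept + drop(crossprod(sub, clock$coefficients))
  age <- if (clock$age_transform == "horvath") .horvath_anti(pred) else pred
  data.frame(sample_id = colnames(beta) %||% sprintf("S%d", seq_len(ncol(beta))),
             dnam_age = age, prop_probes_present = prop_present,
             low_confidence = prop_present < min_present,
             stringsAsFactors = FALSE, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Age acceleration as residuals of DNAm age on chronological age
#'
#' Residuals from the OLS regression of predicted epigenetic age on
#' chronological age ("Acceleration Diff"); mean zero by construction.
#'
#' @param dnam_age predicted ages.
#' @param chron_age chronological ages, same length (n >= 3).
#' @return numeric residual vector.
#' @export
age_acceleration <- function(dnam_age, chron_age) {
  stopifnot(length(dnam_age) == length(chron_age), length(dnam_age) >= 3L)
  if (sd(chron_age) < 1e-12)
    stop("age_acceleration: chronological age is constant; slope undefined",
         call. = FALSE)
  stats::lm(dnam_age ~ chron_age)$residuals
}

#' Standardized group difference in age acceleration
#'
#' Cohen's d (pooled-SD standardized mean difference, case minus control)
#' with its large-sample standard error, ready for
#' [random_effects_meta()].
#'
#' @param residuals age-acceleration residuals.
#' @param group per-sample labels; `case_label` defines cases.
#' @param case_label default `"case"`.
#' @return list `smd`, `se`, `mean_diff`, `n_case`, `n_control`.
#' @export
group_acceleration_diff <- function(residuals, group, case_label = "case") {
  a <- residuals[group == case_label]
  b <- residuals[group != case_label]
  if (length(a) < 2L || length(b) < 2L)
    stop("group_acceleration_diff: both groups need n >= 2", call. = FALSE)
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2))
  d <- if (sp < 1e-12) 0 else (mean(a) - mean(b)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  list(smd = d, se = se, mean_diff = mean(a) - mean(b),
       n_case = n1, n_control = n2)
}
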