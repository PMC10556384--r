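#' Simulation configuration for synthetic methylation cohorts
#'
#' Builds and validates the parameter set driving [generate_cohort()]. The
#' defaults describe a modest array subset: 5000 probes over 5 chromosomes,
#' 30 cases and 30 controls, a low rate of stochastic epigenetic mutations
#' (SEMs) in controls elevated 2.5-fold in cases, and one injected
#' 11-probe epivariation per case.
#'
#' @param n_probes number of probes on the synthetic array.
#' @param n_chromosomes number of chromosomes probes are split across.
#' @param probes_per_gene consecutive probes sharing one synthetic gene.
#' @param n_cases,n_controls group sizes.
#' @param n_studies number of studies for [generate_studies()].
#' @param dmp_fraction fraction of probes given a true group effect.
#' @param dmp_effect beta-scale shift applied to cases at those probes.
#' @param sem_rate_control per-probe SEM probability in controls.
#' @param sem_rate_ratio multiplier applied to that rate in cases.
#' @param epivar_per_case injected SEM-enriched regions per case sample.
#' @param epivar_width probes per injected region (default 11).
#' @param batch_shift_sd SD of per-probe, per-batch beta-scale shifts.
#' @param deletion_runs number of injected detection-failure runs.
#' @param deletion_run_length probes per injected failure run.
#' @param noise_sd per-sample noise SD on the M-value (log2 odds) scale.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_probes = 5000, n_chromosomes = 5, probes_per_gene = 10,
                       n_cases = 30, n_controls = 30, n_studies = 3,
                       dmp_fraction = 0.02, dmp_effect = 0.08,
                       sem_rate_control = 5e-4, sem_rate_ratio = 2.5,
                       epivar_per_case = 1, epivar_width = 11,
                       batch_shift_sd = 0.01, deletion_runs = 2,
                       deletion_run_length = 8, noise_sd = 0.3, seed = 1L) {
  cfg <- list(
    n_probes = as.integer(n_probes), n_chromosomes = as.integer(n_chromosomes),
    probes_per_gene = as.integer(probes_per_gene),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_studies = as.integer(n_studies),
    dmp_fraction = dmp_fraction, dmp_effect = dmp_effect,
    sem_rate_control = sem_rate_control, sem_rate_ratio = sem_rate_ratio,
    epivar_per_case = as.integer(epivar_per_case),
    epivar_width = as.integer(epivar_width),
    batch_shift_sd = batch_shift_sd,
    deletion_runs = as.integer(deletion_runs),
    deletion_run_length = as.integer(deletion_run_length),
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  counts <- c("n_probes", "n_chromosomes", "probes_per_gene", "n_cases",
              "n_controls", "n_studies", "epivar_per_case", "epivar_width",
              "deletion_runs", "deletion_run_length")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0L)
      stop("sim_config: '", f, "' must be a non-negative count", call. = FALSE)
  }
  if (cfg$n_chromosomes < 1L) stop("sim_config: need >= 1 chromosome", call. = FALSE)
  if (cfg$probes_per_gene < 1L) stop("sim_config: probes_per_gene must be >= 1", call. = FALSE)
  if (cfg$dmp_fraction < 0 || cfg$dmp_fraction > 1)
    stop("sim_config: dmp_fraction must lie in [0,1]", call. = FALSE)
  if (cfg$sem_rate_control < 0 || cfg$sem_rate_control > 1 || cfg$sem_rate_ratio < 0)
    stop("sim_config: SEM rates must be non-negative probabilities", call. = FALSE)
  if (cfg$sem_rate_control * cfg$sem_rate_ratio > 1)
    stop("sim_config: sem_rate_control * sem_rate_ratio exceeds 1", call. = FALSE)
  if (cfg$n_probes < cfg$epivar_width)
    stop("sim_config: n_probes must be >= epivar_width", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("sim_config: noise_sd must be positive", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic probe annotation
#'
#' Probes are assigned to chromosomes in contiguous near-equal blocks, with
#' strictly increasing positions within each chromosome and consecutive
#' runs of `probes_per_gene` probes sharing one synthetic gene symbol.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `probe_id`, `chrom`, `pos`, `gene`,
#'   sorted by (chrom, pos); this ordering is the canonical probe order
#'   used by all downstream window and region operations.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$n_probes
  base <- p %/% config$n_chromosomes
  extra <- p %% config$n_chromosomes
  sizes <- rep(base, config$n_chromosomes) + c(rep(1L, extra), rep(0L, config$n_chromosomes - extra))
  chrom <- rep(sprintf("chr%d", seq_len(config$n_chromosomes)), times = sizes)
  pos <- unlist(lapply(sizes, function(n) {
    if (n == 0L) return(integer(0))
    cumsum(sample(50:2000, n, replace = TRUE)) + 10000L
  }), use.names = FALSE)
  gene <- sprintf("GENE%05d", (seq_len(p) - 1L) %/% config$probes_per_gene + 1L)
  data.frame(
    probe_id = sprintf("cg%08d", seq_len(p)),
    chrom = chrom, pos = as.integer(pos), gene = gene,
    stringsAsFactors = FALSE
  )
}

## truncated normal via inverse-CDF: per-sample noise has bounded tails so
## that injected outliers are the only extreme outliers in the cohort
.rtnorm <- function(n, sd, limit = 2) {
  qnorm(runif(n, pnorm(-limit), pnorm(limit))) * sd
}

## place an outlier >= 6 control IQRs from the control median, preferring the
## randomly drawn direction but flipping (or clipping) when the unit interval
## leaves no room on that side
.inject_outliers <- function(med, iqr, dir, mult = 8) {
  off <- mult * pmax(iqr, 1e-4)
  up <- med + off
  dn <- med - off
  up_ok <- up <= 1 - 1e-6
  dn_ok <- dn >= 1e-6
  use_up <- (dir > 0 & up_ok) | (dir <= 0 & !dn_ok & up_ok)
  use_dn <- !use_up & ((dir <= 0 & dn_ok) | (dir > 0 & !up_ok & dn_ok))
  val <- ifelse(use_up, up, ifelse(use_dn, dn, ifelse(med < 0.5, 1 - 1e-6, 1e-6)))
  dir_out <- ifelse(val > med, "hyper", "hypo")
  list(value = clip01(val), direction = dir_out)
}

#' Generate a synthetic case/control methylation cohort with ground truth
#'
#' Produces a beta-value matrix emulating the statistical structure of
#' array methylation data: probe baselines from a bimodal mixture
#' concentrated near 0.1 and 0.9 with a minority intermediate component,
#' per-sample noise on the M-value scale, group effects at a subset of
#' probes, cell-composition-linked probes, per-batch shifts, rare
#' per-probe SEM outliers (rate elevated in cases), contiguous injected
#' epivariation runs private to cases, and runs of failed detection
#' p-values emulating homozygous deletions. Injected SEM and epivariation
#' values are placed at least 6 control IQRs away from the control median
#' of their probe, so a k = 3 interquartile caller can recover them.
#'
#' @param config a [sim_config()].
#' @param study study identifier recorded in the sample sheet.
#' @return a list of class `meth_cohort` with elements `beta` (probes x
#'   samples matrix), `sheet` (sample sheet data.frame), `annotation`,
#'   `detp` (detection p-value matrix), `truth` (ground-truth record) and
#'   `config`.
#' @export
generate_cohort <- function(config, study = "study1") {
  stopifnot(inherits(config, "sim_config"))
  ann <- generate_annotation(config)
  set.seed(config$seed + 1L)
  p <- config$n_probes
  n <- config$n_cases + config$n_controls
  if (n < 2L) stop("generate_cohort: need at least two samples", call. = FALSE)

  group <- c(rep("case", config$n_cases), rep("control", config$n_controls))
  sample_id <- sprintf("%s_S%03d", study, seq_len(n))
  age <- round(runif(n, 4, 45), 1)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  batch <- sample(sprintf("%s_b%d", study, 1:2), n, replace = TRUE)
  ## cell fractions: 5 types, mildly group-linked first component
  cf <- matrix(stats::rgamma(n * 5, shape = c(8, 5, 3, 2, 1)), n, 5, byrow = TRUE)
  cf[group == "case", 1] <- cf[group == "case", 1] * 1.15
  cf <- cf / rowSums(cf)
  colnames(cf) <- sprintf("cell%d", 1:5)

  ## baseline: bimodal probe means on the M scale
  comp <- sample(1:3, p, replace = TRUE, prob = c(0.425, 0.425, 0.15))
  mu <- numeric(p)
  mu[comp == 1] <- rnorm(sum(comp == 1), logit2(0.1), 0.5)
  mu[comp == 2] <- rnorm(sum(comp == 2), logit2(0.9), 0.5)
  mu[comp == 3] <- rnorm(sum(comp == 3), 0, 1)
  m <- matrix(.rtnorm(p * n, config$noise_sd), p, n) + mu

  ## cell-composition effect at 5% of probes
  n_cell_probes <- max(0L, round(0.05 * p))
  cell_probes <- sample.int(p, n_cell_probes)
  if (n_cell_probes > 0L) {
    gamma <- rnorm(n_cell_probes, 0, 2)
    ## clamp the standardized fraction so the cell effect, like the noise,
    ## has bounded tails and cannot mimic an injected outlier
    zcf <- pmin(pmax((cf[, 1] - mean(cf[, 1])) / sd(cf[, 1]), -2), 2)
    m[cell_probes, ] <- m[cell_probes, ] + outer(gamma * 0.05, zcf)
  }

  beta <- clip01(expit2(m))

  ## true differential probes: beta-scale shift in cases
  n_dmp <- round(config$dmp_fraction * p)
  dmp_idx <- sort(sample.int(p, n_dmp))
  if (n_dmp > 0L) {
    sgn <- sample(c(-1, 1), n_dmp, replace = TRUE)
    beta[dmp_idx, group == "case"] <- clip01(
      beta[dmp_idx, group == "case"] + sgn * config$dmp_effect)
  }

  ## batch shifts on the beta scale
  for (b in unique(batch)) {
    shift <- rnorm(p, 0, config$batch_shift_sd)
    beta[, batch == b] <- clip01(beta[, batch == b] + shift)
  }

  ## select SEM cells, then compute control stats excluding those cells
  rate <- ifelse(group == "case",
                 config$sem_rate_control * config$sem_rate_ratio,
                 config$sem_rate_control)
  sem_mask <- matrix(FALSE, p, n)
  for (j in seq_len(n)) {
    k <- rbinom(1L, p, rate[j])
    if (k > 0L) sem_mask[sample.int(p, k), j] <- TRUE
  }
  beta_ref <- beta[, group == "control", drop = FALSE]
  beta_ref[sem_mask[, group == "control", drop = FALSE]] <- NA
  qs <- row_quantiles(beta_ref, c(0.25, 0.5, 0.75))
  med <- qs[, 2]
  iqr <- qs[, 3] - qs[, 1]

  sem_positions <- data.frame(sample_id = character(0), probe_id = character(0),
                              direction = character(0), stringsAsFactors = FALSE)
  if (any(sem_mask)) {
    cells <- which(sem_mask, arr.ind = TRUE)
    inj <- .inject_outliers(med[cells[, 1]], iqr[cells[, 1]],
                            sample(c(-1, 1), nrow(cells), replace = TRUE))
    ## which(arr.ind = TRUE) enumerates column-major, matching beta[sem_mask]
    beta[sem_mask] <- inj$value
    sem_positions <- data.frame(
      sample_id = sample_id[cells[, 2]],
      probe_id = ann$probe_id[cells[, 1]],
      direction = inj$direction, stringsAsFactors = FALSE)
  }

  ## epivariations: runs of epivar_width consecutive outliers in cases
  chrom_rle <- rle(ann$chrom)
  chrom_end <- cumsum(chrom_rle$lengths)
  chrom_start <- chrom_end - chrom_rle$lengths + 1L
  eligible <- which(chrom_rle$lengths >= config$epivar_width)
  epivar_regions <- data.frame(sample_id = character(0), chrom = character(0),
                               start_index = integer(0), end_index = integer(0),
                               direction = character(0), stringsAsFactors = FALSE)
  if (config$epivar_per_case > 0L && config$n_cases > 0L) {
    if (!length(eligible))
      stop("generate_cohort: no chromosome can hold an epivariation of width ",
           config$epivar_width, call. = FALSE)
    for (j in which(group == "case")) {
      taken <- integer(0)
      for (r in seq_len(config$epivar_per_case)) {
        ok <- FALSE
        for (try in 1:100) {
          ci <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
          s <- chrom_start[ci] +
            sample.int(chrom_rle$lengths[ci] - config$epivar_width + 1L, 1L) - 1L
          idx <- s:(s + config$epivar_width - 1L)
          if (!any(idx %in% taken)) { ok <- TRUE; break }
        }
        if (!ok) stop("generate_cohort: failed to place epivariation after 100 tries",
                      call. = FALSE)
        taken <- c(taken, idx)
        dir <- sample(c(-1, 1), 1L)
        inj <- .inject_outliers(med[idx], iqr[idx], rep(dir, length(idx)))
        beta[idx, j] <- inj$value
        epivar_regions <- rbind(epivar_regions, data.frame(
          sample_id = sample_id[j], chrom = ann$chrom[s],
          start_index = s, end_index = s + config$epivar_width - 1L,
          direction = if (dir > 0) "hyper" else "hypo",
          stringsAsFactors = FALSE))
      }
    }
  }

  ## detection p-values: tiny everywhere, failed runs emulate deletions
  detp <- matrix(runif(p * n, 0, 0.005), p, n)
  deletion_regions <- data.frame(sample_id = character(0), chrom = character(0),
                                 start_index = integer(0), end_index = integer(0),
                                 stringsAsFactors = FALSE)
  if (config$deletion_runs > 0L) {
    elig_del <- which(chrom_rle$lengths >= config$deletion_run_length)
    if (!length(elig_del))
      stop("generate_cohort: no chromosome can hold a deletion run", call. = FALSE)
    for (r in seq_len(config$deletion_runs)) {
      j <- sample.int(n, 1L)
      for (try in 1:100) {
        ci <- if (length(elig_del) == 1L) elig_del else sample(elig_del, 1L)
        s <- chrom_start[ci] +
          sample.int(chrom_rle$lengths[ci] - config$deletion_run_length + 1L, 1L) - 1L
        idx <- s:(s + config$deletion_run_length - 1L)
        prev <- deletion_regions[deletion_regions$sample_id == sample_id[j], ]
        ## keep runs in one sample separated so flagged regions stay maximal
        clash <- nrow(prev) && any(idx %in% unlist(Map(seq, prev$start_index - 1L,
                                                       prev$end_index + 1L)))
        if (!clash) break
      }
      detp[idx, j] <- runif(length(idx), 0.05, 0.9)
      deletion_regions <- rbind(deletion_regions, data.frame(
        sample_id = sample_id[j], chrom = ann$chrom[s],
        start_index = s, end_index = s + config$deletion_run_length - 1L,
        stringsAsFactors = FALSE))
    }
  }

  dimnames(beta) <- list(ann$probe_id, sample_id)
  dimnames(detp) <- list(ann$probe_id, sample_id)
  sheet <- data.frame(sample_id = sample_id, group = group, age = age,
                      sex = sex, batch = batch, study = study,
                      stringsAsFactors = FALSE)
  sheet <- cbind(sheet, as.data.frame(cf))

  out <- list(
    beta = beta, sheet = sheet, annotation = ann, detp = detp,
    truth = list(dmp_probe_ids = ann$probe_id[dmp_idx],
                 sem_positions = sem_positions,
                 epivar_regions = epivar_regions,
                 deletion_regions = deletion_regions),
    config = config)
  class(out) <- "meth_cohort"
  out
}

#' Generate a multi-study bundle of synthetic cohorts
#'
#' Studies share the simulation parameters and differ only by a seed
#' offset, study identifier and batch labels.
#'
#' @param config a [sim_config()]; `config$n_studies` cohorts are made.
#' @return list of `meth_cohort` objects named by study id.
#' @export
generate_studies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  out <- lapply(seq_len(config$n_studies), function(i) {
    ci <- config
    ci$seed <- config$seed + 1000L * (i - 1L)
    generate_cohort(ci, study = sprintf("study%d", i))
  })
  names(out) <- sprintf("study%d", seq_len(config$n_studies))
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Beta matrix and detection p-values as TSV (probes as rows, first column
#' `probe_id`), sample sheet as CSV, annotation as TSV, ground truth as
#' JSON.
#'
#' @param cohort a `meth_cohort` from [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "meth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             sheet = file.path(dir, "samples.csv"),
             annotation = file.path(dir, "annotation.tsv"),
             detp = file.path(dir, "detection_p.tsv"),
             truth = file.path(dir, "truth.json"))
  write_beta(cohort$beta, paths["beta"])
  write.csv(cohort$sheet, paths["sheet"], row.names = FALSE, quote = FALSE)
  write.table(cohort$annotation, paths["annotation"], sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_beta(cohort$detp, paths["detp"])
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
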