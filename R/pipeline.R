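#' Build and validate a pipeline configuration
#'
#' Defaults mirror the package's declared analysis conventions: SEM
#' multiplier k = 3, 11-probe windows, per-sample Bonferroni at alpha =
#' 0.05, detection threshold 0.01, deletion runs of >= 3 failed probes,
#' two PLS components from cell fractions, age as a covariate. The
#' quantile-normalization and batch-alignment stand-ins are toggles,
#' off by default, and logged when used.
#'
#' @param studies named list: study -> list of paths (`beta`, `sheet`,
#'   `annotation`, `detp`). May be `NULL` when cohorts are passed to
#'   [run_pipeline()] directly.
#' @param out_dir output directory.
#' @param k SEM IQR multiplier.
#' @param n_window epivariation window width (>= 2).
#' @param alpha epivariation significance level.
#' @param detp_threshold detection-p failure threshold.
#' @param min_run minimum failed-probe run for deletion flagging.
#' @param covariates sample-sheet columns to adjust for.
#' @param n_pls PLS components extracted from cell fractions (0 = none).
#' @param normalize,batch_adjust stage toggles for the normalization and
#'   batch stand-ins.
#' @param stages character vector of enabled stages, any of
#'   `"ewas"`, `"sem"`, `"epivar"`, `"prioritize"`, `"clocks"`.
#' @param clock optional path to a clock coefficient CSV (JSON sidecar
#'   alongside) for the clocks stage.
#' @param known_lists named list of gene-list file paths.
#' @param phenotype_genes path to a phenotype gene list.
#' @param expression path to an expression TSV (column `gene` + regions).
#' @param seed integer seed propagated to all stochastic stages.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(studies = NULL, out_dir = tempfile("methdrift_"),
                            k = 3, n_window = 11L, alpha = 0.05,
                            detp_threshold = 0.01, min_run = 3L,
                            covariates = "age", n_pls = 2L,
                            normalize = FALSE, batch_adjust = FALSE,
                            stages = c("ewas", "sem", "epivar", "prioritize"),
                            clock = NULL, known_lists = list(),
                            phenotype_genes = NULL, expression = NULL,
                            seed = 1L) {
  if (k <= 0) stop("pipeline_config: k must be > 0", call. = FALSE)
  if (n_window < 2L) stop("pipeline_config: n_window must be >= 2", call. = FALSE)
  bad <- setdiff(stages, c("ewas", "sem", "epivar", "prioritize", "clocks"))
  if (length(bad))
    stop("pipeline_config: unknown stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(studies = studies, out_dir = out_dir, k = k,
                 n_window = as.integer(n_window), alpha = alpha,
                 detp_threshold = detp_threshold, min_run = as.integer(min_run),
                 covariates = covariates, n_pls = as.integer(n_pls),
                 normalize = normalize, batch_adjust = batch_adjust,
                 stages = stages, clock = clock, known_lists = known_lists,
                 phenotype_genes = phenotype_genes, expression = expression,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  json <- jsonlite::toJSON(x[order(names(x))], auto_unbox = TRUE, digits = NA,
                           null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

.load_study <- function(paths) {
  list(beta = read_beta(paths$beta),
       sheet = read_sample_sheet(paths$sheet),
       annotation = read_annotation(paths$annotation),
       detp = if (!is.null(paths$detp)) read_beta(paths$detp, check_range = FALSE))
}

#' Run the full multi-level analysis pipeline
#'
#' Per study: detection masking and deletion flagging, optional
#' normalization/batch alignment, PLS covariate extraction, per-probe
#' EWAS with gene-level combination, SEM calling against the control
#' reference with the logistic drift model, and the epivariation window
#' scan. Across studies: weighted-Z meta-analysis of site p-values,
#' random-effects meta-analysis of drift log-odds-ratios (and of age
#' acceleration differences when a clock is configured), cross-study
#' gene overlap and heuristic prioritization. All outputs are written
#' under `config$out_dir` together with a manifest JSON recording the
#' config hash, seed and md5 of every file; rerunning with an identical
#' config reproduces the manifest byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param cohorts optional named list of in-memory `meth_cohort`-like
#'   lists (elements `beta`, `sheet`, `annotation`, `detp`); when absent,
#'   studies are read from `config$studies` paths.
#' @return invisibly, a result bundle: per-study results, meta results,
#'   overlap, evidence and the manifest path.
#' @export
run_pipeline <- function(config, cohorts = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  if (is.null(cohorts)) {
    if (is.null(config$studies))
      stop("run_pipeline: no studies configured", call. = FALSE)
    cohorts <- lapply(config$studies, .load_study)
  }
  studies <- names(cohorts)
  if (is.null(studies) || any(!nzchar(studies)))
    stop("run_pipeline: cohorts must be a named list", call. = FALSE)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(obj, name, writer = NULL) {
    path <- file.path(out_dir, name)
    if (is.null(writer)) {
      write.table(obj, path, sep = "\t", row.names = FALSE, quote = FALSE)
    } else writer(obj, path)
    files <<- c(files, path)
    path
  }

  per_study <- list()
  for (s in studies) {
    stage <- sprintf("preprocess[%s]", s)
    res <- tryCatch({
      co <- cohorts[[s]]
      beta <- co$beta
      ann <- co$annotation
      dels <- NULL
      if (!is.null(co$detp)) {
        beta <- mask_failed(beta, co$detp, config$detp_threshold)
        dels <- flag_deletion_regions(co$detp, ann, config$detp_threshold,
                                      config$min_run)
        emit(dels, sprintf("%s_deletions.tsv", s))
      }
      if (isTRUE(config$normalize)) beta <- normalize_quantile(beta, quiet = TRUE)
      if (isTRUE(config$batch_adjust) && "batch" %in% names(co$sheet))
        beta <- adjust_batch(beta, co$sheet$batch, quiet = TRUE)
      cell_cols <- grep("^cell", names(co$sheet), value = TRUE)
      pls <- NULL
      if (config$n_pls > 0L && length(cell_cols) >= config$n_pls &&
          length(unique(co$sheet$group)) == 2L) {
        pls <- pls_components(as.matrix(co$sheet[cell_cols]), co$sheet$group,
                              config$n_pls)
      }
      list(beta = beta, sheet = co$sheet, annotation = ann, dels = dels,
           pls = pls)
    }, error = function(e)
      stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))

    if ("ewas" %in% config$stages) {
      stage <- sprintf("ewas[%s]", s)
      res$ewas <- tryCatch({
        covs <- intersect(config$covariates, names(res$sheet))
        design <- ewas_design(res$sheet, covs, extra = res$pls)
        site <- fit_site_models(res$beta, design)
        emit(site, sprintf("%s_ewas_sites.tsv", s))
        region <- fit_region_models(site, res$annotation)
        emit(region, sprintf("%s_ewas_regions.tsv", s))
        emit(volcano_data(res$beta, res$sheet$group, site),
             sprintf("%s_volcano.tsv", s))
        list(site = site, region = region)
      }, error = function(e)
        stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    }

    if ("clocks" %in% config$stages && !is.null(config$clock)) {
      stage <- sprintf("clocks[%s]", s)
      res$clock <- tryCatch({
        clk <- read_clock(config$clock)
        ages <- apply_clock(res$beta, clk)
        accel <- age_acceleration(ages$dnam_age, res$sheet$age)
        diff <- group_acceleration_diff(accel, res$sheet$group)
        ages$acceleration <- accel
        emit(ages, sprintf("%s_clock.tsv", s))
        list(ages = ages, diff = diff)
      }, error = function(e)
        stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    }

    if ("sem" %in% config$stages) {
      stage <- sprintf("sem[%s]", s)
      res$sem <- tryCatch({
        ctrl <- res$beta[, res$sheet$group != "case", drop = FALSE]
        ref <- build_reference(ctrl, k = config$k)
        callsets <- call_sems_matrix(res$beta, ref, res$dels, res$annotation)
        bt <- burden_table(callsets)
        emit(bt, sprintf("%s_burden.tsv", s))
        calls <- do.call(rbind, lapply(callsets, function(cs) {
          if (!nrow(cs$calls)) return(NULL)
          idx <- match(cs$calls$probe_id, res$annotation$probe_id)
          data.frame(sample_id = cs$sample_id, probe_id = cs$calls$probe_id,
                     chrom = res$annotation$chrom[idx],
                     pos = res$annotation$pos[idx],
                     direction = cs$calls$direction, beta = cs$calls$beta,
                     lower = ref$lower[idx], upper = ref$upper[idx],
                     stringsAsFactors = FALSE)
        }))
        if (is.null(calls))
          calls <- data.frame(sample_id = character(0), probe_id = character(0),
                              chrom = character(0), pos = integer(0),
                              direction = character(0), beta = numeric(0),
                              lower = numeric(0), upper = numeric(0))
        emit(calls, sprintf("%s_sem_calls.tsv", s))
        covs <- intersect(config$covariates, names(res$sheet))
        model <- fit_burden_model(callsets, res$sheet, covs, extra = res$pls)
        list(reference = ref, callsets = callsets, burden = bt, model = model)
      }, error = function(e)
        stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    }

    if ("epivar" %in% config$stages && !is.null(res$sem)) {
      stage <- sprintf("epivar[%s]", s)
      res$epivar <- tryCatch({
        regions <- scan_cohort(res$sem$callsets, res$annotation,
                               config$n_window, config$alpha)
        emit(regions, sprintf("%s_epivar_regions.tsv", s))
        emit(regions, sprintf("%s_epivar_regions.bed", s), write_regions_bed)
        regions
      }, error = function(e)
        stop("run_pipeline: stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    }
    per_study[[s]] <- res
  }

  meta <- list()
  if (length(studies) >= 2L) {
    if ("ewas" %in% config$stages) {
      study_n <- vapply(per_study, function(r) nrow(r$sheet), numeric(1))
      meta$sites <- meta_sites(lapply(per_study, function(r) r$ewas$site), study_n)
      emit(meta$sites, "meta_sites.tsv")
    }
    if ("sem" %in% config$stages) {
      ors <- vapply(per_study, function(r) r$sem$model$log_or, numeric(1))
      ses <- vapply(per_study, function(r) r$sem$model$se, numeric(1))
      meta$burden <- random_effects_meta(ors, ses)
      meta$burden_forest <- forest_data(ors, ses, labels = studies,
                                        exp_scale = TRUE)
      emit(meta$burden_forest, "meta_burden_forest.tsv")
    }
    if ("clocks" %in% config$stages && !is.null(per_study[[1]]$clock)) {
      sm <- vapply(per_study, function(r) r$clock$diff$smd, numeric(1))
      se <- vapply(per_study, function(r) r$clock$diff$se, numeric(1))
      meta$acceleration <- random_effects_meta(sm, se)
      meta$acceleration_forest <- forest_data(sm, se, labels = studies)
      emit(meta$acceleration_forest, "meta_acceleration_forest.tsv")
    }
  }

  overlap <- NULL
  evidence <- NULL
  if ("epivar" %in% config$stages && "prioritize" %in% config$stages &&
      length(studies) >= 1L) {
    overlap <- cross_overlap(lapply(per_study, `[[`, "epivar"),
                             lapply(per_study, `[[`, "sheet"))
    emit(overlap$upset, "overlap_upset.tsv")
    known <- lapply(config$known_lists, read_gene_list)
    phen <- if (!is.null(config$phenotype_genes))
      read_gene_list(config$phenotype_genes) else character(0)
    expr <- if (!is.null(config$expression))
      read.delim(config$expression, stringsAsFactors = FALSE) else NULL
    evidence <- build_evidence(overlap, known, expr, phen)
    emit(evidence, "gene_evidence.tsv")
  }

  manifest <- list(
    package = "methdrift",
    config_hash = .config_hash(config),
    seed = config$seed,
    studies = as.list(studies),
    files = lapply(sort(files), function(f)
      list(name = basename(f), md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(per_study = per_study, meta = meta, overlap = overlap,
                 evidence = evidence, manifest = manifest_path,
                 out_dir = out_dir))
}
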