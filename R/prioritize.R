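#' Assemble per-gene evidence for prioritization
#'
#' For every case-unique epivariation gene, gathers: the number of
#' distinct case samples carrying it, number of studies, membership in
#' user-supplied known-gene lists, brain expression (mean over the
#' supplied expression table's regions above the cross-gene median) and
#' phenotype-set membership, then computes the additive priority score
#'
#' score = n_case_samples + n_studies + 2*phenotype_hit +
#'         2*brain_expressed + 1*in_any_known_list
#'
#' (weights configurable). Gene symbols are matched case-insensitively.
#'
#' @param overlap report from [cross_overlap()].
#' @param known_lists named list of character gene vectors (may be empty).
#' @param expression data.frame, first column `gene`, remaining columns
#'   per-region mean expression (optional).
#' @param phenotype_genes character vector of phenotype-associated genes
#'   (optional).
#' @param weights named numeric vector with entries `case_samples`,
#'   `studies`, `phenotype`, `expression`, `known`.
#' @return data.frame sorted by decreasing `priority_score`, one row per
#'   case-unique gene.
#' @export
build_evidence <- function(overlap, known_lists = list(), expression = NULL,
                           phenotype_genes = character(0),
                           weights = c(case_samples = 1, studies = 1,
                                       phenotype = 2, expression = 2, known = 1)) {
  genes <- rownames(overlap$membership)
  if (!length(genes))
    return(data.frame(gene = character(0), n_case_samples = integer(0),
                      n_studies = integer(0), in_known = logical(0),
                      brain_expressed = logical(0), phenotype_hit = logical(0),
                      priority_score = numeric(0), stringsAsFactors = FALSE))
  n_studies <- rowSums(overlap$membership)
  n_cases <- overlap$n_case_samples[match(toupper(genes),
                                          toupper(names(overlap$n_case_samples)))]
  n_cases[is.na(n_cases)] <- 0L
  up <- toupper(genes)
  in_known <- rep(FALSE, length(genes))
  known_cols <- list()
  for (nm in names(known_lists)) {
    hit <- up %in% toupper(known_lists[[nm]])
    known_cols[[paste0("known_", nm)]] <- hit
    in_known <- in_known | hit
  }
  brain_expressed <- rep(FALSE, length(genes))
  if (!is.null(expression) && nrow(expression)) {
    reg_cols <- setdiff(names(expression), "gene")
    mean_expr <- rowMeans(as.matrix(expression[, reg_cols, drop = FALSE]),
                          na.rm = TRUE)
    cutoff <- median(mean_expr, na.rm = TRUE)
    idx <- match(up, toupper(expression$gene))
    brain_expressed <- !is.na(idx) & mean_expr[idx] > cutoff
    if (anyNA(idx))
      message("build_evidence: ", sum(is.na(idx)),
              " gene(s) missing from the expression table; treated as not expressed")
  }
  phenotype_hit <- up %in% toupper(phenotype_genes)
  score <- weights[["case_samples"]] * n_cases +
    weights[["studies"]] * n_studies +
    weights[["phenotype"]] * phenotype_hit +
    weights[["expression"]] * brain_expressed +
    weights[["known"]] * in_known
  out <- data.frame(gene = genes, n_case_samples = as.integer(n_cases),
                    n_studies = as.integer(n_studies), in_known = in_known,
                    brain_expressed = brain_expressed,
                    phenotype_hit = phenotype_hit,
                    priority_score = as.numeric(score),
                    stringsAsFactors = FALSE)
  for (nm in names(known_cols)) out[[nm]] <- known_cols[[nm]]
  out <- out[order(-out$priority_score, out$gene), ]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation test
#'
#' p = P(X >= overlap) with X ~ Hypergeometric(|universe|, |gene_set|,
#' |hit_genes|); shares the upper-tail kernel of [window_pvalue()]. A
#' generic stand-in for web-based enrichment services.
#'
#' @param hit_genes character vector of genes of interest (subset of
#'   `universe`).
#' @param gene_set character vector (subset of `universe`).
#' @param universe character vector of all considered genes (non-empty).
#' @return list `overlap` (count), `overlap_genes`, `p`.
#' @export
ora_test <- function(hit_genes, gene_set, universe) {
  if (!length(universe)) stop("ora_test: empty universe", call. = FALSE)
  universe <- unique(toupper(universe))
  hits <- unique(toupper(hit_genes))
  set <- unique(toupper(gene_set))
  if (!all(hits %in% universe) || !all(set %in% universe))
    stop("ora_test: hit_genes and gene_set must be subsets of the universe",
         call. = FALSE)
  ov <- intersect(hits, set)
  p <- window_pvalue(length(universe), length(set), length(hits), length(ov))
  list(overlap = length(ov), overlap_genes = ov, p = p)
}

#' Intersections of case-unique genes with known-gene lists
#'
#' Per-list overlaps plus all multi-list intersection sizes and members
#' (Venn counts).
#'
#' @param case_unique_genes character vector.
#' @param lists named list of character gene vectors.
#' @return list with `per_list` (data.frame `list`, `n_overlap`,
#'   `genes`), and `venn` (data.frame `combination`, `n`, `genes` over
#'   all non-empty list combinations).
#' @export
intersect_known <- function(case_unique_genes, lists) {
  cu <- unique(toupper(case_unique_genes))
  per_list <- do.call(rbind, lapply(names(lists), function(nm) {
    ov <- intersect(cu, toupper(lists[[nm]]))
    data.frame(list = nm, n_overlap = length(ov),
               genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_list))
    per_list <- data.frame(list = character(0), n_overlap = integer(0),
                           genes = character(0), stringsAsFactors = FALSE)
  nm <- names(lists)
  venn <- list()
  if (length(nm)) {
    for (sz in seq_along(nm)) {
      combos <- utils::combn(nm, sz, simplify = FALSE)
      for (cb in combos) {
        ov <- cu
        for (l in cb) ov <- intersect(ov, toupper(lists[[l]]))
        venn[[length(venn) + 1L]] <- data.frame(
          combination = paste(cb, collapse = "&"), n = length(ov),
          genes = paste(sort(ov), collapse = ";"), stringsAsFactors = FALSE)
      }
    }
  }
  venn <- if (length(venn)) do.call(rbind, venn) else
    data.frame(combination = character(0), n = integer(0),
               genes = character(0), stringsAsFactors = FALSE)
  list(per_list = per_list, venn = venn)
}
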