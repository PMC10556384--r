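#' Upper-tail cumulative hypergeometric window p-value
#'
#' Probability of observing at least `k` SEMs in a window of `n` probes
#' when the sample carries `K` SEMs among `N` callable probes:
#' P(X >= k) with X ~ Hypergeometric(N, K, n), upper tail inclusive.
#' Vectorized over all arguments.
#'
#' @param N total callable probes for the sample.
#' @param K total SEMs for the sample (K <= N).
#' @param n window size in probes (n <= N).
#' @param k SEM count in the window (0 <= k <= min(n, K)).
#' @return p-value(s) in (0, 1\].
#' @export
window_pvalue <- function(N, K, n, k) {
  if (any(N < 0) || any(K < 0) || any(n < 0) || any(k < 0))
    stop("window_pvalue: parameters must be non-negative", call. = FALSE)
  if (any(K > N) || any(n > N))
    stop("window_pvalue: need K <= N and n <= N", call. = FALSE)
  if (any(k > pmin(n, K)))
    stop("window_pvalue: k cannot exceed min(n, K)", call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Slide a fixed-width window over the genome and test SEM enrichment
#'
#' Every contiguous run of `n_window` probes on one chromosome (windows
#' slip by single sites and never span chromosomes) is tested for SEM
#' enrichment with [window_pvalue()], using the sample's genome-wide
#' callable-probe total N and SEM total K as the background. Windows with
#' zero SEMs have p = 1 and are omitted from the result; the total number
#' of windows scanned is kept as attribute `n_windows_total` for the
#' Bonferroni correction in [call_regions()].
#'
#' @param callset a `sem_callset` from [call_sems()].
#' @param annotation probe annotation sorted by (chrom, pos).
#' @param n_window window width in probes (default 11).
#' @return data.frame `sample_id`, `chrom`, `start_index`, `end_index`,
#'   `start_pos`, `end_pos`, `n_window`, `k_sem`, `p_hyper`, with
#'   attribute `n_windows_total` (and `N`, `K`).
#' @export
scan_sample <- function(callset, annotation, n_window = 11L) {
  stopifnot(inherits(callset, "sem_callset"), n_window >= 2L)
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      start_index = integer(0), end_index = integer(0),
                      start_pos = integer(0), end_pos = integer(0),
                      n_window = integer(0), k_sem = integer(0),
                      p_hyper = numeric(0), stringsAsFactors = FALSE)
  N <- callset$n_callable
  K <- callset$burden
  x <- as.integer(annotation$probe_id %in% callset$calls$probe_id)
  chrom_f <- factor(annotation$chrom, levels = unique(annotation$chrom))
  blocks <- split(seq_len(nrow(annotation)), chrom_f)
  total <- 0L
  rows <- list()
  for (blk in blocks) {
    L <- length(blk)
    if (L < n_window) {
      warning("scan_sample: chromosome '", annotation$chrom[blk[1]],
              "' has fewer than ", n_window, " probes; skipped")
      next
    }
    nw <- L - n_window + 1L
    total <- total + nw
    if (K == 0L) next
    cs <- c(0L, cumsum(x[blk]))
    kw <- cs[(n_window + 1L):(L + 1L)] - cs[1:nw]
    hit <- which(kw >= 1L)
    if (!length(hit)) next
    si <- blk[hit]
    ei <- blk[hit + n_window - 1L]
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = callset$sample_id, chrom = annotation$chrom[si],
      start_index = si, end_index = ei,
      start_pos = annotation$pos[si], end_pos = annotation$pos[ei],
      n_window = n_window, k_sem = kw[hit],
      p_hyper = window_pvalue(N, K, n_window, kw[hit]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "n_windows_total") <- total
  attr(out, "N") <- N
  attr(out, "K") <- K
  out
}

#' Call epivariation regions from significant windows
#'
#' Windows significant after a per-sample Bonferroni correction over all
#' scanned windows (p <= alpha / n_windows_total) are merged maximally:
#' windows sharing at least one probe or abutting in probe index form one
#' region. Region coordinates span the first to last probe; gene symbols
#' are collected from the annotation; the direction summary counts hyper
#' and hypo SEM calls inside the region when a callset is supplied.
#'
#' @param tests window table from [scan_sample()] (one sample).
#' @param annotation probe annotation sorted by (chrom, pos).
#' @param alpha significance level before correction (default 0.05).
#' @param correction only `"bonferroni_windows"` is implemented.
#' @param callset optional `sem_callset` for SEM counts and directions.
#' @param n_windows_total override for the number of windows tested
#'   (defaults to the attribute carried by `tests`).
#' @return data.frame `sample_id`, `chrom`, `start_index`, `end_index`,
#'   `start_pos`, `end_pos`, `n_probes`, `n_sems`, `min_window_p`,
#'   `n_hyper`, `n_hypo`, `genes` (semicolon-separated).
#' @export
call_regions <- function(tests, annotation, alpha = 0.05,
                         correction = "bonferroni_windows", callset = NULL,
                         n_windows_total = NULL) {
  correction <- match.arg(correction, "bonferroni_windows")
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      start_index = integer(0), end_index = integer(0),
                      start_pos = integer(0), end_pos = integer(0),
                      n_probes = integer(0), n_sems = integer(0),
                      min_window_p = numeric(0), n_hyper = integer(0),
                      n_hypo = integer(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(tests)) return(empty)
  if (is.null(n_windows_total)) n_windows_total <- attr(tests, "n_windows_total")
  if (is.null(n_windows_total)) n_windows_total <- nrow(tests)
  thr <- alpha / n_windows_total
  sig <- tests[tests$p_hyper <= thr, , drop = FALSE]
  if (!nrow(sig)) return(empty)
  sig <- sig[order(match(sig$chrom, unique(annotation$chrom)), sig$start_index), ]
  sem_idx <- if (!is.null(callset))
    match(callset$calls$probe_id, annotation$probe_id) else integer(0)
  out <- list()
  cur <- sig[1, ]
  cur_pmin <- cur$p_hyper
  flush <- function(cur, pmin) {
    idx <- cur$start_index:cur$end_index
    in_reg <- sem_idx[sem_idx %in% idx]
    dirs <- if (!is.null(callset))
      callset$calls$direction[match(in_reg, sem_idx)] else character(0)
    genes <- unique(annotation$gene[idx])
    genes <- genes[!is.na(genes) & genes != ""]
    data.frame(
      sample_id = cur$sample_id, chrom = cur$chrom,
      start_index = cur$start_index, end_index = cur$end_index,
      start_pos = annotation$pos[cur$start_index],
      end_pos = annotation$pos[cur$end_index],
      n_probes = cur$end_index - cur$start_index + 1L,
      n_sems = length(in_reg), min_window_p = pmin,
      n_hyper = sum(dirs == "hyper"), n_hypo = sum(dirs == "hypo"),
      genes = paste(genes, collapse = ";"), stringsAsFactors = FALSE)
  }
  if (nrow(sig) > 1L) {
    for (i in 2:nrow(sig)) {
      w <- sig[i, ]
      if (w$chrom == cur$chrom && w$start_index <= cur$end_index + 1L) {
        cur$end_index <- max(cur$end_index, w$end_index)
        cur_pmin <- min(cur_pmin, w$p_hyper)
      } else {
        out[[length(out) + 1L]] <- flush(cur, cur_pmin)
        cur <- w
        cur_pmin <- w$p_hyper
      }
    }
  }
  out[[length(out) + 1L]] <- flush(cur, cur_pmin)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan all samples of a cohort for epivariations
#'
#' Convenience wrapper: [scan_sample()] + [call_regions()] per callset.
#' Samples with zero SEMs are skipped.
#'
#' @param callsets list of `sem_callset` objects.
#' @param annotation probe annotation sorted by (chrom, pos).
#' @param n_window window width (default 11).
#' @param alpha per-sample significance level (default 0.05).
#' @return data.frame of regions across samples (possibly 0 rows).
#' @export
scan_cohort <- function(callsets, annotation, n_window = 11L, alpha = 0.05) {
  res <- lapply(callsets, function(cs) {
    if (cs$burden == 0L) return(NULL)
    tests <- scan_sample(cs, annotation, n_window)
    call_regions(tests, annotation, alpha = alpha, callset = cs)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_index = integer(0), end_index = integer(0),
                      start_pos = integer(0), end_pos = integer(0),
                      n_probes = integer(0), n_sems = integer(0),
                      min_window_p = numeric(0), n_hyper = integer(0),
                      n_hypo = integer(0), genes = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cross-sample and cross-study overlap of epivariation genes
#'
#' For each study, collects the genes hit by epivariations in at least
#' one case and in zero controls ("case unique"), then builds the
#' gene x study membership matrix, the genes shared by at least two
#' studies, the genes hit in more than `min_cases` distinct case samples
#' (pooled across studies), and an upset-style intersection table of
#' study combinations.
#'
#' @param regions_by_study named list: study -> region data.frame from
#'   [scan_cohort()].
#' @param sheets_by_study named list: study -> sample sheet (for group
#'   labels).
#' @param case_label default `"case"`.
#' @param min_cases threshold for the recurrent-gene list (default 3:
#'   "more than 3 unrelated cases").
#' @return list with `case_unique_by_study`, `membership` (logical gene
#'   x study matrix), `shared_genes` (>= 2 studies), `recurrent_genes`,
#'   `upset` (data.frame `studies`, `n_genes`, `genes`).
#' @export
cross_overlap <- function(regions_by_study, sheets_by_study,
                          case_label = "case", min_cases = 3L) {
  studies <- names(regions_by_study)
  stopifnot(!is.null(studies), all(studies %in% names(sheets_by_study)))
  gene_hits <- function(regions) {
    if (!nrow(regions)) return(data.frame(sample_id = character(0),
                                          gene = character(0)))
    g <- strsplit(regions$genes, ";", fixed = TRUE)
    data.frame(sample_id = rep(regions$sample_id, lengths(g)),
               gene = unlist(g), stringsAsFactors = FALSE)
  }
  case_unique <- list()
  case_gene_samples <- list()
  for (s in studies) {
    hits <- gene_hits(regions_by_study[[s]])
    sheet <- sheets_by_study[[s]]
    grp <- sheet$group[match(hits$sample_id, sheet$sample_id)]
    case_genes <- unique(hits$gene[grp == case_label])
    ctrl_genes <- unique(hits$gene[grp != case_label])
    case_unique[[s]] <- setdiff(case_genes, ctrl_genes)
    cu_hits <- hits[grp == case_label & hits$gene %in% case_unique[[s]], ]
    case_gene_samples[[s]] <- unique(cu_hits)
  }
  all_genes <- sort(unique(unlist(case_unique)))
  membership <- matrix(FALSE, length(all_genes), length(studies),
                       dimnames = list(all_genes, studies))
  for (s in studies) membership[all_genes %in% case_unique[[s]], s] <- TRUE
  shared <- all_genes[rowSums(membership) >= 2L]
  pooled <- do.call(rbind, case_gene_samples)
  n_case_samples <- if (is.null(pooled) || !nrow(pooled)) integer(0) else
    table(pooled$gene)
  recurrent <- names(n_case_samples)[n_case_samples > min_cases]
  pattern <- apply(membership, 1, function(r) paste(studies[r], collapse = "&"))
  upset <- if (length(pattern)) {
    agg <- split(names(pattern), pattern)
    data.frame(studies = names(agg), n_genes = lengths(agg),
               genes = vapply(agg, paste, "", collapse = ";"),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(studies = character(0), n_genes = integer(0),
                    genes = character(0), stringsAsFactors = FALSE)
  list(case_unique_by_study = case_unique, membership = membership,
       shared_genes = shared,
       n_case_samples = as.integer(n_case_samples) |> setNames(names(n_case_samples)),
       recurrent_genes = recurrent, upset = upset)
}

#' Write epivariation regions as BED
#'
#' 0-based half-open intervals (annotation positions are 1-based).
#'
#' @param regions region table from [scan_cohort()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom, start = regions$start_pos - 1L,
                    end = regions$end_pos, sample = regions$sample_id,
                    p = regions$min_window_p, genes = regions$genes)
  write.table(bed, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
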