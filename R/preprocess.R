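#' Mask beta values with failed detection p-values
#'
#' Entries whose detection p-value exceeds `threshold` are set to `NA`;
#' all downstream quantile and model computations exclude missing cells.
#'
#' @param beta probes x samples beta matrix.
#' @param detp detection p-value matrix of identical shape.
#' @param threshold failure threshold, default 0.01.
#' @return the masked beta matrix.
#' @export
mask_failed <- function(beta, detp, threshold = 0.01) {
  if (!identical(dim(beta), dim(detp)))
    stop("mask_failed: beta and detp dimensions differ", call. = FALSE)
  beta[detp > threshold] <- NA
  beta
}

#' Flag putative homozygous-deletion regions from detection failures
#'
#' Per sample, reports every maximal run of at least `min_run` consecutive
#' failed probes (detection p > threshold) lying on one chromosome, in
#' annotation order. Such runs are the array signature of a homozygous
#' deletion and should be excluded from that sample's region-level calls.
#'
#' @param detp detection p-value matrix (probes x samples), rows in
#'   annotation order.
#' @param annotation probe annotation data.frame (`probe_id`, `chrom`,
#'   `pos`, `gene`) sorted by (chrom, pos).
#' @param threshold detection failure threshold (default 0.01).
#' @param min_run minimum run length to flag (default 3).
#' @return data.frame with columns `sample_id`, `chrom`, `start_pos`,
#'   `end_pos`, `start_index`, `end_index`, `n_failed_probes`.
#' @export
flag_deletion_regions <- function(detp, annotation, threshold = 0.01, min_run = 3L) {
  stopifnot(nrow(detp) == nrow(annotation), min_run >= 1L)
  samples <- colnames(detp)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(detp)))
  out <- list()
  failed <- detp > threshold
  ## run-length scan within chromosome blocks, per sample
  chrom_f <- factor(annotation$chrom, levels = unique(annotation$chrom))
  for (j in seq_len(ncol(detp))) {
    if (!any(failed[, j])) next
    for (blk in split(seq_len(nrow(detp)), chrom_f)) {
      r <- rle(failed[blk, j])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_run
      if (!any(keep)) next
      si <- blk[starts[keep]]
      ei <- blk[ends[keep]]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = samples[j],
        chrom = annotation$chrom[si],
        start_pos = annotation$pos[si],
        end_pos = annotation$pos[ei],
        start_index = si, end_index = ei,
        n_failed_probes = ei - si + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_pos = integer(0), end_pos = integer(0),
                      start_index = integer(0), end_index = integer(0),
                      n_failed_probes = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Quantile-normalize a beta matrix across samples
#'
#' Maps every sample's non-missing values onto the cross-sample mean order
#' statistics, preserving within-sample ranks. This is a generic
#' between-array normalization; it is not SWAN and is logged as such.
#'
#' @param beta probes x samples matrix with >= 2 samples; `NA` allowed.
#' @param quiet suppress the method note.
#' @return normalized matrix with the same dimnames.
#' @export
normalize_quantile <- function(beta, quiet = FALSE) {
  if (ncol(beta) < 2L)
    stop("normalize_quantile: need at least two samples", call. = FALSE)
  if (!quiet)
    message("normalize_quantile: generic cross-sample quantile normalization ",
            "(not SWAN)")
  out <- limma::normalizeQuantiles(beta, ties = TRUE)
  out[is.na(beta)] <- NA
  dimnames(out) <- dimnames(beta)
  out
}

#' Align batches per probe on the logit scale
#'
#' For each probe, each batch's M-values (log2 odds of beta) are centered
#' and scaled to the pooled cross-batch mean and SD, then transformed back
#' to (0,1). A simple location/scale alignment; it is not ComBat and is
#' logged as such. Batches with fewer than 3 samples are passed through
#' with a warning.
#'
#' @param beta probes x samples beta matrix.
#' @param batch_labels per-sample batch factor/character vector.
#' @param quiet suppress the method note.
#' @return adjusted beta matrix.
#' @export
adjust_batch <- function(beta, batch_labels, quiet = FALSE) {
  stopifnot(ncol(beta) == length(batch_labels))
  batches <- unique(as.character(batch_labels))
  if (length(batches) < 2L) return(beta)
  if (!quiet)
    message("adjust_batch: per-probe location/scale alignment on the logit ",
            "scale (not ComBat)")
  m <- logit2(clip01(beta))
  pooled_mean <- rowMeans(m, na.rm = TRUE)
  pooled_sd <- apply(m, 1, sd, na.rm = TRUE)
  out <- m
  for (b in batches) {
    cols <- which(as.character(batch_labels) == b)
    if (length(cols) < 3L) {
      warning("adjust_batch: batch '", b, "' has fewer than 3 samples; passed through")
      next
    }
    mb <- m[, cols, drop = FALSE]
    bm <- rowMeans(mb, na.rm = TRUE)
    bs <- apply(mb, 1, sd, na.rm = TRUE)
    scale <- ifelse(is.na(bs) | bs < 1e-12, 1, pooled_sd / bs)
    scale[is.na(scale) | !is.finite(scale)] <- 1
    out[, cols] <- (mb - bm) * scale + pooled_mean
  }
  res <- expit2(out)
  res[is.na(beta)] <- NA
  dimnames(res) <- dimnames(beta)
  res
}

#' Partial least squares scores summarizing cell composition vs group
#'
#' PLS1 via the NIPALS algorithm: extracts successive orthogonal score
#' vectors of the (centered, unit-scaled) cell-fraction matrix maximizing
#' covariance with the binary group indicator. Deterministic; each
#' component's sign is fixed so its first retained loading is
#' non-negative. Scores are typical covariates for EWAS and drift models
#' when cell composition differs between groups.
#'
#' @param cell_fractions samples x cell-types matrix (rows sum to ~1).
#' @param group binary group labels (two levels, or 0/1).
#' @param n_components number of components, at most `ncol(cell_fractions)`.
#' @return samples x n_components score matrix (columns `PLS1`, `PLS2`, ...).
#' @export
pls_components <- function(cell_fractions, group, n_components = 2L) {
  x <- as.matrix(cell_fractions)
  stopifnot(nrow(x) == length(group))
  if (n_components == 0L)
    return(matrix(numeric(0), nrow(x), 0L, dimnames = list(rownames(x), NULL)))
  g <- if (is.numeric(group)) group else as.numeric(factor(group)) - 1
  if (length(unique(g)) != 2L)
    stop("pls_components: group must be binary", call. = FALSE)
  sds <- apply(x, 2, sd)
  drop <- sds < 1e-12
  if (any(drop)) {
    warning("pls_components: dropping zero-variance column(s): ",
            paste(colnames(x)[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
  }
  if (n_components > ncol(x))
    stop("pls_components: n_components exceeds number of usable cell types",
         call. = FALSE)
  xc <- scale(x)
  yc <- g - mean(g)
  scores <- matrix(NA_real_, nrow(x), n_components)
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { scores[, h] <- 0; next }
    w <- w / nw
    if (w[1] < 0) w <- -w
    t_h <- drop(xc %*% w)
    scores[, h] <- t_h
    p_h <- drop(crossprod(xc, t_h)) / sum(t_h^2)
    xc <- xc - tcrossprod(t_h, p_h)
    yc <- yc - t_h * sum(t_h * yc) / sum(t_h^2)
  }
  dimnames(scores) <- list(rownames(cell_fractions),
                           sprintf("PLS%d", seq_len(n_components)))
  scores
}

#' Write deletion regions as a BED file
#'
#' BED uses 0-based half-open coordinates; annotation positions are
#' 1-based, so `start_pos - 1` / `end_pos` are written.
#'
#' @param regions data.frame from [flag_deletion_regions()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_deletions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start_pos - 1L,
                    end = regions$end_pos,
                    sample = regions$sample_id,
                    n_failed = regions$n_failed_probes)
  write.table(bed, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}
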