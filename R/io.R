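#' Read a beta-value (or detection p-value) matrix from TSV
#'
#' Expects a header of sample ids with the first column holding probe
#' ids. Values must lie in \[0,1\]; empty cells become missing and are
#' excluded downstream.
#'
#' @param path TSV path.
#' @param check_range validate the \[0,1\] range (default TRUE).
#' @return numeric matrix, probes x samples, dimnames set.
#' @export
read_beta <- function(path, check_range = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("read_beta: no sample columns in ", path, call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("read_beta: duplicate probe id(s): ",
         paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "),
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (check_range) {
    bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
    if (nrow(bad))
      stop("read_beta: value out of [0,1] at probe '", ids[bad[1, 1]],
           "', sample '", colnames(m)[bad[1, 2]], "'", call. = FALSE)
  }
  m
}

#' Write a beta-value matrix as TSV
#'
#' @param beta probes x samples matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_beta <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta) %||% sprintf("p%d", seq_len(nrow(beta))),
                   beta, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample sheet CSV
#'
#' Requires `sample_id` and `group` columns; all other columns are kept
#' as provided (cell-fraction columns are conventionally named
#' `cell1..cellK`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_sample_sheet: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a probe annotation TSV and sort it into genome order
#'
#' Columns `probe_id`, `chrom`, `pos`, `gene`; rows are sorted by
#' (chrom, pos) on loading, which is the probe order assumed by the
#' window scan.
#'
#' @param path TSV path.
#' @return sorted data.frame.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_annotation: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$probe_id))
    stop("read_annotation: duplicate probe ids", call. = FALSE)
  if (!"gene" %in% names(df)) df$gene <- ""
  df <- df[order(match(df$chrom, unique(df$chrom)), df$pos), ]
  rownames(df) <- NULL
  df
}

#' Read gene list (one symbol per line)
#'
#' @param path text file path.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  unique(x[nzchar(x)])
}
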