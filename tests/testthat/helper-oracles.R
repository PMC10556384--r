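# Independent brute-force oracles used across tests. These deliberately
# re-derive results from definitions (summation, enumeration, per-cell
# checks) rather than calling the code paths they validate.

# upper-tail hypergeometric by direct summation of the mass function
oracle_hyper_tail <- function(N, K, n, k) {
  if (k > min(n, K)) return(0)
  i <- k:min(n, K)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# type-7 quantile from the interpolation formula, written out by hand
oracle_quantile7 <- function(x, p) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# BH adjusted values from the definition: the smallest FDR level at which
# each p-value would be rejected by the step-up rule over all thresholds
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of p[i]
    adj[i] <- min(1, min(m * p[o[r:m]] / (r:m)))
  }
  adj
}

# per-sample maximal runs of failed probes, naive scan
oracle_deletion_runs <- function(detp, annotation, threshold, min_run) {
  out <- list()
  for (j in seq_len(ncol(detp))) {
    run <- integer(0)
    for (i in seq_len(nrow(detp) + 1L)) {
      ok <- i <= nrow(detp) && detp[i, j] > threshold &&
        (length(run) == 0L || annotation$chrom[i] == annotation$chrom[run[1]])
      if (ok) run <- c(run, i)
      else {
        if (length(run) >= min_run)
          out[[length(out) + 1L]] <- data.frame(
            sample = j, start_index = run[1], end_index = run[length(run)])
        run <- if (i <= nrow(detp) && detp[i, j] > threshold) i else integer(0)
      }
    }
  }
  if (!length(out)) return(data.frame(sample = integer(0),
                                      start_index = integer(0),
                                      end_index = integer(0)))
  do.call(rbind, out)
}

# small annotation covering `p` probes on `nchr` chromosomes
tiny_annotation <- function(p, nchr = 1L, probes_per_gene = 5L) {
  chrom <- rep(sprintf("chr%d", seq_len(nchr)), length.out = p)
  chrom <- chrom[order(chrom)]
  pos <- unlist(lapply(split(seq_len(p), chrom), function(ix)
    cumsum(rep(100L, length(ix)))), use.names = FALSE)
  data.frame(probe_id = sprintf("cg%05d", seq_len(p)),
             chrom = sort(chrom), pos = pos,
             gene = sprintf("G%03d", (seq_len(p) - 1L) %/% probes_per_gene + 1L),
             stringsAsFactors = FALSE)
}

# construct a sem_callset without running the caller
fake_callset <- function(sample_id, probe_ids, directions, n_callable, annotation) {
  structure(list(
    sample_id = sample_id,
    calls = data.frame(probe_id = probe_ids, direction = directions,
                       beta = rep(0.99, length(probe_ids)),
                       stringsAsFactors = FALSE),
    burden = length(probe_ids),
    log_burden = log10(length(probe_ids) + 1),
    n_callable = n_callable), class = "sem_callset")
}
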