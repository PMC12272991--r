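# Independent oracles used across tests. Everything here works on plain
# data.frames in BED (0-based half-open) coordinates and deliberately avoids
# the package's interval engine.

# all-vs-all brute-force overlap pairs
bf_intersect <- function(a, b, min_ov = 1L) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_ov)
      out[[length(out) + 1L]] <- c(i, j, ov)
  }
  if (length(out) == 0L)
    return(data.frame(query = integer(0), subject = integer(0),
                      overlap_bp = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2], overlap_bp = m[, 3])
}

# brute-force "keep a-intervals not overlapping b +/- margin"
bf_subtract_near <- function(a, b, margin = 0L) {
  keep <- vapply(seq_len(nrow(a)), function(i) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      if (min(a$end[i], b$end[j] + margin) -
          max(a$start[i], b$start[j] - margin) > 0) return(FALSE)
    }
    TRUE
  }, logical(1))
  a[keep, , drop = FALSE]
}

random_intervals_df <- function(n, chroms = c("chr1", "chr2"),
                                max_pos = 10000L, max_width = 300L) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_width, n, replace = TRUE))
}

df_to_set <- function(df, genome_id = "test") {
  interval_set(df$chrom, df$start, df$end, genome_id = genome_id, sort = FALSE)
}

# two-sided Fisher p by exhaustive fixed-margin hypergeometric enumeration:
# sum of probabilities of all tables (with the observed margins) whose
# probability does not exceed the observed table's
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# hypergeometric upper tail by direct pmf summation
enum_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(dhyper(kk, K, N - K, n))
}

# closed-form Welch t / df / p
closed_form_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# per-offset PWM scoring oracle: naive log-odds recomputation
bf_scan_scores <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  w <- ncol(p$log_odds)
  n <- length(chars) - w + 1L
  if (n < 1L) return(numeric(0))
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(w)) {
      b <- chars[i + j - 1L]
      if (b %in% c("A", "C", "G", "T")) s <- s + p$log_odds[b, j]
    }
    s
  }, numeric(1))
}

# small, fast fixture configuration shared by several test files
small_fixture_config <- function(seed = 1L, ...) {
  fixture_config(seed = seed,
                 chrom_lengths = c(chr1 = 300000L, chr2 = 300000L),
                 n_enhancers_per_lineage = 40L,
                 n_genes = 60L,
                 n_causal_snps = 4L,
                 n_null_snps = 12L,
                 ...)
}
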