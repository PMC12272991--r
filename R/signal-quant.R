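# Signal quantitation over enhancer-centered probes: logRPKM for histone
# marks and accessibility, coverage-weighted CpG methylation, running-average
# profiles, and per-base conservation averaging.

#' Coverage track
#'
#' A per-base signal carrier: non-overlapping sorted runs of constant depth
#' plus the library size. Depth is interpreted as reads assigned to each base
#' (e.g. read starts), so the read count over an interval is the sum of
#' `depth * overlapped bases` and sums to `total_reads` genome-wide when the
#' track is complete.
#'
#' @param runs `GRanges` with a numeric `score` column (depth), e.g. from
#'   [read_bedgraph()]; runs must not overlap.
#' @param total_reads library size (mapped reads), > 0.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(runs, total_reads) {
  stopifnot(is(runs, "GRanges"))
  if (is.null(runs$score)) stop("coverage runs need a numeric 'score' column")
  if (any(runs$score < 0)) stop("depth must be >= 0")
  if (!is.numeric(total_reads) || length(total_reads) != 1 || total_reads <= 0)
    stop("total_reads must be a single positive number")
  runs <- sort_intervals(runs)
  if (length(runs) > 1) {
    same <- as.character(seqnames(runs))[-1] ==
      as.character(seqnames(runs))[-length(runs)]
    if (any(same & start(runs)[-1] <= end(runs)[-length(runs)]))
      stop("coverage runs must not overlap")
  }
  structure(list(runs = runs, total_reads = total_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d runs, library size %g\n",
              length(x$runs), x$total_reads))
  invisible(x)
}

track_counts <- function(track, probes) {
  hits <- findOverlaps(probes, track$runs, ignore.strand = TRUE)
  ov <- width(pintersect(probes[queryHits(hits)],
                         track$runs[subjectHits(hits)], ignore.strand = TRUE))
  contrib <- ov * track$runs$score[subjectHits(hits)]
  counts <- numeric(length(probes))
  if (length(hits)) {
    agg <- tapply(contrib, queryHits(hits), sum)
    counts[as.integer(names(agg))] <- agg
  }
  counts
}

#' Quantify logRPKM over probes
#'
#' log2 reads per kilobase per million mapped reads, the unit of the state
#' classifier. Probe counts are floored at `pseudocount` reads before the log
#' so all values are finite; with the default floor of one read, an empty
#' 1500 bp probe in a 1e6-read library scores `log2(1/1.5) ~ -0.585`.
#'
#' @param track a [coverage_track()].
#' @param probes `GRanges` of uniform width (see [make_probe()]).
#' @param pseudocount read-count floor applied before the log (default 1).
#' @return numeric vector of logRPKM, one value per probe.
#' @export
quantify_logrpkm <- function(track, probes, pseudocount = 1) {
  if (length(probes) == 0L) return(numeric(0))
  w <- unique(width(probes))
  if (length(w) != 1L)
    stop("probes must have uniform width; got widths ", paste(w, collapse = ","))
  if (w < 1L) stop("zero-width probe")
  counts <- pmax(track_counts(track, probes), pseudocount)
  log2(counts / ((w / 1000) * (track$total_reads / 1e6)))
}

#' Methylation call set
#'
#' Validated table of per-CpG bisulfite calls: `chrom`, `pos` (0-based),
#' `methylated`, `total` with `0 <= methylated <= total`, `total >= 1`.
#'
#' @param df data.frame with the four columns above.
#' @return the validated data.frame, class `methylation_calls`.
#' @export
methylation_calls <- function(df) {
  need <- c("chrom", "pos", "methylated", "total")
  if (!all(need %in% names(df)))
    stop("methylation calls need columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (any(df$total < 1)) stop("total coverage must be >= 1 at every site")
  if (any(df$methylated < 0 | df$methylated > df$total))
    stop("methylated counts must lie in [0, total]")
  class(df) <- c("methylation_calls", "data.frame")
  df
}

calls_in_interval <- function(calls, chrom, start0, end0) {
  calls[calls$chrom == chrom & calls$pos >= start0 & calls$pos < end0, ,
        drop = FALSE]
}

#' Percent methylation over a probe
#'
#' Coverage-weighted rate `100 * sum(methylated) / sum(total)` over CpGs
#' inside the probe (the bisulfite convention); `weighted = FALSE` averages
#' per-CpG rates instead. Returns `NA` ("insufficient data") when fewer than
#' `min_calls` covered CpG positions fall inside the probe.
#'
#' @param calls a [methylation_calls()] table.
#' @param probe a single-interval `GRanges` (e.g. the 500 bp enhancer core).
#' @param min_calls minimum covered CpG positions required (default 1).
#' @param weighted coverage-weighted (default) or per-CpG mean.
#' @return percent methylation in \[0, 100\], or `NA_real_`.
#' @export
methylation_rate <- function(calls, probe, min_calls = 1L, weighted = TRUE) {
  stopifnot(length(probe) == 1L, min_calls >= 1L)
  sub <- calls_in_interval(calls, as.character(seqnames(probe)),
                           start(probe) - 1L, end(probe))
  if (nrow(sub) < min_calls) return(NA_real_)
  if (weighted) 100 * sum(sub$methylated) / sum(sub$total)
  else mean(100 * sub$methylated / sub$total)
}

#' Global methylation from tiled windows
#'
#' The genome is tiled in non-overlapping `window`-bp windows; each window
#' with at least one covered CpG contributes its coverage-weighted rate, and
#' windows are then averaged with equal weight.
#'
#' @param calls a [methylation_calls()] table.
#' @param window tile width in bp (default 10 kb).
#' @return percent methylation.
#' @export
global_methylation <- function(calls, window = 10000L) {
  if (nrow(calls) == 0L) stop("no covered CpGs anywhere")
  win <- floor(calls$pos / window)
  key <- paste(calls$chrom, win)
  meth <- tapply(calls$methylated, key, sum)
  tot <- tapply(calls$total, key, sum)
  mean(100 * meth / tot)
}

#' Running-average signal profile
#'
#' Mean depth in consecutive `window`-bp windows across
#' `[center - flank, center + flank)`, the presentation used for
#' accessibility profiles around enhancer centers and SNPs (50 bp windows,
#' 2-3 kb flanks). Bases not covered by any run count as depth 0.
#'
#' @param track a [coverage_track()].
#' @param chrom chromosome name.
#' @param center 0-based center position.
#' @param flank half-width of the profiled span, divisible by `window`.
#' @param window window width in bp (default 50).
#' @return numeric vector of length `2 * flank / window`.
#' @export
profile_running_average <- function(track, chrom, center, flank, window = 50L) {
  if (flank %% window != 0L) stop("flank must be divisible by window")
  n <- 2L * flank / window
  starts0 <- center - flank + (seq_len(n) - 1L) * window
  wins <- GRanges(chrom, IRanges(pmax(starts0, 0) + 1L, starts0 + window))
  track_counts(track, wins) / window
}

#' Aggregate profiles across samples
#'
#' Elementwise mean and population standard deviation across a stack of
#' equal-length profiles (the solid-line / shaded-band presentation for
#' donor groups).
#'
#' @param profiles list (or matrix rows) of equal-length numeric vectors.
#' @return list with `mean` and `sd` vectors.
#' @export
aggregate_profiles <- function(profiles) {
  if (is.matrix(profiles)) profiles <- asplit(profiles, 1)
  if (length(profiles) == 0L) stop("empty profile collection")
  len <- unique(lengths(profiles))
  if (length(len) != 1L) stop("profiles must have equal lengths")
  m <- do.call(rbind, profiles)
  mu <- colMeans(m)
  list(mean = mu,
       sd = sqrt(colMeans(sweep(m, 2, mu)^2)))
}

#' Average per-base score over a probe
#'
#' Mean of defined per-base scores (e.g. phastCons conservation) across a
#' `width`-bp probe centered on the interval; bases without a score are
#' excluded from the denominator. `NA` when no base is defined.
#'
#' @param base_scores data.frame `chrom`, `pos` (0-based), `score`.
#' @param iv single-interval `GRanges`.
#' @param width probe width (default 1 kb).
#' @return mean score or `NA_real_`.
#' @export
average_score_over_probe <- function(base_scores, iv, width = 1000L) {
  probe <- make_probe(iv, width)
  sub <- base_scores[base_scores$chrom == as.character(seqnames(probe)) &
                       base_scores$pos >= start(probe) - 1L &
                       base_scores$pos < end(probe) &
                       !is.na(base_scores$score), , drop = FALSE]
  if (nrow(sub) == 0L) return(NA_real_)
  mean(sub$score)
}
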