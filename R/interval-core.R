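# Interval algebra on GRanges with BED-style (0-based half-open) coordinates
# at the user boundary. Internally everything is a GRanges (1-based closed);
# conversion happens exactly once, in the constructors and the readers.

#' Construct an interval set
#'
#' Builds a sorted `GRanges` from BED-style coordinates (0-based start,
#' exclusive end). The assembly label travels with the object as
#' `metadata(x)$genome_id` and is checked by every pairwise operation, so
#' intervals from different assemblies can never be intersected silently.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open span, `start < end`.
#' @param name,score,strand optional per-interval annotation (BED columns
#'   4-6); `strand` must be one of `+`, `-`, `.`.
#' @param genome_id assembly label (e.g. `"GRCh38"`, or a synthetic tag).
#' @param sort sort by (chrom, start, end)? Default `TRUE`.
#' @return `GRanges` with `genome_id` in its metadata.
#' @export
interval_set <- function(chrom, start, end, name = NULL, score = NULL,
                         strand = NULL, genome_id = "unknown", sort = TRUE) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(chrom) == 0L) {
    gr <- GRanges()
  } else {
    if (any(is.na(chrom) | !nzchar(chrom)))
      stop("chromosome names must be non-empty")
    if (any(start < 0) || any(start >= end))
      stop("intervals must satisfy 0 <= start < end (BED convention)")
    gr <- GRanges(chrom, IRanges(start + 1L, end),
                  strand = if (is.null(strand)) "*" else
                    ifelse(strand == ".", "*", strand))
    if (!is.null(name)) gr$name <- name
    if (!is.null(score)) gr$score <- score
  }
  metadata(gr)$genome_id <- genome_id
  if (sort && length(gr)) gr <- sort_intervals(gr)
  gr
}

#' @rdname interval_set
#' @param x a `GRanges`.
#' @export
genome_id <- function(x) {
  gid <- metadata(x)$genome_id
  if (is.null(gid)) "unknown" else gid
}

#' @rdname interval_set
#' @param value replacement assembly label.
#' @export
`genome_id<-` <- function(x, value) {
  metadata(x)$genome_id <- value
  x
}

sort_intervals <- function(gr) {
  out <- gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
  metadata(out) <- metadata(gr)
  out
}

#' BED-style accessors
#'
#' 0-based start and exclusive end of a `GRanges`, for callers that think in
#' BED coordinates.
#' @param gr a `GRanges`.
#' @return integer vector.
#' @export
bed_start <- function(gr) start(gr) - 1L

#' @rdname bed_start
#' @export
bed_end <- function(gr) end(gr)

# put two GRanges on the union of their seqlevels so cross-set overlap and
# distance operations are silent about chromosomes present in only one set
align_seqlevels <- function(a, b) {
  lv <- union(seqlevels(a), seqlevels(b))
  suppressWarnings({
    seqlevels(a) <- lv
    seqlevels(b) <- lv
  })
  list(a = a, b = b)
}

check_same_genome <- function(a, b) {
  ga <- genome_id(a); gb <- genome_id(b)
  if (!identical(ga, gb))
    stop(sprintf("genome_id mismatch: '%s' vs '%s'; refusing to compare intervals across assemblies",
                 ga, gb))
  invisible(TRUE)
}

#' Overlapping interval pairs
#'
#' All pairs (i, j) such that interval i of `a` and interval j of `b` share at
#' least `min_overlap_bp` bases. Equivalent to `bedtools intersect -wo` with
#' a minimum-overlap filter expressed in bases rather than a fraction.
#'
#' @param a,b `GRanges` sharing a `genome_id`.
#' @param min_overlap_bp minimum shared bases; default 1 (any overlap).
#' @return data.frame with columns `query` (index into `a`), `subject`
#'   (index into `b`) and `overlap_bp`.
#' @export
intersect_pairs <- function(a, b, min_overlap_bp = 1L) {
  check_same_genome(a, b)
  if (min_overlap_bp < 1L) stop("min_overlap_bp must be >= 1")
  al <- align_seqlevels(a, b); a <- al$a; b <- al$b
  hits <- findOverlaps(a, b, minoverlap = min_overlap_bp, ignore.strand = TRUE)
  ov <- width(pintersect(a[queryHits(hits)], b[subjectHits(hits)],
                         ignore.strand = TRUE))
  data.frame(query = queryHits(hits), subject = subjectHits(hits),
             overlap_bp = ov)
}

#' Fixed-width probe centered on an interval
#'
#' Returns the `width`-bp window centered on the midpoint of each interval,
#' the quantitation probe used throughout (1500 bp for histone-mark logRPKM,
#' 500 bp for methylation cores, 1 kb for conservation). The midpoint is
#' `floor((start + end) / 2)` in 0-based coordinates and the probe is
#' `[mid - floor(w/2), mid + ceiling(w/2))`; a probe that would underflow
#' position 0 is shifted right to start at 0 so that probe length (the RPKM
#' denominator) is always exactly `width`.
#'
#' @param iv `GRanges`.
#' @param width probe width in bp, >= 1.
#' @return `GRanges` of constant width, same metadata columns and genome_id.
#' @export
make_probe <- function(iv, width) {
  width <- as.integer(width)
  if (width < 1L) stop("probe width must be >= 1")
  s0 <- start(iv) - 1L
  e0 <- end(iv)
  mid <- floor((s0 + e0) / 2)
  p0 <- pmax(mid - floor(width / 2), 0)
  out <- GRanges(seqnames(iv), IRanges(p0 + 1L, p0 + width),
                 strand = strand(iv))
  mcols(out) <- mcols(iv)
  metadata(out)$genome_id <- genome_id(iv)
  out
}

#' Subtract intervals with a safety margin
#'
#' Members of `a` that do not overlap any interval of `b` extended by
#' `margin` bp on both sides. This is the TSS-exclusion filter (margin 200)
#' of lineage-specific enhancer calling, but is generic.
#'
#' @param a,b `GRanges` sharing a `genome_id`.
#' @param margin symmetric extension of every `b` interval, in bp.
#' @return subset of `a` (order preserved).
#' @export
subtract_near <- function(a, b, margin = 0L) {
  check_same_genome(a, b)
  if (length(b) == 0L || length(a) == 0L) return(a)
  bx <- GRanges(seqnames(b),
                IRanges(pmax(start(b) - margin, 1L), end(b) + margin))
  al <- align_seqlevels(a, bx)
  out <- subsetByOverlaps(al$a, al$b, invert = TRUE, ignore.strand = TRUE)
  metadata(out) <- metadata(a)
  out
}

#' TSS annotation
#'
#' Single-base transcription start sites with gene names, as a width-1
#' `GRanges` (BED-style `end = start + 1`).
#'
#' @param chrom chromosome names.
#' @param pos 0-based TSS positions.
#' @param gene gene symbols.
#' @inheritParams interval_set
#' @return `GRanges` with a `gene` metadata column.
#' @export
tss_annotation <- function(chrom, pos, gene, genome_id = "unknown") {
  gr <- interval_set(chrom, pos, pos + 1, genome_id = genome_id, sort = FALSE)
  gr$gene <- gene
  gid <- genome_id(gr)
  gr <- sort_intervals(gr)
  metadata(gr)$genome_id <- gid
  gr
}
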