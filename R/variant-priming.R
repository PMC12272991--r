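# Donor-panel analysis of priming-altering SNPs: replicate-consensus
# accessibility peaks, genotype-stratified gain/loss calls at enhancers,
# PWM motif scanning and ref/alt effect classification, and per-motif
# Fisher association between motif membership and altered accessibility.

#' Donor panel
#'
#' Per-donor genotypes, replicate ATAC peak sets and (optionally) coverage
#' tracks. High-confidence peaks per donor are derived at construction with
#' [high_confidence_peaks()].
#'
#' @param donors character vector of donor IDs.
#' @param genotypes character matrix SNP id x donor with entries `hom-ref`,
#'   `het`, `hom-alt`, `missing`.
#' @param replicate_peaks named list donor -> list of `GRanges` (one per
#'   ATAC replicate).
#' @param snps data.frame as from [read_vcf_biallelic_snps()].
#' @param tracks optional named list donor -> [coverage_track()].
#' @param min_support replicate-consensus threshold (default 2, i.e. a peak
#'   must appear in at least two replicates).
#' @return object of class `donor_panel` with a `hc_peaks` element.
#' @export
donor_panel <- function(donors, genotypes, replicate_peaks, snps,
                        tracks = NULL, min_support = 2L) {
  stopifnot(all(donors %in% colnames(genotypes)),
            all(donors %in% names(replicate_peaks)))
  if (any(lengths(replicate_peaks[donors]) < 1L))
    stop("every donor needs >= 1 replicate peak set")
  hc <- lapply(replicate_peaks[donors], high_confidence_peaks,
               min_support = min_support)
  structure(list(donors = donors,
                 genotypes = genotypes[, donors, drop = FALSE],
                 replicate_peaks = replicate_peaks[donors],
                 hc_peaks = hc, snps = snps, tracks = tracks,
                 min_support = min_support),
            class = "donor_panel")
}

#' @export
print.donor_panel <- function(x, ...) {
  cat(sprintf("donor_panel: %d donors, %d SNPs, consensus >= %d replicates\n",
              length(x$donors), nrow(x$snps), x$min_support))
  invisible(x)
}

#' Replicate-consensus ("high confidence") peaks
#'
#' Merged regions supported by overlapping peaks from at least `min_support`
#' distinct replicates, computed per base. With `min_support = 1` this is
#' the merged union of the replicates; with `min_support` equal to the
#' number of replicates it is their per-base intersection.
#'
#' @param replicates list of `GRanges` peak sets.
#' @param min_support minimum number of supporting replicates (default 2).
#' @return `GRanges` of consensus regions.
#' @export
high_confidence_peaks <- function(replicates, min_support = 2L) {
  if (length(replicates) < min_support)
    stop("need at least min_support replicate sets")
  reps <- lapply(replicates, function(g) reduce(granges(g), ignore.strand = TRUE))
  chroms <- unique(unlist(lapply(reps, function(g) as.character(seqnames(g)))))
  if (length(chroms) == 0L) return(GRanges())
  maxend <- max(c(1L, unlist(lapply(reps, function(g)
    if (length(g)) max(end(g)) else 0L))))
  covs <- lapply(reps, function(g) {
    seqlevels(g) <- chroms
    coverage(g, width = setNames(rep(maxend, length(chroms)), chroms))
  })
  support <- Reduce(`+`, covs)
  irl <- slice(support, lower = min_support, rangesOnly = TRUE)
  if (sum(lengths(irl)) == 0L) return(GRanges())
  out <- GRanges(rep(names(irl), lengths(irl)), unlist(irl, use.names = FALSE))
  sort_intervals(out)
}

#' Genotype-stratified priming-alteration call at one enhancer/SNP
#'
#' Donors are split by genotype at the SNP: alt carriers (het or hom-alt,
#' i.e. "SNP present") versus hom-ref. The call is `gain` when every alt
#' carrier has a high-confidence accessibility peak overlapping the enhancer
#' and no hom-ref donor does, `loss` for the mirror pattern, and `none`
#' otherwise (any discordance). When either group has fewer than `min_group`
#' genotyped donors the pair is `untestable` — distinct from `none`.
#' Donors carrying a second SNP inside the same enhancer can be excluded
#' with `exclude_confounded`.
#'
#' @param enhancer single-interval `GRanges`.
#' @param snp_id row id in `panel$snps` / `panel$genotypes`.
#' @param panel a [donor_panel()].
#' @param min_group minimum donors per genotype group (default 2).
#' @param exclude_confounded drop donors carrying a different alt allele at
#'   another SNP inside this enhancer (default `FALSE`).
#' @return list: `direction` (`gain`/`loss`/`none`/`untestable`),
#'   `alt_donors`, `ref_donors`, `alt_peak`, `ref_peak` (logical vectors).
#' @export
detect_priming_alteration <- function(enhancer, snp_id, panel, min_group = 2L,
                                      exclude_confounded = FALSE) {
  stopifnot(length(enhancer) == 1L)
  snp <- panel$snps[panel$snps$id == snp_id, ]
  if (nrow(snp) != 1L) stop("unknown SNP id: ", snp_id)
  if (!(snp$chrom == as.character(seqnames(enhancer)) &
        snp$pos >= start(enhancer) - 1L & snp$pos < end(enhancer)))
    stop("SNP ", snp_id, " does not fall inside the enhancer")
  gt <- panel$genotypes[snp_id, ]
  donors <- panel$donors
  if (exclude_confounded) {
    others <- panel$snps[panel$snps$id != snp_id &
                           panel$snps$chrom == snp$chrom &
                           panel$snps$pos >= start(enhancer) - 1L &
                           panel$snps$pos < end(enhancer), "id"]
    if (length(others)) {
      confound <- apply(panel$genotypes[others, donors, drop = FALSE], 2,
                        function(g) any(g %in% c("het", "hom-alt")))
      donors <- donors[!confound]
      gt <- gt[donors]
    }
  }
  alt_donors <- donors[gt[donors] %in% c("het", "hom-alt")]
  ref_donors <- donors[gt[donors] == "hom-ref"]
  has_peak <- vapply(donors, function(d)
    length(findOverlaps(enhancer, panel$hc_peaks[[d]],
                        ignore.strand = TRUE)) > 0, logical(1))
  out <- list(snp = snp_id,
              alt_donors = alt_donors, ref_donors = ref_donors,
              alt_peak = has_peak[alt_donors], ref_peak = has_peak[ref_donors])
  if (length(alt_donors) < min_group || length(ref_donors) < min_group) {
    out$direction <- "untestable"
    return(out)
  }
  out$direction <-
    if (all(out$alt_peak) && !any(out$ref_peak)) "gain"
    else if (!any(out$alt_peak) && all(out$ref_peak)) "loss"
    else "none"
  out
}

#' Alteration calls for every SNP inside a set of enhancers
#'
#' @param enhancers enhancer `GRanges` (with `enhancer_id`).
#' @param panel a [donor_panel()].
#' @inheritParams detect_priming_alteration
#' @return data.frame: `snp`, `enhancer_id`, `direction`, `altered`
#'   (logical; `NA` when untestable).
#' @export
panel_alteration_calls <- function(enhancers, panel, min_group = 2L,
                                   exclude_confounded = FALSE) {
  snp_gr <- interval_set(panel$snps$chrom, panel$snps$pos, panel$snps$pos + 1,
                         genome_id = genome_id(enhancers), sort = FALSE)
  hits <- findOverlaps(snp_gr, enhancers, ignore.strand = TRUE)
  if (length(hits) == 0L)
    return(data.frame(snp = character(0), enhancer_id = character(0),
                      direction = character(0), altered = logical(0)))
  if (exclude_confounded) {
    # confounder exclusion changes the donor set per SNP; go one by one
    res <- lapply(seq_along(hits), function(i) {
      call <- detect_priming_alteration(
        enhancers[subjectHits(hits)[i]], panel$snps$id[queryHits(hits)[i]],
        panel, min_group = min_group, exclude_confounded = TRUE)
      data.frame(snp = call$snp,
                 enhancer_id = enhancers$enhancer_id[subjectHits(hits)[i]],
                 direction = call$direction, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
  } else {
    # vectorized: per-donor enhancer membership once, then group logic on
    # matrices (cross-checked against detect_priming_alteration in tests)
    has_peak <- vapply(panel$donors, function(d)
      overlapsAny(enhancers, panel$hc_peaks[[d]], ignore.strand = TRUE),
      logical(length(enhancers)))
    if (is.null(dim(has_peak)))
      has_peak <- matrix(has_peak, nrow = length(enhancers),
                         dimnames = list(NULL, panel$donors))
    gt <- panel$genotypes[panel$snps$id[queryHits(hits)], panel$donors,
                          drop = FALSE]
    alt_mask <- gt == "het" | gt == "hom-alt"
    ref_mask <- gt == "hom-ref"
    hp <- has_peak[subjectHits(hits), , drop = FALSE]
    n_alt <- rowSums(alt_mask); n_ref <- rowSums(ref_mask)
    alt_pk <- rowSums(alt_mask & hp); ref_pk <- rowSums(ref_mask & hp)
    direction <- rep("none", length(hits))
    direction[alt_pk == n_alt & ref_pk == 0] <- "gain"
    direction[alt_pk == 0 & ref_pk == n_ref] <- "loss"
    direction[n_alt < min_group | n_ref < min_group] <- "untestable"
    out <- data.frame(snp = panel$snps$id[queryHits(hits)],
                      enhancer_id = enhancers$enhancer_id[subjectHits(hits)],
                      direction = direction, stringsAsFactors = FALSE)
  }
  out$altered <- ifelse(out$direction == "untestable", NA,
                        out$direction %in% c("gain", "loss"))
  rownames(out) <- NULL
  out
}

#' Position weight matrix
#'
#' @param name motif name.
#' @param matrix 4 x width matrix of base probabilities, rows `A`, `C`, `G`,
#'   `T`; each column must sum to 1 (within 1e-9).
#' @param background background base frequencies (default uniform).
#' @param score_threshold_fraction hit threshold as a fraction of the
#'   maximum achievable log-odds score (default 0.8).
#' @return object of class `pwm`.
#' @export
pwm <- function(name, matrix, background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                score_threshold_fraction = 0.8) {
  stopifnot(nrow(matrix) == 4)
  rownames(matrix) <- c("A", "C", "G", "T")
  if (any(abs(colSums(matrix) - 1) > 1e-9))
    stop("PWM columns must each sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  # log-odds with a floor on probabilities so absent bases stay finite
  lo <- log2(pmax(matrix, 1e-6) / background)
  structure(list(name = name, matrix = matrix, background = background,
                 log_odds = lo,
                 max_score = sum(apply(lo, 2, max)),
                 score_threshold_fraction = score_threshold_fraction),
            class = "pwm")
}

#' @rdname pwm
#' @param x a `pwm`.
#' @export
consensus_sequence <- function(x) {
  paste(rownames(x$matrix)[apply(x$matrix, 2, which.max)], collapse = "")
}

#' Read PWMs in JASPAR pfm or MEME minimal format
#'
#' JASPAR pfm: `>name` header then four count rows (A, C, G, T), optionally
#' bracketed. MEME minimal: `MOTIF name` blocks with a letter-probability
#' matrix. Counts/probabilities are normalised per position.
#'
#' @param path file path.
#' @param score_threshold_fraction passed to [pwm()].
#' @return named list of `pwm` objects.
#' @export
read_jaspar_pfm <- function(path, score_threshold_fraction = 0.8) {
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0L) stop("no '>' headers in ", path)
  out <- list()
  for (i in seq_along(idx)) {
    name <- sub("^>\\s*", "", lines[idx[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    last <- if (i < length(idx)) idx[i + 1] - 1 else length(lines)
    rows <- lines[(idx[i] + 1):last]
    rows <- rows[nzchar(trimws(rows))][1:4]
    mat <- t(vapply(rows, function(r) {
      r <- gsub("^[ACGT]?\\s*\\[?|\\]\\s*$", "", trimws(r))
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }, numeric(nchar_matrix_width(rows[1]))))
    mat <- sweep(mat, 2, colSums(mat), "/")
    out[[name]] <- pwm(name, mat,
                       score_threshold_fraction = score_threshold_fraction)
  }
  out
}

nchar_matrix_width <- function(row) {
  r <- gsub("^[ACGT]?\\s*\\[?|\\]\\s*$", "", trimws(row))
  length(strsplit(trimws(r), "\\s+")[[1]])
}

#' @rdname read_jaspar_pfm
#' @export
read_meme_minimal <- function(path, score_threshold_fraction = 0.8) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  if (length(starts) == 0L) stop("no MOTIF blocks in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    name <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]][2]
    last <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    block <- lines[starts[i]:last]
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr) != 1L) stop("MOTIF ", name, ": missing letter-probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[hdr]))
    rows <- block[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    out[[name]] <- pwm(name, t(mat),
                       score_threshold_fraction = score_threshold_fraction)
  }
  out
}

#' @rdname read_jaspar_pfm
#' @param pwms named list of `pwm` objects.
#' @export
write_jaspar_pfm <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    counts <- round(p$matrix * 100, 2)
    c(paste0(">", p$name),
      vapply(c("A", "C", "G", "T"), function(b)
        sprintf("%s  [ %s ]", b, paste(format(counts[b, ], trim = TRUE),
                                       collapse = " ")), ""))
  }))
  writeLines(lines, path)
  invisible(path)
}

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(s) {
  as.character(reverseComplement(DNAString(s)))
}

score_offsets <- function(seq_chars, lo) {
  w <- ncol(lo)
  n <- length(seq_chars) - w + 1L
  if (n < 1L) return(numeric(0))
  # N (or any non-ACGT) contributes zero log-odds
  base_idx <- match(seq_chars, c("A", "C", "G", "T"))
  scores <- numeric(n)
  for (j in seq_len(w)) {
    idx <- base_idx[j:(j + n - 1L)]
    contrib <- ifelse(is.na(idx), 0, lo[cbind(idx, j)])
    scores <- scores + contrib
  }
  scores
}

#' Scan a sequence with PWMs
#'
#' Reports every offset and strand whose log-odds score is at least
#' `score_threshold_fraction x maximum achievable score` for the PWM. Both
#' strands are scanned (minus strand via the reverse complement); `N` bases
#' contribute zero log-odds.
#'
#' @param sequence DNA string over `A,C,G,T,N`.
#' @param pwms list of [pwm()] objects.
#' @return data.frame: `motif`, `offset` (0-based, on the given strand's
#'   forward coordinates), `strand`, `score`, `width`.
#' @export
scan_motifs <- function(sequence, pwms) {
  sequence <- toupper(sequence)
  chars_f <- strsplit(sequence, "")[[1]]
  chars_r <- strsplit(revcomp(sequence), "")[[1]]
  n <- length(chars_f)
  res <- lapply(pwms, function(p) {
    thr <- p$score_threshold_fraction * p$max_score
    w <- ncol(p$log_odds)
    hits <- list()
    sf <- score_offsets(chars_f, p$log_odds)
    i <- which(sf >= thr)
    if (length(i))
      hits$f <- data.frame(motif = p$name, offset = i - 1L, strand = "+",
                           score = sf[i], width = w)
    sr <- score_offsets(chars_r, p$log_odds)
    i <- which(sr >= thr)
    if (length(i))
      hits$r <- data.frame(motif = p$name, offset = n - w - (i - 1L),
                           strand = "-", score = sr[i], width = w)
    if (length(hits)) do.call(rbind, hits) else NULL
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(motif = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      width = integer(0))
  rownames(out) <- NULL
  out[order(out$motif, out$offset, out$strand), , drop = FALSE]
}

#' Classify the effect of a SNP on one motif
#'
#' Compares the best hit score of `motif` between the reference and
#' alternate alleles of the same window: `introduced` (absent -> present),
#' `ablated` (present -> absent), `weakened` / `strengthened` (present in
#' both, score shifted by more than `tolerance` bits), else `unchanged`.
#' Swaps (one motif ablated while another is introduced over the SNP) are
#' detected by [snp_motif_effects()].
#'
#' @param ref_hits,alt_hits [scan_motifs()] output for the two alleles.
#' @param motif motif name.
#' @param tolerance minimum score change (bits) to call weakened /
#'   strengthened (default 1).
#' @return one of `introduced`, `ablated`, `weakened`, `strengthened`,
#'   `unchanged`.
#' @export
classify_snp_motif_effect <- function(ref_hits, alt_hits, motif,
                                      tolerance = 1) {
  rs <- ref_hits$score[ref_hits$motif == motif]
  as_ <- alt_hits$score[alt_hits$motif == motif]
  ref_present <- length(rs) > 0; alt_present <- length(as_) > 0
  if (!ref_present && alt_present) return("introduced")
  if (ref_present && !alt_present) return("ablated")
  if (!ref_present && !alt_present) return("unchanged")
  delta <- max(as_) - max(rs)
  if (delta < -tolerance) "weakened"
  else if (delta > tolerance) "strengthened"
  else "unchanged"
}

#' Per-motif effect table for one SNP, including swaps
#'
#' Scans the reference and alternate alleles of a window around a SNP,
#' restricts to hits whose motif window covers the SNP position, classifies
#' each motif with [classify_snp_motif_effect()], and relabels an ablated
#' motif as `swapped` (with `to` = the introduced motif) when a different
#' motif is introduced over the same SNP.
#'
#' @param ref_seq,alt_seq window sequences differing only at the SNP base.
#' @param pwms list of [pwm()] objects.
#' @param snp_offset 0-based offset of the SNP within the window.
#' @param tolerance see [classify_snp_motif_effect()].
#' @return data.frame: `motif`, `effect`, `to`, `ref_score`, `alt_score`.
#' @export
snp_motif_effects <- function(ref_seq, alt_seq, pwms, snp_offset,
                              tolerance = 1) {
  covers_snp <- function(h) h[h$offset <= snp_offset &
                                h$offset + h$width > snp_offset, , drop = FALSE]
  ref_hits <- covers_snp(scan_motifs(ref_seq, pwms))
  alt_hits <- covers_snp(scan_motifs(alt_seq, pwms))
  motifs <- vapply(pwms, function(p) p$name, "")
  eff <- vapply(motifs, function(m)
    classify_snp_motif_effect(ref_hits, alt_hits, m, tolerance), "")
  best <- function(h, m) if (any(h$motif == m)) max(h$score[h$motif == m]) else NA_real_
  out <- data.frame(
    motif = motifs,
    effect = eff,
    to = NA_character_,
    ref_score = vapply(motifs, best, numeric(1), h = ref_hits),
    alt_score = vapply(motifs, best, numeric(1), h = alt_hits),
    stringsAsFactors = FALSE)
  introduced <- out$motif[out$effect == "introduced"]
  if (length(introduced)) {
    abl <- out$effect == "ablated"
    out$effect[abl] <- "swapped"
    out$to[abl] <- introduced[1]
  }
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' p-value by hypergeometric enumeration (via [stats::fisher.test()]) and
#' the sample odds ratio `ad/bc`, with a Haldane correction (+0.5 per cell)
#' when any cell is zero.
#'
#' @param a,b,c,d cell counts, row-wise.
#' @return list: `p_value`, `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  tab <- matrix(c(a, c, b, d), 2)  # column-major: rows (a,b),(c,d)
  if (any(tab < 0)) stop("cell counts must be >= 0")
  p <- fisher.test(tab)$p.value
  if (any(tab == 0)) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else or <- (a * d) / (b * c)
  list(p_value = p, odds_ratio = or)
}

#' Per-motif association between motif membership and altered accessibility
#'
#' For each motif, tests the 2x2 table (SNP inside a motif instance vs not)
#' x (enhancer accessibility altered vs not) with a two-sided Fisher exact
#' test. Untestable SNPs are excluded; motifs overlapping no SNP are skipped
#' with a message. BH-adjusted p-values are reported alongside the raw p
#' thresholded at `alpha`.
#'
#' @param snp_motif_overlaps logical matrix SNP x motif, or named list
#'   SNP id -> character vector of motifs containing the SNP.
#' @param alteration_calls data.frame from [panel_alteration_calls()].
#' @param alpha raw-p significance threshold (default 0.05).
#' @return data.frame: `motif`, `a`, `b`, `c`, `d`, `odds_ratio`, `p`,
#'   `p_adj`, `significant`, ordered by p.
#' @export
motif_priming_association <- function(snp_motif_overlaps, alteration_calls,
                                      alpha = 0.05) {
  calls <- alteration_calls[!is.na(alteration_calls$altered), , drop = FALSE]
  if (nrow(calls) == 0L) stop("no testable SNPs")
  if (is.list(snp_motif_overlaps) && !is.matrix(snp_motif_overlaps)) {
    motifs <- sort(unique(unlist(snp_motif_overlaps)))
    m <- sapply(motifs, function(mo) vapply(
      calls$snp, function(s) mo %in% snp_motif_overlaps[[s]], logical(1)))
    if (is.null(dim(m))) m <- matrix(m, nrow = nrow(calls),
                                     dimnames = list(calls$snp, motifs))
  } else {
    m <- snp_motif_overlaps[calls$snp, , drop = FALSE]
  }
  altered <- calls$altered
  res <- lapply(colnames(m), function(mo) {
    inm <- m[, mo]
    if (!any(inm)) {
      message("motif_priming_association: motif '", mo,
              "' overlaps no testable SNP; skipped")
      return(NULL)
    }
    a <- sum(inm & altered); b <- sum(inm & !altered)
    c_ <- sum(!inm & altered); d <- sum(!inm & !altered)
    ft <- fisher_exact_2x2(a, b, c_, d)
    data.frame(motif = mo, a = a, b = b, c = c_, d = d,
               odds_ratio = ft$odds_ratio, p = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no motif overlapped any testable SNP")
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out[order(out$p), ]
}
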