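grs <- function(start, end, chrom = "chr1") {
  g <- interval_set(chrom, start, end, genome_id = "g", sort = FALSE)
  g
}

test_that("replicate-consensus peaks follow the per-base support rule", {
  reps <- list(grs(c(100, 1000), c(200, 1100)),
               grs(150, 260),
               grs(5000, 5100))
  hc <- high_confidence_peaks(reps, min_support = 2)
  # only 150-200 is covered by two replicates
  expect_equal(bed_start(hc), 150)
  expect_equal(bed_end(hc), 200)

  # union (overlapping replicate peaks merge) and intersection limits
  expect_equal(length(high_confidence_peaks(reps, 1)), 3L)
  expect_equal(length(high_confidence_peaks(reps, 3)), 0L)

  # brute-force per-base support counting on random replicates
  set.seed(60)
  for (rep in 1:12) {
    rp <- lapply(1:3, function(i) {
      df <- random_intervals_df(sample(3:12, 1), chroms = "chr1",
                                max_pos = 2000, max_width = 150)
      df_to_set(df)
    })
    for (ms in 1:3) {
      hc <- high_confidence_peaks(rp, ms)
      support <- integer(2500)
      for (g in rp) {
        covered <- logical(2500)
        for (i in seq_along(g))
          covered[(bed_start(g)[i] + 1):bed_end(g)[i]] <- TRUE
        support <- support + covered
      }
      got <- logical(2500)
      if (length(hc))
        for (i in seq_along(hc))
          got[(bed_start(hc)[i] + 1):bed_end(hc)[i]] <- TRUE
      expect_equal(got, support >= ms)
    }
  }
})

make_panel <- function(peaks_by_donor, gt, snps) {
  donors <- names(peaks_by_donor)
  gt_mat <- matrix(gt, nrow = nrow(snps), byrow = TRUE,
                   dimnames = list(snps$id, donors))
  reps <- lapply(peaks_by_donor, function(p) list(p, p, p))
  donor_panel(donors, gt_mat, reps, snps)
}

test_that("priming-alteration calls require within-group unanimity", {
  enh <- grs(1000, 2000)
  enh$enhancer_id <- "e1"
  snps <- data.frame(chrom = "chr1", pos = 1500, id = "s1",
                     ref = "C", alt = "T")
  peak <- grs(900, 2100)
  none <- grs(50000, 50100)
  # all alt carriers open, all hom-ref closed -> gain
  panel <- make_panel(list(d1 = peak, d2 = peak, d3 = none, d4 = none,
                           d5 = none),
                      c("het", "hom-alt", "hom-ref", "hom-ref", "hom-ref"),
                      snps)
  call <- detect_priming_alteration(enh, "s1", panel)
  expect_equal(call$direction, "gain")
  # mirror pattern -> loss
  panel_l <- make_panel(list(d1 = none, d2 = none, d3 = peak, d4 = peak,
                             d5 = peak),
                        c("het", "hom-alt", "hom-ref", "hom-ref", "hom-ref"),
                        snps)
  expect_equal(detect_priming_alteration(enh, "s1", panel_l)$direction,
               "loss")
  # discordant alt group -> none
  panel_n <- make_panel(list(d1 = peak, d2 = none, d3 = none, d4 = none),
                        c("het", "hom-alt", "hom-ref", "hom-ref"), snps)
  expect_equal(detect_priming_alteration(enh, "s1", panel_n)$direction,
               "none")
  # only one alt donor -> untestable (distinct from none)
  panel_u <- make_panel(list(d1 = peak, d2 = none, d3 = none),
                        c("het", "hom-ref", "hom-ref"), snps)
  expect_equal(detect_priming_alteration(enh, "s1", panel_u)$direction,
               "untestable")
  # SNP outside the enhancer is rejected
  out <- grs(9000, 9100); out$enhancer_id <- "e2"
  expect_error(detect_priming_alteration(out, "s1", panel), "inside")
})

test_that("vectorized panel calls equal the per-SNP route", {
  set.seed(61)
  n_snp <- 30; n_donor <- 6
  donors <- sprintf("d%02d", 1:n_donor)
  enh <- grs((1:n_snp - 1) * 1000, (1:n_snp - 1) * 1000 + 500)
  enh$enhancer_id <- sprintf("e%02d", 1:n_snp)
  snps <- data.frame(chrom = "chr1", pos = (1:n_snp - 1) * 1000 + 250,
                     id = sprintf("s%02d", 1:n_snp), ref = "A", alt = "G")
  gt <- matrix(sample(c("hom-ref", "het", "hom-alt", "missing"),
                      n_snp * n_donor, TRUE, prob = c(.4, .3, .2, .1)),
               n_snp, n_donor, dimnames = list(snps$id, donors))
  reps <- lapply(setNames(donors, donors), function(d) {
    lapply(1:3, function(r) {
      keep <- runif(n_snp) < 0.5
      df_to_set(data.frame(chrom = "chr1", start = (which(keep) - 1) * 1000,
                           end = (which(keep) - 1) * 1000 + 500))
    })
  })
  panel <- donor_panel(donors, gt, reps, snps)
  fast <- panel_alteration_calls(enh, panel)
  slow <- vapply(seq_len(n_snp), function(i)
    detect_priming_alteration(enh[i], snps$id[i], panel)$direction, "")
  expect_equal(fast$direction[match(snps$id, fast$snp)], slow)
})

test_that("motif scanning finds consensus hits on both strands", {
  set.seed(62)
  p <- epiprime:::random_pwm("M1", 8)
  cons <- consensus_sequence(p)
  hits <- scan_motifs(cons, list(p))
  expect_equal(hits$offset, 0L)
  expect_equal(hits$score, p$max_score, tolerance = 1e-12)
  expect_true("+" %in% hits$strand)

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  hits_rc <- scan_motifs(rc, list(p))
  expect_true(any(hits_rc$strand == "-" &
                    abs(hits_rc$score - p$max_score) < 1e-12))

  # sequence shorter than motif -> empty
  expect_equal(nrow(scan_motifs("ACGT", list(p))), 0L)
})

test_that("scanning matches the brute-force per-offset oracle", {
  set.seed(63)
  for (rep in 1:10) {
    p <- epiprime:::random_pwm("M", sample(5:9, 1), consensus_p = 0.6)
    seq <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
    p$score_threshold_fraction <- 0.3   # low threshold: many hits
    hits <- scan_motifs(seq, list(p))
    fw <- bf_scan_scores(seq, p)
    rv <- bf_scan_scores(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq))), p)
    thr <- 0.3 * p$max_score
    expect_equal(sort(hits$score[hits$strand == "+"]),
                 sort(fw[fw >= thr]), tolerance = 1e-12)
    expect_equal(sort(hits$score[hits$strand == "-"]),
                 sort(rv[rv >= thr]), tolerance = 1e-12)
    # strand symmetry of the full hit set
    n <- nchar(seq); w <- ncol(p$matrix)
    rev_hits <- scan_motifs(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq))), list(p))
    mirrored <- sort(n - w - rev_hits$offset[rev_hits$strand == "-"])
    expect_equal(mirrored, sort(hits$offset[hits$strand == "+"]))
  }
})

test_that("scanning agrees with Biostrings::matchPWM on plus-strand hits", {
  set.seed(64)
  p <- epiprime:::random_pwm("M1", 8)
  seq <- paste0(epiprime:::random_dna(20), consensus_sequence(p),
                epiprime:::random_dna(20))
  hits <- scan_motifs(seq, list(p))
  plus <- hits[hits$strand == "+", ]
  # independent implementation: Biostrings log2-odds PWM at the same cutoff
  bpwm <- log2(pmax(p$matrix, 1e-6) / 0.25)
  m <- Biostrings::matchPWM(bpwm, Biostrings::DNAString(seq),
                            min.score = paste0(100 * 0.8, "%"))
  expect_equal(sort(plus$offset), sort(BiocGenerics::start(m) - 1L))
})

test_that("SNP motif effects classify introduction, ablation, swap, weakening", {
  set.seed(65)
  pa <- epiprime:::random_pwm("TFA", 8)
  ca <- consensus_sequence(pa)
  # motif B = motif A with a different preferred base at position 4
  mb <- pa$matrix
  alt_base <- setdiff(c("A", "C", "G", "T"), substr(ca, 4, 4))[1]
  mb[, 4] <- 0.05; mb[alt_base, 4] <- 0.85
  mb <- sweep(mb, 2, colSums(mb), "/")
  pb <- pwm("TFB", mb)
  pwms <- list(pa, pb)

  flank_l <- epiprime:::random_dna(10)
  flank_r <- epiprime:::random_dna(10)
  ref <- paste0(flank_l, ca, flank_r)
  alt <- ref
  substr(alt, 14, 14) <- alt_base     # SNP at motif position 4
  eff <- snp_motif_effects(ref, alt, pwms, snp_offset = 13)
  expect_equal(eff$effect[eff$motif == "TFA"], "swapped")
  expect_equal(eff$to[eff$motif == "TFA"], "TFB")
  expect_equal(eff$effect[eff$motif == "TFB"], "introduced")

  # pure ablation when no alternative motif is introduced
  worst <- epiprime:::worst_base(pa, 4)
  alt2 <- ref; substr(alt2, 14, 14) <- worst
  eff2 <- snp_motif_effects(ref, alt2, list(pa), snp_offset = 13)
  expect_equal(eff2$effect[eff2$motif == "TFA"], "ablated")

  # weakened: score drop beyond tolerance but still above threshold
  soft <- pa; soft$score_threshold_fraction <- 0.5
  eff3 <- snp_motif_effects(ref, alt2, list(soft), snp_offset = 13)
  expect_equal(eff3$effect[eff3$motif == "TFA"], "weakened")

  # direct classifier edge: absent on both alleles -> unchanged
  expect_equal(classify_snp_motif_effect(
    data.frame(motif = character(0), score = numeric(0)),
    data.frame(motif = character(0), score = numeric(0)), "TFA"),
    "unchanged")
})

test_that("Fisher exact p and sample odds ratio behave as specified", {
  ft <- fisher_exact_2x2(4, 0, 0, 4)
  expect_equal(ft$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(2, 2, 2, 2)$p_value, 1)
  # Haldane-corrected sample OR with a zero cell
  expect_equal(ft$odds_ratio, (4.5 * 4.5) / (0.5 * 0.5))
  expect_equal(fisher_exact_2x2(6, 3, 2, 9)$odds_ratio, 6 * 9 / (3 * 2))

  # transpose invariance
  set.seed(66)
  for (rep in 1:20) {
    tb <- sample(0:12, 4, replace = TRUE)
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])$p_value,
                 fisher_exact_2x2(tb[1], tb[3], tb[2], tb[4])$p_value,
                 tolerance = 1e-12)
  }
})

test_that("motif association builds the right tables and skips empty motifs", {
  calls <- data.frame(snp = sprintf("s%d", 1:8),
                      enhancer_id = sprintf("e%d", 1:8),
                      direction = c(rep("loss", 4), rep("none", 4)),
                      altered = c(rep(TRUE, 4), rep(FALSE, 4)))
  ov <- list(s1 = "M1", s2 = "M1", s3 = "M1", s4 = "M1",
             s5 = character(0), s6 = character(0), s7 = character(0),
             s8 = character(0))
  res <- motif_priming_association(ov, calls)
  expect_equal(res$a[res$motif == "M1"], 4)
  expect_equal(res$d[res$motif == "M1"], 4)
  expect_equal(res$p[res$motif == "M1"], 2 / choose(8, 4), tolerance = 1e-12)

  # untestable SNPs are excluded before tabulation
  calls2 <- rbind(calls, data.frame(snp = "s9", enhancer_id = "e9",
                                    direction = "untestable", altered = NA))
  ov$s9 <- "M1"
  res2 <- motif_priming_association(ov, calls2)
  expect_equal(res2$a + res2$b + res2$c + res2$d, rep(8L, nrow(res2)))

  # motif with no overlapping SNP is skipped with a message
  m <- cbind(M1 = c(rep(TRUE, 4), rep(FALSE, 4)), M2 = rep(FALSE, 8))
  rownames(m) <- calls$snp
  expect_message(res3 <- motif_priming_association(m, calls), "skipped")
  expect_false("M2" %in% res3$motif)
})
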