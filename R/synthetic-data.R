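# Seeded synthetic multi-omic fixture generator with planted ground truth.
# The generator emulates the statistical structure the pipeline is built to
# detect: lineage-specific H3K27ac peaks, an epiblast mark profile per
# planted chromatin state, hypomethylated accessible primed enhancer cores,
# exclusive enhancer-promoter links, lineage-restricted up-regulation of
# primed-linked genes, and donor genotypes whose alternate alleles flip
# accessibility at motif-overlapping positions.

#' Fixture configuration
#'
#' All knobs of [generate_fixture()], with defaults chosen to mirror the
#' scale and contrasts of real lineage-priming datasets: hundreds of
#' lineage-specific enhancers per tissue, ~27% of them primed in the
#' epiblast, methylation ~25% at primed cores against a ~75% global level, a
#' 0.93 log2 (~1.9-fold) expression effect for primed-linked genes in their
#' lineage, and a 10-donor panel with triplicate accessibility peak calls.
#'
#' Mark intensities are Gaussian per planted state on the logRPKM scale with
#' draws truncated at 3 SD, so planted states sit strictly on the correct
#' side of the classifier thresholds; methylation is beta-binomial per CpG;
#' replicate peak dropout is Bernoulli.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param lineages tissue labels for the differentiated lineages.
#' @param epiblast epiblast tissue label used for state classification.
#' @param n_enhancers_per_lineage enhancers planted per lineage.
#' @param enhancer_width enhancer interval width (bp).
#' @param state_fractions named fractions for `primed`, `active`, `poised`
#'   (remainder is inactive).
#' @param thresholds a [state_thresholds()]; classifier decision boundaries
#'   the mark model is separated from.
#' @param mark_means list state -> named vector of mark means (logRPKM).
#' @param mark_sd SD of mark draws (logRPKM).
#' @param probe_width quantitation probe width (bp).
#' @param library_size reads per emitted coverage track.
#' @param methylation list: `global_mean`, `primed_mean` (percent),
#'   `dispersion` (beta-binomial), `core_width`, `cpg_spacing`,
#'   `background_spacing`, `mean_coverage`.
#' @param n_genes genes in the expression matrix / TSS annotation.
#' @param interaction_rate fraction of each enhancer subgroup linked to a
#'   gene by a PCHiC interaction.
#' @param n_shared_genes genes deliberately linked to two subgroups (removed
#'   by the exclusivity filter).
#' @param expression_effect log2 up-regulation of primed-linked genes in
#'   their lineage (0.93 ~ 1.9-fold).
#' @param expression_baseline_sd SD of per-gene baseline expression (log2).
#' @param expression_noise_sd residual per-cell noise (log2).
#' @param n_donors,n_replicates donor panel dimensions.
#' @param peak_noise per-replicate peak dropout probability.
#' @param n_motifs,motif_width PWM library dimensions.
#' @param n_causal_motifs motifs whose disruption flips accessibility.
#' @param n_causal_snps SNPs planted inside causal-motif instances.
#' @param n_null_snps SNPs with genotype-independent accessibility.
#' @param snp_window window (odd bp) of sequence carried around each SNP.
#' @param min_group minimum donors per genotype group for testability.
#' @param genome_id assembly tag for all emitted intervals.
#' @return list of class `fixture_config`.
#' @export
fixture_config <- function(seed = 1L,
                           chrom_lengths = c(chr1 = 1000000L, chr2 = 1000000L),
                           lineages = c("hNPC", "hME"),
                           epiblast = "hESC",
                           n_enhancers_per_lineage = 300L,
                           enhancer_width = 1000L,
                           state_fractions = c(primed = 0.27, active = 0.10,
                                               poised = 0.10),
                           thresholds = human_thresholds(),
                           mark_means = list(
                             active = c(H3K27ac = 4.5, H3K27me3 = 0.5, H3K4me1 = 2.5),
                             poised = c(H3K27ac = 1.0, H3K27me3 = 3.5, H3K4me1 = 2.5),
                             primed = c(H3K27ac = 1.0, H3K27me3 = 0.5, H3K4me1 = 3.0),
                             inactive = c(H3K27ac = 1.0, H3K27me3 = 0.5, H3K4me1 = -0.5)),
                           mark_sd = 0.3,
                           probe_width = 1500L,
                           library_size = 1e6,
                           methylation = list(global_mean = 75, primed_mean = 25,
                                              dispersion = 0.1, core_width = 500L,
                                              cpg_spacing = 50L,
                                              background_spacing = 1000L,
                                              mean_coverage = 8),
                           n_genes = 300L,
                           interaction_rate = 0.75,
                           n_shared_genes = 4L,
                           expression_effect = 0.93,
                           expression_baseline_sd = 1,
                           expression_noise_sd = 0.03,
                           n_donors = 10L,
                           n_replicates = 3L,
                           peak_noise = 0.05,
                           n_motifs = 10L,
                           motif_width = 8L,
                           n_causal_motifs = 1L,
                           n_causal_snps = 6L,
                           n_null_snps = 30L,
                           snp_window = 61L,
                           min_group = 2L,
                           genome_id = "synthetic1") {
  cfg <- as.list(environment())
  fr <- cfg$state_fractions
  if (any(fr < 0) || sum(fr) > 1)
    stop("state fractions must be >= 0 and sum to <= 1")
  if (cfg$mark_sd <= 0) stop("mark_sd must be > 0")
  if (cfg$n_donors < 2 * cfg$min_group)
    stop("n_donors too small for genotype groups of min_group")
  if (cfg$snp_window %% 2 == 0) stop("snp_window must be odd")
  class(cfg) <- "fixture_config"
  cfg
}

# truncated-Gaussian mark draw: clamp at 3 SD so a planted state can never
# cross its decision boundary
draw_mark <- function(n, mean, sd) mean + sd * pmax(pmin(rnorm(n), 3), -3)

# realized logRPKM after count rounding, matching quantify_logrpkm()
realized_logrpkm <- function(logrpkm, probe_width, library_size) {
  counts <- pmax(round(2^logrpkm * (probe_width / 1000) * library_size / 1e6), 1)
  log2(counts / ((probe_width / 1000) * (library_size / 1e6)))
}

random_pwm <- function(name, width, consensus_p = 0.85) {
  cons <- sample(4, width, replace = TRUE)
  mat <- matrix((1 - consensus_p) / 3, 4, width)
  mat[cbind(cons, seq_len(width))] <- consensus_p
  rownames(mat) <- c("A", "C", "G", "T")
  pwm(name, mat)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

worst_base <- function(p, pos) {
  rownames(p$matrix)[which.min(p$matrix[, pos])]
}

#' Generate a complete synthetic multi-omic fixture
#'
#' Produces, in memory, every input the pipeline consumes — per-tissue
#' H3K27ac peak sets (with shared-lineage and TSS-overlapping decoys that
#' the specificity filters must remove), epiblast coverage tracks per
#' histone mark, an accessibility track, CpG methylation calls, a TSS
#' annotation, PCHiC interactions, an expression matrix, a PWM library, a
#' gene-set library, and a donor panel with genotypes and replicate peak
#' sets — together with the planted `truth`, which is serialized alongside
#' the fixture but never consumed by the pipeline under test.
#'
#' Identical seeds give byte-identical bundles (and files, when `dir` is
#' given).
#'
#' @param cfg a [fixture_config()].
#' @param dir optional directory; when given, the bundle is written via
#'   [write_fixture()].
#' @return list with elements `config`, `tss`, `lineage_peaks`,
#'   `epiblast_tracks`, `atac_track`, `methylation`, `pchic`, `expression`,
#'   `gene_sets`, `pwms`, `panel`, `snp_windows`, `enhancer_truth`, `truth`.
#' @export
generate_fixture <- function(cfg, dir = NULL) {
  stopifnot(is(cfg, "fixture_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed)

  chroms <- names(cfg$chrom_lengths)
  n_chrom <- length(chroms)
  n_lin <- length(cfg$lineages)
  n_per <- cfg$n_enhancers_per_lineage
  n_shared_decoys <- 6L
  n_total_slots <- n_lin * n_per + n_shared_decoys

  ## ---- genome layout ----------------------------------------------------
  spacing <- 2500L
  slots_per_chrom <- ceiling(n_total_slots / n_chrom)
  zone_start <- 10000L
  zone_end <- zone_start + spacing * slots_per_chrom
  genes_per_chrom <- ceiling(cfg$n_genes / n_chrom)
  gene_zone_start <- zone_end + 30000L
  gene_zone_end <- gene_zone_start + genes_per_chrom * 1000L + 5000L
  if (any(gene_zone_end > cfg$chrom_lengths))
    stop("genome too small for the requested enhancers and genes; ",
         "increase chrom_lengths")

  slot_chrom <- rep(chroms, each = slots_per_chrom)[seq_len(n_total_slots)]
  slot_idx <- rep(seq_len(slots_per_chrom), n_chrom)[seq_len(n_total_slots)]
  slot_start <- zone_start + (slot_idx - 1L) * spacing +
    (spacing - cfg$enhancer_width) %/% 2L
  perm <- sample(n_total_slots)
  slot_chrom <- slot_chrom[perm]; slot_start <- slot_start[perm]

  ## ---- enhancers and planted states ------------------------------------
  lineage <- rep(cfg$lineages, each = n_per)
  n_enh <- n_lin * n_per
  fr <- cfg$state_fractions
  per_state <- function(n) {
    counts <- c(primed = round(fr[["primed"]] * n),
                active = round(fr[["active"]] * n),
                poised = round(fr[["poised"]] * n))
    counts <- c(counts, inactive = n - sum(counts))
    sample(rep(names(counts), counts))
  }
  state <- unlist(lapply(seq_len(n_lin), function(i) per_state(n_per)))
  enh <- interval_set(slot_chrom[seq_len(n_enh)], slot_start[seq_len(n_enh)],
                      slot_start[seq_len(n_enh)] + cfg$enhancer_width,
                      genome_id = cfg$genome_id, sort = FALSE)
  enh$enhancer_id <- sprintf("%s_enh%04d", lineage,
                             unlist(lapply(seq_len(n_lin), function(i) seq_len(n_per))))
  enh$lineage <- lineage
  enh$planted_state <- state

  ## ---- epiblast marks: draws, tracks, realized records ------------------
  marks <- c("H3K27ac", "H3K27me3", "H3K4me1")
  drawn <- sapply(marks, function(mk) {
    mu <- vapply(state, function(s) cfg$mark_means[[s]][[mk]], numeric(1))
    draw_mark(n_enh, mu, cfg$mark_sd)
  })
  probes <- make_probe(enh, cfg$probe_width)
  epiblast_tracks <- lapply(setNames(marks, marks), function(mk) {
    counts <- pmax(round(2^drawn[, mk] * (cfg$probe_width / 1000) *
                           cfg$library_size / 1e6), 1)
    runs <- GRanges(seqnames(probes), ranges(probes))
    runs$score <- counts / cfg$probe_width
    coverage_track(runs, total_reads = cfg$library_size)
  })
  realized <- apply(drawn, 2, realized_logrpkm,
                    probe_width = cfg$probe_width,
                    library_size = cfg$library_size)
  records <- enhancer_records(enh, lineage, realized[, "H3K27ac"],
                              realized[, "H3K27me3"], realized[, "H3K4me1"],
                              cfg$thresholds)
  if (!all(as.character(records$state) == state))
    stop("internal error: planted states not recovered by the classifier")
  # subgroups are assigned within each lineage's enhancer set
  rec_list <- lapply(cfg$lineages, function(l)
    select_subgroups(records[records$lineage == l]))
  records <- do.call(c, rec_list)
  metadata(records)$genome_id <- cfg$genome_id

  ## ---- peak sets per lineage tissue (with decoys) -----------------------
  shared_i <- seq(n_enh + 1L, n_total_slots)
  shared_peaks <- interval_set(slot_chrom[shared_i], slot_start[shared_i],
                               slot_start[shared_i] + cfg$enhancer_width,
                               genome_id = cfg$genome_id, sort = FALSE)
  ## ---- genes / TSS -------------------------------------------------------
  gene_names <- sprintf("gene%04d", seq_len(cfg$n_genes))
  gchrom <- rep(chroms, each = genes_per_chrom)[seq_len(cfg$n_genes)]
  gpos <- gene_zone_start +
    (rep(seq_len(genes_per_chrom), n_chrom)[seq_len(cfg$n_genes)] - 1L) * 1000L
  tss <- tss_annotation(gchrom, gpos, gene_names, genome_id = cfg$genome_id)

  lineage_peaks <- lapply(setNames(cfg$lineages, cfg$lineages), function(l) {
    own <- records[records$lineage == l]
    jitter <- sample(-50:50, length(own), replace = TRUE)
    own_pk <- GRanges(seqnames(own),
                      IRanges(start(own) + jitter, end(own) + jitter))
    di <- sample(length(gpos), n_shared_decoys)
    decoys <- GRanges(gchrom[di],
                      IRanges(gpos[di] - 400L + 1L, gpos[di] + 400L))
    pk <- c(own_pk, granges(shared_peaks), decoys)
    pk$name <- sprintf("%s_peak%05d", l, seq_along(pk))
    pk$score <- round(runif(length(pk), 100, 1000))
    pk$signalValue <- round(runif(length(pk), 5, 50), 2)
    pk$pValue <- round(runif(length(pk), 5, 100), 2)
    pk$qValue <- round(runif(length(pk), 2, 50), 2)
    pk$peak <- width(pk) %/% 2L
    metadata(pk)$genome_id <- cfg$genome_id
    sort_intervals(pk)
  })

  ## ---- methylation -------------------------------------------------------
  me <- cfg$methylation
  cores <- make_probe(records, me$core_width)
  n_cpg <- me$core_width %/% me$cpg_spacing
  cpg_pos <- as.vector(outer(seq_len(n_cpg) * me$cpg_spacing - me$cpg_spacing %/% 2L,
                             start(cores) - 1L, `+`))
  cpg_chrom <- rep(as.character(seqnames(cores)), each = n_cpg)
  is_primed <- rep(records$state == "primed", each = n_cpg)
  m_mean <- ifelse(is_primed, me$primed_mean, me$global_mean) / 100
  s <- (1 - me$dispersion) / me$dispersion
  rate <- rbeta(length(cpg_pos), m_mean * s, (1 - m_mean) * s)
  bg_pos <- unlist(lapply(chroms, function(ch)
    seq(500L, cfg$chrom_lengths[[ch]] - 500L, by = me$background_spacing)))
  bg_chrom <- rep(chroms, vapply(chroms, function(ch)
    length(seq(500L, cfg$chrom_lengths[[ch]] - 500L,
               by = me$background_spacing)), integer(1)))
  in_core <- overlapsAny(
    GRanges(bg_chrom, IRanges(bg_pos + 1L, bg_pos + 1L)), cores,
    ignore.strand = TRUE)
  bg_pos <- bg_pos[!in_core]; bg_chrom <- bg_chrom[!in_core]
  bg_rate <- rbeta(length(bg_pos), me$global_mean / 100 * s,
                   (1 - me$global_mean / 100) * s)
  all_chrom <- c(cpg_chrom, bg_chrom)
  all_pos <- c(cpg_pos, bg_pos)
  all_rate <- c(rate, bg_rate)
  total <- 1L + rpois(length(all_pos), me$mean_coverage - 1)
  meth <- rbinom(length(all_pos), total, all_rate)
  methylation <- methylation_calls(data.frame(
    chrom = all_chrom, pos = all_pos, methylated = meth, total = total))
  methylation <- methylation[order(methylation$chrom, methylation$pos), ]
  class(methylation) <- c("methylation_calls", "data.frame")
  # planted contrast must be present in every fixture (pooled over cores)
  primed_cores <- cores[records$state == "primed"]
  call_gr <- GRanges(methylation$chrom,
                     IRanges(methylation$pos + 1L, methylation$pos + 1L))
  in_primed <- overlapsAny(call_gr, primed_cores, ignore.strand = TRUE)
  primed_rate <- 100 * sum(methylation$methylated[in_primed]) /
    sum(methylation$total[in_primed])
  glob <- global_methylation(methylation)
  if (!(primed_rate < glob - 10))
    stop("internal error: planted hypomethylation contrast absent")

  ## ---- accessibility track ----------------------------------------------
  acc_core <- make_probe(records, 500L)
  acc_runs <- GRanges(seqnames(acc_core), ranges(acc_core))
  acc_runs$score <- ifelse(records$state %in% c("primed", "active"), 3, 0.5)
  atac_track <- coverage_track(acc_runs, total_reads = cfg$library_size)

  ## ---- PCHiC links, gene groups, expression ------------------------------
  groups <- list()
  for (l in cfg$lineages) for (sg in c("ePrimed", "eNon-primed"))
    groups[[paste(l, sg, sep = "|")]] <-
      records$enhancer_id[records$lineage == l & records$subgroup == sg]
  gene_pool <- gene_names
  link_rows <- list()
  gene_truth <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    n_link <- round(cfg$interaction_rate * length(ids))
    linked <- sample(ids, n_link)
    genes <- gene_pool[seq_len(n_link)]
    gene_pool <- gene_pool[-seq_len(n_link)]
    link_rows[[g]] <- data.frame(gene = genes, enhancer_id = linked,
                                 stringsAsFactors = FALSE)
    gene_truth[[g]] <- data.frame(
      gene = genes, group = g,
      effect = if (grepl("ePrimed", g)) cfg$expression_effect else 0,
      lineage = sub("\\|.*", "", g), stringsAsFactors = FALSE)
  }
  # genes linked to two subgroups: removed by the exclusivity filter
  if (cfg$n_shared_genes > 0) {
    l1 <- cfg$lineages[1]
    shared_genes <- gene_pool[seq_len(cfg$n_shared_genes)]
    gene_pool <- gene_pool[-seq_len(cfg$n_shared_genes)]
    link_rows[["shared"]] <- data.frame(
      gene = rep(shared_genes, 2),
      enhancer_id = c(sample(groups[[paste(l1, "ePrimed", sep = "|")]],
                             cfg$n_shared_genes),
                      sample(groups[[paste(l1, "eNon-primed", sep = "|")]],
                             cfg$n_shared_genes)),
      stringsAsFactors = FALSE)
    gene_truth[["shared"]] <- data.frame(
      gene = shared_genes, group = "shared", effect = 0, lineage = NA,
      stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, link_rows)
  rownames(links) <- NULL
  ei <- match(links$enhancer_id, records$enhancer_id)
  gi <- match(links$gene, tss$gene)
  pchic <- data.frame(
    baitChr = as.character(seqnames(tss))[gi],
    baitStart = pmax(start(tss)[gi] - 1L - 1000L, 0L),
    baitEnd = start(tss)[gi] - 1L + 1000L,
    baitName = links$gene,
    oeChr = as.character(seqnames(records))[ei],
    oeStart = pmax(start(records)[ei] - 1L - 250L, 0L),
    oeEnd = end(records)[ei] + 250L,
    score = round(runif(nrow(links), 5, 15), 2),
    stringsAsFactors = FALSE)
  gene_truth <- do.call(rbind, gene_truth)
  rownames(gene_truth) <- NULL

  tissues <- c(cfg$epiblast, cfg$lineages)
  mu <- rnorm(cfg$n_genes, 5, cfg$expression_baseline_sd)
  expression <- sapply(setNames(tissues, tissues), function(t) {
    eff <- numeric(cfg$n_genes)
    hit <- gene_truth$lineage %in% t & gene_truth$effect != 0
    eff[match(gene_truth$gene[hit], gene_names)] <- gene_truth$effect[hit]
    mu + eff + rnorm(cfg$n_genes, 0, cfg$expression_noise_sd)
  })
  rownames(expression) <- gene_names

  # gene-set library: one term per planted group (padded with unlinked
  # genes) plus random terms; universe = all genes
  gene_sets <- list()
  for (g in names(groups)) {
    gs <- gene_truth$gene[gene_truth$group == g]
    gene_sets[[paste0("term_", gsub("[^A-Za-z0-9]+", "_", g))]] <-
      c(gs, sample(gene_pool, min(10, length(gene_pool))))
  }
  for (i in 1:5)
    gene_sets[[sprintf("term_random%02d", i)]] <- sample(gene_names, 30)

  ## ---- PWM library, SNPs, donor panel ------------------------------------
  pwms <- lapply(seq_len(cfg$n_motifs), function(i)
    random_pwm(sprintf("SMOT%02d", i), cfg$motif_width))
  names(pwms) <- vapply(pwms, function(p) p$name, "")
  causal_motifs <- names(pwms)[seq_len(cfg$n_causal_motifs)]

  eprimed <- records[records$subgroup == "ePrimed"]
  n_snps <- cfg$n_causal_snps * cfg$n_causal_motifs + cfg$n_null_snps
  if (length(eprimed) < n_snps)
    stop("not enough ePrimed enhancers for the requested SNPs")
  snp_enh <- sample(seq_along(eprimed), n_snps)
  half <- cfg$snp_window %/% 2L
  donors <- sprintf("d%02d", seq_len(cfg$n_donors))

  snp_rows <- list(); win_rows <- list(); gt_rows <- list()
  for (i in seq_len(n_snps)) {
    e <- eprimed[snp_enh[i]]
    causal <- i <= cfg$n_causal_snps * cfg$n_causal_motifs
    motif <- if (causal)
      causal_motifs[((i - 1L) %/% cfg$n_causal_snps) + 1L]
    else if (i %% 2 == 0) sample(setdiff(names(pwms), causal_motifs), 1)
    else NA_character_
    center0 <- (start(e) - 1L + end(e)) %/% 2L
    win <- random_dna(cfg$snp_window)
    snp_off <- half  # SNP at window center
    if (!is.na(motif)) {
      p <- pwms[[motif]]
      w <- ncol(p$matrix)
      mpos <- sample(seq_len(w), 1)           # motif column hit by the SNP
      mstart <- snp_off - (mpos - 1L)         # 0-based within window
      cons <- consensus_sequence(p)
      substr(win, mstart + 1L, mstart + w) <- cons
      ref_base <- substr(cons, mpos, mpos)
      alt_base <- worst_base(p, mpos)
    } else {
      ref_base <- substr(win, snp_off + 1L, snp_off + 1L)
      alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
    }
    alt_win <- win
    substr(alt_win, snp_off + 1L, snp_off + 1L) <- alt_base
    id <- sprintf("snp%03d", i)
    snp_rows[[i]] <- data.frame(
      chrom = as.character(seqnames(e)), pos = center0, id = id,
      ref = ref_base, alt = alt_base, stringsAsFactors = FALSE)
    win_rows[[i]] <- data.frame(
      id = id, enhancer_id = e$enhancer_id, causal = causal,
      motif = motif, ref_seq = win, alt_seq = alt_win,
      snp_offset = snp_off, stringsAsFactors = FALSE)
    n_alt <- sample(cfg$min_group:(cfg$n_donors - cfg$min_group), 1)
    carriers <- sample(donors, n_alt)
    gt <- setNames(rep("hom-ref", cfg$n_donors), donors)
    gt[carriers] <- sample(c("het", "hom-alt"), n_alt, replace = TRUE,
                           prob = c(0.7, 0.3))
    gt_rows[[i]] <- gt
  }
  snps <- do.call(rbind, snp_rows)
  snp_windows <- do.call(rbind, win_rows)
  genotypes <- do.call(rbind, gt_rows)
  rownames(genotypes) <- snps$id

  # accessible enhancers: primed and active states, all donors, modulated by
  # causal SNPs (alt carriers lose the peak) and replicate dropout
  accessible <- records[records$state %in% c("primed", "active")]
  replicate_peaks <- lapply(setNames(donors, donors), function(d) {
    drop_enh <- character(0)
    for (i in which(snp_windows$causal)) {
      if (genotypes[snp_windows$id[i], d] %in% c("het", "hom-alt"))
        drop_enh <- c(drop_enh, snp_windows$enhancer_id[i])
    }
    base <- accessible[!accessible$enhancer_id %in% drop_enh]
    lapply(seq_len(cfg$n_replicates), function(r) {
      keep <- runif(length(base)) >= cfg$peak_noise
      pk <- granges(base[keep])
      metadata(pk)$genome_id <- cfg$genome_id
      pk
    })
  })
  panel <- donor_panel(donors, genotypes, replicate_peaks, snps,
                       min_support = cfg$min_group)

  truth <- list(
    enhancers = data.frame(
      enhancer_id = records$enhancer_id,
      chrom = as.character(seqnames(records)),
      start = start(records) - 1L, end = end(records),
      lineage = as.character(records$lineage),
      state = as.character(records$state),
      subgroup = as.character(records$subgroup), stringsAsFactors = FALSE),
    genes = gene_truth,
    snps = snp_windows[, c("id", "enhancer_id", "causal", "motif")],
    causal_motifs = causal_motifs)

  bundle <- list(config = cfg, tss = tss, lineage_peaks = lineage_peaks,
                 epiblast_tracks = epiblast_tracks, atac_track = atac_track,
                 methylation = methylation, pchic = pchic,
                 expression = expression, gene_sets = gene_sets,
                 pwms = pwms, panel = panel, snp_windows = snp_windows,
                 enhancer_truth = records, truth = truth)
  if (!is.null(dir)) write_fixture(bundle, dir)
  bundle
}

#' Null donor panel for calibration
#'
#' A donor panel in which accessibility is independent of genotype: every
#' SNP sits on its own enhancer, genotype groups are balanced at the
#' testability minimum, and each donor's peak presence at each enhancer is
#' an independent fair coin. Motif membership (`snp_motif_overlaps`) is
#' likewise assigned independently. Used to measure the type-I error of
#' [motif_priming_association()].
#'
#' @param cfg a [fixture_config()]; uses `n_null_snps` SNPs, `n_donors`
#'   donors (split into minimal genotype groups) and `n_motifs` motifs.
#' @return list: `panel` (a [donor_panel()]), `enhancers` (`GRanges`),
#'   `snp_motif_overlaps` (logical SNP x motif matrix).
#' @export
generate_null_panel <- function(cfg) {
  stopifnot(is(cfg, "fixture_config"))
  if (cfg$n_donors < 2 * cfg$min_group) stop("need donors for both groups")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed + 20000L)
  n <- cfg$n_null_snps
  if (n < 1) stop("n_null_snps must be >= 1")
  donors <- sprintf("d%02d", seq_len(cfg$n_donors))
  enh <- interval_set(rep("chrN", n), (seq_len(n) - 1L) * 1000L + 100L,
                      (seq_len(n) - 1L) * 1000L + 600L,
                      genome_id = cfg$genome_id, sort = FALSE)
  enh$enhancer_id <- sprintf("null_enh%05d", seq_len(n))
  snps <- data.frame(chrom = "chrN", pos = (seq_len(n) - 1L) * 1000L + 350L,
                     id = sprintf("nsnp%05d", seq_len(n)),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotypes <- t(vapply(seq_len(n), function(i) {
    gt <- setNames(rep("hom-ref", cfg$n_donors), donors)
    gt[sample(donors, cfg$min_group)] <- "het"
    gt
  }, character(cfg$n_donors)))
  rownames(genotypes) <- snps$id
  open <- matrix(runif(n * cfg$n_donors) < 0.5, n, cfg$n_donors,
                 dimnames = list(snps$id, donors))
  replicate_peaks <- lapply(setNames(donors, donors), function(d) {
    pk <- granges(enh[open[, d]])
    metadata(pk)$genome_id <- cfg$genome_id
    rep(list(pk), cfg$n_replicates)
  })
  panel <- donor_panel(donors, genotypes, replicate_peaks, snps,
                       min_support = cfg$min_group)
  overlaps <- matrix(runif(n * cfg$n_motifs) < 0.5, n, cfg$n_motifs,
                     dimnames = list(snps$id,
                                     sprintf("SMOT%02d", seq_len(cfg$n_motifs))))
  list(panel = panel, enhancers = enh, snp_motif_overlaps = overlaps)
}
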