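# End-to-end orchestration: fixture/real inputs in, per-stage TSV/BED
# outputs, a run manifest with content hashes, and a summary report.

#' Pipeline configuration
#'
#' @param fixture_dir directory in the layout of [write_fixture()] (real
#'   data can be arranged the same way).
#' @param out_dir output directory.
#' @param species `"human"` or `"mouse"`: selects the classifier threshold
#'   preset unless `thresholds` is given.
#' @param thresholds optional [state_thresholds()] overriding the preset.
#' @param probe_width mark quantitation probe (default 1500 bp).
#' @param meth_core_width methylation core probe (default 500 bp).
#' @param proximity promoter-proximity cutoff (default 20 kb).
#' @param min_group donor-group minimum for variant testability.
#' @param alpha raw-p significance threshold for reports.
#' @param seed run seed (recorded in the manifest).
#' @param stages subset of `c("enhancers", "methylation", "genes",
#'   "expression", "variants")` to run (`"enhancers"` is always required).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fixture_dir, out_dir,
                            species = c("human", "mouse"),
                            thresholds = NULL,
                            probe_width = 1500L,
                            meth_core_width = 500L,
                            proximity = 20000L,
                            min_group = 2L,
                            alpha = 0.05,
                            seed = 1L,
                            stages = c("enhancers", "methylation", "genes",
                                       "expression", "variants")) {
  species <- match.arg(species)
  if (!dir.exists(fixture_dir)) stop("fixture_dir does not exist: ", fixture_dir)
  if (is.null(thresholds)) thresholds <- species_thresholds(species)
  stages <- union("enhancers", stages)
  cfg <- list(fixture_dir = fixture_dir, out_dir = out_dir, species = species,
              thresholds = thresholds, probe_width = probe_width,
              meth_core_width = meth_core_width, proximity = proximity,
              min_group = min_group, alpha = alpha, seed = seed,
              stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config, fixture_manifest) {
  key <- paste(c(config$species, unlist(config$thresholds),
                 config$probe_width, config$meth_core_width,
                 config$proximity, config$min_group, config$alpha,
                 config$seed, sort(config$stages),
                 names(fixture_manifest$files),
                 unlist(fixture_manifest$files)), collapse = "|")
  tmp <- tempfile(); writeLines(key, tmp)
  on.exit(unlink(tmp))
  unname(md5sum(tmp))
}

records_to_df <- function(records) {
  data.frame(enhancer_id = records$enhancer_id,
             chrom = as.character(seqnames(records)),
             start = start(records) - 1L, end = end(records),
             lineage = as.character(records$lineage),
             H3K27ac = records$H3K27ac, H3K27me3 = records$H3K27me3,
             H3K4me1 = records$H3K4me1,
             state = as.character(records$state),
             subgroup = as.character(records$subgroup),
             stringsAsFactors = FALSE)
}

df_to_records <- function(df, genome_id) {
  gr <- interval_set(df$chrom, df$start, df$end, genome_id = genome_id,
                     sort = FALSE)
  gr$enhancer_id <- df$enhancer_id
  gr$lineage <- df$lineage
  gr$H3K27ac <- df$H3K27ac; gr$H3K27me3 <- df$H3K27me3
  gr$H3K4me1 <- df$H3K4me1
  gr$state <- factor(df$state, levels = STATE_LEVELS)
  gr$subgroup <- factor(df$subgroup, levels = SUBGROUP_LEVELS)
  gr
}

#' Run the full analysis
#'
#' Calls lineage-specific enhancers, classifies epiblast states and
#' subgroups, quantifies subgroup methylation, assigns enhancers to genes
#' and tests enrichment, tests lineage expression dynamics, and runs the
#' donor-panel variant analysis. Each stage writes TSVs under `out_dir`; a
#' `run_manifest.json` records the content hash of (config + input files),
#' and a rerun with unchanged inputs reloads completed stages from disk
#' instead of recomputing them. `summary.json` collects the headline
#' numbers.
#'
#' @param config a [pipeline_config()].
#' @return list with `records`, `priming`, `methylation`, `genes`,
#'   `expression`, `variants`, `summary` (elements `NULL` for stages not
#'   run), invisibly also written under `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(is(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  fx <- read_fixture(config$fixture_dir)
  hash <- config_hash(config, fx$manifest)
  man_path <- file.path(out, "run_manifest.json")
  prev <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = TRUE) else NULL
  completed <- if (!is.null(prev) && identical(prev$run_hash, hash))
    prev$completed else character(0)
  done <- character(0)
  set.seed(config$seed)

  stage_cached <- function(name, paths) {
    name %in% completed && all(file.exists(file.path(out, paths)))
  }

  ## ---- stage: enhancers --------------------------------------------------
  rec_path <- "enhancer_records.tsv"
  if (stage_cached("enhancers", rec_path)) {
    message("run_all: stage 'enhancers' up to date; reloading")
    rec_df <- read.delim(file.path(out, rec_path))
  } else {
    rec_list <- lapply(names(fx$lineage_peaks), function(l) {
      target <- fx$lineage_peaks[[l]]
      ulterior <- fx$lineage_peaks[setdiff(names(fx$lineage_peaks), l)]
      called <- call_lineage_specific_enhancers(target, ulterior, fx$tss)
      probes <- make_probe(called, config$probe_width)
      quant <- lapply(fx$epiblast_tracks, quantify_logrpkm, probes = probes)
      rec <- enhancer_records(granges(called), l, quant$H3K27ac,
                              quant$H3K27me3, quant$H3K4me1,
                              config$thresholds)
      rec$enhancer_id <- sprintf("%s_enh%04d", l, seq_along(rec))
      metadata(rec)$genome_id <- fx$genome_id
      select_subgroups(rec)
    })
    records <- do.call(c, rec_list)
    metadata(records)$genome_id <- fx$genome_id
    rec_df <- records_to_df(records)
    write.table(rec_df, file.path(out, rec_path), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_subgroup_beds(records, file.path(out, "subgroup_beds"))
  }
  records <- df_to_records(rec_df, fx$genome_id)
  metadata(records)$genome_id <- fx$genome_id
  done <- c(done, "enhancers")
  priming <- do.call(rbind, lapply(split(seq_along(records),
                                         as.character(records$lineage)),
    function(i) data.frame(lineage = records$lineage[i[1]],
                           n_enhancers = length(i),
                           priming_fraction = priming_fraction(records[i]))))
  rownames(priming) <- NULL
  write.table(priming, file.path(out, "priming_fractions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  results <- list(records = records, priming = priming, methylation = NULL,
                  genes = NULL, expression = NULL, variants = NULL)

  ## ---- stage: methylation ------------------------------------------------
  if ("methylation" %in% config$stages) {
    mpath <- "subgroup_methylation.tsv"
    if (stage_cached("methylation", mpath)) {
      message("run_all: stage 'methylation' up to date; reloading")
      meth_df <- read.delim(file.path(out, mpath))
    } else {
      cores <- make_probe(records, config$meth_core_width)
      rates <- vapply(seq_along(cores), function(i)
        methylation_rate(fx$methylation, cores[i]), numeric(1))
      meth_df <- data.frame(enhancer_id = records$enhancer_id,
                            lineage = as.character(records$lineage),
                            subgroup = as.character(records$subgroup),
                            methylation = rates)
      write.table(meth_df, file.path(out, mpath), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    grp <- split(meth_df$methylation[!is.na(meth_df$methylation)],
                 meth_df$subgroup[!is.na(meth_df$methylation)])
    grp <- grp[names(grp) %in% c("ePrimed", "eNon-primed")]
    aov_res <- if (length(grp) == 2 && all(lengths(grp) >= 2))
      anova_oneway(grp) else NULL
    results$methylation <- list(per_enhancer = meth_df,
                                global = global_methylation(fx$methylation),
                                anova = aov_res)
    done <- c(done, "methylation")
  }

  ## ---- stage: genes ------------------------------------------------------
  if ("genes" %in% config$stages) {
    asn <- assign_enhancers(records, fx$pchic, fx$tss,
                            proximity = config$proximity)
    excl <- filter_exclusive(asn)
    write.table(asn$assignments, file.path(out, "gene_assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    enr <- list()
    if (!is.null(fx$gene_sets)) {
      for (g in unique(excl$groups)) {
        gs <- excl$gene[excl$groups == g]
        if (length(gs) >= 3)
          enr[[g]] <- enrich(gs, fx$gene_sets, alpha = config$alpha)
      }
      enr_df <- do.call(rbind, lapply(names(enr), function(g)
        cbind(group = g, enr[[g]])))
      if (!is.null(enr_df))
        write.table(enr_df, file.path(out, "enrichment.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }
    results$genes <- list(assignments = asn$assignments, exclusive = excl,
                          enrichment = enr)
    done <- c(done, "genes")
  }

  ## ---- stage: expression -------------------------------------------------
  if ("expression" %in% config$stages && !is.null(results$genes)) {
    excl <- results$genes$exclusive
    epi <- fx$epiblast
    lineages <- names(fx$lineage_peaks)
    rows <- list()
    for (l in lineages) for (sg in c("ePrimed", "eNon-primed")) {
      g <- paste(l, sg, sep = "|")
      genes <- excl$gene[excl$groups == g]
      genes <- intersect(genes, rownames(fx$expression))
      if (length(genes) < 2) next
      fc <- group_fold_change(genes, fx$expression, epi, l)
      wt <- welch_t(fx$expression[genes, l], fx$expression[genes, epi])
      rows[[g]] <- data.frame(group = g, n_genes = length(genes),
                              fold_change = fc, log2_fold = log2(fc),
                              t = wt$statistic, df = wt$df, p = wt$p_value,
                              stars = significance_stars(wt$p_value))
    }
    expr_df <- do.call(rbind, rows)
    rownames(expr_df) <- NULL
    write.table(expr_df, file.path(out, "expression_dynamics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$expression <- expr_df
    done <- c(done, "expression")
  }

  ## ---- stage: variants ---------------------------------------------------
  if ("variants" %in% config$stages && !is.null(fx$panel) &&
      nrow(fx$panel$snps) > 0) {
    eprimed <- records[records$subgroup == "ePrimed"]
    metadata(eprimed)$genome_id <- fx$genome_id
    calls <- panel_alteration_calls(eprimed, fx$panel,
                                    min_group = config$min_group)
    half <- 30L
    snps <- fx$panel$snps
    idx <- match(calls$snp, snps$id)
    win <- interval_set(snps$chrom[idx],
                        pmax(snps$pos[idx] - half, 0),
                        snps$pos[idx] + half + 1L,
                        genome_id = fx$genome_id, sort = FALSE)
    seqs <- read_fasta_region(fx$genome, win)
    snp_off <- snps$pos[idx] - (start(win) - 1L)
    overlaps <- lapply(seq_along(seqs), function(i) {
      hits <- scan_motifs(seqs[i], fx$pwms)
      hits <- hits[hits$offset <= snp_off[i] &
                     hits$offset + hits$width > snp_off[i], ]
      unique(hits$motif)
    })
    names(overlaps) <- calls$snp
    assoc <- tryCatch(
      motif_priming_association(overlaps, calls, alpha = config$alpha),
      error = function(e) { message("variant stage: ", conditionMessage(e)); NULL })
    effects <- do.call(rbind, lapply(seq_along(seqs), function(i) {
      alt <- seqs[i]
      substr(alt, snp_off[i] + 1L, snp_off[i] + 1L) <- snps$alt[idx[i]]
      eff <- snp_motif_effects(seqs[i], alt, fx$pwms, snp_off[i])
      eff <- eff[eff$effect != "unchanged", , drop = FALSE]
      if (nrow(eff)) cbind(snp = calls$snp[i], eff) else NULL
    }))
    write.table(calls, file.path(out, "alteration_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(assoc))
      write.table(assoc, file.path(out, "motif_associations.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(effects))
      write.table(effects, file.path(out, "snp_motif_effects.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    results$variants <- list(calls = calls, associations = assoc,
                             effects = effects)
    done <- c(done, "variants")
  }

  ## ---- summary + manifest ------------------------------------------------
  summary <- list(
    n_enhancers = length(records),
    priming_fractions = setNames(as.list(priming$priming_fraction),
                                 priming$lineage),
    global_methylation = if (!is.null(results$methylation))
      results$methylation$global else NULL,
    methylation_anova_p = if (!is.null(results$methylation) &&
                              !is.null(results$methylation$anova))
      results$methylation$anova$p_value else NULL,
    n_exclusive_genes = if (!is.null(results$genes))
      nrow(results$genes$exclusive) else NULL,
    expression = if (!is.null(results$expression))
      setNames(as.list(results$expression$fold_change),
               results$expression$group) else NULL,
    n_testable_snps = if (!is.null(results$variants))
      sum(!is.na(results$variants$calls$altered)) else NULL,
    n_altered = if (!is.null(results$variants))
      sum(results$variants$calls$altered, na.rm = TRUE) else NULL,
    top_motif = if (!is.null(results$variants) &&
                    !is.null(results$variants$associations))
      results$variants$associations$motif[1] else NULL)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(list(run_hash = hash, seed = config$seed,
                            species = config$species,
                            completed = done),
                       man_path, auto_unbox = TRUE, pretty = TRUE)
  results$summary <- summary
  invisible(results)
}
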