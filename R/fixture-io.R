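# Serialization of a synthetic fixture to the standard on-disk formats the
# pipeline reads back (BED, narrowPeak, bedGraph, methylation TSV, VCF,
# FASTA, GMT, JASPAR pfm, TSV matrices), with a manifest.

write_narrowpeak <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   name = if (is.null(gr$name)) "." else gr$name,
                   score = if (is.null(gr$score)) 0 else gr$score,
                   strand = ".",
                   signalValue = if (is.null(gr$signalValue)) 0 else gr$signalValue,
                   pValue = if (is.null(gr$pValue)) -1 else gr$pValue,
                   qValue = if (is.null(gr$qValue)) -1 else gr$qValue,
                   peak = if (is.null(gr$peak)) -1L else gr$peak)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_bedgraph <- function(track, path) {
  runs <- track$runs
  df <- data.frame(chrom = as.character(seqnames(runs)),
                   start = start(runs) - 1L, end = end(runs),
                   score = runs$score)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_minimal_vcf <- function(snps, genotypes, path) {
  donors <- colnames(genotypes)
  gt_code <- c("hom-ref" = "0/0", "het" = "0/1", "hom-alt" = "1/1",
               "missing" = "./.")
  body <- vapply(seq_len(nrow(snps)), function(i)
    paste(c(snps$chrom[i], snps$pos[i] + 1L, snps$id[i], snps$ref[i],
            snps$alt[i], ".", "PASS", ".", "GT",
            gt_code[genotypes[snps$id[i], donors]]), collapse = "\t"),
    character(1))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", donors), collapse = "\t"),
               body), path)
  invisible(path)
}

#' Write a fixture bundle to disk
#'
#' Emits the bundle of [generate_fixture()] into a self-describing directory
#' in the formats the pipeline reads: `tss.bed`, `peaks/<tissue>.narrowPeak`,
#' `tracks/<mark>.bedgraph` (plus `atac.bedgraph`), `methylation.tsv`,
#' `pchic.tsv`, `expression.tsv`, `gene_sets.gmt`, `pwms.pfm`, `genome.fa`,
#' `panel/genotypes.vcf`, `panel/<donor>_rep<k>.narrowPeak`, the planted
#' `truth.json`, and a `manifest.json` with md5 checksums for every file.
#' Chromosome sequences are random DNA with each SNP's reference window
#' spliced in, so sequence extracted at a SNP matches the planted motif
#' context.
#'
#' @param bundle output of [generate_fixture()].
#' @param dir target directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_fixture <- function(bundle, dir) {
  cfg <- bundle$config
  for (d in c("", "peaks", "tracks", "panel"))
    dir.create(file.path(dir, d), showWarnings = FALSE, recursive = TRUE)
  tss_out <- granges(bundle$tss)
  tss_out$name <- bundle$tss$gene
  write_bed(tss_out, file.path(dir, "tss.bed"))
  for (l in names(bundle$lineage_peaks))
    write_narrowpeak(bundle$lineage_peaks[[l]],
                     file.path(dir, "peaks", paste0(l, ".narrowPeak")))
  for (mk in names(bundle$epiblast_tracks))
    write_bedgraph(bundle$epiblast_tracks[[mk]],
                   file.path(dir, "tracks", paste0(mk, ".bedgraph")))
  write_bedgraph(bundle$atac_track, file.path(dir, "tracks", "atac.bedgraph"))
  write.table(bundle$methylation, file.path(dir, "methylation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$pchic, file.path(dir, "pchic.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv_matrix(bundle$expression, file.path(dir, "expression.tsv"))
  write_gmt(bundle$gene_sets, file.path(dir, "gene_sets.gmt"))
  write_jaspar_pfm(bundle$pwms, file.path(dir, "pwms.pfm"))

  # genome: random DNA (re-derived from the seed) with SNP reference
  # windows spliced in at their planted positions
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed + 10000L)
  seqs <- lapply(cfg$chrom_lengths, random_dna)
  half <- cfg$snp_window %/% 2L
  snps <- bundle$panel$snps
  for (i in seq_len(nrow(snps))) {
    ch <- snps$chrom[i]
    s0 <- snps$pos[i] - half
    substr(seqs[[ch]], s0 + 1L, s0 + cfg$snp_window) <-
      bundle$snp_windows$ref_seq[i]
  }
  writeXStringSet(DNAStringSet(unlist(seqs)), file.path(dir, "genome.fa"),
                  width = 80L)
  write_minimal_vcf(snps, bundle$panel$genotypes,
                    file.path(dir, "panel", "genotypes.vcf"))
  for (d in names(bundle$panel$replicate_peaks)) {
    reps <- bundle$panel$replicate_peaks[[d]]
    for (r in seq_along(reps))
      write_narrowpeak(reps[[r]],
                       file.path(dir, "panel",
                                 sprintf("%s_rep%d.narrowPeak", d, r)))
  }
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", na = "null", auto_unbox = TRUE)

  files <- setdiff(list.files(dir, recursive = TRUE), "manifest.json")
  manifest <- list(
    format = "epiprime-fixture/1",
    genome_id = cfg$genome_id,
    epiblast = cfg$epiblast,
    lineages = as.list(cfg$lineages),
    donors = as.list(bundle$panel$donors),
    n_replicates = cfg$n_replicates,
    library_size = cfg$library_size,
    seed = cfg$seed,
    files = as.list(setNames(unname(md5sum(file.path(dir, files))), files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Read a fixture directory back into a bundle
#'
#' Inverse of [write_fixture()] for the components the pipeline consumes
#' (the planted truth is deliberately not loaded here).
#'
#' @param dir fixture directory with a `manifest.json`.
#' @return list resembling the in-memory bundle (without `truth`).
#' @export
read_fixture <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  gid <- man$genome_id
  lineages <- unlist(man$lineages)
  lineage_peaks <- lapply(setNames(lineages, lineages), function(l)
    read_narrowpeak(file.path(dir, "peaks", paste0(l, ".narrowPeak")),
                    genome_id = gid))
  marks <- c("H3K27ac", "H3K27me3", "H3K4me1")
  epiblast_tracks <- lapply(setNames(marks, marks), function(mk)
    read_bedgraph(file.path(dir, "tracks", paste0(mk, ".bedgraph")),
                  total_reads = man$library_size, genome_id = gid))
  tss_gr <- read_bed(file.path(dir, "tss.bed"), genome_id = gid)
  tss <- tss_annotation(as.character(seqnames(tss_gr)), start(tss_gr) - 1L,
                        tss_gr$name, genome_id = gid)
  snps <- read_vcf_biallelic_snps(file.path(dir, "panel", "genotypes.vcf"))
  donors <- unlist(man$donors)
  replicate_peaks <- lapply(setNames(donors, donors), function(d)
    lapply(seq_len(man$n_replicates), function(r)
      read_narrowpeak(file.path(dir, "panel",
                                sprintf("%s_rep%d.narrowPeak", d, r)),
                      genome_id = gid)))
  panel <- donor_panel(donors, attr(snps, "genotypes"), replicate_peaks,
                       snps)
  list(manifest = man,
       genome_id = gid,
       epiblast = man$epiblast,
       tss = tss,
       lineage_peaks = lineage_peaks,
       epiblast_tracks = epiblast_tracks,
       atac_track = read_bedgraph(file.path(dir, "tracks", "atac.bedgraph"),
                                  total_reads = man$library_size,
                                  genome_id = gid),
       methylation = read_methylation_calls(file.path(dir, "methylation.tsv")),
       pchic = read_pchic(file.path(dir, "pchic.tsv")),
       expression = read_tsv_matrix(file.path(dir, "expression.tsv")),
       gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")),
       pwms = read_jaspar_pfm(file.path(dir, "pwms.pfm")),
       genome = read_fasta(file.path(dir, "genome.fa")),
       panel = panel)
}
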