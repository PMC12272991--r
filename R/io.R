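# Readers and writers for the standard formats the pipeline touches.
# Interval formats go through rtracklayer so coordinate conventions are
# handled once and correctly; VCF goes through vcfR. Only formats with no
# installed reader (JASPAR pfm, MEME minimal, PCHiC tables, GMT) are parsed
# here directly.

with_file_context <- function(path, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("while reading '%s': %s", path, conditionMessage(e)),
         call. = FALSE))
}

#' Read / write BED intervals
#'
#' Thin wrappers over [rtracklayer::import()]/[rtracklayer::export()] that
#' attach and check the `genome_id` metadata used by the interval engine.
#'
#' @param path file path.
#' @param genome_id assembly label to attach.
#' @return `GRanges` (reader) or invisibly the path (writer).
#' @export
read_bed <- function(path, genome_id = "unknown") {
  gr <- with_file_context(path, rtracklayer::import(path, format = "BED"))
  metadata(gr)$genome_id <- genome_id
  sort_intervals(gr)
}

#' @rdname read_bed
#' @param gr intervals to write.
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a narrowPeak file
#'
#' ENCODE narrowPeak is BED6+4: signalValue, pValue, qValue and the summit
#' offset (`peak`) are kept as metadata columns.
#'
#' @inheritParams read_bed
#' @return `GRanges` with narrowPeak metadata columns.
#' @export
read_narrowpeak <- function(path, genome_id = "unknown") {
  gr <- with_file_context(path, rtracklayer::import(
    path, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer")))
  metadata(gr)$genome_id <- genome_id
  sort_intervals(gr)
}

#' Read a bedGraph coverage file
#'
#' @inheritParams read_bed
#' @param total_reads library size to attach (see [coverage_track()]).
#' @return a `coverage_track`.
#' @export
read_bedgraph <- function(path, total_reads, genome_id = "unknown") {
  gr <- with_file_context(path, rtracklayer::import(path, format = "bedGraph"))
  metadata(gr)$genome_id <- genome_id
  coverage_track(gr, total_reads = total_reads)
}

#' Read biallelic SNPs from a VCF
#'
#' Returns only biallelic single-nucleotide variants; indels and multiallelic
#' records are skipped with a message giving the counts. Genotypes are
#' simplified to `hom-ref`, `het`, `hom-alt` or `missing` per sample.
#'
#' @param path VCF (4.x) file path.
#' @return data.frame with columns `chrom`, `pos` (0-based), `id`, `ref`,
#'   `alt`, plus attribute `genotypes`: a character matrix SNPs x donors.
#' @export
read_vcf_biallelic_snps <- function(path) {
  v <- with_file_context(path, vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!is_snp)
  if (n_skip > 0)
    message(sprintf("read_vcf_biallelic_snps: skipped %d non-SNP/multiallelic record(s)",
                    n_skip))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  snps <- data.frame(
    chrom = fix[is_snp, "CHROM"],
    pos = as.integer(fix[is_snp, "POS"]) - 1L,  # to 0-based
    id = ifelse(is.na(fix[is_snp, "ID"]) | fix[is_snp, "ID"] == ".",
                paste0(fix[is_snp, "CHROM"], ":", fix[is_snp, "POS"]),
                fix[is_snp, "ID"]),
    ref = ref[is_snp], alt = alt[is_snp],
    stringsAsFactors = FALSE)
  gt <- gt_raw[is_snp, , drop = FALSE]
  simplify_gt <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep("missing", length(g))
    out[g %in% "0/0"] <- "hom-ref"
    out[g %in% c("0/1", "1/0")] <- "het"
    out[g %in% "1/1"] <- "hom-alt"
    out
  }
  gmat <- apply(gt, 2, simplify_gt)
  if (is.null(dim(gmat))) gmat <- matrix(gmat, nrow = nrow(snps),
                                         dimnames = list(NULL, colnames(gt)))
  rownames(gmat) <- snps$id
  attr(snps, "genotypes") <- gmat
  snps
}

#' Read genome sequence and extract interval sequences
#'
#' @param path FASTA file.
#' @return `DNAStringSet` keyed by chromosome.
#' @export
read_fasta <- function(path) {
  dss <- with_file_context(path, readDNAStringSet(path))
  names(dss) <- sub("\\s.*$", "", names(dss))
  dss
}

#' @rdname read_fasta
#' @param genome `DNAStringSet` from [read_fasta()].
#' @param gr intervals to extract (BED-convention `GRanges`).
#' @return character vector of sequences, one per interval.
#' @export
read_fasta_region <- function(genome, gr) {
  chr <- as.character(seqnames(gr))
  missing_chr <- setdiff(unique(chr), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from FASTA: ", paste(missing_chr, collapse = ", "))
  vapply(seq_along(gr), function(i)
    as.character(subseq(genome[[chr[i]]], start(gr)[i], end(gr)[i])),
    character(1))
}

#' Read a TSV matrix (header row, first column = row names)
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_tsv_matrix <- function(path) {
  df <- with_file_context(path,
    read.delim(path, row.names = 1, check.names = FALSE))
  as.matrix(df)
}

#' @rdname read_tsv_matrix
#' @param mat matrix to write.
#' @export
write_tsv_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CpG methylation calls
#'
#' Expects a four-column TSV `chrom  pos  methylated  total` with `pos`
#' 0-based. [read_bismark_cov()] adapts the Bismark coverage format
#' (`chrom start end pct meth unmeth`, 1-based) to the same structure.
#'
#' @param path file path.
#' @return validated methylation call data.frame (see [methylation_calls()]).
#' @export
read_methylation_calls <- function(path) {
  df <- with_file_context(path, read.delim(
    path, header = TRUE,
    colClasses = c("character", "integer", "integer", "integer")))
  names(df) <- c("chrom", "pos", "methylated", "total")
  methylation_calls(df)
}

#' @rdname read_methylation_calls
#' @export
read_bismark_cov <- function(path) {
  df <- with_file_context(path, read.delim(path, header = FALSE))
  if (ncol(df) != 6) stop("Bismark coverage files have 6 columns")
  methylation_calls(data.frame(
    chrom = as.character(df[[1]]),
    pos = as.integer(df[[2]]) - 1L,
    methylated = as.integer(df[[5]]),
    total = as.integer(df[[5]]) + as.integer(df[[6]])))
}

#' Read significant PCHiC interactions
#'
#' Tab-delimited with header:
#' `baitChr baitStart baitEnd baitName oeChr oeStart oeEnd score`.
#' Coordinates are BED-convention; `baitName` may carry several gene symbols
#' separated by `;` (multi-gene baits keep all of them).
#'
#' @param path file path.
#' @return data.frame of interactions.
#' @export
read_pchic <- function(path) {
  df <- with_file_context(path, read.delim(path, header = TRUE))
  need <- c("baitChr", "baitStart", "baitEnd", "baitName",
            "oeChr", "oeStart", "oeEnd", "score")
  if (!all(need %in% names(df)))
    stop("PCHiC table must have columns: ", paste(need, collapse = " "))
  df[need]
}

#' Read a GMT gene-set library
#'
#' @param path GMT file (term, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- with_file_context(path, readLines(path))
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    if (length(f) < 3) stop("GMT lines need term, description and >= 1 gene")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}
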