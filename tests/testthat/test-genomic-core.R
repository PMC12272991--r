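test_that("intersect_pairs reports overlap pairs with BED arithmetic", {
  a <- interval_set("chr1", 100, 200, genome_id = "g")
  b <- interval_set("chr1", 150, 250, genome_id = "g")
  p <- intersect_pairs(a, b)
  expect_equal(nrow(p), 1L)
  expect_equal(p$overlap_bp, 50)

  b2 <- interval_set("chr2", 100, 200, genome_id = "g")
  expect_equal(nrow(intersect_pairs(a, b2)), 0L)

  # min_overlap_bp filters exactly at the boundary
  b3 <- interval_set("chr1", 150, 250, genome_id = "g")
  expect_equal(nrow(intersect_pairs(a, b3, min_overlap_bp = 50)), 1L)
  expect_equal(nrow(intersect_pairs(a, b3, min_overlap_bp = 51)), 0L)
})

test_that("interval operations refuse mismatched assemblies", {
  a <- interval_set("chr1", 1, 10, genome_id = "GRCh38")
  b <- interval_set("chr1", 1, 10, genome_id = "GRCm38")
  expect_error(intersect_pairs(a, b), "genome_id mismatch")
  expect_error(subtract_near(a, b, 0), "genome_id mismatch")
})

test_that("interval_set validates BED invariants", {
  expect_error(interval_set("chr1", 10, 10), "start < end")
  expect_error(interval_set("chr1", -1, 10), "start < end")
  expect_error(interval_set("", 1, 10), "non-empty")
})

test_that("intersect_pairs matches the brute-force oracle on random sets", {
  set.seed(41)
  for (rep in 1:40) {
    a_df <- random_intervals_df(sample(1:60, 1))
    b_df <- random_intervals_df(sample(1:60, 1))
    min_ov <- sample(c(1, 5, 50), 1)
    got <- intersect_pairs(df_to_set(a_df), df_to_set(b_df), min_ov)
    want <- bf_intersect(a_df, b_df, min_ov)
    key <- function(d) sort(paste(d$query, d$subject, d$overlap_bp))
    expect_equal(key(got), key(want))
  }
})

test_that("make_probe centers, clips, and is idempotent", {
  iv <- interval_set("chr1", 1000, 2000, genome_id = "g")
  p500 <- make_probe(iv, 500)
  expect_equal(c(bed_start(p500), bed_end(p500)), c(1250, 1750))
  p1500 <- make_probe(iv, 1500)
  expect_equal(c(bed_start(p1500), bed_end(p1500)), c(750, 2250))

  tiny <- interval_set("chr1", 100, 101, genome_id = "g")
  clipped <- make_probe(tiny, 500)
  expect_equal(c(bed_start(clipped), bed_end(clipped)), c(0, 500))
  expect_equal(width(clipped), 500)

  # idempotence in width when no clipping occurs
  set.seed(42)
  for (rep in 1:20) {
    s <- sample(5000:9000, 1)
    iv <- interval_set("chr3", s, s + sample(1:2000, 1), genome_id = "g")
    w <- sample(c(100, 501, 1500), 1)
    p1 <- make_probe(iv, w)
    p2 <- make_probe(p1, w)
    expect_equal(start(p1), start(p2))
    expect_equal(end(p1), end(p2))
  }
  expect_error(make_probe(iv, 0), "width")
})

test_that("subtract_near removes margin-extended overlaps and partitions a", {
  a <- interval_set("chr1", 4900, 4950, genome_id = "g")
  tssb <- interval_set("chr1", 5000, 5001, genome_id = "g")
  expect_equal(length(subtract_near(a, tssb, 200)), 0L)

  a2 <- interval_set("chr1", 6000, 6100, genome_id = "g")
  kept <- subtract_near(a2, tssb, 200)
  expect_equal(length(kept), 1L)
  expect_equal(bed_start(kept), 6000)

  # margin 0 with disjoint sets is the identity
  expect_equal(length(subtract_near(a2, tssb, 0)), 1L)

  # partition property against the brute-force oracle
  set.seed(43)
  for (rep in 1:25) {
    a_df <- random_intervals_df(sample(1:50, 1))
    b_df <- random_intervals_df(sample(1:20, 1))
    margin <- sample(c(0, 10, 200), 1)
    got <- subtract_near(df_to_set(a_df), df_to_set(b_df), margin)
    want <- bf_subtract_near(a_df, b_df, margin)
    expect_equal(length(got), nrow(want))
    if (length(got))
      expect_equal(bed_start(got), want$start)
    # removed + kept = a
    expect_equal(length(got) + (nrow(a_df) - nrow(want)), nrow(a_df))
  }
})

test_that("BED round trip preserves intervals", {
  gr <- interval_set(c("chr1", "chr1", "chr2"), c(10, 500, 3),
                     c(100, 900, 44), name = c("a", "b", "c"),
                     genome_id = "g")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(gr, f)
  back <- read_bed(f, genome_id = "g")
  expect_equal(bed_start(back), bed_start(gr))
  expect_equal(bed_end(back), bed_end(gr))
  expect_equal(back$name, gr$name)
})

test_that("narrowPeak reader retains score, signal and summit offset", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(paste(c("chr1", 100, 600, "peak1", 750, ".",
                     12.5, 30.1, 25.2, 210), collapse = "\t"), f)
  np <- read_narrowpeak(f)
  expect_equal(bed_start(np), 100)
  expect_equal(np$score, 750)
  expect_equal(np$signalValue, 12.5)
  expect_equal(np$peak, 210)
})

test_that("VCF reader keeps biallelic SNPs, skips indels, maps genotypes", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "donorA", "donorB"), collapse = "\t"),
    paste(c("chr7", "154794358", "rs1", "C", "T", ".", "PASS", ".", "GT",
            "0/1", "1/1"), collapse = "\t"),
    paste(c("chr7", "200", "indel1", "CA", "C", ".", "PASS", ".", "GT",
            "0/0", "0/1"), collapse = "\t")), f)
  expect_message(snps <- read_vcf_biallelic_snps(f), "skipped 1")
  expect_equal(nrow(snps), 1L)
  expect_equal(snps$pos, 154794358 - 1)  # converted to 0-based
  gt <- attr(snps, "genotypes")
  expect_equal(unname(gt["rs1", c("donorA", "donorB")]),
               c("het", "hom-alt"))
})

test_that("TSV matrix and FASTA region access round-trip", {
  m <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("g", 1:4), c("hESC", "hNPC", "hME")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_tsv_matrix(m, f)
  expect_equal(read_tsv_matrix(f), m, tolerance = 1e-8)

  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGTACGTAC", ">chr2", "GGGGCCCC"), fa)
  genome <- read_fasta(fa)
  gr <- interval_set(c("chr1", "chr2"), c(0, 4), c(4, 8), genome_id = "g")
  expect_equal(read_fasta_region(genome, gr), c("ACGT", "CCCC"))
  bad <- interval_set("chrX", 0, 4, genome_id = "g")
  expect_error(read_fasta_region(genome, bad), "chrX")
})
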