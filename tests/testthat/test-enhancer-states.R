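test_that("sequential classifier applies threshold rules in fixed order", {
  h <- human_thresholds()
  expect_equal(as.character(classify_state(3.5, 0.1, 0.5, h)), "active")
  # poised takes precedence over primed even with high H3K4me1
  expect_equal(as.character(classify_state(0.0, 2.5, 5.0, h)), "poised")
  # mouse primed rule is inclusive (>= 0.4)
  m <- mouse_thresholds()
  expect_equal(as.character(classify_state(0.0, 0.0, 0.4, m)), "primed")
  # human primed rule is strict (> 1.2)
  expect_equal(as.character(classify_state(0.0, 0.0, 1.2, h)), "inactive")
  expect_equal(as.character(classify_state(0.0, 0.0, 1.2 + 1e-9, h)), "primed")
})

test_that("YAML threshold presets reproduce the built-in species presets", {
  path <- system.file("extdata", "thresholds.yaml", package = "epiprime")
  h <- read_thresholds_yaml(path, "human")
  expect_equal(h[c("active_k27ac", "poised_k27me3", "primed_k4me1",
                   "primed_inclusive")],
               unclass(human_thresholds())[c("active_k27ac", "poised_k27me3",
                                             "primed_k4me1",
                                             "primed_inclusive")])
  m <- read_thresholds_yaml(path, "mouse")
  expect_true(m$primed_inclusive)
  expect_equal(m$primed_k4me1, 0.4)
  expect_error(read_thresholds_yaml(path, "zebrafish"), "zebrafish")
})

test_that("classifier errors name the missing mark and is idempotent", {
  h <- human_thresholds()
  expect_error(classify_state(1, NA, 1, h), "H3K27me3")
  expect_error(classify_state(numeric(0), 1, 1, h), "H3K27ac")

  set.seed(48)
  k27ac <- rnorm(50, 2, 2); k27me3 <- rnorm(50, 1, 1); k4me1 <- rnorm(50, 1, 1)
  s1 <- classify_state(k27ac, k27me3, k4me1, h)
  s2 <- classify_state(k27ac, k27me3, k4me1, h)
  expect_identical(s1, s2)
  expect_true(all(!is.na(s1)))  # exactly one state each
})

test_that("lineage-specific calling removes TSS-near and ulterior peaks", {
  tss <- tss_annotation("chr1", 10000, "geneA", genome_id = "g")
  target <- interval_set("chr1", 1000, 2000, genome_id = "g")
  ulterior <- list(interval_set("chr1", 1500, 2500, genome_id = "g"))
  expect_equal(length(
    call_lineage_specific_enhancers(target, ulterior, tss)), 0L)

  ulterior2 <- list(interval_set("chr1", 3000, 4000, genome_id = "g"))
  kept <- call_lineage_specific_enhancers(target, ulterior2, tss)
  expect_equal(bed_start(kept), 1000)

  expect_warning(
    call_lineage_specific_enhancers(interval_set(character(0), integer(0),
                                                 integer(0), genome_id = "g"),
                                    ulterior2, tss), "empty")
})

test_that("lineage-specific calling matches a brute-force three-way filter", {
  set.seed(49)
  for (rep in 1:15) {
    target <- random_intervals_df(60)
    ult1 <- random_intervals_df(25)
    ult2 <- random_intervals_df(25)
    tss_df <- data.frame(chrom = sample(c("chr1", "chr2"), 10, TRUE),
                         start = sample.int(10000, 10))
    tss <- tss_annotation(tss_df$chrom, tss_df$start,
                          paste0("g", 1:10), genome_id = "test")
    got <- call_lineage_specific_enhancers(
      df_to_set(target), list(df_to_set(ult1), df_to_set(ult2)), tss,
      margin = 200)
    tss_iv <- data.frame(chrom = tss_df$chrom, start = tss_df$start,
                         end = tss_df$start + 1)
    want <- bf_subtract_near(target, tss_iv, 200)
    want <- bf_subtract_near(want, ult1, 0)
    want <- bf_subtract_near(want, ult2, 0)
    expect_equal(length(got), nrow(want))
    if (length(got)) expect_equal(bed_start(got), want$start)
  }
})

test_that("prior-annotation subsetting keeps lineage-exclusive enhancers", {
  prior <- interval_set(c("chr1", "chr1", "chr1"),
                        c(1000, 5000, 9000), c(2000, 6000, 10000),
                        genome_id = "g")
  peaks <- list(
    hNPC = interval_set("chr1", c(1200, 5100), c(1800, 5900), genome_id = "g"),
    hME = interval_set("chr1", 5200, 6100, genome_id = "g"))
  # enhancer 1 overlaps hNPC only -> retained; enhancer 2 overlaps both ->
  # excluded; enhancer 3 overlaps neither -> excluded
  got <- subset_by_prior_annotation(prior, prior, peaks, "hNPC")
  expect_equal(bed_start(got), 1000)
  got_me <- subset_by_prior_annotation(prior, prior, peaks, "hME")
  expect_equal(length(got_me), 0L)

  empty <- interval_set(character(0), integer(0), integer(0), genome_id = "g")
  expect_equal(length(subset_by_prior_annotation(prior, empty, peaks, "hNPC")),
               0L)
  expect_error(subset_by_prior_annotation(prior, prior, peaks, "hMSC"),
               "hMSC")
})

make_records <- function(k4me1_inactive, n_primed, thr = human_thresholds()) {
  n_in <- length(k4me1_inactive)
  n <- n_in + n_primed
  iv <- interval_set(rep("chr1", n), seq_len(n) * 1000,
                     seq_len(n) * 1000 + 500, genome_id = "g")
  enhancer_records(iv, "hNPC",
                   h3k27ac = rep(0, n), h3k27me3 = rep(0, n),
                   h3k4me1 = c(rep(3, n_primed), k4me1_inactive), thr)
}

test_that("subgroup selection takes the lowest-H3K4me1 inactive records", {
  set.seed(50)
  k4 <- runif(10, -1, 1)
  rec <- select_subgroups(make_records(k4, n_primed = 4))
  expect_equal(sum(rec$subgroup == "eNon-primed"), 4L)
  expect_equal(sum(rec$subgroup == "intermediate"), 6L)
  sel <- rec$H3K4me1[rec$subgroup == "eNon-primed"]
  expect_equal(sort(sel), sort(k4)[1:4])

  # fewer inactive than primed: all inactive selected, none intermediate
  rec2 <- select_subgroups(make_records(runif(3), n_primed = 5))
  expect_equal(sum(rec2$subgroup == "eNon-primed"), 3L)
  expect_equal(sum(rec2$subgroup == "intermediate"), 0L)

  # no primed records -> no eNon-primed
  rec3 <- select_subgroups(make_records(runif(5), n_primed = 0))
  expect_equal(sum(rec3$subgroup == "eNon-primed"), 0L)
  expect_equal(sum(rec3$subgroup == "intermediate"), 5L)
})

test_that("subgroup partition contract holds on random fixtures", {
  set.seed(51)
  for (rep in 1:25) {
    rec <- select_subgroups(make_records(runif(sample(0:30, 1), -2, 2),
                                         n_primed = sample(0:10, 1)))
    n_inactive <- sum(rec$state == "inactive")
    n_primed <- sum(rec$state == "primed")
    n_enp <- sum(rec$subgroup == "eNon-primed")
    n_int <- sum(rec$subgroup == "intermediate")
    expect_equal(n_enp, min(n_primed, n_inactive))
    expect_equal(n_enp + n_int, n_inactive)
    if (n_enp > 0 && n_int > 0)
      expect_lte(max(rec$H3K4me1[rec$subgroup == "eNon-primed"]),
                 min(rec$H3K4me1[rec$subgroup == "intermediate"]))
  }
})

test_that("priming fraction is a simple percentage", {
  rec <- select_subgroups(make_records(runif(6), n_primed = 2))
  expect_equal(priming_fraction(rec), 100 * 2 / 8)
  all_primed <- make_records(numeric(0), n_primed = 5)
  expect_equal(priming_fraction(all_primed), 100)
  set.seed(52)
  for (rep in 1:10) {
    np <- sample(0:12, 1); ni <- sample(1:12, 1)
    rec <- make_records(runif(ni), n_primed = np)
    expect_equal(priming_fraction(rec), 100 * np / (np + ni))
  }
  expect_error(priming_fraction(all_primed[0]), "no enhancer")
})
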