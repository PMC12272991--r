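# Lineage-specific enhancer calling and the sequential epiblast chromatin
# state classifier (active -> poised -> primed -> inactive), plus the
# ePrimed / ePoised / eNon-primed / intermediate subgrouping.

STATE_LEVELS <- c("active", "poised", "primed", "inactive")
SUBGROUP_LEVELS <- c("ePrimed", "ePoised", "eNon-primed", "intermediate", "none")

#' State classifier thresholds
#'
#' Decision boundaries (logRPKM) of the sequential classifier. Rules fire in
#' the fixed order active (H3K27ac), poised (H3K27me3), primed (H3K4me1);
#' everything left is inactive. All comparisons are strict `>` except that
#' the mouse primed rule is inclusive (`>=`), controlled by
#' `primed_inclusive`.
#'
#' `human_thresholds()` is H3K27ac > 2.97, H3K27me3 > 2, H3K4me1 > 1.2;
#' `mouse_thresholds()` is H3K27ac > 1.2, H3K27me3 > 1.25, H3K4me1 >= 0.4.
#'
#' @param active_k27ac,poised_k27me3,primed_k4me1 logRPKM cutoffs.
#' @param primed_inclusive is the H3K4me1 comparison `>=` rather than `>`?
#' @return object of class `state_thresholds`.
#' @export
state_thresholds <- function(active_k27ac, poised_k27me3, primed_k4me1,
                             primed_inclusive = FALSE) {
  vals <- c(active_k27ac, poised_k27me3, primed_k4me1)
  if (any(!is.finite(vals))) stop("thresholds must be finite")
  structure(list(active_k27ac = active_k27ac, poised_k27me3 = poised_k27me3,
                 primed_k4me1 = primed_k4me1,
                 primed_inclusive = isTRUE(primed_inclusive)),
            class = "state_thresholds")
}

#' @rdname state_thresholds
#' @export
human_thresholds <- function() state_thresholds(2.97, 2, 1.2, FALSE)

#' @rdname state_thresholds
#' @export
mouse_thresholds <- function() state_thresholds(1.2, 1.25, 0.4, TRUE)

#' @rdname state_thresholds
#' @param species `"human"` or `"mouse"`.
#' @export
species_thresholds <- function(species) {
  switch(match.arg(species, c("human", "mouse")),
         human = human_thresholds(), mouse = mouse_thresholds())
}

#' @rdname state_thresholds
#' @param path YAML file with fields `active_k27ac`, `poised_k27me3`,
#'   `primed_k4me1`, `primed_inclusive`, or a top-level species name mapping
#'   to such a block (see `system.file("extdata", "thresholds.yaml",
#'   package = "epiprime")` for the shipped human/mouse presets).
#' @param preset which top-level block to use when the file holds several.
#' @export
read_thresholds_yaml <- function(path, preset = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(preset)) {
    if (is.null(y[[preset]])) stop("no preset '", preset, "' in ", path)
    y <- y[[preset]]
  }
  need <- c("active_k27ac", "poised_k27me3", "primed_k4me1")
  if (!all(need %in% names(y)))
    stop("threshold YAML needs fields: ", paste(need, collapse = ", "))
  state_thresholds(y$active_k27ac, y$poised_k27me3, y$primed_k4me1,
                   isTRUE(y$primed_inclusive))
}

#' @export
print.state_thresholds <- function(x, ...) {
  cat(sprintf("state_thresholds: H3K27ac > %g; H3K27me3 > %g; H3K4me1 %s %g\n",
              x$active_k27ac, x$poised_k27me3,
              if (x$primed_inclusive) ">=" else ">", x$primed_k4me1))
  invisible(x)
}

#' Call lineage-specific enhancers
#'
#' H3K27ac peaks of the target tissue that do not overlap an annotated TSS
#' (+/- `margin` bp) and do not overlap any ulterior-lineage H3K27ac peak.
#'
#' @param target_peaks `GRanges` of the tissue's H3K27ac peaks.
#' @param ulterior_peaks list of `GRanges`, one per ulterior tissue.
#' @param tss a [tss_annotation()].
#' @param margin TSS exclusion margin in bp (default 200).
#' @return subset of `target_peaks`.
#' @export
call_lineage_specific_enhancers <- function(target_peaks, ulterior_peaks, tss,
                                            margin = 200L) {
  if (length(target_peaks) == 0L) {
    warning("empty target peak set; returning empty enhancer set")
    return(target_peaks)
  }
  out <- subtract_near(target_peaks, tss, margin)
  for (ult in ulterior_peaks) out <- subtract_near(out, ult, 0L)
  out
}

#' Restrict candidates to prior-annotated, lineage-exclusive enhancers
#'
#' Members of a prior enhancer annotation that overlap the candidate set and
#' the focal lineage's H3K27ac peaks but no other profiled lineage's peaks —
#' the route used for early-development lineages where an external enhancer
#' catalogue exists.
#'
#' @param candidates `GRanges` delimiting the search space (pass the prior
#'   list itself to impose no extra restriction).
#' @param prior_enhancers `GRanges` of previously annotated enhancers.
#' @param lineage_peaks named list tissue -> `GRanges` of H3K27ac peaks.
#' @param own_lineage name of the focal tissue (must be in `lineage_peaks`).
#' @return subset of `prior_enhancers`.
#' @export
subset_by_prior_annotation <- function(candidates, prior_enhancers,
                                       lineage_peaks, own_lineage) {
  if (!own_lineage %in% names(lineage_peaks))
    stop("own_lineage '", own_lineage, "' not in lineage_peaks")
  if (length(prior_enhancers) == 0L) return(prior_enhancers)
  keep <- overlapsAny(prior_enhancers, candidates, ignore.strand = TRUE) &
    overlapsAny(prior_enhancers, lineage_peaks[[own_lineage]],
                ignore.strand = TRUE)
  for (tissue in setdiff(names(lineage_peaks), own_lineage))
    keep <- keep & !overlapsAny(prior_enhancers, lineage_peaks[[tissue]],
                                ignore.strand = TRUE)
  out <- prior_enhancers[keep]
  metadata(out) <- metadata(prior_enhancers)
  out
}

#' Sequential chromatin state classification
#'
#' Applies the threshold rules in fixed order: active if H3K27ac exceeds its
#' cutoff; otherwise poised if H3K27me3 does; otherwise primed if H3K4me1
#' does; otherwise inactive. Exactly one state per enhancer.
#'
#' @param h3k27ac,h3k27me3,h3k4me1 epiblast logRPKM vectors (equal length).
#' @param thr a [state_thresholds()].
#' @return factor with levels active, poised, primed, inactive.
#' @export
classify_state <- function(h3k27ac, h3k27me3, h3k4me1, thr) {
  marks <- list(H3K27ac = h3k27ac, H3K27me3 = h3k27me3, H3K4me1 = h3k4me1)
  for (nm in names(marks)) {
    if (is.null(marks[[nm]]) || length(marks[[nm]]) == 0L || any(is.na(marks[[nm]])))
      stop("missing or NA values for mark ", nm)
  }
  stopifnot(is(thr, "state_thresholds"))
  primed_hit <- if (thr$primed_inclusive) h3k4me1 >= thr$primed_k4me1
                else h3k4me1 > thr$primed_k4me1
  state <- ifelse(h3k27ac > thr$active_k27ac, "active",
           ifelse(h3k27me3 > thr$poised_k27me3, "poised",
           ifelse(primed_hit, "primed", "inactive")))
  factor(state, levels = STATE_LEVELS)
}

#' Build classified enhancer records
#'
#' Attaches epiblast mark quantifications and the state call to an enhancer
#' `GRanges`, producing the record every downstream stage consumes.
#'
#' @param intervals enhancer `GRanges`.
#' @param lineage tissue label (scalar or vector).
#' @param h3k27ac,h3k27me3,h3k4me1 epiblast logRPKM per enhancer.
#' @param thr a [state_thresholds()].
#' @return `GRanges` with columns `enhancer_id`, `lineage`, the three marks,
#'   `state` and `subgroup` (initialised to `"none"`).
#' @export
enhancer_records <- function(intervals, lineage, h3k27ac, h3k27me3, h3k4me1,
                             thr) {
  gr <- intervals
  if (is.null(gr$enhancer_id))
    gr$enhancer_id <- sprintf("%s_enh%04d", lineage[1], seq_along(gr))
  gr$lineage <- lineage
  gr$H3K27ac <- h3k27ac
  gr$H3K27me3 <- h3k27me3
  gr$H3K4me1 <- h3k4me1
  gr$state <- classify_state(h3k27ac, h3k27me3, h3k4me1, thr)
  gr$subgroup <- factor("none", levels = SUBGROUP_LEVELS)
  metadata(gr) <- metadata(intervals)
  gr
}

#' Assign ePrimed / ePoised / eNon-primed / intermediate subgroups
#'
#' All primed records become ePrimed and all poised records ePoised. From the
#' inactive class, the `n = min(|ePrimed|, |inactive|)` records with the
#' lowest epiblast H3K4me1 become eNon-primed (a similarly sized low-H3K4me1
#' contrast group); remaining inactive records are intermediate. Ties at the
#' cutoff rank are broken by (chrom, start) ascending. Active records keep
#' subgroup `"none"`.
#'
#' @param records classified enhancer `GRanges` from [enhancer_records()].
#' @return the records with `subgroup` filled in.
#' @export
select_subgroups <- function(records) {
  if (any(is.na(records$state))) stop("records must be classified first")
  sub <- rep("none", length(records))
  sub[records$state == "primed"] <- "ePrimed"
  sub[records$state == "poised"] <- "ePoised"
  inact <- which(records$state == "inactive")
  n_sel <- min(sum(records$state == "primed"), length(inact))
  if (length(inact)) {
    ord <- inact[order(records$H3K4me1[inact],
                       as.character(seqnames(records))[inact],
                       start(records)[inact])]
    sub[head(ord, n_sel)] <- "eNon-primed"
    sub[tail(ord, length(inact) - n_sel)] <- "intermediate"
  }
  records$subgroup <- factor(sub, levels = SUBGROUP_LEVELS)
  records
}

#' Fraction of lineage-specific enhancers that are primed
#'
#' @param records classified enhancer `GRanges`.
#' @return percent in \[0, 100\].
#' @export
priming_fraction <- function(records) {
  if (length(records) == 0L) stop("no enhancer records")
  100 * sum(records$state == "primed") / length(records)
}

#' Write one BED6 file per subgroup
#'
#' Names follow `lineage|state|subgroup`; score is the epiblast H3K4me1
#' logRPKM.
#'
#' @param records subgrouped enhancer `GRanges`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_subgroup_beds <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sg in levels(droplevels(records$subgroup))) {
    r <- records[records$subgroup == sg]
    if (length(r) == 0L) next
    out <- GRanges(seqnames(r), ranges(r), strand = "*")
    out$name <- paste(r$lineage, r$state, sg, sep = "|")
    out$score <- r$H3K4me1
    p <- file.path(dir, paste0("enhancers_", gsub("[^A-Za-z0-9]+", "_", sg), ".bed"))
    write_bed(out, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
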