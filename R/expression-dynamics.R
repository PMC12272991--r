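# Expression dynamics of enhancer-associated gene groups: percentile-rank
# normalization across tissues, Welch's t, median fold change, one-way ANOVA.

#' Percentile-rank normalization within tissues
#'
#' Converts each tissue column to percentile positions: mid-ranks are scaled
#' as `(rank - 1) / (n - 1) * 100`, so the top gene of a tissue sits at 100,
#' the bottom at 0, and a fully tied column at 50. Invariant under any
#' strictly monotone transform of a column.
#'
#' @param matrix numeric genes x tissues matrix (needs >= 2 genes).
#' @return matrix of the same shape with values in \[0, 100\].
#' @export
percentile_rank <- function(matrix) {
  if (nrow(matrix) < 2L) stop("need >= 2 genes per tissue")
  apply(matrix, 2, function(x) (rank(x, ties.method = "average") - 1) /
          (length(x) - 1) * 100)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom,
#' two-sided. When both groups are degenerate (zero variance) with equal
#' means the comparison is reported as no difference (t = 0, p = 1) with a
#' message. Group means and the linear-scale fold change
#' `2^(mean(x) - mean(y))` (inputs assumed log2-scale) are returned.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list: `statistic`, `df`, `p_value`, `group_means`, `fold_change`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  gm <- c(x = mean(x), y = mean(y))
  fc <- 2^(gm[["x"]] - gm[["y"]])
  if (sd(x) == 0 && sd(y) == 0) {
    if (gm[["x"]] == gm[["y"]]) {
      message("welch_t: both groups degenerate with equal means; p = 1 by convention")
      return(list(statistic = 0, df = NA_real_, p_value = 1,
                  group_means = gm, fold_change = fc))
    }
    stop("zero variance in both groups with unequal means: t undefined")
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, group_means = gm, fold_change = fc)
}

#' Fold change of median group expression between tissues
#'
#' `2^(median_target - median_reference)` over the gene group, assuming
#' log2-scale expression — the contrast used to report lineage-restricted
#' up-regulation of enhancer-linked gene groups (e.g. ~1.9-fold).
#'
#' @param group_genes character vector of gene names.
#' @param matrix genes x tissues expression matrix (log2 scale).
#' @param reference_tissue,target_tissue column names.
#' @return linear-scale fold change.
#' @export
group_fold_change <- function(group_genes, matrix, reference_tissue,
                              target_tissue) {
  if (length(group_genes) == 0L) stop("empty gene group")
  missing_genes <- setdiff(group_genes, rownames(matrix))
  if (length(missing_genes))
    stop("gene(s) absent from matrix: ",
         paste(head(missing_genes, 5), collapse = ", "))
  sub <- matrix[group_genes, , drop = FALSE]
  2^(median(sub[, target_tissue]) - median(sub[, reference_tissue]))
}

#' One-way ANOVA across groups
#'
#' Classic (pooled-variance) one-way F test across two or more groups, as
#' used for per-enhancer methylation comparisons between subgroups. When all
#' values are identical the F statistic is undefined and the comparison is
#' reported as no difference (p = 1) with a message. Significance stars:
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list: `statistic` (F), `df` (between, within), `p_value`,
#'   `group_means`, `stars`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups, use.names = FALSE)
  gm <- vapply(groups, mean, numeric(1))
  if (sd(y) == 0) {
    message("anova_oneway: all values identical; p = 1 by convention")
    return(list(statistic = NA_real_, df = c(length(groups) - 1,
                                             length(y) - length(groups)),
                p_value = 1, group_means = gm, stars = ""))
  }
  g <- factor(rep(names(groups), lengths(groups)))
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  p <- ow$p.value
  list(statistic = unname(ow$statistic),
       df = unname(ow$parameter), p_value = p, group_means = gm,
       stars = significance_stars(p))
}

#' @rdname anova_oneway
#' @param p p-value(s).
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
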