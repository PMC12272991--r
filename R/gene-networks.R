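# Enhancer-to-gene assignment via the PCHiC + promoter-proximity hybrid
# model, exclusivity filtering, and local hypergeometric gene-set enrichment.

#' Assign enhancers to genes
#'
#' A gene-enhancer edge exists iff the enhancer overlaps a promoter-
#' interacting (other-end) fragment whose bait maps to the gene, or the gap
#' between the enhancer and the gene's TSS is at most `proximity` bp
#' (0 when they overlap). Multi-gene baits (semicolon-separated `baitName`)
#' produce edges to every named gene.
#'
#' @param enhancers classified enhancer `GRanges` (needs `enhancer_id`,
#'   `lineage`, `subgroup`).
#' @param interactions PCHiC table from [read_pchic()] (may be `NULL`).
#' @param promoters a [tss_annotation()] with a `gene` column.
#' @param proximity promoter-proximity cutoff in bp (default 20 kb).
#' @return list with `edges` (one row per gene-enhancer link, with `via`
#'   `"pchic"` or `"proximity"`) and `assignments` (one row per gene:
#'   `gene`, `n_enhancers`, `groups` as `lineage|subgroup` labels collapsed
#'   with `,`, and logical `exclusive`).
#' @export
assign_enhancers <- function(enhancers, interactions, promoters,
                             proximity = 20000L) {
  check_same_genome(enhancers, promoters)
  al <- align_seqlevels(enhancers, promoters)
  enhancers <- al$a; promoters <- al$b
  edges <- list()
  if (!is.null(interactions) && nrow(interactions)) {
    oe <- interval_set(interactions$oeChr, interactions$oeStart,
                       interactions$oeEnd, genome_id = genome_id(enhancers),
                       sort = FALSE)
    al <- align_seqlevels(enhancers, oe); enhancers <- al$a; oe <- al$b
    hits <- findOverlaps(enhancers, oe, ignore.strand = TRUE)
    if (length(hits)) {
      genes <- strsplit(interactions$baitName[subjectHits(hits)], ";")
      reps <- lengths(genes)
      edges[["pchic"]] <- data.frame(
        gene = unlist(genes),
        enhancer_id = rep(enhancers$enhancer_id[queryHits(hits)], reps),
        lineage = rep(as.character(enhancers$lineage[queryHits(hits)]), reps),
        subgroup = rep(as.character(enhancers$subgroup[queryHits(hits)]), reps),
        via = "pchic", stringsAsFactors = FALSE)
    }
  }
  # all promoters within the cutoff: overlap against enhancers extended by
  # `proximity`, then compute the exact edge-to-TSS gap
  ext <- GRanges(seqnames(enhancers),
                 IRanges(pmax(start(enhancers) - proximity - 1L, 1L),
                         end(enhancers) + proximity + 1L))
  hits <- findOverlaps(ext, promoters, ignore.strand = TRUE)
  if (length(hits)) {
    gap <- distance(enhancers[queryHits(hits)], promoters[subjectHits(hits)],
                    ignore.strand = TRUE)
    keep <- !is.na(gap) & gap <= proximity
    hits <- hits[keep]
    if (length(hits))
      edges[["prox"]] <- data.frame(
        gene = promoters$gene[subjectHits(hits)],
        enhancer_id = enhancers$enhancer_id[queryHits(hits)],
        lineage = as.character(enhancers$lineage[queryHits(hits)]),
        subgroup = as.character(enhancers$subgroup[queryHits(hits)]),
        via = "proximity", stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(gene = character(0), enhancer_id = character(0),
               lineage = character(0), subgroup = character(0),
               via = character(0))
  rownames(edges) <- NULL
  edges <- unique(edges)
  grp <- paste(edges$lineage, edges$subgroup, sep = "|")
  assignments <- if (nrow(edges)) {
    do.call(rbind, lapply(split(seq_len(nrow(edges)), edges$gene), function(i) {
      groups <- sort(unique(grp[i]))
      data.frame(gene = edges$gene[i[1]],
                 n_enhancers = length(unique(edges$enhancer_id[i])),
                 groups = paste(groups, collapse = ","),
                 exclusive = length(groups) == 1L,
                 stringsAsFactors = FALSE)
    }))
  } else data.frame(gene = character(0), n_enhancers = integer(0),
                    groups = character(0), exclusive = logical(0))
  rownames(assignments) <- NULL
  list(edges = edges, assignments = assignments)
}

#' Keep genes linked to a single (lineage, subgroup) group
#'
#' @param assignments the `assignments` element of [assign_enhancers()]
#'   output (or the whole list).
#' @return filtered assignments data.frame.
#' @export
filter_exclusive <- function(assignments) {
  if (is.list(assignments) && !is.data.frame(assignments))
    assignments <- assignments$assignments
  assignments[assignments$exclusive, , drop = FALSE]
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail test (`P(X >= k)`) of a query gene set
#' against each term of a library, the local equivalent of an over-
#' representation analysis: population = library universe, successes = term
#' genes, draws = query genes. Query genes outside the universe are dropped
#' with a message. Benjamini-Hochberg adjustment is applied across terms.
#'
#' @param gene_set character vector of query genes.
#' @param library named list of term -> gene vectors (e.g. [read_gmt()]).
#' @param universe all annotatable genes; default union of the library.
#' @param alpha significance threshold on the raw p (default 0.05),
#'   mirroring figure-style reporting; adjusted p is also returned.
#' @return data.frame: `term`, `k` (overlap), `K` (term size), `n` (draws),
#'   `N` (universe), `p`, `p_adj`, `significant`.
#' @export
enrich <- function(gene_set, library, universe = NULL, alpha = 0.05) {
  if (length(gene_set) == 0L) stop("empty gene set")
  if (length(library) == 0L) stop("empty annotation library")
  if (is.null(universe)) universe <- unique(unlist(library))
  bad <- vapply(library, function(g) !all(g %in% universe), logical(1))
  if (any(bad)) stop("library term(s) outside the universe: ",
                     paste(names(library)[bad], collapse = ", "))
  dropped <- setdiff(gene_set, universe)
  if (length(dropped))
    message(sprintf("enrich: dropped %d query gene(s) not in the universe",
                    length(dropped)))
  q <- intersect(gene_set, universe)
  if (length(q) == 0L) stop("no query genes left after universe filtering")
  N <- length(universe); n <- length(q)
  res <- do.call(rbind, lapply(names(library), function(term) {
    K <- length(intersect(library[[term]], universe))
    k <- length(intersect(q, library[[term]]))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  res[order(res$p), ]
}
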