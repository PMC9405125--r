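# Gene/QTL overlap annotation of final CNVRs and Fisher-based term
# enrichment with cluster enrichment scores.

#' Assign gene features to CNV regions
#'
#' A gene is assigned to a region iff their intervals share at least 1 bp.
#'
#' @param regions Region data.frame (e.g. one specificity label of the final
#'   set): `final_id` (or `region_id`), `chrom`, `start_bp`, `end_bp`.
#' @param genes Gene features: `gene_id`, optional `symbol`, `chrom`,
#'   `start_bp`, `end_bp`.
#' @param chromosomes Chromosome universe; genes on chromosomes outside it
#'   are skipped with a warning. Defaults to the regions' chromosomes.
#' @return A list: `assignments` (data.frame `region_id`, `gene_id`),
#'   `genes_by_region` (named list), `n_regions_with_genes`, `n_genes`
#'   (distinct assigned genes).
#' @export
genes_in_regions <- function(regions, genes, chromosomes = NULL) {
  id_col <- if ("final_id" %in% names(regions)) "final_id" else "region_id"
  if (is.null(chromosomes)) chromosomes <- unique(regions$chrom)
  off <- !(genes$chrom %in% chromosomes)
  if (any(off)) {
    warning(sprintf(
      "skipping %d gene(s) on chromosome(s) absent from the region universe: %s",
      sum(off), paste(unique(genes$chrom[off]), collapse = ", ")
    ))
    genes <- genes[!off, , drop = FALSE]
  }
  empty <- list(
    assignments = data.frame(region_id = character(0), gene_id = character(0),
                             stringsAsFactors = FALSE),
    genes_by_region = list(), n_regions_with_genes = 0L, n_genes = 0L
  )
  if (nrow(regions) == 0L || nrow(genes) == 0L) return(empty)
  hits <- GenomicRanges::findOverlaps(.as_granges(genes, chromosomes),
                                      .as_granges(regions, chromosomes))
  if (length(hits) == 0L) return(empty)
  assignments <- data.frame(
    region_id = regions[[id_col]][S4Vectors::subjectHits(hits)],
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    stringsAsFactors = FALSE
  )
  assignments <- assignments[order(assignments$region_id,
                                   assignments$gene_id), , drop = FALSE]
  rownames(assignments) <- NULL
  list(
    assignments = assignments,
    genes_by_region = split(assignments$gene_id, assignments$region_id),
    n_regions_with_genes = length(unique(assignments$region_id)),
    n_genes = length(unique(assignments$gene_id))
  )
}

#' QTL overlap report for candidate genes of CNV regions
#'
#' Emits one row per (region, QTL) pair where at least one of the region's
#' assigned genes overlaps the QTL interval by >= 1 bp (overlap is assessed
#' gene-by-gene, not on the region bounds). Regions whose genes hit QTL of
#' two or more distinct trait categories are flagged.
#'
#' @param region_genes Output of [genes_in_regions()].
#' @param genes Gene feature data.frame (coordinates of the assigned genes).
#' @param qtls QTL features: `qtl_id`, `trait`, `category` (trait category
#'   used for the multi-trait flag), `source`, `chrom`, `start_bp`,
#'   `end_bp`.
#' @return A list: `overlaps` (data.frame `region_id`, `qtl_id`, `trait`,
#'   `category`, `source`, `genes` comma-joined) and
#'   `multi_category_regions` (region ids hit by >= 2 categories).
#' @export
qtl_overlap_report <- function(region_genes, genes, qtls) {
  empty <- list(
    overlaps = data.frame(region_id = character(0), qtl_id = character(0),
                          trait = character(0), category = character(0),
                          source = character(0), genes = character(0),
                          stringsAsFactors = FALSE),
    multi_category_regions = character(0)
  )
  asg <- region_genes$assignments
  if (nrow(asg) == 0L || nrow(qtls) == 0L) return(empty)
  g <- genes[match(unique(asg$gene_id), genes$gene_id), , drop = FALSE]
  chroms <- unique(c(g$chrom, qtls$chrom))
  hits <- GenomicRanges::findOverlaps(.as_granges(g, chroms),
                                      .as_granges(qtls, chroms))
  if (length(hits) == 0L) return(empty)
  gene_qtl <- data.frame(
    gene_id = g$gene_id[S4Vectors::queryHits(hits)],
    qtl_idx = S4Vectors::subjectHits(hits), stringsAsFactors = FALSE
  )
  joined <- merge(asg, gene_qtl, by = "gene_id")
  if (nrow(joined) == 0L) return(empty)
  key <- split(joined, list(joined$region_id, joined$qtl_idx), drop = TRUE)
  rows <- lapply(key, function(d) {
    qi <- d$qtl_idx[1]
    data.frame(
      region_id = d$region_id[1],
      qtl_id = as.character(qtls$qtl_id[qi]),
      trait = qtls$trait[qi],
      category = qtls$category[qi],
      source = qtls$source[qi],
      genes = paste(sort(unique(d$gene_id)), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  overlaps <- do.call(rbind, rows)
  overlaps <- overlaps[order(overlaps$region_id, overlaps$qtl_id), ,
                       drop = FALSE]
  rownames(overlaps) <- NULL
  n_cat <- tapply(overlaps$category, overlaps$region_id,
                  function(x) length(unique(x)))
  list(
    overlaps = overlaps,
    multi_category_regions = sort(names(n_cat)[n_cat >= 2L])
  )
}

#' One-sided Fisher term enrichment against a background gene set
#'
#' For every term with at least one gene in the list, tests
#' over-representation of the term in the gene list versus the background
#' with a one-sided Fisher exact test (hypergeometric upper tail) and
#' reports the fold enrichment `(k/n) / (K/N)`.
#'
#' @param list_genes Character vector of candidate genes (must be a subset
#'   of the background).
#' @param background_genes Character vector, the background universe.
#' @param term_map Data.frame `gene_id`, `term_id`, optional `term_name`.
#' @param adjust If `TRUE`, add Benjamini-Hochberg adjusted p-values (raw
#'   p-values are always reported).
#' @return A data.frame sorted by p-value: `term_id`, `term_name`, `k`,
#'   `n`, `K`, `N`, `p_value`, `fold_enrichment` (and `p_adjust` when
#'   requested).
#' @export
fisher_enrichment <- function(list_genes, background_genes, term_map,
                              adjust = FALSE) {
  list_genes <- unique(as.character(list_genes))
  background_genes <- unique(as.character(background_genes))
  if (length(list_genes) == 0L) stop("`list_genes` must be non-empty")
  if (!all(list_genes %in% background_genes)) {
    stop("`list_genes` must be a subset of `background_genes`")
  }
  n <- length(list_genes)
  N <- length(background_genes)
  term_map <- term_map[term_map$gene_id %in% background_genes, , drop = FALSE]
  if (!"term_name" %in% names(term_map)) term_map$term_name <- term_map$term_id

  terms <- unique(term_map$term_id)
  rows <- lapply(terms, function(tid) {
    tg <- unique(term_map$gene_id[term_map$term_id == tid])
    K <- length(tg)
    k <- sum(list_genes %in% tg)
    if (k == 0L) return(NULL)
    p <- fisher.test(
      matrix(c(k, n - k, K - k, N - K - (n - k)), nrow = 2),
      alternative = "greater"
    )$p.value
    data.frame(
      term_id = tid,
      term_name = term_map$term_name[match(tid, term_map$term_id)],
      k = k, n = n, K = K, N = N, p_value = p,
      fold_enrichment = (k / n) / (K / N),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), n = integer(0), K = integer(0),
                      N = integer(0), p_value = numeric(0),
                      fold_enrichment = numeric(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  if (adjust) out$p_adjust <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Enrichment score of a term cluster
#'
#' The cluster enrichment score is `-log10` of the geometric mean of the
#' member terms' Fisher p-values; a score of at least 1.3 (equivalent to a
#' single-term p-value of 0.05) is flagged significant.
#'
#' @param p_values Numeric vector of member-term p-values in `(0, 1]`
#'   (zeros are clamped to 1e-300 with a warning).
#' @param cluster_id Optional cluster label.
#' @param score_threshold Significance threshold on the score.
#' @return A list: `cluster_id`, `n_terms`, `enrichment_score`,
#'   `significant`.
#' @export
cluster_score <- function(p_values, cluster_id = NA_character_,
                          score_threshold = 1.3) {
  if (length(p_values) == 0L) stop("`p_values` must be non-empty")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("`p_values` must be in (0, 1]")
  }
  if (any(p_values == 0)) {
    warning("p-value of 0 clamped to 1e-300")
    p_values[p_values == 0] <- 1e-300
  }
  score <- -mean(log10(p_values))
  list(
    cluster_id = cluster_id,
    n_terms = length(p_values),
    enrichment_score = score,
    significant = score >= score_threshold
  )
}

#' Score user-supplied term clusters from an enrichment table
#'
#' Joins a cluster definition (`cluster_id`, `term_id`) against the rows of
#' [fisher_enrichment()] and scores every cluster that has at least one
#' tested member term.
#'
#' @param enrichment Output of [fisher_enrichment()].
#' @param clusters Data.frame `cluster_id`, `term_id`.
#' @param score_threshold Significance threshold (default 1.3).
#' @return A data.frame: `cluster_id`, `n_terms`, `enrichment_score`,
#'   `significant`, sorted by decreasing score.
#' @export
score_clusters <- function(enrichment, clusters, score_threshold = 1.3) {
  merged <- merge(clusters, enrichment[, c("term_id", "p_value")],
                  by = "term_id")
  if (nrow(merged) == 0L) {
    return(data.frame(cluster_id = character(0), n_terms = integer(0),
                      enrichment_score = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(split(merged, merged$cluster_id), function(d) {
    cs <- cluster_score(d$p_value, d$cluster_id[1], score_threshold)
    data.frame(cluster_id = cs$cluster_id, n_terms = cs$n_terms,
               enrichment_score = cs$enrichment_score,
               significant = cs$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$enrichment_score, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
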