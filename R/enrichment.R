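#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `k` annotated genes when drawing a
#' query of size `n` without replacement from a universe of `N` genes of
#' which `K` carry the annotation (the one-sided Fisher exact test).
#' Computed via `phyper()` which works in log-space combinatorics, so it
#' is stable for large counts.
#'
#' @param k annotated genes in the query.
#' @param K annotated genes in the universe.
#' @param n query size.
#' @param N universe size.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (!(N >= 0 && K >= 0 && K <= N && n >= 0 && n <= N &&
        k >= 0 && k <= min(K, n)))
    stop("invalid hypergeometric configuration (need 0 <= k <= min(K, n),",
         " 0 <= K, n <= N)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric gene-set enrichment with BH-FDR
#'
#' Tests every annotation term containing at least one query gene with
#' the upper-tail hypergeometric test, then applies Benjamini-Hochberg
#' adjustment independently within each annotation category (GO and
#' KEGG terms are corrected separately).
#'
#' @param query character vector of gene symbols.
#' @param annotations list of gene-set annotations (see [read_gmt()]).
#' @param universe background gene set; defaults to all genes carrying
#'   at least one annotation.  The query must be a subset.
#' @return data.frame with columns `term_id`, `term_name`, `category`,
#'   `k`, `K`, `n`, `N`, `p`, `q`, sorted by `p` ascending with ties
#'   broken by `term_id`.
#' @export
enrich <- function(query, annotations, universe = NULL) {
  if (length(query) == 0L) stop("empty query gene set")
  query <- unique(toupper(query))
  if (is.null(universe))
    universe <- unique(toupper(unlist(lapply(annotations, `[[`, "genes"))))
  else universe <- unique(toupper(universe))
  missing <- setdiff(query, universe)
  if (length(missing))
    stop("query genes absent from the universe: ",
         paste(missing, collapse = ", "))
  N <- length(universe); n <- length(query)
  rows <- lapply(annotations, function(a) {
    genes <- intersect(unique(toupper(a$genes)), universe)
    k <- length(intersect(genes, query))
    if (k == 0L) return(NULL)
    data.frame(term_id = a$term_id, term_name = a$term_name,
               category = a$category, k = k, K = length(genes),
               n = n, N = N,
               p = hypergeom_pvalue(k, length(genes), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(term_id = character(), term_name = character(),
                      category = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (cat in unique(res$category)) {
    idx <- res$category == cat
    res$q[idx] <- p.adjust(res$p[idx], method = "BH")
  }
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select significant terms (and a top-k reporting view)
#'
#' Significance is `q < alpha`; for figure-style reporting the `top_k`
#' best terms by p-value are also returned regardless of significance,
#' each flagged.
#'
#' @param results enrichment data.frame from [enrich()].
#' @param alpha FDR threshold, in (0, 1); default 0.05.
#' @param top_k size of the reporting view; default 10.
#' @return list with `significant` (rows with `q < alpha`) and `top`
#'   (the `top_k` best rows with a logical `significant` column).
#' @export
select_significant <- function(results, alpha = 0.05, top_k = 10L) {
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  sig <- results[results$q < alpha, , drop = FALSE]
  top <- utils::head(results, top_k)
  top$significant <- top$q < alpha
  rownames(sig) <- rownames(top) <- NULL
  list(significant = sig, top = top)
}

#' Genes annotated to significant terms of a category
#'
#' @param results enrichment data.frame (one category).
#' @param annotations the annotation list the results came from.
#' @param query the query gene set (membership is reported within it).
#' @param alpha FDR threshold.
#' @return character vector of query genes in >= 1 significant term.
#' @export
significant_term_genes <- function(results, annotations, query,
                                   alpha = 0.05) {
  sig <- results$term_id[results$q < alpha]
  genes <- unique(toupper(unlist(
    lapply(annotations[sig], `[[`, "genes"))))
  sort(intersect(unique(toupper(query)), genes))
}

#' Genes present in both significant GO terms and significant KEGG
#' pathways
#'
#' @param sig_go,sig_kegg character vectors of genes backing the
#'   significant terms of each category (see
#'   [significant_term_genes()]).
#' @return sorted character vector of the intersection.
#' @export
genes_in_both <- function(sig_go, sig_kegg) {
  sort(intersect(unique(toupper(sig_go)), unique(toupper(sig_kegg))))
}

#' Screen per-miRNA targets for cancer-pathway membership
#'
#' For each candidate miRNA, keeps the predicted target genes that (a)
#' survived the GO-and-KEGG significance screen and (b) belong to at
#' least one designated cancer-related pathway.
#'
#' @param genes genes surviving [genes_in_both()] (the screen gate).
#' @param annotations KEGG annotation list.
#' @param cancer_ids term ids treated as cancer-related pathways
#'   (default `"hsa05200"`, the pan-cancer KEGG pathway).
#' @param per_mirna_edges edge data.frame (`mirna`, `gene`) from
#'   [predict_targets()].
#' @return named list, miRNA id -> sorted unique gene vector (empty
#'   vectors retained for miRNAs with no surviving target).
#' @export
screen_cancer_pathways <- function(genes, annotations,
                                   cancer_ids = "hsa05200",
                                   per_mirna_edges) {
  missing <- setdiff(cancer_ids, names(annotations))
  if (length(missing))
    stop("cancer pathway ids absent from the annotation: ",
         paste(missing, collapse = ", "))
  cancer_genes <- unique(toupper(unlist(
    lapply(annotations[cancer_ids], `[[`, "genes"))))
  keep <- intersect(unique(toupper(genes)), cancer_genes)
  out <- lapply(split(toupper(per_mirna_edges$gene),
                      per_mirna_edges$mirna),
                function(g) sort(intersect(unique(g), keep)))
  out[unique(per_mirna_edges$mirna)]
}
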