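#' Build a bipartite miRNA-gene network
#'
#' One node per miRNA and per gene, one unweighted edge per predicted
#' (miRNA, gene) regulation.  A miRNA id colliding with a gene symbol
#' would make the two parts ambiguous and is rejected.
#'
#' @param per_mirna_targets named list, miRNA id -> character vector of
#'   target gene symbols (deduplicated per miRNA; empty vectors allowed).
#' @return an object of class `BipartiteNetwork` with fields `mirnas`,
#'   `genes`, `edges` (data.frame `mirna`, `gene`).
#' @export
build_network <- function(per_mirna_targets) {
  stopifnot(is.list(per_mirna_targets), !is.null(names(per_mirna_targets)))
  edges <- do.call(rbind, lapply(names(per_mirna_targets), function(m) {
    g <- per_mirna_targets[[m]]
    if (anyDuplicated(g))
      stop("duplicate target genes for ", m, " (deduplicate first)")
    if (length(g) == 0L) return(NULL)
    data.frame(mirna = m, gene = as.character(g), stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(mirna = character(), gene = character(),
                        stringsAsFactors = FALSE)
  edges <- unique(edges)
  mirnas <- unique(edges$mirna)
  genes <- unique(edges$gene)
  clash <- intersect(mirnas, genes)
  if (length(clash))
    stop("identifier used as both miRNA and gene (prefix one namespace): ",
         paste(clash, collapse = ", "))
  rownames(edges) <- NULL
  structure(list(mirnas = mirnas, genes = genes, edges = edges),
            class = "BipartiteNetwork")
}

#' @export
print.BipartiteNetwork <- function(x, ...) {
  cat("BipartiteNetwork:", length(x$mirnas), "miRNAs,",
      length(x$genes), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Node degrees of a bipartite network
#'
#' @param network a `BipartiteNetwork`.
#' @param side `"mirna"` or `"gene"`.
#' @return named integer vector of degrees (zero-degree nodes absent,
#'   since nodes only exist through edges).
#' @export
network_degree <- function(network, side = c("mirna", "gene")) {
  side <- match.arg(side)
  stopifnot(inherits(network, "BipartiteNetwork"))
  tab <- table(network$edges[[side]])
  setNames(as.integer(tab), names(tab))
}

#' Rank miRNAs by cancer-pathway target count to nominate key miRNAs
#'
#' Key miRNAs are the regulators with the most distinct target genes in
#' the network.  The report covers every miRNA, sorted by target count
#' descending with ties broken by id; the top `top_n` rows are selected,
#' together with any further rows tied with the `top_n`-th count.
#'
#' @param network a `BipartiteNetwork` with at least one edge.
#' @param top_n number of key miRNAs to nominate; default 3.
#' @return data.frame `mirna`, `target_count`, `rank` (dense), `selected`.
#' @export
rank_key_mirnas <- function(network, top_n = 3L) {
  stopifnot(inherits(network, "BipartiteNetwork"))
  if (nrow(network$edges) == 0L) stop("empty network")
  if (top_n < 1L) stop("top_n must be >= 1")
  deg <- network_degree(network, "mirna")
  out <- data.frame(mirna = names(deg), target_count = unname(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$target_count, out$mirna), , drop = FALSE]
  out$rank <- match(out$target_count,
                    sort(unique(out$target_count), decreasing = TRUE))
  n_eff <- min(top_n, nrow(out))
  out$selected <- out$target_count >= out$target_count[n_eff]
  rownames(out) <- NULL
  out
}

#' Export a bipartite network to SIF or TSV edge-list
#'
#' SIF lines read `mirna targets gene`; the TSV form is a two-column
#' edge list with a header.  [import_network()] round-trips both.
#'
#' @param network a `BipartiteNetwork` with at least one edge.
#' @param path output file path.
#' @param format `"sif"` or `"tsv"`.
#' @return invisibly, `path`.
#' @export
export_network <- function(network, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "BipartiteNetwork"))
  if (nrow(network$edges) == 0L) stop("refusing to export an empty network")
  e <- network$edges[order(network$edges$mirna, network$edges$gene), ,
                     drop = FALSE]
  if (format == "sif") {
    writeLines(paste(e$mirna, "targets", e$gene), path)
  } else {
    write_tsv(e, path)
  }
  invisible(path)
}

#' Import a bipartite network written by [export_network()]
#'
#' @param path file path.
#' @param format `"sif"` or `"tsv"`.
#' @return a `BipartiteNetwork`.
#' @export
import_network <- function(path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    f <- strsplit(readLines(path), " ", fixed = TRUE)
    if (any(vapply(f, length, integer(1)) != 3L) ||
        any(vapply(f, `[`, character(1), 2L) != "targets"))
      stop("malformed SIF line (expected 'mirna targets gene')")
    edges <- data.frame(mirna = vapply(f, `[`, character(1), 1L),
                        gene = vapply(f, `[`, character(1), 3L),
                        stringsAsFactors = FALSE)
  } else {
    edges <- read_tsv(path)
  }
  build_network(split(edges$gene, factor(edges$mirna,
                                         unique(edges$mirna))))
}
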