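#' Scan one 3'UTR for canonical seed-match sites of one miRNA
#'
#' Finds every occurrence of the reverse complement of the miRNA seed
#' (positions 2-7) in the UTR (5'->3') and classifies it by the two
#' canonical embellishments: a match to miRNA position 8 immediately
#' 5' of the seed match, and an adenine in the target opposite miRNA
#' position 1, immediately 3' of it.
#'
#' \describe{
#'   \item{8mer}{position-8 match and the A1 adenine; reported span 8 nt.}
#'   \item{7mer-m8}{position-8 match only; span 7 nt.}
#'   \item{7mer-A1}{A1 adenine only; span 7 nt.}
#'   \item{6mer}{the bare seed match; span 6 nt.}
#' }
#'
#' Each seed occurrence is reported once with its longest applicable
#' type; reported coordinates are 1-based inclusive over the full
#' classified span (so an 8mer's span includes both flanking positions).
#' Sites whose span would include an `N` are suppressed.  U/T and case
#' differences in either sequence are immaterial.
#'
#' @param mirna_id id of the miRNA.
#' @param mirna_seq mature sequence, 5'->3', length >= 8 nt.
#' @param accession,gene UTR identity.
#' @param utr_seq UTR sequence, 5'->3' (DNA; `N` allowed).
#' @return data.frame with columns `mirna`, `accession`, `gene`,
#'   `site_type`, `start`, `end`, `site_sequence`; zero rows when there
#'   is no match.
#' @export
seed_matches <- function(mirna_id, mirna_seq, accession, gene, utr_seq) {
  mirna_seq <- as_dna(mirna_seq)
  utr_seq <- as_dna(utr_seq)
  if (nchar(mirna_seq) < 8L)
    stop("miRNA shorter than 8 nt: ", mirna_id)
  empty <- data.frame(mirna = character(), accession = character(),
                      gene = character(), site_type = character(),
                      start = integer(), end = integer(),
                      site_sequence = character(), stringsAsFactors = FALSE)
  L <- nchar(utr_seq)
  if (L < 8L) return(empty)
  seed6 <- dna_revcomp(substr(mirna_seq, 2L, 7L))          # 6-nt seed match
  m8_base <- dna_complement(substr(mirna_seq, 8L, 8L))     # 5'-flank match

  hits <- find_overlapping(seed6, utr_seq)
  if (!length(hits)) return(empty)
  rows <- lapply(hits, function(s) {
    has_m8 <- s > 1L && substr(utr_seq, s - 1L, s - 1L) == m8_base
    has_a1 <- s + 6L <= L && substr(utr_seq, s + 6L, s + 6L) == "A"
    if (has_m8 && has_a1) {
      type <- "8mer"; st <- s - 1L; en <- s + 6L
    } else if (has_m8) {
      type <- "7mer-m8"; st <- s - 1L; en <- s + 5L
    } else if (has_a1) {
      type <- "7mer-A1"; st <- s; en <- s + 6L
    } else {
      type <- "6mer"; st <- s; en <- s + 5L
    }
    site <- substr(utr_seq, st, en)
    if (grepl("N", site, fixed = TRUE)) return(NULL)
    data.frame(mirna = mirna_id, accession = accession, gene = gene,
               site_type = type, start = st, end = en,
               site_sequence = site, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Predict miRNA target genes over a UTR database
#'
#' Runs [seed_matches()] for every (miRNA, UTR) pair and aggregates the
#' sites into one edge per (miRNA, gene).  By default a gene counts as a
#' target only when at least one site of type 7mer-A1, 7mer-m8 or 8mer
#' exists in any of its transcripts; 6mer-only support is recorded in
#' the site table but produces no edge unless `min_site = "6mer"`.
#'
#' @param mirnas named character vector of mature sequences (names = ids).
#' @param utr_db data.frame with columns `accession`, `gene`, `sequence`
#'   (as from [read_utr_fasta()] or [simulate_utrs()]).
#' @param min_site weakest site type sufficient for a target call:
#'   `"7mer"` (default) or `"6mer"`.
#' @return list with `sites` (all classified sites) and `edges`
#'   (data.frame `mirna`, `gene`, `n_sites`, `site_types`; one row per
#'   predicted miRNA-gene pair, sites sorted by start within a pair).
#' @export
predict_targets <- function(mirnas, utr_db, min_site = c("7mer", "6mer")) {
  min_site <- match.arg(min_site)
  stopifnot(is.character(mirnas), !is.null(names(mirnas)))
  if (!is.data.frame(utr_db) || nrow(utr_db) == 0L)
    stop("empty UTR database")
  stopifnot(all(c("accession", "gene", "sequence") %in% names(utr_db)))
  site_list <- list()
  for (i in seq_along(mirnas)) {
    for (j in seq_len(nrow(utr_db))) {
      site_list[[length(site_list) + 1L]] <-
        seed_matches(names(mirnas)[i], mirnas[[i]],
                     utr_db$accession[j], utr_db$gene[j],
                     utr_db$sequence[j])
    }
  }
  sites <- do.call(rbind, site_list)
  sufficient <- if (min_site == "6mer") c("6mer", "7mer-A1", "7mer-m8", "8mer")
                else c("7mer-A1", "7mer-m8", "8mer")
  keep <- sites[sites$site_type %in% sufficient, , drop = FALSE]
  if (nrow(keep)) {
    keep <- keep[order(keep$mirna, keep$gene, keep$start), , drop = FALSE]
    key <- paste(keep$mirna, keep$gene, sep = "\r")
    edges <- do.call(rbind, lapply(split(keep, factor(key, unique(key))),
      function(d) data.frame(
        mirna = d$mirna[1], gene = d$gene[1], n_sites = nrow(d),
        site_types = paste(d$site_type, collapse = ","),
        stringsAsFactors = FALSE)))
    rownames(edges) <- NULL
    edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  } else {
    edges <- data.frame(mirna = character(), gene = character(),
                        n_sites = integer(), site_types = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(sites) <- rownames(edges) <- NULL
  list(sites = sites, edges = edges)
}

#' Rank predicted target genes by their number of upstream miRNAs
#'
#' Counts, for every gene, the distinct candidate miRNAs with a
#' predicted edge to it, sorts genes by that regulator count
#' (descending, ties broken by symbol), and selects the top fraction.
#' All genes tied with the boundary gene's count are included, so the
#' selection may exceed `ceiling(fraction * n)`.
#'
#' @param edges edge data.frame from [predict_targets()] (columns
#'   `mirna`, `gene`).
#' @param candidate_mirnas restrict counting to these miRNA ids
#'   (default: all miRNAs present in `edges`).
#' @param fraction top fraction to select, in (0, 1]; default 0.25.
#' @return data.frame `gene`, `regulator_count`, `selected`, sorted by
#'   count descending then gene ascending.
#' @export
rank_by_regulator_count <- function(edges, candidate_mirnas = NULL,
                                    fraction = 0.25) {
  if (!is.data.frame(edges) || nrow(edges) == 0L)
    stop("empty edge list")
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0, 1]")
  if (!is.null(candidate_mirnas)) {
    keep <- normalize_mirna_id(edges$mirna) %in%
      normalize_mirna_id(candidate_mirnas)
    edges <- edges[keep, , drop = FALSE]
    if (nrow(edges) == 0L) stop("no edges from the candidate miRNAs")
  }
  edges <- unique(edges[, c("mirna", "gene")])
  counts <- tapply(edges$mirna, edges$gene,
                   function(m) length(unique(m)))
  out <- data.frame(gene = names(counts),
                    regulator_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$regulator_count, out$gene), , drop = FALSE]
  n_sel <- ceiling(fraction * nrow(out))
  cutoff <- out$regulator_count[n_sel]
  out$selected <- out$regulator_count >= cutoff
  rownames(out) <- NULL
  out
}
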