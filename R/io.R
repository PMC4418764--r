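#' Write an expression matrix and its sample sheet to TSV
#'
#' The on-disk layout is a pair of files: an intensity table whose first
#' column is `mirna` and remaining columns are sample ids, plus a sample
#' sheet with columns `sample_id`, `patient_id`, `grade`, `tissue`.
#'
#' @param em an `ExpressionMatrix` (see [expression_matrix()]).
#' @param expr_path,samples_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(em, expr_path, samples_path) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  tab <- data.frame(mirna = rownames(em$intensities),
                    em$intensities, check.names = FALSE)
  write_tsv(tab, expr_path)
  write_tsv(em$samples, samples_path)
  invisible(c(expr_path, samples_path))
}

#' Read an expression matrix and sample sheet from TSV
#'
#' @param expr_path,samples_path paths written by [write_expression()]
#'   (or equivalent external files).
#' @return an `ExpressionMatrix`.
#' @export
read_expression <- function(expr_path, samples_path) {
  tab <- read_tsv(expr_path)
  if (names(tab)[1] != "mirna")
    stop("expression TSV must have 'mirna' as its first column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$mirna
  samples <- read_tsv(samples_path)
  expression_matrix(m, samples)
}

#' Read mature miRNA sequences from FASTA
#'
#' @param path FASTA file of mature miRNAs (RNA or DNA alphabet; U/T and
#'   case differences are tolerated).
#' @return named character vector of RNA sequences, names = miRNA ids.
#' @export
read_mirna_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as_rna(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Read a 3'UTR database from FASTA
#'
#' Headers follow the convention `accession|gene_symbol`; a header
#' without a `|` is used as both accession and symbol.
#'
#' @param path FASTA file of 3'UTR sequences.
#' @return data.frame with columns `accession`, `gene`, `sequence` (DNA,
#'   uppercase).
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  hdr <- sub("\\s.*$", "", names(ss))
  parts <- strsplit(hdr, "|", fixed = TRUE)
  data.frame(
    accession = vapply(parts, `[`, character(1), 1L),
    gene = vapply(parts, function(p) p[min(2L, length(p))], character(1)),
    sequence = as_dna(as.character(ss)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    for (st in starts)
      cat(substr(s, st, min(st + width - 1L, nchar(s))), "\n",
          sep = "", file = con)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one tab-separated line per set — term id, description,
#' then member gene symbols.
#'
#' @param path GMT file path.
#' @param category label attached to every set (e.g. "GO" or "KEGG").
#' @return list of annotations, each a list with `term_id`, `term_name`,
#'   `category`, `genes`.
#' @export
read_gmt <- function(path, category = "GO") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line (need id, description, >=1 gene): ", ln)
    list(term_id = f[1], term_name = f[2], category = category,
         genes = unique(toupper(f[-(1:2)])))
  })
  names(out) <- vapply(out, `[[`, character(1), "term_id")
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets list of annotations as returned by [read_gmt()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    if (length(s$genes) == 0L) stop("term with zero genes: ", s$term_id)
    paste(c(s$term_id, s$term_name, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
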