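#' Specify a paired tumor/normal expression simulation
#'
#' Describes the stated world of a simulated cohort: the number of
#' miRNAs, tumor/normal pairs per grade, the planted true log2 fold
#' changes, and the log-normal intensity model.  Normal-tissue
#' log2-intensities are drawn per miRNA and patient from
#' `Normal(baseline_log2_mean, baseline_log2_sd)`; the paired tumor
#' log2-intensity is the normal value plus the miRNA's true log2 fold
#' change plus `Normal(0, noise_sd)` measurement noise.
#'
#' @param n_mirnas total number of miRNAs (>= number planted).
#' @param pairs_per_grade named integer vector: tumor/normal pairs per
#'   grade (default three grades of three pairs, the profiled cohort
#'   size).
#' @param planted_up named numeric vector, miRNA id -> true log2FC (> 0).
#' @param planted_down named numeric vector, miRNA id -> true log2FC (< 0).
#' @param baseline_log2_mean,baseline_log2_sd log2-intensity baseline
#'   (defaults 8 and 1.5, a typical two-color array dynamic range).
#' @param noise_sd tumor-side measurement noise, log2 units.
#' @param rng_seed integer seed; the simulation is a pure function of the
#'   spec including this seed.
#' @return an object of class `SimulationSpec`.
#' @export
simulation_spec <- function(n_mirnas = 500,
                            pairs_per_grade = c(GI = 3, GII = 3, GIII = 3),
                            planted_up = numeric(),
                            planted_down = numeric(),
                            baseline_log2_mean = 8,
                            baseline_log2_sd = 1.5,
                            noise_sd = 0.2,
                            rng_seed = 1L) {
  if (length(planted_up) && (is.null(names(planted_up)) ||
                             any(planted_up <= 0)))
    stop("planted_up must be a named vector of positive log2FCs")
  if (length(planted_down) && (is.null(names(planted_down)) ||
                               any(planted_down >= 0)))
    stop("planted_down must be a named vector of negative log2FCs")
  if (length(intersect(names(planted_up), names(planted_down))))
    stop("planted up and down sets must be disjoint")
  if (n_mirnas < length(planted_up) + length(planted_down))
    stop("n_mirnas smaller than the number of planted miRNAs")
  if (baseline_log2_sd <= 0) stop("baseline_log2_sd must be positive")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (is.null(names(pairs_per_grade)) || any(pairs_per_grade < 1))
    stop("pairs_per_grade must be a named vector of counts >= 1")
  structure(list(n_mirnas = as.integer(n_mirnas),
                 pairs_per_grade = pairs_per_grade,
                 planted_up = planted_up, planted_down = planted_down,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "SimulationSpec")
}

#' Simulate a paired tumor/normal expression cohort
#'
#' @param spec a `SimulationSpec`.
#' @return list with elements `expression` (an `ExpressionMatrix`,
#'   linear-scale strictly positive intensities) and `truth` (data.frame
#'   `mirna`, `direction` in up/down/null, `log2fc`), covering every
#'   simulated miRNA exactly once.
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  planted <- c(spec$planted_up, spec$planted_down)
  n_null <- spec$n_mirnas - length(planted)
  null_ids <- if (n_null > 0)
    sprintf("sim-miR-null-%04d", seq_len(n_null)) else character()
  if (any(null_ids %in% names(planted)))
    stop("planted ids collide with generated null ids")
  ids <- c(names(planted), null_ids)
  true_fc <- c(unname(planted), rep(0, n_null))
  names(true_fc) <- ids

  grades <- rep(names(spec$pairs_per_grade), spec$pairs_per_grade)
  patients <- sprintf("%s_p%d", grades,
                      unlist(lapply(spec$pairs_per_grade, seq_len)))
  samples <- data.frame(
    sample_id = c(paste0(patients, "_T"), paste0(patients, "_N")),
    patient_id = rep(patients, 2L),
    grade = rep(grades, 2L),
    tissue = rep(c("tumor", "normal"), each = length(patients)),
    stringsAsFactors = FALSE)

  n_m <- length(ids); n_p <- length(patients)
  log2int <- with_seed(spec$rng_seed, {
    normal <- matrix(rnorm(n_m * n_p, spec$baseline_log2_mean,
                           spec$baseline_log2_sd), n_m, n_p)
    noise <- if (spec$noise_sd > 0)
      matrix(rnorm(n_m * n_p, 0, spec$noise_sd), n_m, n_p)
    else matrix(0, n_m, n_p)
    tumor <- normal + true_fc + noise
    cbind(tumor, normal)
  })
  m <- 2 ^ log2int
  rownames(m) <- ids
  colnames(m) <- samples$sample_id

  truth <- data.frame(
    mirna = ids,
    direction = ifelse(true_fc > 0, "up", ifelse(true_fc < 0, "down", "null")),
    log2fc = unname(true_fc), stringsAsFactors = FALSE)
  list(expression = expression_matrix(m, samples), truth = truth)
}

#' Simulate a 3'UTR corpus with planted miRNA binding sites
#'
#' Background sequence is i.i.d. uniform over A/C/G/T; planted site
#' sequences are then written at their stated 1-based offsets.  Any
#' accidental background occurrence of a cleaning pattern (by default the
#' planted site sequences themselves) outside a planted span is
#' re-randomized, so the returned truth table is exhaustive: a seed scan
#' for those patterns finds the planted sites and nothing else.
#'
#' @param genes character vector of gene symbols (one UTR each;
#'   accessions are generated as `SYN_<gene>`).
#' @param length UTR length in nt (single value or one per gene).
#' @param planted_sites data.frame with columns `gene`, `offset`
#'   (1-based), `site_sequence` (DNA or RNA); may have zero rows.
#' @param rng_seed integer seed.
#' @param clean_patterns DNA patterns to scrub from the background;
#'   defaults to the planted site sequences.
#' @return list with `utrs` (data.frame `accession`, `gene`, `sequence`)
#'   and `truth` (the planted sites with an `end` column added).
#' @export
simulate_utrs <- function(genes, length = 600L, planted_sites = NULL,
                          rng_seed = 1L, clean_patterns = NULL) {
  stopifnot(is.character(genes), !anyDuplicated(genes))
  lens <- rep_len(as.integer(length), base::length(genes))
  names(lens) <- genes
  if (is.null(planted_sites))
    planted_sites <- data.frame(gene = character(), offset = integer(),
                                site_sequence = character())
  stopifnot(all(c("gene", "offset", "site_sequence") %in%
                  names(planted_sites)))
  planted_sites$site_sequence <- as_dna(planted_sites$site_sequence)
  planted_sites$end <- planted_sites$offset +
    nchar(planted_sites$site_sequence) - 1L
  if (!all(planted_sites$gene %in% genes))
    stop("planted site refers to unknown gene")
  if (any(planted_sites$offset < 1L) ||
      any(planted_sites$end > lens[planted_sites$gene]))
    stop("planted site does not fit within its UTR")
  for (g in unique(planted_sites$gene)) {
    p <- planted_sites[planted_sites$gene == g, , drop = FALSE]
    p <- p[order(p$offset), , drop = FALSE]
    if (nrow(p) > 1L && any(p$offset[-1L] <= p$end[-nrow(p)]))
      stop("overlapping planted sites on gene ", g)
  }
  if (is.null(clean_patterns))
    clean_patterns <- unique(planted_sites$site_sequence)
  clean_patterns <- unique(as_dna(clean_patterns))

  alphabet <- c("A", "C", "G", "T")
  utr_seqs <- with_seed(rng_seed, {
    vapply(genes, function(g) {
      chars <- sample(alphabet, lens[[g]], replace = TRUE)
      p <- planted_sites[planted_sites$gene == g, , drop = FALSE]
      protected <- logical(lens[[g]])
      for (i in seq_len(nrow(p))) {
        span <- p$offset[i]:p$end[i]
        chars[span] <- strsplit(p$site_sequence[i], "")[[1]]
        protected[span] <- TRUE
      }
      # scrub accidental pattern occurrences outside planted spans
      repeat {
        seqstr <- paste(chars, collapse = "")
        dirty <- integer()
        for (pat in clean_patterns) {
          for (h in find_overlapping(pat, seqstr)) {
            span <- h:(h + nchar(pat) - 1L)
            if (!all(protected[span])) dirty <- c(dirty, span[!protected[span]])
          }
        }
        if (!base::length(dirty)) break
        chars[unique(dirty)] <- sample(alphabet, base::length(unique(dirty)),
                                       replace = TRUE)
      }
      seqstr
    }, character(1))
  })
  utrs <- data.frame(accession = paste0("SYN_", genes), gene = genes,
                     sequence = unname(utr_seqs), stringsAsFactors = FALSE)
  list(utrs = utrs, truth = planted_sites)
}

#' Simulate a gene-set annotation corpus with planted enrichment
#'
#' Writes term -> gene-set annotations where designated terms over-sample
#' a query gene list: an enriched term contains
#' `round(fraction * length(query))` query genes, topped up with
#' background genes; null terms are drawn uniformly from the universe.
#'
#' @param universe character vector of gene symbols.
#' @param query character vector, subset of `universe`.
#' @param n_terms number of terms.
#' @param genes_per_term genes per term.
#' @param enriched named numeric vector; names are term ids among the
#'   generated `"<category>:NNNN"` ids, values are the fraction of the
#'   query each enriched term annotates, in (0, 1].
#' @param rng_seed integer seed.
#' @param category category label for the generated sets.
#' @return list with `sets` (annotation list as from [read_gmt()]) and
#'   `truth` (data.frame `term_id`, `enriched`, `fraction`).
#' @export
simulate_annotations <- function(universe, query, n_terms = 100L,
                                 genes_per_term = 50L,
                                 enriched = numeric(), rng_seed = 1L,
                                 category = "GO") {
  stopifnot(all(query %in% universe))
  if (length(enriched)) {
    if (is.null(names(enriched)) || any(enriched <= 0) || any(enriched > 1))
      stop("enriched must be a named vector of fractions in (0, 1]")
  }
  if (genes_per_term < 1L) stop("term with zero genes requested")
  term_ids <- sprintf("%s:%04d", category, seq_len(n_terms))
  bad <- setdiff(names(enriched), term_ids)
  if (length(bad)) stop("enriched names not among generated term ids: ",
                        paste(bad, collapse = ", "))
  background <- setdiff(universe, query)
  sets <- with_seed(rng_seed, {
    lapply(term_ids, function(tid) {
      if (tid %in% names(enriched)) {
        nq <- min(round(enriched[[tid]] * length(query)), genes_per_term,
                  length(query))
        g <- c(sample(query, nq),
               sample(background, min(genes_per_term - nq,
                                      length(background))))
      } else {
        g <- sample(universe, min(genes_per_term, length(universe)))
      }
      list(term_id = tid, term_name = paste0("synthetic term ", tid),
           category = category, genes = sort(unique(toupper(g))))
    })
  })
  names(sets) <- term_ids
  truth <- data.frame(
    term_id = term_ids,
    enriched = term_ids %in% names(enriched),
    fraction = ifelse(term_ids %in% names(enriched),
                      enriched[term_ids], NA_real_),
    stringsAsFactors = FALSE)
  list(sets = sets, truth = truth)
}

#' Simulate mature miRNA sequences with fixed seeds
#'
#' Generates random 22-nt mature RNA sequences for a list of miRNA ids,
#' guaranteeing distinct seed regions so that their planted target sites
#' are unambiguous.
#'
#' @param mirna_ids character vector of ids.
#' @param rng_seed integer seed.
#' @return named character vector of RNA sequences.
#' @export
simulate_mirnas <- function(mirna_ids, rng_seed = 1L) {
  stopifnot(is.character(mirna_ids), !anyDuplicated(mirna_ids))
  alphabet <- c("A", "C", "G", "U")
  with_seed(rng_seed, {
    seqs <- character(0)
    seeds_seen <- character(0)
    for (id in mirna_ids) {
      repeat {
        s <- paste(sample(alphabet, 22L, replace = TRUE), collapse = "")
        sd <- substr(s, 2L, 8L)
        if (!(sd %in% seeds_seen)) { seeds_seen <- c(seeds_seen, sd); break }
      }
      seqs[[id]] <- s
    }
    seqs
  })
}
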