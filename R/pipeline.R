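#' Configure an end-to-end pipeline run
#'
#' Two execution modes are supported.  `"simulation"` generates every
#' input from the synthetic-data module (expression cohort, mature
#' miRNAs, UTR corpus with planted sites, annotation corpora with a
#' planted cancer pathway) and runs all stages.  `"fixture"` starts from
#' the packaged published tables: the per-grade differential lists feed
#' the intersection stage and the published per-miRNA cancer-pathway
#' target lists feed the network stage directly, short-circuiting the
#' target-prediction and enrichment stages whose original inputs are
#' unrecoverable.
#'
#' @param mode `"simulation"` or `"fixture"`.
#' @param out_dir artifact directory (created if absent).
#' @param rng_seed single integer driving all randomness.
#' @param threshold_fold differential-call fold threshold (> 1).
#' @param de_mode `"mean"` or `"all_pairs"` (see
#'   [call_grade_differential()]).
#' @param min_site weakest site type counted as a target call.
#' @param fraction top fraction of ranked targets carried into
#'   enrichment.
#' @param alpha FDR threshold for term significance.
#' @param cancer_ids KEGG ids treated as cancer-related pathways.
#' @param top_n key miRNAs to nominate.
#' @param excluded miRNAs removed after validation (fixture mode
#'   default: `"hsa-miR-200c"`, the candidate whose qRT-PCR direction
#'   contradicted the array).
#' @param sim simulation-mode knobs: `n_mirnas`, `pairs_per_grade`,
#'   `n_planted_up`, `n_planted_down`, `planted_log2fc`, `noise_sd`,
#'   `n_genes`, `utr_length`, `site_prob`, `n_terms`, `genes_per_term`.
#' @return an object of class `PipelineConfig`.
#' @export
pipeline_config <- function(mode = c("simulation", "fixture"),
                            out_dir,
                            rng_seed = 1L,
                            threshold_fold = 2,
                            de_mode = "mean",
                            min_site = "7mer",
                            fraction = 0.25,
                            alpha = 0.05,
                            cancer_ids = "hsa05200",
                            top_n = 3L,
                            excluded = NULL,
                            sim = list()) {
  mode <- match.arg(mode)
  if (is.null(excluded))
    excluded <- if (mode == "fixture") "hsa-miR-200c" else character()
  sim_defaults <- list(n_mirnas = 500L,
                       pairs_per_grade = c(GI = 3L, GII = 3L, GIII = 3L),
                       n_planted_up = 12L, n_planted_down = 12L,
                       planted_log2fc = 2, noise_sd = 0.2,
                       n_genes = 60L, utr_length = 600L, site_prob = 0.3,
                       n_terms = 50L, genes_per_term = 20L)
  sim <- utils::modifyList(sim_defaults, sim)
  structure(list(mode = mode, out_dir = out_dir,
                 rng_seed = as.integer(rng_seed),
                 threshold_fold = threshold_fold, de_mode = de_mode,
                 min_site = min_site, fraction = fraction, alpha = alpha,
                 cancer_ids = cancer_ids, top_n = as.integer(top_n),
                 excluded = excluded, sim = sim),
            class = "PipelineConfig")
}

# Internal: stable hash of a config (md5 of its canonical JSON).
# The artifact directory is excluded: two runs of the same analysis into
# different directories are the same run.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

# Internal: stage-tagged error propagation.
stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full key-miRNA discovery pipeline
#'
#' Executes the configured stages in order, writing each stage's TSV
#' artifacts under `config$out_dir`, and returns a run report.  The run
#' is a pure function of the config (including its seed): re-running
#' with an identical config reproduces byte-identical artifacts.
#'
#' @param config a `PipelineConfig`.
#' @return a `RunReport` list: per-stage counts, the common set, the
#'   key-miRNA table, parameter echo, package version and config hash.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  report <- list(mode = config$mode,
                 version = as.character(packageVersion("mirkey")),
                 config_hash = config_hash(config),
                 parameters = unclass(config))

  if (config$mode == "simulation") {
    s <- config$sim
    common <- stage("diffexpr", {
      up_ids <- sprintf("sim-miR-up-%03d", seq_len(s$n_planted_up))
      down_ids <- sprintf("sim-miR-down-%03d", seq_len(s$n_planted_down))
      spec <- simulation_spec(
        n_mirnas = s$n_mirnas, pairs_per_grade = s$pairs_per_grade,
        planted_up = setNames(rep(s$planted_log2fc, length(up_ids)), up_ids),
        planted_down = setNames(rep(-s$planted_log2fc, length(down_ids)),
                                down_ids),
        noise_sd = s$noise_sd, rng_seed = config$rng_seed)
      sim <- simulate_expression(spec)
      write_expression(sim$expression, out("expression.tsv"),
                       out("samples.tsv"))
      write_tsv(sim$truth, out("truth_expression.tsv"))
      recs <- pairwise_log2fc(sim$expression)
      calls <- call_grade_differential(recs, config$threshold_fold,
                                       config$de_mode)
      calls_df <- do.call(rbind, lapply(names(calls$calls), function(g) {
        ids <- c(calls$calls[[g]]$up, calls$calls[[g]]$down)
        data.frame(grade = rep(g, length(ids)), mirna = ids,
                   direction = rep(c("up", "down"),
                                   c(length(calls$calls[[g]]$up),
                                     length(calls$calls[[g]]$down))),
                   stringsAsFactors = FALSE)
      }))
      write_tsv(calls_df, out("calls.tsv"))
      common <- common_dysregulated(calls)
      common <- apply_validation_exclusions(common, config$excluded)
      write_tsv(data.frame(mirna = c(common$up, common$down),
                           direction = rep(c("up", "down"),
                                           c(length(common$up),
                                             length(common$down)))),
                out("common.tsv"))
      report$counts$common_up <- length(common$up)
      report$counts$common_down <- length(common$down)
      common
    })

    targets <- stage("targets", {
      candidates <- c(common$up, common$down)
      if (!length(candidates)) stop("empty common set, nothing to predict")
      mirnas <- simulate_mirnas(candidates, rng_seed = config$rng_seed + 1L)
      write_fasta(mirnas, out("mirnas.fa"))
      genes <- sprintf("GENE%03d", seq_len(s$n_genes))
      # plant a 7mer-m8 site (match to miRNA 2-8) for a random subset of
      # (miRNA, gene) pairs, at non-overlapping offsets
      planted <- with_seed(config$rng_seed + 2L, {
        rows <- list()
        for (g in genes) {
          pick <- candidates[stats::runif(length(candidates)) < s$site_prob]
          if (!length(pick)) next
          offs <- 30L + 40L * seq_along(pick)
          for (i in seq_along(pick)) {
            site <- dna_revcomp(as_dna(substr(mirnas[[pick[i]]], 2L, 8L)))
            rows[[length(rows) + 1L]] <- data.frame(
              gene = g, offset = offs[i], site_sequence = site,
              mirna = pick[i], stringsAsFactors = FALSE)
          }
        }
        do.call(rbind, rows)
      })
      corpus <- simulate_utrs(genes, length = s$utr_length,
                              planted_sites = planted[, 1:3],
                              rng_seed = config$rng_seed + 3L,
                              clean_patterns = dna_revcomp(
                                as_dna(substr(mirnas, 2L, 8L))))
      write_fasta(setNames(corpus$utrs$sequence,
                           paste(corpus$utrs$accession, corpus$utrs$gene,
                                 sep = "|")), out("utrs.fa"))
      pred <- predict_targets(mirnas, corpus$utrs, config$min_site)
      write_tsv(pred$sites, out("sites.tsv"))
      write_tsv(pred$edges, out("edges.tsv"))
      ranked <- rank_by_regulator_count(pred$edges, candidates,
                                        config$fraction)
      write_tsv(ranked, out("ranked_targets.tsv"))
      report$counts$predicted_edges <- nrow(pred$edges)
      report$counts$selected_genes <- sum(ranked$selected)
      list(edges = pred$edges, ranked = ranked, universe = genes)
    })

    screened <- stage("enrichment", {
      query <- targets$ranked$gene[targets$ranked$selected]
      go <- simulate_annotations(targets$universe, query,
                                 n_terms = s$n_terms,
                                 genes_per_term = s$genes_per_term,
                                 enriched = setNames(0.8, "GO:0001"),
                                 rng_seed = config$rng_seed + 4L,
                                 category = "GO")
      kegg <- simulate_annotations(targets$universe, query,
                                   n_terms = s$n_terms,
                                   genes_per_term = s$genes_per_term,
                                   enriched = setNames(0.8, "KEGG:0001"),
                                   rng_seed = config$rng_seed + 5L,
                                   category = "KEGG")
      # designate a planted cancer pathway holding most query genes
      cancer <- with_seed(config$rng_seed + 6L, {
        nq <- min(round(0.8 * length(query)), length(query))
        bg <- setdiff(targets$universe, query)
        n_bg <- max(0L, min(s$genes_per_term - nq, length(bg)))
        list(term_id = config$cancer_ids[1],
             term_name = "synthetic pathways-in-cancer stand-in",
             category = "KEGG",
             genes = sort(c(sample(query, nq), sample(bg, n_bg))))
      })
      kegg$sets[[cancer$term_id]] <- cancer
      write_gmt(go$sets, out("go.gmt"))
      write_gmt(kegg$sets, out("kegg.gmt"))
      res_go <- enrich(query, go$sets, targets$universe)
      res_kegg <- enrich(query, kegg$sets, targets$universe)
      write_tsv(res_go, out("enrichment_go.tsv"))
      write_tsv(res_kegg, out("enrichment_kegg.tsv"))
      both <- genes_in_both(
        significant_term_genes(res_go, go$sets, query, config$alpha),
        significant_term_genes(res_kegg, kegg$sets, query, config$alpha))
      screened <- screen_cancer_pathways(both, kegg$sets,
                                         config$cancer_ids,
                                         targets$edges)
      report$counts$genes_in_both <- length(both)
      screened
    })
    per_mirna <- screened
  } else {
    per_mirna <- stage("fixture", {
      callset <- load_table_fixture("T1")
      common <- common_dysregulated(callset)
      report$counts$intersection_up <- length(common$up)
      report$counts$intersection_down <- length(common$down)
      # reconcile against the published table's own common-set
      # designation: entries present in every grade's list but not
      # designated (miR-768-3p) are removed with an audit record
      pub <- attr(callset, "published_common")
      not_designated <- c(mirna_setdiff(common$up, pub$up),
                          mirna_setdiff(common$down, pub$down))
      if (length(not_designated)) {
        common <- apply_validation_exclusions(common, not_designated)
        report$counts$not_designated_excluded <- length(not_designated)
        report$not_designated <- not_designated
      }
      report$counts$common_up_pre <- length(common$up)
      report$counts$common_down_pre <- length(common$down)
      common <- apply_validation_exclusions(common, config$excluded)
      write_tsv(data.frame(mirna = c(common$up, common$down),
                           direction = rep(c("up", "down"),
                                           c(length(common$up),
                                             length(common$down)))),
                out("common.tsv"))
      report$counts$common_up <- length(common$up)
      report$counts$common_down <- length(common$down)
      load_table_fixture("T2")
    })
  }

  key <- stage("network", {
    net <- build_network(per_mirna)
    export_network(net, out("network.sif"), "sif")
    export_network(net, out("network_edges.tsv"), "tsv")
    key <- rank_key_mirnas(net, config$top_n)
    write_tsv(key, out("key_mirnas.tsv"))
    report$counts$network_edges <- nrow(net$edges)
    key
  })
  report$key_mirnas <- key[key$selected, , drop = FALSE]
  class(report) <- "RunReport"
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE),
             out("report.json"))
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("mirkey run (", x$mode, " mode), config ", x$config_hash, "\n",
      sep = "")
  for (nm in names(x$counts)) cat("  ", nm, ": ", x$counts[[nm]], "\n",
                                  sep = "")
  cat("key miRNAs:\n")
  print(x$key_mirnas, row.names = FALSE)
  invisible(x)
}
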