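test_that("simulate_expression honors planted fold changes and the seed", {
  spec <- simulation_spec(
    n_mirnas = 20, pairs_per_grade = c(GI = 3, GII = 3),
    planted_up = c(m1 = 2), planted_down = c(m2 = -1.5),
    noise_sd = 0, rng_seed = 11)
  sim <- simulate_expression(spec)
  em <- sim$expression

  # noise-free: every tumor/normal pair shows exactly the planted fold
  recs <- pairwise_log2fc(em)
  expect_equal(recs$log2fc[recs$mirna == "m1"], rep(2, 6))
  expect_equal(recs$log2fc[recs$mirna == "m2"], rep(-1.5, 6))
  nulls <- recs$log2fc[!(recs$mirna %in% c("m1", "m2"))]
  expect_equal(nulls, rep(0, length(nulls)))

  # determinism: same spec, same seed, bit-identical output
  sim2 <- simulate_expression(spec)
  expect_identical(sim$expression$intensities, sim2$expression$intensities)
  expect_identical(sim$truth, sim2$truth)

  # truth table covers every miRNA exactly once
  expect_setequal(sim$truth$mirna, rownames(em$intensities))
  expect_false(anyDuplicated(sim$truth$mirna) > 0)
  expect_true(all(em$intensities > 0))
})

test_that("simulate_expression Monte-Carlo mean matches the planted value", {
  spec <- simulation_spec(
    n_mirnas = 1, pairs_per_grade = c(G = 1000),
    planted_up = c(m1 = 1.5), noise_sd = 0.3, rng_seed = 42)
  recs <- pairwise_log2fc(simulate_expression(spec)$expression)
  expect_lt(abs(mean(recs$log2fc) - 1.5), 3 * 0.3 / sqrt(1000))
})

test_that("simulation_spec rejects invalid worlds", {
  expect_error(simulation_spec(planted_up = c(a = 1), planted_down = c(a = -1)),
               "disjoint")
  expect_error(simulation_spec(planted_up = c(a = -1)), "positive")
  expect_error(simulation_spec(n_mirnas = 1, planted_up = c(a = 1, b = 2)),
               "smaller")
  expect_error(simulation_spec(baseline_log2_sd = 0), "positive")
})

test_that("simulate_utrs plants sites verbatim and cleans the background", {
  planted <- data.frame(gene = "VEGFA", offset = 483,
                        site_sequence = "CACTGGA")
  corpus <- simulate_utrs("VEGFA", length = 600, planted_sites = planted,
                          rng_seed = 3)
  expect_identical(substr(corpus$utrs$sequence, 483, 489), "CACTGGA")
  expect_equal(corpus$truth$end, 489)

  # cleaned background: no accidental seed matches when none are planted
  bare <- simulate_utrs("G1", length = 2000, rng_seed = 5,
                        clean_patterns = c("CACTGG", "ACACTGG"))
  expect_false(grepl("CACTGG", bare$utrs$sequence, fixed = TRUE))

  # determinism
  again <- simulate_utrs("VEGFA", length = 600, planted_sites = planted,
                         rng_seed = 3)
  expect_identical(corpus$utrs, again$utrs)

  expect_error(
    simulate_utrs("g", length = 100,
                  planted_sites = data.frame(
                    gene = "g", offset = c(10, 12),
                    site_sequence = c("CACTGGA", "CACTGGA"))),
    "overlapping")
  expect_error(
    simulate_utrs("g", length = 20,
                  planted_sites = data.frame(
                    gene = "g", offset = 18, site_sequence = "CACTGGA")),
    "fit")
})

test_that("planted UTR corpus round-trips through the seed-match engine", {
  set.seed(902)
  mirnas <- setNames(random_rna(5), paste0("mir", 1:5))
  genes <- sprintf("G%02d", 1:50)
  seeds7 <- vapply(mirnas, function(m) {
    comp <- c(A = "T", C = "G", G = "C", U = "A")
    paste(rev(comp[strsplit(substr(m, 2, 8), "")[[1]]]), collapse = "")
  }, character(1))
  planted <- do.call(rbind, lapply(1:20, function(i) {
    data.frame(gene = genes[i], offset = 50 + 13 * i,
               mirna = names(mirnas)[(i %% 5) + 1],
               stringsAsFactors = FALSE)
  }))
  planted$site_sequence <- unname(seeds7[planted$mirna])
  # clean against the bare 6-nt seed matches so planted truth is exhaustive
  corpus <- simulate_utrs(genes, length = 400,
                          planted_sites = planted[, c("gene", "offset",
                                                      "site_sequence")],
                          rng_seed = 77,
                          clean_patterns = substr(seeds7, 2, 7))
  pred <- predict_targets(mirnas, corpus$utrs)
  got <- pred$edges[, c("mirna", "gene")]
  want <- unique(planted[, c("mirna", "gene")])
  expect_setequal(paste(got$mirna, got$gene),
                  paste(want$mirna, want$gene))
  # and the recovered sites sit exactly where they were planted
  sites <- pred$sites[order(pred$sites$gene), ]
  planted_o <- planted[order(planted$gene), ]
  expect_equal(sites$start, planted_o$offset)
  expect_true(all(sites$site_type %in% c("7mer-m8", "8mer")))
})

test_that("simulate_annotations is deterministic and plants recoverable enrichment", {
  universe <- sprintf("GENE%04d", 1:2000)
  query <- universe[1:40]
  enr <- setNames(rep(0.8, 5), sprintf("GO:%04d", 1:5))

  ann <- simulate_annotations(universe, query, n_terms = 100,
                              genes_per_term = 50, enriched = enr,
                              rng_seed = 1)
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(ann$sets, f1)
  write_gmt(simulate_annotations(universe, query, n_terms = 100,
                                 genes_per_term = 50, enriched = enr,
                                 rng_seed = 1)$sets, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(sum(ann$truth$enriched), 5L)

  # planted terms occupy the top 5 ranks by p-value in >= 95/100 seeds
  hits <- vapply(1:100, function(s) {
    a <- simulate_annotations(universe, query, n_terms = 100,
                              genes_per_term = 50, enriched = enr,
                              rng_seed = s)
    res <- enrich(query, a$sets, universe)
    all(names(enr) %in% res$term_id[1:5])
  }, logical(1))
  expect_gte(sum(hits), 95)

  expect_error(simulate_annotations(universe, query, genes_per_term = 0),
               "zero genes")
  expect_error(simulate_annotations(universe, query,
                                    enriched = c(`GO:0001` = 1.2)),
               "fraction")
})

test_that("table fixtures load with their published structure", {
  t1 <- load_table_fixture("T1")
  expect_s3_class(t1, "DifferentialCallSet")
  expect_identical(t1$calls$GI$up[1:4],
                   c("hsa-miR-452", "hsa-miR-487a", "hsa-miR-491-3p",
                     "hsa-miR-200c"))
  expect_length(t1$calls$GI$up, 12)
  expect_length(t1$calls$GII$down, 17)
  pub <- attr(t1, "published_common")
  expect_length(pub$up, 4)
  expect_length(pub$down, 8)

  t2 <- load_table_fixture("T2")
  expect_named(t2, c("miR-199-5p", "miR-22", "miR-429"))
  expect_true(all(c("TGFBR1", "VEGFA") %in% t2[["miR-199-5p"]]))
  expect_equal(lengths(t2), c(`miR-199-5p` = 53L, `miR-22` = 53L,
                              `miR-429` = 51L))

  t3 <- load_table_fixture("T3")
  expect_length(unique(t3$gene), 6)
  expect_true(all(t3$end - t3$start + 1 %in% c(7, 8)))
})
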