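test_that("pairwise_log2fc matches an element-wise ratio oracle", {
  # identity case
  set.seed(1)
  base <- matrix(runif(20, 10, 100), 5, 4,
                 dimnames = list(paste0("m", 1:5), NULL))
  em <- make_matrix(base, base)
  expect_equal(pairwise_log2fc(em)$log2fc, rep(0, 20))

  # exact ratio
  em4 <- make_matrix(base * 4, base)
  expect_equal(pairwise_log2fc(em4)$log2fc, rep(2, 20))

  # random matrix vs independent per-cell oracle
  set.seed(2)
  tum <- matrix(runif(300, 1, 1000), 50, 6,
                dimnames = list(sprintf("m%02d", 1:50), NULL))
  nor <- matrix(runif(300, 1, 1000), 50, 6,
                dimnames = list(sprintf("m%02d", 1:50), NULL))
  em <- make_matrix(tum, nor)
  recs <- pairwise_log2fc(em)
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    p <- as.integer(sub("^GI_p", "", r$patient_id))
    expect_identical(r$log2fc,
                     unname(log2(tum[r$mirna, p] / nor[r$mirna, p])))
  }
})

test_that("expression_matrix validates pairing and positivity", {
  m <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  samples <- data.frame(sample_id = c("s1", "s2"), patient_id = "p1",
                        grade = "GI", tissue = c("tumor", "tumor"))
  expect_error(expression_matrix(m, samples), "pair")
  samples$tissue <- c("tumor", "normal")
  expect_silent(expression_matrix(m, samples))
  m[1, 1] <- 0
  expect_error(expression_matrix(m, samples), "positive")
})

test_that("call_grade_differential uses strict thresholds in both modes", {
  # mean fold change exactly at the threshold is NOT called
  recs <- data.frame(mirna = "m1", patient_id = paste0("p", 1:3),
                     grade = "GI", log2fc = c(1, 1, 1))  # mean fold = 2.0
  calls <- call_grade_differential(recs, threshold_fold = 2)
  expect_length(calls$calls$GI$up, 0)
  recs$log2fc <- c(1.01, 1, 1)
  expect_identical(call_grade_differential(recs, 2)$calls$GI$up, "m1")

  # all_pairs requires every pair to clear the bar
  recs$log2fc <- c(3, 3, 0.5)
  expect_length(call_grade_differential(recs, 2, "all_pairs")$calls$GI$up, 0)
  expect_identical(call_grade_differential(recs, 2, "mean")$calls$GI$up, "m1")

  expect_error(call_grade_differential(recs, threshold_fold = 1), "> 1")
})

test_that("random call sets equal an independent threshold-scan oracle", {
  set.seed(33)
  n_m <- 200
  recs <- expand.grid(mirna = sprintf("m%03d", 1:n_m),
                      patient_id = paste0("p", 1:3),
                      stringsAsFactors = FALSE)
  recs$grade <- "GI"
  recs$log2fc <- rnorm(nrow(recs), 0, 1.5)
  for (mode in c("mean", "all_pairs")) {
    calls <- call_grade_differential(recs, 2, mode)$calls$GI
    for (m in unique(recs$mirna)) {
      v <- recs$log2fc[recs$mirna == m]
      folds <- 2 ^ v
      up <- if (mode == "mean") 2 ^ mean(v) > 2 else all(folds > 2)
      down <- if (mode == "mean") 2 ^ mean(v) < 0.5 else all(folds < 0.5)
      expect_identical(m %in% calls$up, up)
      expect_identical(m %in% calls$down, down)
    }
  }
})

test_that("fold-change antisymmetry and threshold monotonicity hold", {
  set.seed(4)
  tum <- matrix(runif(60, 1, 100), 10, 6,
                dimnames = list(paste0("m", 1:10), NULL))
  nor <- matrix(runif(60, 1, 100), 10, 6,
                dimnames = list(paste0("m", 1:10), NULL))
  grades <- rep(c("GI", "GII"), each = 3)
  em <- make_matrix(tum, nor, grades)
  em_sw <- make_matrix(nor, tum, grades)
  r <- pairwise_log2fc(em); r_sw <- pairwise_log2fc(em_sw)
  expect_equal(r_sw$log2fc, -r$log2fc)
  c1 <- call_grade_differential(r, 1.5)
  c2 <- call_grade_differential(r_sw, 1.5)
  for (g in names(c1$calls)) {
    expect_identical(c1$calls[[g]]$up, c2$calls[[g]]$down)
    expect_identical(c1$calls[[g]]$down, c2$calls[[g]]$up)
  }
  # raising the threshold never adds a call
  for (thr in c(1.2, 1.5, 2, 3, 5)) {
    lo <- call_grade_differential(r, thr)
    hi <- call_grade_differential(r, thr * 1.5)
    for (g in names(lo$calls)) {
      expect_true(all(hi$calls[[g]]$up %in% lo$calls[[g]]$up))
      expect_true(all(hi$calls[[g]]$down %in% lo$calls[[g]]$down))
    }
  }
})

test_that("common_dysregulated intersects per-grade calls", {
  cs <- differential_callset(list(
    GI = list(up = c("hsa-miR-1", "hsa-miR-2"), down = c("hsa-miR-9")),
    GII = list(up = c("miR-1", "miR-3"), down = c("miR-9", "miR-2")),
    GIII = list(up = c("miR-1", "miR-2"), down = c("miR-9"))))
  common <- common_dysregulated(cs)
  # miR-1 up everywhere; miR-2 up in GI/GIII but down in GII -> excluded
  expect_identical(common$up, "hsa-miR-1")
  expect_identical(common$down, "hsa-miR-9")
  # structural invariant: common is a subset of every grade's call set
  for (g in names(cs$calls)) {
    expect_true(all(normalize_mirna_id(common$up) %in%
                      normalize_mirna_id(cs$calls[[g]]$up)))
    expect_true(all(normalize_mirna_id(common$down) %in%
                      normalize_mirna_id(cs$calls[[g]]$down)))
  }
  # pairwise-disjoint grade lists give an empty common set
  empty <- common_dysregulated(differential_callset(list(
    GI = list(up = "a", down = "b"), GII = list(up = "c", down = "d"))))
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
  expect_error(common_dysregulated(differential_callset(
    list(GI = list(up = "a", down = "b")))), "two grades")
})

test_that("validation exclusions remove ids with an audit trail", {
  common <- structure(list(up = c("hsa-miR-200c", "hsa-miR-452"),
                           down = "hsa-miR-22", grades = c("GI", "GII")),
                      class = "CommonSet")
  out <- apply_validation_exclusions(common, "miR-200c")
  expect_identical(out$up, "hsa-miR-452")
  expect_identical(attr(out, "audit")$action, "removed_up")
  # absent id: unchanged output plus a logged no-op
  noop <- apply_validation_exclusions(common, "miR-999")
  expect_identical(noop$up, common$up)
  expect_identical(attr(noop, "audit")$action, "not_present")
  # empty exclusion is the identity
  ident <- apply_validation_exclusions(common, character())
  expect_identical(ident$up, common$up)
  expect_identical(ident$down, common$down)
})

test_that("planted truth is recovered across seeds (sensitivity/specificity)", {
  # noise_sd 0.2, |log2FC| 1.5, 3 pairs/grade: common-set recovery should
  # have sensitivity and specificity >= 0.95 aggregated over 100 seeds
  n_up <- 6; n_down <- 6; n_m <- 100
  tp <- fp <- fn <- tn <- 0
  for (s in 1:100) {
    spec <- simulation_spec(
      n_mirnas = n_m,
      planted_up = setNames(rep(1.5, n_up), paste0("up", 1:n_up)),
      planted_down = setNames(rep(-1.5, n_down), paste0("dn", 1:n_down)),
      noise_sd = 0.2, rng_seed = s)
    sim <- simulate_expression(spec)
    common <- common_dysregulated(
      call_grade_differential(pairwise_log2fc(sim$expression), 2))
    called <- c(common$up, common$down)
    truth_pos <- sim$truth$mirna[sim$truth$direction != "null"]
    truth_neg <- sim$truth$mirna[sim$truth$direction == "null"]
    tp <- tp + sum(truth_pos %in% called)
    fn <- fn + sum(!(truth_pos %in% called))
    fp <- fp + sum(truth_neg %in% called)
    tn <- tn + sum(!(truth_neg %in% called))
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tn / (tn + fp), 0.95)
})
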