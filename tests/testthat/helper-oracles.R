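# Independent oracles used across the suite.  These deliberately share
# no code with the package internals: plain substring comparisons,
# explicit combinatorial sums and the textbook step-up, so that
# agreement is evidence and not tautology.

# Brute-force seed-site scan: tests all four site patterns at every
# offset of the UTR and keeps the longest match per seed-match start.
oracle_seed_scan <- function(mirna_seq, utr_seq) {
  to_dna <- function(x) chartr("Uu", "Tt", toupper(x))
  rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
  }
  m <- to_dna(mirna_seq); u <- toupper(to_dna(utr_seq))
  seed6 <- rc(substr(m, 2, 7))
  m8seed <- rc(substr(m, 2, 8))
  patterns <- list(
    list(type = "8mer", pat = paste0(m8seed, "A"), seed_off = 2L),
    list(type = "7mer-m8", pat = m8seed, seed_off = 2L),
    list(type = "7mer-A1", pat = paste0(seed6, "A"), seed_off = 1L),
    list(type = "6mer", pat = seed6, seed_off = 1L)
  )
  found <- list()
  for (p in patterns) {
    w <- nchar(p$pat)
    if (nchar(u) < w) next
    for (i in seq_len(nchar(u) - w + 1L)) {
      if (substr(u, i, i + w - 1L) != p$pat) next
      s <- i + p$seed_off - 1L  # seed-match start
      key <- as.character(s)
      if (is.null(found[[key]]))  # patterns are tried longest-first
        found[[key]] <- data.frame(site_type = p$type, start = i,
                                   end = i + w - 1L,
                                   stringsAsFactors = FALSE)
    }
  }
  if (!length(found))
    return(data.frame(site_type = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, found[order(as.integer(names(found)))])
  rownames(out) <- NULL
  out
}

# Explicit hypergeometric upper tail by combinatorial enumeration.
oracle_hyper <- function(k, K, n, N) {
  js <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Textbook Benjamini-Hochberg: step-up rejections and adjusted values.
oracle_bh <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  # rejections: largest i with p_(i) <= i/m * alpha, reject all up to it
  below <- which(ps <= seq_len(m) / m * alpha)
  reject_sorted <- logical(m)
  if (length(below)) reject_sorted[seq_len(max(below))] <- TRUE
  # adjusted: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
  q_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m); q[o] <- q_sorted
  reject <- logical(m); reject[o] <- reject_sorted
  list(q = q, reject = reject)
}

# Pooled-variance Student t by the textbook formula.
oracle_student_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Tiny paired cohort builder used by several files.
make_matrix <- function(tumor, normal, grades = NULL) {
  # tumor, normal: miRNA x patient matrices of linear intensities
  stopifnot(identical(dim(tumor), dim(normal)))
  n_p <- ncol(tumor)
  if (is.null(grades)) grades <- rep("GI", n_p)
  patients <- sprintf("%s_p%d", grades, seq_len(n_p))
  m <- cbind(tumor, normal)
  rownames(m) <- rownames(tumor)
  colnames(m) <- c(paste0(patients, "_T"), paste0(patients, "_N"))
  samples <- data.frame(
    sample_id = colnames(m),
    patient_id = rep(patients, 2), grade = rep(grades, 2),
    tissue = rep(c("tumor", "normal"), each = n_p),
    stringsAsFactors = FALSE)
  expression_matrix(m, samples)
}

random_rna <- function(n, len = 22L) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
          collapse = ""), character(1))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
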