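#' Construct a paired tumor/normal expression matrix
#'
#' The central expression container: a strictly positive, linear-scale
#' intensity matrix (miRNAs in rows, samples in columns) plus a sample
#' sheet pairing each patient's tumor and adjacent-normal sample and
#' recording its tumor grade.
#'
#' @param intensities numeric matrix, miRNAs x samples, strictly
#'   positive, with row and column names.
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `grade`, `tissue` (`tissue` in `"tumor"`/`"normal"`); one row per
#'   column of `intensities`.
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(intensities, samples) {
  stopifnot(is.matrix(intensities), is.numeric(intensities),
            !is.null(rownames(intensities)), !is.null(colnames(intensities)),
            is.data.frame(samples))
  need <- c("sample_id", "patient_id", "grade", "tissue")
  if (!all(need %in% names(samples)))
    stop("sample sheet needs columns: ", paste(need, collapse = ", "))
  if (!setequal(samples$sample_id, colnames(intensities)) ||
      anyDuplicated(samples$sample_id))
    stop("sample sheet ids must match intensity column names exactly")
  if (!all(samples$tissue %in% c("tumor", "normal")))
    stop("tissue must be 'tumor' or 'normal'")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("intensities must be finite and strictly positive")
  # every patient: exactly one tumor and one normal sample
  for (p in unique(samples$patient_id)) {
    tt <- samples$tissue[samples$patient_id == p]
    if (!(sum(tt == "tumor") == 1L && sum(tt == "normal") == 1L))
      stop("patient ", p, " is not a single tumor/normal pair")
  }
  samples <- samples[match(colnames(intensities), samples$sample_id), ,
                     drop = FALSE]
  rownames(samples) <- NULL
  structure(list(intensities = intensities, samples = samples),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$intensities), "miRNAs x",
      ncol(x$intensities), "samples (",
      length(unique(x$samples$patient_id)), "tumor/normal pairs )\n")
  cat("grades:", paste(sort(unique(x$samples$grade)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-pair log2 fold changes (tumor vs adjacent normal)
#'
#' For every miRNA and every patient, computes
#' `log2(tumor intensity / normal intensity)` on the linear intensities.
#'
#' @param em an `ExpressionMatrix`.
#' @return data.frame with columns `mirna`, `patient_id`, `grade`,
#'   `log2fc`; one row per (miRNA, patient).
#' @export
pairwise_log2fc <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  s <- em$samples
  patients <- unique(s$patient_id)
  recs <- lapply(patients, function(p) {
    tum <- s$sample_id[s$patient_id == p & s$tissue == "tumor"]
    nor <- s$sample_id[s$patient_id == p & s$tissue == "normal"]
    data.frame(
      mirna = rownames(em$intensities),
      patient_id = p,
      grade = s$grade[s$patient_id == p & s$tissue == "tumor"],
      log2fc = log2(em$intensities[, tum] / em$intensities[, nor]),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
  out <- do.call(rbind, recs)
  if (any(!is.finite(out$log2fc))) stop("non-finite fold change produced")
  out
}

#' Call per-grade differential miRNAs at a fold-change threshold
#'
#' A miRNA is called up-regulated in a grade when its fold change exceeds
#' `threshold_fold` (strictly: "more than" the threshold), down-regulated
#' when it falls below `1/threshold_fold`.  In `mode = "mean"` the
#' criterion applies to the mean per-pair log2 fold change within the
#' grade; in `mode = "all_pairs"` every pair in the grade must
#' individually exceed the threshold in the same direction.
#'
#' @param records fold-change records from [pairwise_log2fc()].
#' @param threshold_fold linear fold-change threshold (> 1); default 2.
#' @param mode `"mean"` (default) or `"all_pairs"`.
#' @return an object of class `DifferentialCallSet`: per grade, character
#'   vectors `up` and `down`, plus the threshold and mode used.
#' @export
call_grade_differential <- function(records, threshold_fold = 2,
                                    mode = c("mean", "all_pairs")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(records),
            all(c("mirna", "grade", "log2fc") %in% names(records)))
  if (!is.numeric(threshold_fold) || length(threshold_fold) != 1L ||
      threshold_fold <= 1)
    stop("threshold_fold must be a single number > 1")
  thr <- log2(threshold_fold)
  grades <- unique(records$grade)
  calls <- lapply(grades, function(g) {
    r <- records[records$grade == g, , drop = FALSE]
    if (nrow(r) == 0L) stop("grade with zero pairs: ", g)
    per <- split(r$log2fc, r$mirna)
    up_ok <- switch(mode,
      mean = vapply(per, function(v) mean(v) > thr, logical(1)),
      all_pairs = vapply(per, function(v) all(v > thr), logical(1)))
    down_ok <- switch(mode,
      mean = vapply(per, function(v) mean(v) < -thr, logical(1)),
      all_pairs = vapply(per, function(v) all(v < -thr), logical(1)))
    list(up = sort(names(per)[up_ok]), down = sort(names(per)[down_ok]))
  })
  names(calls) <- grades
  structure(list(calls = calls, threshold_fold = threshold_fold,
                 mode = mode),
            class = "DifferentialCallSet")
}

#' Build a call set directly from per-grade up/down lists
#'
#' Used when the per-grade differential lists come from an external
#' source (e.g. a published table) rather than from intensity data.
#'
#' @param calls named list (one element per grade), each a list with
#'   character vectors `up` and `down`.
#' @param threshold_fold threshold the external lists were derived with.
#' @return a `DifferentialCallSet`.
#' @export
differential_callset <- function(calls, threshold_fold = 2) {
  for (g in names(calls)) {
    ov <- mirna_intersect(calls[[g]]$up, calls[[g]]$down)
    if (length(ov) > 0)
      stop("grade ", g, ": miRNAs in both up and down: ",
           paste(ov, collapse = ", "))
  }
  structure(list(calls = calls, threshold_fold = threshold_fold,
                 mode = "external"),
            class = "DifferentialCallSet")
}

#' Intersect per-grade calls into the commonly dysregulated set
#'
#' A miRNA is commonly up-regulated when it is called up in every grade,
#' commonly down-regulated when called down in every grade.  A miRNA
#' called up in one grade and down in another is excluded from both sets.
#' Matching is on normalized ids ([normalize_mirna_id()]).
#'
#' @param callset a `DifferentialCallSet` covering at least two grades.
#' @return an object of class `CommonSet`: character vectors `up` and
#'   `down` plus the contributing grades.
#' @export
common_dysregulated <- function(callset) {
  stopifnot(inherits(callset, "DifferentialCallSet"))
  calls <- callset$calls
  if (length(calls) < 2L) stop("need at least two grades to intersect")
  up <- Reduce(mirna_intersect, lapply(calls, `[[`, "up"))
  down <- Reduce(mirna_intersect, lapply(calls, `[[`, "down"))
  any_down <- unique(unlist(lapply(calls, `[[`, "down")))
  any_up <- unique(unlist(lapply(calls, `[[`, "up")))
  up <- mirna_setdiff(up, any_down)
  down <- mirna_setdiff(down, any_up)
  structure(list(up = sort(up), down = sort(down), grades = names(calls)),
            class = "CommonSet")
}

#' @export
print.CommonSet <- function(x, ...) {
  cat("CommonSet over grades", paste(x$grades, collapse = "/"), ":",
      length(x$up), "up,", length(x$down), "down\n")
  invisible(x)
}

#' Remove miRNAs whose validation contradicted the array direction
#'
#' Candidates whose follow-up quantification (e.g. qRT-PCR) showed the
#' opposite direction are dropped from the common set.  Removals (and
#' no-op exclusions of absent ids) are recorded in an `audit` attribute.
#'
#' @param common a `CommonSet`.
#' @param excluded character vector of miRNA ids to drop.
#' @return a `CommonSet` with an `audit` data.frame attribute
#'   (columns `mirna`, `action` in `"removed_up"`, `"removed_down"`,
#'   `"not_present"`).
#' @export
apply_validation_exclusions <- function(common, excluded) {
  stopifnot(inherits(common, "CommonSet"))
  excluded <- as.character(excluded)
  acts <- vapply(excluded, function(id) {
    if (length(mirna_intersect(common$up, id))) "removed_up"
    else if (length(mirna_intersect(common$down, id))) "removed_down"
    else "not_present"
  }, character(1))
  out <- structure(
    list(up = mirna_setdiff(common$up, excluded),
         down = mirna_setdiff(common$down, excluded),
         grades = common$grades),
    class = "CommonSet")
  attr(out, "audit") <- data.frame(mirna = excluded, action = unname(acts),
                                   stringsAsFactors = FALSE)
  out
}
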