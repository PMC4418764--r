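#' Relative expression by the delta-delta-Ct (Livak) method
#'
#' Per sample, the target Ct is first normalized to the reference small
#' RNA (U6): `dCt = target_ct - reference_ct`.  Each sample's ddCt is
#' its dCt minus the mean control-group dCt, and relative expression is
#' `2^(-ddCt)`.  Anchoring on the mean control dCt makes the control
#' group's geometric-mean fold exactly 1.  Technical replicates (rows
#' sharing a `sample_id`) are averaged on the Ct scale before dCt.
#'
#' @param ct data.frame with columns `sample_id`, `condition`
#'   (`"case"`/`"control"`), `target_ct`, `reference_ct`.
#' @return data.frame `sample_id`, `condition`, `dct`, `ddct`,
#'   `rel_expr`, one row per sample.
#' @export
ddct_relative_expression <- function(ct) {
  need <- c("sample_id", "condition", "target_ct", "reference_ct")
  stopifnot(is.data.frame(ct), all(need %in% names(ct)))
  if (any(!is.finite(ct$target_ct)) || any(!is.finite(ct$reference_ct)))
    stop("missing or non-finite Ct value")
  if (!all(ct$condition %in% c("case", "control")))
    stop("condition must be 'case' or 'control'")
  if (!any(ct$condition == "case") || !any(ct$condition == "control"))
    stop("need at least one case and one control sample")
  # average technical replicates on the Ct scale
  agg <- do.call(rbind, lapply(split(ct, ct$sample_id), function(d) {
    if (length(unique(d$condition)) != 1L)
      stop("sample ", d$sample_id[1], " appears under both conditions")
    data.frame(sample_id = d$sample_id[1], condition = d$condition[1],
               target_ct = mean(d$target_ct),
               reference_ct = mean(d$reference_ct),
               stringsAsFactors = FALSE)
  }))
  agg$dct <- agg$target_ct - agg$reference_ct
  anchor <- mean(agg$dct[agg$condition == "control"])
  agg$ddct <- agg$dct - anchor
  agg$rel_expr <- 2 ^ (-agg$ddct)
  agg <- agg[order(agg$condition, agg$sample_id),
             c("sample_id", "condition", "dct", "ddct", "rel_expr")]
  rownames(agg) <- NULL
  agg
}

#' Normalized dual-luciferase activities
#'
#' Per-well activity is the Renilla/Firefly ratio, controlling for
#' transfection efficiency; optionally the activities are rescaled so
#' the control-group mean equals 1.
#'
#' @param luc data.frame with columns `condition`, `renilla`, `firefly`
#'   (all readings > 0).
#' @param normalize_to_control rescale so mean control activity is 1
#'   (default TRUE; requires >= 1 control well).
#' @return the input with an `activity` column appended.
#' @export
luciferase_ratio <- function(luc, normalize_to_control = TRUE) {
  stopifnot(is.data.frame(luc),
            all(c("condition", "renilla", "firefly") %in% names(luc)))
  if (any(luc$renilla <= 0) || any(luc$firefly <= 0))
    stop("luciferase readings must be strictly positive")
  luc$activity <- luc$renilla / luc$firefly
  if (normalize_to_control) {
    ctrl <- luc$activity[luc$condition == "control"]
    if (!length(ctrl)) stop("no control wells to normalize to")
    luc$activity <- luc$activity / mean(ctrl)
  }
  luc
}

#' Two-sample t-test (pooled-variance Student or Welch)
#'
#' The pooled-variance Student form (the default, matching standard
#' two-group comparisons of assay readouts) uses
#' `sp2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)` and
#' `df = n1 + n2 - 2`; the Welch form uses per-group variances with
#' Satterthwaite degrees of freedom.  The p-value is two-sided.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"student"` (default) or `"welch"`.
#' @return list with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two observations")
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) stop("zero variance in both groups")
  n1 <- length(a); n2 <- length(b)
  if (variant == "student") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2) ^ 2 /
      ((v1 / n1) ^ 2 / (n1 - 1) + (v2 / n2) ^ 2 / (n2 - 1))
  }
  t <- (mean(a) - mean(b)) / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
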