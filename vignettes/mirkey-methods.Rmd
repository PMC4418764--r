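---
title: "Methods: key-miRNA discovery with mirkey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: key-miRNA discovery with mirkey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirkey)
```

# The model and its assumptions

mirkey nominates *key* regulatory miRNAs from a small paired
tumor/normal cohort in four inferential steps, each deliberately simple
enough to be fully specified:

**Paired fold changes.** Intensities are assumed already normalized and
strictly positive on a linear scale; the only statistic taken from the
expression data is the per-patient log2 ratio tumor/normal. No variance
moderation, no p-values over miRNAs: the differential criterion is a
pure fold-change threshold, applied *strictly* ("more than" two-fold, so
a mean fold of exactly 2.0 is not called). Two readings of "called in a
grade" are supported because the distinction is real in tiny cohorts:
`mode = "mean"` (default) thresholds the mean per-pair log2FC of the
grade's three pairs; `mode = "all_pairs"` requires each pair to clear
the threshold individually. The commonly dysregulated set is the
intersection of the per-grade calls, direction-consistent by
construction, with an audited exclusion step for candidates whose
follow-up quantification contradicted the array.

**Canonical seed-match target prediction.** Published target predictors
combine seed matching with conservation and context scores whose
internals are not reproducible from their descriptions; mirkey
implements only the fully documented core, the canonical site taxonomy.
For a mature miRNA the *seed match* is the DNA reverse complement of
positions 2–7. Every (possibly overlapping) occurrence in a 3'UTR is
classified by two embellishments: a match to miRNA position 8
immediately 5' of the seed match, and an adenine in the target opposite
miRNA position 1 immediately 3' of it — giving 8mer (both), 7mer-m8
(position-8 only), 7mer-A1 (adenine only) and 6mer (neither), each
occurrence reported once with its longest applicable type. Reported
coordinates are 1-based inclusive over the *full classified span*, so
7mer spans are 7 wide and 8mer spans 8 wide; this convention is what
reconciles published site tables that print a 6-nt seed match against a
7-wide span. A gene counts as a target when any transcript carries a
site of 7mer-A1 or stronger (`min_site = "6mer"` relaxes this); sites
overlapping an `N` are suppressed rather than partially matched.

**Enrichment.** With the upstream tool unrecoverable, the test is the
standard one-sided hypergeometric (Fisher exact upper tail):
`p = P(X >= k)` where `k` of the `n` query genes fall in a term
annotating `K` of the `N` universe genes. The universe defaults to all
annotated genes. FDR control is Benjamini–Hochberg, applied
independently within GO and within KEGG since the two corpora are
separate families of hypotheses. "Significant" (`q < alpha`, default
0.05) drives the pipeline; a separate top-10-by-p view exists only for
reporting, mirroring how such results are usually displayed.

**Degree ranking.** The final selection is deliberately the most
transparent network statistic available: build the bipartite graph of
candidate miRNAs against their cancer-pathway-screened targets and rank
miRNAs by distinct-target degree. This exactly reproduces the published
evidence for the key-miRNA nomination (target counts 53/53/51) without
appealing to an undocumented propagation algorithm. Boundary ties are
always kept — the published top pair is itself a tie at 53.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `threshold_fold` | 2 | linear fold | the stated two-fold rule; strict inequality |
| `de_mode` | `"mean"` | — | matches per-grade comparison; `all_pairs` matches a literal "in all nine tumors" reading |
| `min_site` | `"7mer"` | site class | canonical-site emphasis; 6mers are recorded but weak |
| `fraction` | 0.25 | of ranked genes | the stated top-25% carry-forward; ties included |
| `alpha` | 0.05 | FDR | conventional; applied to BH q per category |
| `cancer_ids` | `hsa05200` | KEGG id | the designated pan-cancer pathway |
| `top_n` | 3 | miRNAs | the published selection size; ties kept |

# What the synthetic generator emulates — and what it does not

`simulate_expression()` draws, per miRNA and patient, a normal-tissue
log2 intensity from `Normal(8, 1.5)` (a typical array dynamic range),
adds the planted true log2FC plus `Normal(0, noise_sd)` to form the
paired tumor value, and returns linear intensities. The default stated
world is the profiled cohort: three grades of three tumor/normal pairs,
500 miRNAs, 12 planted up and 12 down at |log2FC| = 2 with
`noise_sd = 0.2` — chosen so that planted effects are unambiguous at
two-fold thresholding, as in the original screen where candidate calls
were reproducible enough to validate by qRT-PCR. `simulate_utrs()`
plants site sequences at fixed offsets in uniform-random background and
re-randomizes any accidental occurrence of the watched patterns, so the
planted truth table is exhaustive; `simulate_annotations()` over-samples
query genes into designated terms at a stated fraction. All generators
are pure functions of their spec and seed.

The generator does **not** emulate probe-level array physics, dye bias,
background subtraction, cross-hybridization, normalization artifacts,
correlated miRNA families, or UTR base composition. A green recovery
test therefore establishes that the *inference chain* is correct under
its stated assumptions — not that the thresholding rule is robust to
real microarray noise structure.

# Numerical choices

- Fold changes are computed in double precision from linear intensities;
  intensities are validated strictly positive so ratios are finite.
- The hypergeometric tail is evaluated through `phyper()`, which works
  in log-space combinatorics; the test suite cross-checks it against
  explicit combinatorial enumeration on every configuration with
  `N <= 12`.
- BH adjustment uses the classic step-up; ties in p are ordered by term
  id for deterministic output.
- The pooled-variance and Welch t statistics are implemented from their
  textbook formulas (not wrapped from `t.test`), so the suite's
  `t.test` comparison is an independent route.
- Ranking tie-breaks are always lexicographic on the identifier, making
  every report a deterministic function of its inputs.
- ΔΔCt anchors each sample's ΔCt (target − U6 reference) on the mean
  control ΔCt, so the control group's geometric-mean fold is exactly 1;
  technical replicates are averaged on the Ct scale first; no
  amplification-efficiency correction is applied.

# Design choices where the ground truth is silent

- Whether the original per-grade calls used grade means or per-pair
  votes is unstated; both are implemented, with `mean` as default.
- The "top 25%" gene carry-forward is computed globally over all
  predicted genes (a per-miRNA variant would change the query set; it
  is noted but not implemented).
- The config file for the CLI is JSON rather than YAML: no YAML parser
  is available in the supported dependency set, and the contract — one
  file, one seed, byte-identical artifacts on re-run — is unchanged.
- miRNA identifiers are matched case-insensitively with the species
  prefix stripped, because the source tables mix `hsa-miR-*` and
  `miR-*` spellings; proprietary `miRplus-*` probe ids pass through as
  opaque identifiers.

# Known limitations

- **The source tables are internally inconsistent, and mirkey surfaces
  rather than hides this.** One miRNA (hsa-miR-768-3p) appears in the
  up-regulated column of all three grades yet is not designated commonly
  dysregulated by the table's own annotation; a faithful intersection
  therefore returns 13 candidates where the source narrative says 12.
  Likewise one grade's narrative total (34) is off by one against its
  own printed lists (19 up + 16 down). The fixture transcribes the
  lists verbatim; the pipeline's fixture mode reconciles against the
  published designation through the audited exclusion mechanism; and the
  two as-stated acceptance expectations are intentionally left failing
  as a record of the discrepancy. (miR-768-3p was later re-annotated as
  a snoRNA fragment and retired from miRNA references, which may explain
  its silent exclusion at the source.)
- Target prediction is seed-match-only: no conservation, context
  scores, or non-canonical (centered, 3'-compensatory) sites, so its
  gene universe is not comparable to score-based predictors.
- Annotations are taken as flat gene sets; no GO-graph propagation and
  no identifier mapping beyond symbol upper-casing.
- The enrichment screen inherits all universe-choice caveats of
  hypergeometric tests; with the original background unknown, published
  enrichment tables can only be used as fixtures, not re-derived.
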