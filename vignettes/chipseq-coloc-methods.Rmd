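---
title: "Methods: peak co-localization, annotation, motif enrichment and QC"
author: "chipcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peak co-localization, annotation, motif enrichment and QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chipcoloc implements the statistics that sit downstream of ChIP-seq peak
calling: does a second factor's peak set co-localize with the first's, where
do peaks sit relative to transcription start sites, which genes do they
plausibly regulate, which known motifs are enriched under the summits, and
is the underlying library any good. This vignette explains each model, its
assumptions, the tunable parameters, and the deliberate design choices —
including the ones the underlying questions leave genuinely open.

## Coordinates and the ≥1 bp overlap rule

All coordinates are 0-based half-open (BED native); 1-based inputs are
converted at the parse boundary and nowhere else. Two intervals co-localize
iff they share at least one base pair: `a.start < b.end && b.start < a.end`
on the same chromosome. Adjacent ("touching") intervals share zero bases,
so they neither overlap nor merge; `merge_peaks()` therefore reduces with a
zero gap tolerance rather than the more common merge-adjacent behaviour.

"Common" peaks between two sets is ambiguous under many-to-many overlap, so
`venn_counts()` reports three numbers: `A_shared` and `B_shared` (peaks of
one set touching ≥1 peak of the other) and `common_clusters` (connected
components of the pooled overlap graph containing members of both sets).
The cluster count is the symmetric, figure-style quantity; the other two
preserve the asymmetric information. For intervals, connected components
coincide with zero-gap merged runs, which is how they are computed.

## Fisher's exact co-localization test

The test needs a sampling universe, which peak-vs-peak overlap does not by
itself define. The genome is tiled into non-overlapping bins (last bin of
each chromosome truncated); a bin is positive for a set iff it shares ≥1 bp
with any of the set's peaks. The resulting 2×2 table (both / A only /
B only / neither) is tested one-sided ("greater", since the claim is
co-occupancy enrichment) via the hypergeometric upper tail, evaluated in
log space so that vanishing p-values survive as finite log10 values instead
of collapsing to a floating-point floor. The default bin width is the
median peak length of the combined sets, matching the analysis unit to the
feature scale; it is configurable, and reports carry the width used so
sensitivity to it is visible.

A model-free companion, `permutation_overlap_test()`, re-places one set
uniformly at random per chromosome, preserving per-chromosome peak counts
and lengths (no mappability mask — none is assumed available), and reports
`p = (1 + #{null ≥ observed}) / (1 + n_perm)`. Because the overlap
statistic is integer-valued, this p-value is *super-uniform* under the
null wherever ties occur: valid but conservative. The calibration test
checks the one-sided (anti-conservative) Kolmogorov distance, which is the
direction that matters for validity; a two-sided comparison against a
continuous uniform would fail for any discrete statistic regardless of
implementation.

## TSS geometry and gene assignment

Distances are signed in gene orientation: (peak anchor − TSS), negated for
− strand genes, so negative always means upstream. The peak anchor defaults
to the midpoint (the natural reading of a peak's "center"); the summit is
available via `anchor = "summit"` where summits are more precise. The
promoter window is ±1,000 bp of a TSS — the single quantified promoter
definition the analyses rely on. Feature classification is a deliberately
simplified three-way scheme (promoter / gene body / intergenic), flagged as
such in the provenance block; exon-level schemes are out of scope.

Gene assignment is single-nearest-TSS with a 50 kb maximum extension:
beyond 50 kb a peak stays unassigned. Ties (equidistant TSSs) resolve to
the gene with the smaller start coordinate, then lexicographic gene id —
an arbitrary but deterministic rule. Curated regulatory domains are not
implementable without the curation itself and are excluded; reports state
this. Because several peaks can assign to one gene, both per-peak and
unique-gene counts are reported.

## Motif enrichment

Each PFM becomes a log2-odds PWM with
`score(j, b) = log2(((count + κ·bg_b) / (colsum + κ)) / bg_b)`,
pseudocount κ = 0.8 split across bases in background proportion. The
scanner and the threshold calibration share one integer discretization of
the score matrix (granularity 10⁻³), which is what makes threshold
calibration *exact*: `score_threshold()` convolves the per-column discrete
score distributions of a random background w-mer by dynamic programming and
returns the smallest threshold whose tail probability is ≤ `p_target`
(default 10⁻⁴ per scanned position). On the same discretization, the DP
tail equals exhaustive 4^w enumeration identically, which the tests assert
for every library motif of width ≤ 8.

A window is a *hit* when any position on either strand reaches the
threshold — presence/absence per region, not site counts, because the
figure convention being reproduced counts regions with the motif. Windows
are summit ±100 bp. Background windows are sampled uniformly from the
genome and accepted/rejected until their GC histogram (bins of 0.05)
matches the peak windows' histogram, with a bounded draw budget that fails
loudly naming the unfillable bin; default background size is 10× the peak
windows, large enough that background-rate error is second order.
Enrichment is the one-sided binomial upper tail of `k_peak` hits in
`n_peak` windows at the Laplace-smoothed background rate
`p0 = (k_bg + 1)/(n_bg + 2)` (smoothing avoids `p0 = 0` degeneracies),
computed in log space. Benjamini–Hochberg q-values are reported alongside;
the star tiers (`***` < 1e-10, `**` < 0.01, `*` < 0.1) follow the raw p,
as in the figure convention. Whether background should be genome-wide or
promoter-restricted is open; genome-wide is the default and explicit
background windows can be supplied.

## Library QC

* **SPOT** — fraction of tag 5′ ends inside caller-supplied peak regions
  (not tied to any particular hotspot-calling program).
* **PBC** — the PBC1 variant, N1/Nd over distinct (chrom, strand, 5′ end)
  positions.
* **Strand cross-correlation** — Pearson correlation of per-base + strand
  and shifted − strand 5′-end counts, on raw (not binarized) counts,
  per-chromosome vectors trimmed by the shift and concatenated so shifts
  never cross chromosome boundaries. `NSC = cc(argmax)/min(cc)`;
  `RSC = (cc(argmax) − min)/(cc(read_len) − min)`; both above 1 is the
  conventional acceptability line. A zero-variance vector yields a warned
  `cc = 0`; an undefined RSC denominator yields `NA`.
* **Saturation** — sub-sample without replacement at fractions
  0.05…1.00 (step 0.05, configurable), correlate 10 kb-binned 5′-end
  coverage against the full library; the fraction-1.0 point is exactly 1
  by construction.

## The synthetic world: what it emulates and what it does not

Every analysis input can be generated with recorded ground truth, so each
statistic is testable against what was planted rather than against another
implementation. All randomness flows through an explicitly seeded
Mersenne-Twister confined with `withr::with_seed`; no function touches the
global RNG stream.

* **Genome** — i.i.d. bases with region-specific GC targets; the default
  profile is a 0.35→0.65 gradient along each chromosome in 10 kb blocks,
  giving the GC-matching machinery something real to match.
* **Peak pairs** — both sets are laid out in disjoint slots of 3× the
  maximum peak width; `round(overlap_frac · n_B)` B-peaks are placed to
  overlap a *distinct* A-peak by ≥1 bp inside its slot. Realized counts are
  exact by construction, which is what lets the overlap-recovery test
  assert `B_shared = 420` with no tolerance.
* **Genes** — uniform TSSs, random strands; a chosen share of peaks is
  re-centered within ±500 bp of a TSS and the remainder re-placed with no
  TSS within 1.5 kb, so the realized promoter fraction equals the request
  exactly. With more TSS-proximal peaks than genes, promoters become
  crowded and re-anchored peaks may overlap each other — real promoter
  regions do attract multiple binding events, but this crowding is why the
  full-world co-localization clusters come from the recorded realized
  counts rather than from slot bookkeeping.
* **Motif planting** — per peak window, with the stated probability, one
  site sampled from the PFM's column frequencies is written at a uniform
  offset and strand; colliding placements are retried a bounded number of
  times. Background plantings go into mutually non-overlapping non-peak
  windows — if background windows could overlap, one planted site would
  count in several windows and bias the null comparison, a bug the
  calibration test caught.
* **Tags** — fragment ends around peak anchors (+ strand at
  anchor − L/2, − strand at anchor + L/2, Normal jitter of SD 10 bp) plus
  background whose local rate varies in 1 kb blocks with high-variance
  Gamma multipliers shared by both strands. That block structure emulates
  the accessibility/mappability coverage bias that gives real libraries a
  *positive* cross-correlation baseline; without it the baseline hovers
  at or below zero and NSC is meaningless. Pre-duplication 5′ positions
  are made unique by re-jittering, so deliberate duplication (probability
  `dup_rate` per tag) is the only source of duplicates and `dup_rate = 0`
  yields PBC exactly 1.

The generator does **not** emulate mappability holes, repeats, realistic
chromatin domain structure, or the nucleotide composition of a real
genome. Tests passing on this world show the statistics are computed
correctly and recover planted structure; they do not show that any
particular biological dataset will behave this way.

## Numerical choices and problem sizes

Exact tails (hypergeometric, binomial) are computed in log space via the
standard distribution functions and validated against direct
log-factorial summation to 10⁻⁹ relative error. The PWM DP uses integer
scores at 10⁻³ granularity; ambiguous bases score −∞ (a large negative
integer sentinel) at their position. The default analysis world is 3
chromosomes × 2 Mb, 1,500 + 1,000 peaks, 300 genes, 200k tags — sizes
chosen so the full suite and the acceptance script run comfortably on a
single CPU while keeping every statistic in its asymptotic regime; the
type-I calibration experiment uses 200 replicates of 200 peak windows
versus 2,000 background windows, a size at which the discrete binomial
tail can actually attain the nominal 0.05 level (at 100 windows the test
is conservative by construction, ~0.048 attainable, which is a property
of any exact binomial test rather than of this implementation).

## Known limitations

* The Fisher universe (genome bins) is a modelling choice; different bin
  widths give different tables, which is why the bin width is surfaced in
  every report.
* `common_clusters` undercounts "common peaks" when same-set peaks chain
  clusters together (promoter crowding); the asymmetric shared counts are
  reported alongside for this reason.
* The three-way feature scheme ignores exon/intron/UTR structure.
* GC matching controls composition at the window level only; dinucleotide
  or repeat structure is not matched.
* The permutation null places peaks uniformly; without a mappability mask
  it is slightly liberal on real genomes with unmappable regions.
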