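---
title: "synapa: methods, parameter choices, and what the synthetic world establishes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{synapa: methods, parameter choices, and what the synthetic world establishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapa)
```

## The measurement model

3′-end sequencing captures one read per polyadenylated transcript, at the
cleavage/poly(A) site. At the cluster level, the data for a gene with
alternative polyadenylation (APA) are a small set of discrete 3′-end
positions, each with per-sample read counts. Everything in this package
rests on three assumptions:

* **Read ends pile up tightly around true sites.** Cleavage is imprecise by
  a few bases, so clusters are seeded at high-depth positions and extended
  a fixed 15 bases each side, merging overlapping or abutting intervals
  (two seeds 30 bases apart plainly describe one site).
* **Internal priming is predictable from the genome.** Oligo-dT primers
  anneal to genomic A-stretches, producing artifactual "ends" immediately
  upstream of A-rich sequence on the transcribed strand. Masking candidate
  bases by downstream A-content removes this signal before any clustering.
* **A high-confidence 3′-end catalog exists.** Long-read derived or
  curated 3′ ends let us discard clusters (often residual artifacts or
  degradation) that fall outside 50-nt windows around any validated end.

### Internal-priming blacklist

A base $b$ on strand $s$ is masked iff, on the transcribed strand, the run
of A starting at $b+1$ has length $\ge k$, or at least $h$ of the $w$ bases
immediately downstream are A. Two presets reflect different library
chemistries and tolerances:

| preset | run $k$ | density $h/w$ | downstream gene window |
|---|---|---|---|
| `xrip` | 6 | 7/10 | 500 nt |
| `synaptosome` | 4 | 6/8 | 2000 nt |

Bases within 25 nt of an annotated 3′ end are never masked — annotated
sites downstream of genomic A-runs are real despite their sequence context.
Numerical choices worth stating explicitly:

* The A-run is evaluated from the base *immediately downstream* ($b+1$),
  because priming occurs in the template downstream of the observed end.
* On the minus strand, "downstream" runs toward lower coordinates and A on
  the transcribed strand is T on the reference.
* At contig ends the run rule needs the full $k$ bases to fire; the density
  rule uses whatever bases remain against the same hit count $h$
  (conservative: truncation can only reduce hits).
* The exemption is applied to the candidate base only, not to the density
  window — a window may straddle an exemption zone.
* Masking happens *before* seeding (masked positions contribute no depth),
  matching a filter-then-cluster workflow.

### Cluster calling, validation, gene assignment

Seeds are positions where any *single sample* reaches depth 6 (pooling
samples would let many shallow libraries fabricate sites). Summits are the
position of maximal pooled depth, leftmost on ties (determinism). Validation
keeps clusters intersecting $[v-25, v+26)$ around a validated end $v$; the
interval convention throughout is 0-based half-open, so a cluster whose end
equals a window start does not intersect it. Clusters are assigned to the
same-strand gene whose body-or-downstream-window contains the summit,
nearest 3′ boundary winning when windows overlap.

## The negative-binomial test

The differential test is a deliberately small, fully specified stand-in for
heavyweight DE frameworks, so that its calibration can be certified by
simulation rather than by citation:

* size factors by median-of-ratios (features with any zero excluded from
  the geometric-mean reference);
* per-feature NB dispersion $\alpha$ by method of moments within each
  condition, df-weighted across the two conditions, floored at $10^{-8}$;
* shrinkage: final $\alpha$ is the 50/50 blend of the feature estimate and
  a least-squares trend $a_0 + a_1/\mu$ fitted across features (coefficients
  clamped at zero; median fallback). The fixed 0.5 weight is a documented
  simplification — the moment estimator at 3 replicates is individually
  noisy, and blending with a 2000-feature trend restores usable tail
  behavior (measured type-I error ≈ 0.05–0.07 at nominal 0.05);
* log2 fold change from normalized condition means with pseudocount 0.5;
  Wald statistic uses the delta-method SE
  $\sqrt{\sum_c (\mu_c + \alpha\mu_c^2)/(n_c(\mu_c+0.5)^2)}/\ln 2$ and a
  normal reference; BH adjustment over tested (not all-zero) features.

Target calling applies directional thresholds (log₂(IP/input) > 1,
p < 0.05, baseMean > 10, log₂(IP/control-IP) > 1). The fold-change rule is
implemented as *directional* rather than on |log₂FC|, because IP targets
are enrichments; `target_call_params(absolute_lfc = TRUE)` restores the
literal two-sided rule. The control-IP comparison is fold-change-only (no
p threshold) — a deliberate reading of an under-specified rule, flagged
here. The unadjusted p is used for target calling; BH-adjusted p for the
fraction-enrichment calls, following the respective stated rules.

## Weighted 3′ UTR length and localization calls

For each APA gene and condition, the expression-weighted length is
$W = \sum_i f_i e_i$ with $e_i$ the isoform's share of the gene's
size-factor-normalized, replicate-averaged expression and $f_i$ either the
real length fraction (length / longest length) or the ranked fraction
$i/k$. The ranked metric deliberately discards length magnitudes: it is
robust to a single very long isoform dominating the real metric.

Four difference statistics per gene (subtracted and log₂ difference, each
metric) are z-standardized **across genes**, and a gene is called if it
passes the one-tailed 5% point ($|z| \ge 1.645$) in *any* distribution.
Design choices:

* Both tails use $\alpha = 0.05$ each (genes are classified in both
  directions); this is an interpretation of a one-tailed rule applied
  bidirectionally, and is the package default.
* A gene triggering in opposite directions across distributions is
  classified `ns` with a `conflict` flag — the package never invents a
  direction by majority vote.
* `min_expr` (default: mean normalized count ≥ 5 in at least one
  condition) defines "expressed" for isoform retention; genes must by
  default be expressed in both conditions (`require_both = TRUE`).
* With fewer than 30 APA genes the normal approximation is unreliable and
  a warning is raised; distributions with zero variance are skipped.

Because the z-scores are computed on the realized distribution (planted
effects included), large planted fractions widen the thresholds; this is a
property of the procedure itself, not of the implementation.

## Isoform binding preference

Clusters are split at the gene-specific proximal poly(A) site — defined as
the most proximal *expressed* isoform end, configurable to an
annotation-supplied site. A cluster whose summit equals the site is
proximal (tie rule, documented). The long-isoform proportion
distal/(proximal+distal) uses condition-averaged normalized counts, and the
preference test is a paired two-sided Student's t across genes (the pairing
is per gene between sample types; an unpaired variant is available). All
differences exactly zero gives $t=0, p=1$; a nonzero constant difference is
flagged degenerate rather than reported as $p=0$ silently.

For genes with annotated proximal and distal 3′ ends, region counting
whitelists the 100 bases upstream of (and including) each end — 3′-seq
signal precedes the poly(A) site — and accepts other in-region reads only
within ±25 nt of a validated end.

## Enrichment and motif scanning

Fisher's exact two-sided p is the sum of hypergeometric probabilities of
tables (margins fixed) no more probable than the observed one, with a
relative tolerance factor of $10^{-12}$ on the probability comparison; this
is implemented directly on `dhyper` rather than via `stats::fisher.test`
so the tolerance is under the package's control and certifiable against an
independent log-binomial enumeration. The enrichment ratio is the
category-conditional fraction over the background-conditional fraction;
both "all expressed genes" and "non-localized genes" backgrounds are just
arguments. The default motif ships as the Pumilio response element
consensus `UGUANAUA` — configurable, because a consensus string is a
modeling choice, not ground truth. Motif matches are counted at every
start position (IUPAC degenerate letters, U≡T), offsets 0-based.

## The synthetic world

The generator emits the world the pipeline assumes: non-overlapping,
strand-alternating genes (isolating cluster-to-gene assignment from
ambiguity, which gets dedicated fixtures), 1–4 isoforms per gene spaced
≥ 300 nt, Dirichlet baseline usage shares, negative-binomial replicate
counts (dispersion 0.1, mean depth 200 reads per expressed isoform per
sample, 3 replicates — desk-scale but realistic for a targeted 3′-seq
experiment), Gaussian read-end scatter (SD 3 nt), and internal-priming
reads placed exactly at planted A-tract decoys (runs of ≥ 8 A on the
transcribed strand, ≥ 50 nt from any true site so the filter's sensitivity
and specificity are measurable, 5% of reads).

Values chosen once where no external statement fixed them: usage
concentration 5 (moderately uneven isoform usage), intergenic gap 1000 nt
(downstream windows of one gene may touch the next, opposite-strand gene —
realistic and harmless given strand-aware assignment), decoys one per gene.

Planted effects: localized genes receive a ±0.4 shift of the distal usage
share in the synaptosome condition. Carrier genes are drawn among APA genes
whose baseline distal share can absorb the full shift, so the planted truth
equals the stated effect; if eligible genes run out, the shift is clamped
into [0.01, 0.99] and renormalized (the fallback documented here). RIP
target genes get an 8× count multiplier in RIP samples, with an extra 2×
on non-proximal isoforms (`distal_binding_weight`), so the analytic
expectation for RIP/input count ratios is 8 (proximal) and 16 (distal).

**What a green test establishes — and what it does not.** The synthetic
world has no overlapping genes, no chimeric or antisense signal, no
mappability artifacts, no positional biases beyond Gaussian scatter, no
partial internal-priming decoys (decoy reads sit exactly at decoy
positions), and its validated-end catalog is complete and exact. Recovery
results on it certify the *implementation* of the filters and statistics
(no coding errors, correct conventions, calibrated tests at the stated
effect sizes), not the biological performance of the workflow on real
tissue libraries, where the validated-end catalog is incomplete and
internal priming is a continuum.

## Known limitations

* The DE module is a calibrated stand-in: no outlier refitting, no
  multi-factor designs, no exact replication of reference-framework
  shrinkage.
* The localization procedure is the z-on-summary-statistic rule as stated;
  it is not a per-isoform differential usage test (no beta-binomial model)
  and inherits the threshold-widening property noted above.
* Read-end extraction conventions from raw alignments (which mate, which
  offset) are deliberately out of scope: the pipeline starts from read
  3′-end positions in BED form.
* The motif module is presence/absence enrichment, not a ranking-based
  motif discovery tool.
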