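---
title: "Tb-seq analysis: models, parameters, and design choices"
author: "tbseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tb-seq analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbseq)
```

## The measurement model

Terbium(III) binds folded RNA at pockets of concentrated negative
electrostatic potential -- the same pockets that recruit Mg^2+^ -- and,
where the local backbone adopts an in-line geometry, catalyses
phosphodiester scission. In a sequencing readout each scission event
becomes a reverse-transcription termination: RT walks 3'→5' from a
gene-specific primer and falls off at the cleaved phosphate. A probing
library therefore encodes per-nucleotide cleavage propensity in where
its truncated cDNAs end.

For each transcript position the counting layer tallies, over all
aligned reads, *stops* (reads whose 5'-most aligned base is that
position) and *read-throughs* (reads that traverse it). The
termination probability is estimated conditionally on reads reaching
the position:

$$ \hat{P}(\mathrm{stop})_p \;=\; \frac{n_{\mathrm{stop},p}}
   {n_{\mathrm{stop},p} + n_{\mathrm{readthrough},p}} $$

Because the estimator is conditional, intrinsic RT drop-off 3' of a
position does not bias it, only its effective sample size. Raw
reactivity is the treated-minus-untreated difference of these
probabilities; negatives are preserved until normalization so that
quality control and differential analyses see the full signal.

**Stop attribution.** The scission leaves a 5'-OH fragment whose last
templated base is the read's 5'-most aligned base, so the stop is
recorded there (`stop_offset = 0`). The original counting convention
of published termination-counting pipelines is not documented to one
base; the offset is therefore exposed (`stop_offset` of -1/0/+1)
rather than hard-coded. Soft-clipped bases never contribute: the SAM
`POS` field already excludes them. Minus-strand alignments are
rejected with a warning because gene-specific priming makes the
protocol strand-specific, and an optional `exclude_region` suppresses
stop (not read-through) counting inside the primer binding site,
where truncations are primer artifacts.

## Coverage filtering and normalization

Positions are usable only with **more than 10,000 read-throughs**
(strict inequality). At that depth the binomial standard error of a
1% stop probability is about 10^-3^, an order of magnitude below the
weakest site signals the calling criteria are designed for.

To compare probing contexts whose overall cleavage efficiencies
differ (in vitro vs lysate), each profile is scaled by its own
top-decile statistic: the normalization factor *F* is the mean of the
defined raw values at or above their 90th percentile (`norm_stat =
"mean"`; the percentile value itself via `"p90"`). Values are clamped
into [0, 1] before multiplying by 8, so normalized reactivity lives
on a 0--8 scale:

```{r norm-example}
raw <- c(seq(0.05, 0.75, length.out = 16), 0.2, 0.8, 0.9, 1.1)
norm <- normalize_reactivity(raw)
attr(norm, "norm_factor")   # F = mean(0.9, 1.1) = 1
norm[c(17, 19, 20)]         # 0.2 -> 1.6, 0.9 -> 7.2, 1.1 clamps to 8
```

The scale's conventional "1--8" label is treated as a display range,
not an additive offset: adding 1 would make a truly unreactive
nucleotide nonzero and destroy the subtraction semantics of the raw
scale, so the package maps zero reactivity to zero. The top-decile
*mean* (rather than the percentile itself) is kept as the default
because it is insensitive to the exact interpolation rule at the 90th
percentile while still being dominated by genuine signal; both
statistics are scale-invariant, which tests assert.

## Calling strong cleavage sites

Specific, site-bound cleavage is separated from spontaneous RT
termination by three criteria, evaluated at every position that is
unmasked in *all* contributing profiles (position 1 is always
dropped: full-length cDNAs pile up there by construction):

1. normalized reactivity strictly above 0.5 at the reference
   concentration -- 0.5 mM for in vitro probing, 1 mM for lysate
   contexts -- in **each** replicate individually, not in the mean;
2. reproducibility in at least two independent replicates;
3. concentration dependence: Spearman rank correlation of the
   replicate-averaged signal with the Tb^3+^ concentration series
   ≥ 0.5 when three or more concentrations are available, a strict
   increase when exactly two are, and not evaluable (no site called,
   with a warning) below that.

Criterion 3's statistic is computed on **raw** reactivity by default.
This is a deliberate design choice: per-profile normalization divides
by a top-decile factor that genuine sites themselves dominate, so a
real site sits at the 8.0 ceiling of its profile at *every*
concentration at which it is detectable -- the normalized
concentration series of a true site is the constant vector
(8, 8, ...), whose rank correlation is undefined. The raw series
preserves the dose response that the criterion exists to test
(`conc_signal = "norm"` restores the literal alternative). Spearman
with average ranks for ties is used because the Hill-type response
saturates at high concentration, where only the ordering, not the
spacing, is informative.

## Protein-dependence (ΔTb) profiles

Probing intact lysate and Proteinase-K-deproteinized lysate gives two
normalized profiles whose difference,

$$ \Delta\mathrm{Tb}_p = \mathrm{norm}_{\mathrm{protK},p}
   - \mathrm{norm}_{\mathrm{lysate},p}, $$

classifies positions at a symmetric cutoff of 0.5: `delta <= -0.5` is
a *loss on deproteinization* (structure that depends on bound
protein), `delta >= +0.5` a *gain* (often rearrangement once proteins
are stripped). Class names are operational rather than mechanistic on
purpose; a gain does not identify a protein-binding site. The two
arms are normalized independently -- each context has its own
cleavage efficiency, which is exactly what the normalization exists
to absorb -- and the usable mask is the intersection of the arms. The
context check in `compute_delta()` is a hard error by default because
the subtraction order is a sign convention that silent misuse would
invert.

## Backbone compression geometry

On a 3-D structure, compact tertiary modules pinch every-other
phosphate pairs together. The package computes
$d(n, n+2) = \lVert P_n - P_{n+2} \rVert$ over a chain's residues,
defined only when residues *n*, *n*+1, *n*+2 are present with
consecutive author numbers, no insertion codes, and phosphorus atoms
on *n* and *n*+2 -- chain breaks and engineered inserts therefore
never fabricate a distance. Altlocs resolve to the highest-occupancy
conformer (ties: first altloc code); multi-model files default to
model 1.

The no-tertiary-structure reference is an analytic A-form helix
(rise 2.81 Å, twist 32.7° per residue, phosphate axial radius 9.2 Å),
whose intra-strand d(n, n+2) is constant at about 11.4 Å:

```{r helix}
helix <- pn_pn2_distances(ideal_aform_helix(12))
round(helix$d_n_n2[1], 2)
```

Compressed turns in deposited structures fall well below this, into
a 5.5--9.1 Å band, versus 9.6--12.5 Å for helical runs.
`compare_site_distances()` contrasts a called site set against a
reference set with summary statistics and a two-sided Wilcoxon
rank-sum test, mapping probing coordinates onto author numbering by a
constant offset, since construct numbering rarely matches deposition.
When a deposited structure is used as the reference, the helical
segment must be chosen by the analyst; for the *O. iheyensis* group
II intron the package's own validation uses residues 340--351 as a
stem run within domain 4, a selection documented here because the
original segment choice behind the printed band is not recorded
anywhere recoverable. Torsion-angle correlates were deliberately left
out of scope: cleavage requires in-line geometry that this metric
does not capture, which is also the method's known false-negative
mode (a Tb^3+^-bound site that cannot reach in-line alignment is
never cleaved).

## The read simulator

The generator mirrors the gene-specific-primed library: an RT attempt
starts at `primer_start` and walks toward position 1, terminating at
position *p* with probability

$$ s_p = b + (1 - b)\,\kappa_p \cdot m(c), $$

where *b* is the concentration-independent background drop-off,
κ~p~ the cleavage propensity of a seeded site, and
*m(c) = c / (c + K~half~)* a Hill-type saturating concentration
response (*m* = 0 untreated; `"linear"` is available). The default
`K_half = 0.5` mM places the in vitro reference concentration at
half-saturation, consistent with probing series over 0.01--2 mM in
which 0.5 mM gives strong but unsaturated signal. Attempts surviving
the whole walk are the full-length cDNA class and are recorded as
stops at position 1, which the site caller excludes by default.
Reads shorter than `min_read_length` are discarded and counted,
mimicking library size selection.

Rather than drawing one Bernoulli per position per read, the
simulator samples each read's stop directly from the walk's exact
stop-position distribution,
$P(\text{stop at } p) = s_p \prod_{q > p} (1 - s_q)$ with the
survival mass at position 1 -- distributionally identical to the
literal walk, deterministic given a seed, and about three orders of
magnitude faster, which is what makes multi-million-read validation
experiments practical on one CPU.

What the simulator does *not* emulate: sequencing errors, PCR
duplicates, ligation bias (mitigated experimentally by a
random-hexamer adapter), mutational (MaP-style) signal -- terbium
probing is a pure termination readout -- and any position-dependence
of RT processivity beyond the uniform background *b*. Passing
recovery tests on simulated data therefore demonstrates correctness
of the estimators and calling logic under the stated generative
model, not robustness to alignment artifacts or library-preparation
biases in real data.

## Validation problem sizes

The package validates itself at two scales, chosen as realistic
desk-scale stand-ins for a probing experiment on a 300-nt transcript:

* **Site recovery**: 10 seeded sites (κ = 0.15), b = 0.01,
  2 replicates × {0.01, 0.1, 0.5, 1, 2} mM plus per-replicate
  untreated controls, 10^6^ reads per library -- enough for more than
  10,000 read-throughs across the central 250 nt, so the published
  coverage filter is active rather than vacuous. Expected outcome,
  asserted in the tests: all 10 sites called, zero false positives,
  raw reactivity within 4 binomial SE of ground truth at every site.
* **ΔTb recovery**: two lysate arms sharing 5 sites and differing at
  5 (κ 0.15 native vs 0.02 deproteinized), probed at 1 mM with
  1.6 × 10^7^ reads per library, five independent seeds. The depth is
  set by the noise amplification of per-profile normalization (about
  8/F ≈ 400 at these parameters): at 1.6 × 10^7^ reads the
  normalized-difference noise SD is ≈ 0.1, putting the 0.5 cutoff at
  ≈ 5σ so that exactly the five protein-dependent sites are flagged.

## Degenerate inputs and numerical conventions

* Quantiles use R's default (type 7) interpolation; scale invariance
  of the normalization makes the choice immaterial to within-profile
  comparisons.
* `normalize_reactivity()` refuses profiles with fewer than 10
  defined positions or a non-positive normalization factor, rather
  than returning a silently meaningless scale.
* A position with zero stops and zero read-throughs yields the masked
  sentinel (`NA`), which propagates through subtraction,
  normalization, calling, and ΔTb classification.
* Counting is order-invariant and additive over read sets; both
  properties are asserted against a brute-force position × read
  oracle.
* Wilcoxon comparisons of zero-variance but identical distance sets
  report p = 1 instead of `NaN`.

## Known limitations

Single-transcript scope (one reference per run, by design of the
gene-specific protocol); no FDR machinery (the calling criteria are
deterministic thresholds, not hypothesis tests); no RT drop-off
correction beyond background subtraction -- a warning is emitted when
the untreated mean stop probability exceeds 0.05; and structural
interpretation stops at backbone compression, since metal-site
assignment from cryo-EM-era structure databases is not reliable
enough to train anything finer.
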