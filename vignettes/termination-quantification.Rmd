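---
title: "Quantifying termination, attenuation and readthrough from stranded coverage"
author: "ttkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying termination, attenuation and readthrough from stranded coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttkit)
```

## The measurement problem

Conditional depletion of a termination factor changes transcription
globally: signal runs past polyadenylation sites (readthrough), polymerase
releases prematurely near promoters (attenuation), splicing becomes less
efficient, and total nascent RNA synthesis can drop by tens of percent.
Because the perturbation is global, library-internal normalisation
(sequencing depth) silently erases the effect being measured; every
quantity in this package is therefore defined either on a spike-in
calibrated scale or as a within-gene ratio that cancels scale altogether.

All genomic coordinates inside the package are 1-based closed intervals,
the native convention of `GenomicRanges`/`IRanges` on which the containers
are built. GFF3 input is read directly; BED input is shifted from its
0-based half-open convention at the file boundary. A transcription unit is
a stranded interval with a TSS (5' end in transcription orientation), a
PAS (3' end) and a sorted, non-overlapping exon chain. Windows are always
constructed in transcription orientation, so every index is invariant
under the mirror transform (reverse-complement the genome, flip
coordinates and strands) — a property the test suite asserts on random
data.

## Per-gene indices

Let $d(W)$ denote mean per-base signal over window $W$ on the gene's
strand.

**Attenuation.** $A = d(\mathrm{TSS}..\mathrm{TSS}{+}300) /
d(\mathrm{TSS}{+}300..\mathrm{PAS})$. Uniform coverage gives $A = 1$;
premature termination concentrates signal 5' and raises $A$. Genes longer
than 600 bp are considered, and a gene is called attenuated when
$A_\mathrm{depleted}/A_\mathrm{control} \ge 1.5$ (boundary inclusive, both
indices defined). The comparison is across conditions rather than on the
treated index alone: an intrinsically pause-prone gene has a high index in
both conditions and should not be called, whereas the condition ratio
isolates the depletion effect.

**Readthrough.** $R = d(\mathrm{PAS}{+}1..\mathrm{PAS}{+}500) /
d(\mathrm{TSS}{+}250..\mathrm{PAS})$. Normalising to the gene body makes
the index usable when transcription is globally down; the 500 bp window is
a default (not dictated by the design), and the PAS-anchored log2-ratio
heatmap is the complementary genome-wide display.

**Cleavage.** $C = d(\mathrm{PAS}{-}5..\mathrm{PAS}{+}4) /
d(\mathrm{PAS}{-}500..\mathrm{PAS}{-}100)$, i.e. a 10 nt window centred on
the cleavage site over a 400 bp body window offset 100 bp upstream (the
body window is placed inside the gene; "around the PAS" is reconciled as
the half-open 10-base span covering offsets −5..+4). Efficient
cotranscriptional cleavage depletes nascent signal at and beyond the site,
so *defects* in cleavage raise $C$: in simulation $C$ is strictly
monotone decreasing in cleavage efficiency.

**Intron retention.** Per intron, intronic density over the mean of the
two flanking exon densities; per gene, the mean of defined per-intron
ratios. Fully spliced introns give 0, unspliced give 1.

Zero-denominator cases propagate as `NA` with a `reason` attribute, never
as infinities, and selection functions require defined values. All
thresholds are inclusive (`>=`). Candidate PAS sites are filtered for a
PAS hexamer in the 50 bp immediately upstream (sense strand, site base
excluded — the published rule does not state whether the site base is
included; exclusion was chosen and is a one-line change in
`select_pas_site()` for sensitivity analysis). Exact prominence ties are
broken by distance to the annotated end, then by coordinate, making
selection deterministic.

## Normalisation model

Spike-in factors are ratios of spike-in read counts:
$f_s = n^\mathrm{spike}_\mathrm{ref} / n^\mathrm{spike}_s$, so the
reference maps to exactly 1 and uniform rescaling of all spike counts
cancels. The depth-normalise-then-reverse sequence used upstream of
spike-in scaling in the occupancy workflow is algebraically the identity;
`apply_normalization()` exposes it as such and logs both factors rather
than multiplying and dividing the track. Input subtraction clamps at zero
(`max(IP − input, 0)`), which is the published rule and guarantees the
nonnegativity invariant of the coverage container. When a perturbation is
known to distort the spike-in species itself (e.g. auxin affecting the
spiked cells), the configuration accepts `normalization: depth_only`,
which falls back to experimental-read ratios.

## Metagenes

Gene bodies between 250 bp after the TSS and 250 bp before the PAS are cut
into equal-length bins (fixed-size flanks are binned at a constant bin
size); each cell is the mean per-base density over its genomic span, so a
gene's row depends only on the *shape* of its signal — dilating a gene and
its signal together leaves the row unchanged, which the tests assert
exactly. Log2 ratios use a pseudocount of 0.01 (in units of mean per-base
density; the source analyses do not state one) to keep empty bins finite
while leaving typical signal (~10–50×) essentially untouched. Confidence
bands are percentile bootstrap over genes (1000 resamples by default,
seeded); the bootstrap converges to the CLT band on Gaussian rows, which
is asserted at 400 rows within 20%. Heatmap row order defaults to
descending control-sample body signal and is configurable — published
figure orderings are rarely stated, so none is hard-coded.

## Kinetics models

Anisotropy decays are rescaled to $[0,1]$ and fitted with
$y(t) = (1-c)\,e^{-kt} + c$, $k > 0$, $-1 < c < 1$, by bounded
Levenberg–Marquardt (`minpack.lm::nls.lm`; rate initialised by log-linear
regression on the upper half of the decay). The plateau is a free
parameter because real traces do not decay to exactly zero; it is allowed
to go mildly negative because rescaling a trace that has not finished
decaying maps its true asymptote below zero, and clamping at zero
demonstrably biases the rate. Half-life is parametric, $\ln 2 / k$ — the
time-to-0.5 reading would conflate rate and plateau. Non-decaying input
returns a failure object (`ok = FALSE`), not an exception, so screening
loops survive bad wells.

Binding titrations use the depletion-aware 1:1 isotherm
$f = \frac{(P+L+K_d) - \sqrt{(P+L+K_d)^2 - 4PL}}{2L}$ with total protein
$P$ and probe $L$, because at $L = 50$ nM the probe is not negligible
against nanomolar-range $K_d$; the hyperbolic form $P/(P+K_d)$ is its
limit for $L \ll K_d$, and the tests check both the limit and exact
recovery of $K_d$ across 10 nM–1 µM. Parameter covariances come from the
Jacobian cross-product at the optimum scaled by residual variance.
Reporter activities are blank-corrected, OD-normalised and scaled so the
mean control equals 1.

## What the simulator emulates — and what it does not

`make_genome_annotation()` + `simulate_coverage()` produce: two 500 kb
chromosomes with 200 non-overlapping genes (log-uniform lengths
0.7–4 kb, gaps 1–3 kb — gene-dense but clear of the 250 bp isolation
flank, so the planted effects are attributable to single genes); 10% of
genes attenuated in the depleted condition with a planted 5'/body ratio of
3; 20% of genes carrying 1–3 introns with retention 0.05 (control) vs 0.3
(depleted); exponential readthrough tails beyond the PAS (length-scale
40 bp for clean termination, 800 bp for the 30% of genes planted as
readthrough-prone in depletion — an exponential was chosen for its single
interpretable parameter, no particular tail shape being dictated by the
data); a global
40% transcription loss in depletion; per-base Poisson counting noise
(expectation mode, `noise = Inf`, returns the mean field exactly, which
makes every index analytically predictable and is used for
strict-monotonicity tests); expression levels log-normal around a mean
body coverage of 20; and library counts with a 100:1
experimental:spike-in mixture in which the spike amount is fixed at mixing
time, so global loss shows up in experimental reads only. PAS hexamers
are planted 26–31 bp upstream of each annotated end; poly-T tracts can be
planted downstream of the PAS to emulate the sequence bias of
attenuation-prone genes.

What it does **not** emulate: mappability and GC artefacts, fragment-level
correlation of counting noise (neighbouring bases are independent Poisson
here, so real tracks are noisier at fixed mean), overlapping and nested
transcription units, antisense leakage, and any upstream alignment
artefacts. Passing the planted-effect recovery tests therefore shows the
estimators are correct and well-calibrated on their own model, not that
they are robust to every artefact of real libraries. One realistic
confounder *is* present: long readthrough tails from upstream genes bleed
into downstream neighbours in the depleted condition, which is exactly the
interference the isolated-gene filter and the condition-ratio selection
are there to absorb.

Recovery claims are aggregate where the estimator's single-draw scatter
makes per-draw claims seed luck: the ~3-fold half-life change is recovered
as the mean over replicate pairs (single pairs scatter with sd ≈ 0.25
around 3 at σ = 0.02), the σ = 0.02 rate recovery is stated as median and
bias over 200 seeded replicates (median ≈ 2.5%, bias < 0.5%; individual
replicates can reach ~10% because rate and plateau trade off on a rescaled
noisy trace), and readthrough separation is the pairwise exceedance
probability (AUC) between planted and clean genes.

## Problem sizes and numerical choices

Default analyses run at the fixture scale above (200 genes, 1 Mb of
genome, two conditions); the acceptance script uses 1000-instance oracle
sweeps and 200-replicate kinetics recoveries, which complete in well under
a minute each on a single core. Optimiser iterations are capped at 500
(10^4 function evaluations); convergence uses `minpack.lm` defaults
(relative tolerances ≈ 1.5 × 10⁻⁸ — explicitly tightening them to 10⁻¹⁰
makes the underlying solver abort on perfectly conditioned data and buys
nothing at these noise levels). Bootstrap and all simulators take explicit
seeds; the pipeline derives every stage seed from the single configured
seed, and stage manifests record the configuration hash so byte-identical
reruns are checkable.

## Known limitations

- The GFF3 reader resolves `gene ← (mRNA/transcript) ← exon` structures
  with one intermediate level and one transcript per gene; it is not a
  general-purpose GFF3 model (alternative isoforms are collapsed by union
  of exons).
- `chip_target_set()` implements the threshold rule (≥ 2× universe mean);
  it does not reimplement peak calling, and upstream read processing
  (alignment, deduplication) is out of scope — inputs are coverage
  tracks.
- Differential-expression clustering and GO enrichment around the
  attenuation gene sets are deliberately not reimplemented.
- The headline gene counts of the motivating studies (thousands of
  isolated TUs, hundreds of attenuated genes) depend on the real genome
  annotation and deposited libraries; the synthetic fixture reproduces the
  *properties* of the estimators, not those counts.
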