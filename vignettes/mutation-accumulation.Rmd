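---
title: "Models and methods for diploid mutation-accumulation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for diploid mutation-accumulation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutaccum)
```

mutaccum analyses de novo mutations in diploid mutation-accumulation (MA)
lines: lineages propagated through single-cell bottleneck passages
(~25 mitotic generations each) so that selection is minimal and the
spontaneous spectrum of a genotype can be read directly from its
accumulated mutations. In a hybrid diploid whose two parental haplotypes
differ at tens of thousands of constitutive markers, loss of
heterozygosity (LOH) — by mitotic recombination, gene conversion,
break-induced replication (BIR), deletion or chromosome loss — is
observable as runs of homozygous markers, and the interplay between de
novo mutations and LOH (passive fixation or elimination of heterozygous
mutations) becomes measurable passage by passage. This vignette
documents the underlying models, the tunable parameters, and the design
choices behind each module.

## The simulation model

`simulate_lineage()` is a discrete-time forward simulator; each step is
one bottleneck passage.

**Mutation arrival.** New SNVs (and, separately, InDels) arrive as a
Poisson process with expectation $\mu \cdot 2G \cdot g$ per passage,
where $\mu$ is the per-nucleotide per-generation rate, $G$ the haploid
genome length and $g$ the generations per passage. Defaults:
$\mu_{SNV} = 1.8\times10^{-10}$, $g = 25$, and $G = 12{,}071{,}326$ bp
(the sixteen R64 nuclear chromosome lengths), giving
$\approx 0.109$ new SNVs per clone per passage — a wild-type diploid
yeast. Placement is uniform over the genome; each mutation lands on one
homolog chosen fairly. The InDel rate defaults to $10^{-11}$ (an order
of magnitude below the SNV rate, matching the rarity of wild-type
InDels), with 90% of InDels placed in homopolymer tracts (slippage);
observed mutator spectra put this fraction near 518/564.

**LOH events.** LOH tracts arrive at `loh_rate` per passage (default
0.09, the wild-type range; strong mutators reach 1.2–2.5). With
probability `p_terminal` (default 0.2) a tract is terminal: anchored at
a chromosome end, the hallmark of BIR or a single cross-over. Otherwise
it is interstitial (gene-conversion-like or double cross-over) and
placed uniformly. Tract lengths are log-uniform between configurable
bounds; the defaults span the observed ranges (interstitial 17 bp to
846 kb, terminal 55 bp to 1,079 kb). A log-uniform covers these four
orders of magnitude without committing to a mechanistic length model;
the family is pluggable (`"fixed"` is provided for deterministic tests).

**Segregation.** When a new tract overlaps pre-existing heterozygous
variants, each variant is *fixed* (homozygous) if it lies on the
retained homolog and *eliminated* otherwise. Because the retained
homolog is chosen fairly, this is a fair Bernoulli per variant — the
two-step model in which a mutation first arises heterozygous and is
later made homozygous (or erased) by an overlapping recombination event,
with the two nonsister chromatids segregating symmetrically.

**Copy number.** Whole-chromosome aneuploidies (gain to CN 3 or loss to
CN 1) and one-homolog structural deletions update local copy number,
eliminate or hemizygose the variants they remove, and homogenize the
markers they cover. A region made homozygous once cannot lose
heterozygosity again: marker ground truth applies the *first* covering
homogenizing interval.

**Observables.** `emit_observables()` adds the only noise in the model:
per-variant depth $DP \sim \mathrm{Poisson}(d \cdot CN/2)$ and alt depth
$\sim \mathrm{Binomial}(DP, f)$ with $f$ the true allele fraction (0.5
het at CN 2; 1 homozygous; 1/3 or 2/3 on trisomes), and likewise for
per-marker parental allele depths. Default depth $d = 50\times$.
Sequencing/genotyping *error* (miscalled bases) is off: the simulator
emulates depth sampling, not base errors, so tests passing on its output
show correctness of the segmentation/classification logic at realistic
depth noise, not robustness to miscalls, contamination, mapping
artifacts or mosaic colonies — all absent from the model.

**Reproducibility.** Each lineage uses an RNG stream seeded
`seed + lineage_id - 1`; the marker map derives from a fixed offset of
the config seed so all clones of an experiment share it. Identical seeds
give bit-identical outputs.

## Thresholds and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| het window | AF in [0.3, 0.7] | called heterozygous at CN 2 |
| hom threshold | AF >= 0.9 | called homozygous |
| trisomic tolerance | ±0.12 around 1/3, 2/3 | `het_trisomic` at CN 3 |
| min depth | 10 reads | below: `unresolved` / `missing` |
| min markers per LOH run | 3 | the consecutive-marker rule |
| SV span threshold | 50 bp | small InDels observed up to 44 bp; structural deletions from 62 bp — 50 separates the ranges |
| homopolymer min tract | 4 bp | shortest slippage-prone run annotated |
| whole-chromosome fraction | 0.9 | aneuploidy vs local CN change |
| breakpoint window | ±1 kb | feature annotation around LOH edges |

Published analyses state only "allelic ratio ~0.5" and "~1.0"; the
windows above are this package's explicit operationalization and are all
configurable arguments.

## LOH segmentation choices

* **Missing markers do not break runs.** A depth dropout inside a true
  tract must not fragment it; a run may therefore span missing markers,
  and its reported `n_markers` counts informative markers only.
* **One discordant homozygous marker breaks a run** (tolerance 0). Error
  tolerance would require a noise model for miscalls, which the package
  deliberately does not assume.
* **Terminal is judged against informative markers**, not sequence ends:
  subtelomeres are marker-poor, and a tract reaching the outermost
  informative marker is indistinguishable from one reaching the telomere.
* **Region coordinates are the marker span** (first to last marker of
  the run), not extended toward flanking heterozygous markers; length
  statistics are therefore conservative by up to one inter-marker
  interval per edge.
* **Resolution limit.** A tract spanning fewer than 3 markers is
  invisible. With the default tract-length distribution a large share of
  simulated tracts falls below marker resolution, so detected LOH rates
  understate simulated rates unless tract lengths are kept above ~3
  marker spacings; parameter-recovery experiments in the test suite use
  a 30 kb minimum length at ~3 kb marker spacing for exactly this
  reason — they test estimator calibration, not detectability.

## Mechanism classification

`classify_homozygous_origin()` is a decision list: chromosome loss
(whole chromosome CN 1), then deletion overlap (local CN < 2), then
`rec` (CN 2 inside an LOH region), then double slippage (a second,
distinct InDel in the same homopolymer tract, both at heterozygous
allele fractions — two homologs carrying different slippage products, so
the *tract* is homozygous-mutant while each call looks heterozygous),
else unexplained. Copy number is tested before LOH overlap because a
deletion inside a larger LOH region is better explained by the deletion,
the more direct signal. Variants inside an LOH region lacking nearby
marker support are still `rec` — the marker-resolution limit again.

## Trajectories

Variant identity across passages is positional (chrom, pos, ref, alt).
A variant absent at up to `dropout_tolerance` (default 1) intermediate
passages but present on both sides is imputed present, so a single
unrecoverable passage does not masquerade as an elimination followed by
an impossible re-mutation. A fixation is a het-to-hom transition between
consecutive passages; an elimination is a present variant that stays
absent to the end of the surveyed range (pass `passages` explicitly so
trailing mutation-free passages count). Events are linked to the LOH
difference between the flanking passages: a fixation requires a new or
extended region overlapping the variant, and by construction the
retained haplotype of that region *is* the carrier homolog; an
elimination implies the opposite. Observed data cannot phase a
heterozygous variant directly, so the linked region's haplotype is
reported as the inferred carrier; in simulations, where the carrier is
known, the direction is enforced and verified. Births and fates within
the *same* passage are invisible to per-passage data (the variant is
never seen heterozygous); ground-truth comparisons therefore count only
fates after the birth passage.

## Spectra and signature refitting

Spectra use the standard 96 pyrimidine-strand trinucleotide contexts in
fixed lexicographic order (substitution, then 5' base, then 3' base).
Refitting solves the non-negative least squares problem
$\min_{x \ge 0} \lVert Mx - y \rVert_2$ with a Lawson–Hanson active-set
implementation; the solution is checked (in tests) against the KKT
conditions — the gradient $M^\top(y - Mx)$ is zero on active coordinates
and nonpositive on zero coordinates — and against an independent solver.
No sparsity penalty or signature preselection is applied; relative
contributions are $x/\sum x$. A rank-deficient active set falls back to
a zero coefficient for the dependent column. The shipped
`synthetic_signatures.tsv` is a *synthetic* 8-column catalog (sparse
random profiles) for simulation and testing; real analyses should load a
published catalog (e.g. COSMIC v2's 30 signatures) with
`read_signature_matrix()`.

## Fluctuation tests

The mutant-count distribution of a Luria–Delbrück fluctuation culture is
computed by the Ma–Sandri–Sarkar recursion
$p_0 = e^{-m}$, $p_k = \frac{m}{k}\sum_{j=0}^{k-1}\frac{p_j}{k-j+1}$,
whose tail decays like $m/k^2$ (truncation at $k_{max}$ leaves
$O(m/k_{max})$ mass — there is no exponentially small cutoff). The MLE
of $m$ maximizes the log-likelihood over $\log m$ (bounded search,
`stats::optimize`), with a 95% profile-likelihood interval by
root-finding on the likelihood-ratio statistic. All-zero counts sit on
the boundary: $\hat m = 0$ with a one-sided upper limit from
$P(\text{all zero}) = e^{-nm}$. The per-generation rate is $m/N_t$.
Partial plating applies Stewart's efficiency factor
$(e-1)/(e\ln e)$ to $m$ — an approximation to the exact thinned
likelihood, adequate for $e \gtrsim 0.1$. This estimator replaces
web-tool implementations whose algorithms are unpublished; both target
the same Luria–Delbrück model.

Strain comparisons use the two-sided Mann–Whitney–Wilcoxon test, exact
for groups of at most 20 untied observations (verified against
exhaustive enumeration of all rank assignments for groups up to 8),
normal approximation with tie/continuity correction otherwise.

## Problem sizes used in validation

The test suite validates at deliberately desk-scale sizes: burden
recovery on 500 wild-type lineages of 25 passages; parameter recovery on
100 replicate experiments of 16 clones (100 passages for the wild-type
rate, 25 for the 20x mutator and the LOH experiments at 4,000 markers);
segmentation against a brute-force oracle on 10,000 random tracks;
200-replicate calibrations for signature refitting (1,000-mutation
Poisson resamples) and fluctuation MLE coverage ($m = 2$, 50 cultures).
For the LOH-rate recovery the standard error is the Poisson-count SE
$\sqrt{N}/(\text{clones}\times\text{passages})$ — the correct SE for a
Poisson event count, and stabler than a 16-clone sample SD.

## Known limitations

* No read-level or base-error simulation; no mapping artifacts,
  contamination, or mosaic (mixed-colony) passages.
* No mitochondrial or rDNA copy-number dynamics.
* LOH detection cannot see tracts below 3 marker spacings, and merged
  overlapping tracts are counted once; detected rates are lower bounds
  at high LOH rates.
* Mechanism calls do not distinguish cross-over from gene conversion
  from BIR at the per-variant level; only tract-level
  interstitial/terminal labels are available.
* The double-slippage rule requires both InDels to be called; a dropout
  of one partner leaves the case unexplained.
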