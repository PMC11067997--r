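---
title: "Zygosity-based sex determination: models, statistics and design notes"
author: "zygosex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zygosity-based sex determination: models, statistics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zygosex)
```

## The system being modelled

In *Bicyclus anynana* butterflies (and, convergently, in honeybees via
*csd*), sex is decided by allelic state at a single locus rather than by a
female-specific chromosome factor.  At the Z-linked masculinizer locus:

* one allele (WZ or Z0 **hemizygote**) → female;
* two **distinct** alleles (ZZ heterozygote) → male;
* two **identical** alleles (ZZ homozygote) → female-typical transcription
  with a male karyotype, failed dosage compensation, and death as a
  late-stage embryo ("black egg").

Unconditional homozygote lethality is a strong form of heterozygote
advantage.  It generates negative frequency-dependent balancing selection:
a new allele can never meet itself in a zygote, so rare alleles enjoy a
transmission advantage, and populations accumulate spectacular allelic
richness with an allele frequency spectrum dominated by singletons.

The functional polymorphism concentrates in two exons of the gene: a
hypervariable region (HVR) in exon 8 — an asparagine-rich simple sequence
repeat of 7–24 residues drawn from {N, H, S, W, Y}, encoded almost
exclusively by ANT/NAT codons — and a hyperdiverse exon 9.

The package provides (i) a forward simulator of the system, so every
downstream statistic can be exercised on data with known truth, and (ii)
the analyses used to characterise it: codon-aware diversity, allele
richness extrapolation, compatibility resampling, Mendelian/sexing tests,
and dosage-compensation ratios.

## The forward simulator

`simulatePopulation()` runs discrete, non-overlapping generations with
equal fecundity (the biology specifies no particular demography, so the
simplest neutral demography is used).  Each generation, eggs are formed by
random mating; a WZ mother transmits W or her Z allele with probability
1/2, the father transmits either of his two alleles with probability 1/2,
and zygotes receiving two identical alleles are removed before adulthood.
The adult census (`nFemales`, `nMales`) is then refilled from surviving
zygotes.  Allele identity is amino-acid identity; a hook for coarser
functional specificity classes is deliberately *not* modelled (alleles
whose sequences differ are assumed mutually compatible).

Design choices worth knowing about:

* **Z0 oogenesis.** Z0 females lack a W entirely; their unpaired Z
  univalent is assumed to segregate randomly, so half their eggs carry
  the Z and half carry no sex chromosome.  The true segregation ratio is
  unknown (the univalent shows a tendency to self-pairing); the 1/2 value
  is an explicit, documented assumption of `simulateBrood()` and
  `expectedOffspring()`.
* **The Z0 route.** With probability `z0Rate` (default 0.004, the
  observed wild frequency of W-less females) an egg destined to inherit W
  becomes a Z0 daughter instead.
* **WZZ males** are classifiable by `classifyIndividual()` but are not
  generated by the simulator's default life cycle; sex-chromosome
  nondisjunction is outside the mutation model.
* **Extinction** is a value, not a crash: if the adult census cannot be
  refilled the run stops with `isExtinct(state)` set.

### The HVR mutation model

`mutateHaplotype()` applies three processes per transmission:

* **Slippage** (`muSlip`): a single-codon expansion or contraction of the
  HVR, drawn with equal probability and *rejected* at the configured
  bounds (default 7 and 24 residues).  Bell-shaped length distributions
  emerge from the bounded random walk rather than being imposed.
* **HVR point substitution** (`muPoint`, per codon): replacement within
  the ANT/NAT codon alphabet.
* **E9 nonsynonymous substitution** (`muE9`, per codon): amino-acid
  changing substitutions in the exon-9 portion, outside the HVR.

One subtlety: the observed HVR alphabet is {N, H, S, W, Y}, but
tryptophan's only codon (TGG) cannot follow the ANT/NAT pattern that the
other four residues obey (AAT, CAT, AGT, TAT).  The generator therefore
uses the strictly ANT/NAT alphabet {N, H, S, Y} (N-biased, 60%), so that
generated HVRs satisfy the codon-pattern invariant exactly, while
validation of user data additionally tolerates W/TGG.  Codon-usage
profiling (`codonUsageProfile()`) reports whether a data set's HVR codons
are pure ANT/NAT.

### Canonical study conditions

Mutation rate magnitudes for this locus are unknown; what matters for the
qualitative regime is the product of census size and mutation rate, which
sets the equilibrium allele number.  The wild effective population size
is far too large to simulate directly, so `csdConfig()` applies the
standard population-genetic rescaling — census down, mutation up — to
place a census of 1000 + 1000 into the high-richness regime: mutation
rates (2e-3 per HVR codon, 4e-3 slippage, 4e-4 per E9 codon, per
transmission) hold roughly a thousand alleles at equilibrium after 150
generations.  Samples of 228 simulated females then show ~80% singleton
alleles, haplotype diversity above 0.99, and iChao1 extrapolations in the
several-hundreds — the same qualitative profile as wild samples.  Because
the rescaled census is still small, occasional alleles drift to a few
percent, so the abundance tail of a sample can reach ~4–9 copies rather
than the hard truncation at 3 seen in the (much larger) wild population;
this is a finite-size artefact of the rescaling, not a feature of the
biology.

## Codon-aware diversity

`neiGojoboriPair()` implements unweighted pathway counting of synonymous
and nonsynonymous sites and differences.  Conventions, each of which is
pinned by tests against an independent brute-force pathway oracle over
all 61 × 61 sense-codon pairs:

* substitutions to stop codons count as nonsynonymous for site counting,
  so per-codon sites always sum to 3;
* multi-hit codons average step counts over all minimal pathways that
  avoid stop intermediates (with a documented fallback if every pathway
  is blocked);
* codon columns containing a gap or ambiguity in either member of a pair
  are skipped — pairwise deletion at codon granularity.

A consequence worth noting: on degenerate micro-examples the synonymous
p-distance can exceed 1 (e.g. TTT vs TTC is one synonymous difference over
one-third of a synonymous site, p_s = 3).  This is a property of the
estimator, not a bug, and disappears at realistic sequence lengths.

`slidingWindowDiversity()` uses 99-nt windows with 75-nt overlap by
default, stepping from alignment position 0, and reports the final
partial window with its true length.  All haplotypes are weighted equally
(not by frequency).  Indels, which occur at this locus strictly in
multiples of three nucleotides, are counted per gapped codon ("a 6-nt gap
= 2 triplet indels"), the convention that makes per-triplet normalisation
natural; because a multi-codon gap could defensibly be counted as a
single mutational event instead, both interpretations are exposed
(`indelMode = "per-codon"` default, `"per-event"` alternative).  Shared gaps are not pairwise differences.
Bootstrap SEs (default 100 replicates) resample codon columns within the
window.  Total nucleotide diversity in `exonDiversity()` is a p-distance
with an optional Jukes–Cantor correction; the maximum-composite-likelihood
variant used by some GUI tools is approximated by these with small
expected deviation, while π_s/π_n follow Nei–Gojobori p-distances exactly.

HVR boundaries cannot be derived by rule from an alignment; region spans
are always explicit inputs (`regions()` on a `CodingAlignment`, or a
BED-like 0-based half-open span file via `readRegionsBed()`).

`amovaPhiSt()` computes the AMOVA fixation index from squared pairwise
distances via the Excoffier variance components, with label-permutation
p-values.  Permutation p-values are reported with the (hits + 1)/(n + 1)
convention, so they are never 0.

## Allele richness

`effectiveWildCorrection()` collapses repeated alleles within lab-reared
G1 populations to a single count (family structure makes within-family
copies non-independent), yielding the "effective number of wild females".
`iChao1()` implements Chao1 (bias-corrected form when f2 = 0) and the
improved iChao1 estimator, which adds an f3/f4 term with f4 replaced by 1
when f4 = 0.  The 95% CI uses the standard log-transform on
(estimate − S_obs); the estimator variance comes from a delta method over
all observed abundance-frequency counts with the usual multinomial
covariances (Cov(f_i, f_j) = −f_i f_j / Ŝ).  Alleles are compared at the
amino-acid level by default (pass nucleotide-level identifiers to work at
the nucleotide level), and samples from demographically isolated
populations may be pooled before estimation because differentiation at
this locus is negligible.

On simulator populations with known allele number, the 95% CI covers the
truth in ~90% of replicate samples of 60 females — slightly below nominal
because iChao1 is a lower-bound estimator with residual negative bias at
small n.

## Compatibility analysis

`pairDistances()` implements the four distances used to describe allele
pairs in viable heterozygous males: HVR length difference, HVR
Levenshtein distance (unaligned amino acids), non-HVR Levenshtein
distance, and a composite.  A whole-sequence mixed-model phylogenetic
distance would require integer recoding of the unalignable HVR plus
external tree software, so the fourth metric is a documented composite
(normalised HVR edit distance plus non-HVR p-distance, equal weights);
conclusions drawn from it should be treated as approximate.  `simulateHeterozygousMales()` is the
resampling null: pairs drawn with replacement from the empirical
haplotype frequencies, homozygous draws discarded; the resulting pair
distribution equals 2 p_i p_j / (1 − Σ p²).  Observed-versus-simulated
comparison uses a two-sample Kolmogorov–Smirnov test per metric (chosen
because the metrics are one-dimensional and the question is one of
distribution shape), and non-rejection *supports* (never proves) the
hypothesis that all sampled pairs are compatible.

## Mendelian and sexing tests

`expectedOffspring()` enumerates zygote classes: a shared-allele cross
loses 1/4 of zygotes (half of all ZZ) as homozygotes; a non-sharing cross
loses none.  `segregationChisq()` treats zero-expectation classes as hard
constraints (a homozygote in a non-sharing cross is a rule violation, not
a χ² contribution).  `hwHomozygoteDeficit()` tests the hom/het split of an
adult male sample against Σp² estimated from contemporary females, with an
explicit underpowered flag when the expected homozygote count is below 5.
`fisherExact2x2()` uses the standard two-sided point-probability
definition (8/8 daughters vs 0/8 sons gives exactly 2/12870 ≈ 0.000155).
`knockdownContingency()` applies Pearson's χ² **without** continuity
correction by default: with Yates' correction the 0/14-vs-11/20 knockdown
contrast does not reach p < 0.001 (p ≈ 0.0027 vs ≈ 0.0007), and the
uncorrected statistic is the conventional choice at these sample sizes;
both variants are exposed.

## Dosage compensation

Expression tables are `SummarizedExperiment`s with a gene class (A/Z) and
a sample zygosity class (hem/het/hom); quantification is upstream and out
of scope.  `filterExpression()` applies the strict "> minAbund in ≥
minSamples samples" rule (defaults 1 and 3).  `zaMedians()` summarises
each gene by its within-class replicate mean, then takes medians across
genes; pooling samples before the median is an equally defensible
aggregation, so the per-gene form is the documented default and the raw
matrix is always available for the alternative.
Ratio distributions exclude genes with a zero denominator mean (counted
and reported, not treated as infinite).  Displays use log2.
`zaCutoffSweep()` evaluates the Z:A ratios over the full grid of
minimum-sample (1–12) and minimum-abundance (>0, >1, >2) cutoffs; on
conforming synthetic data the homozygote ratio exceeds the compensated
classes at every grid point.  The generator's defaults place compensated
Z:A at 0.6 (centre of the observed 0.5–0.7) and elevate homozygotes by
1.87, the observed median hom/hem differential; with lognormal noise of
sd 0.25 the module recovers the configured factor within ±0.1 at 500 Z
genes.

## Numerical and testing notes

* All randomness flows through explicit seeds (`SimConfig@seed`, or
  `seed` arguments); identical config + seed reproduces outputs
  bit-for-bit.
* Problem sizes used by the test-suite simulations — censuses of a few
  hundred to a thousand, 25–250 generations, 200-replicate coverage and
  calibration experiments, 500-gene recovery checks — were chosen so the
  statistical claims are testable with comfortable margins at desk scale.
* What passing simulator-based tests shows, and what it does not: the
  generator emulates the zygosity rule, Mendelian segregation, HVR repeat
  mutation, singleton-dominated spectra and the dosage-compensation
  pattern, but not sequencing error, allele dropout, alignment ambiguity
  in real HVRs, population structure, or functional haplogroups
  (sequence-distinct but incompatible alleles).  Agreement on synthetic
  data therefore validates the statistics, not any claim about a
  particular wild data set.
* Known limitations: the composite pair distance is a stand-in for the
  tree-based metric; total π is p-distance/JC rather than maximum
  composite likelihood; iChao1 CIs keep mild undercoverage at very small
  samples; the rescaled census fattens the allele-abundance tail as noted
  above.
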