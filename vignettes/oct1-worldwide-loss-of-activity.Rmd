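---
title: "Worldwide loss of OCT1 activity: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Worldwide loss of OCT1 activity: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lofscape)
```

## The scientific problem

OCT1 (SLC22A1) is the major organic cation transporter of human
hepatocytes; it imports vitamin B1 and cationic drugs such as metformin,
morphine and tropisetron. Its coding region is unusually polymorphic, and a
handful of amino-acid substitutions (plus one in-frame single-codon
deletion, Met420del) abolish or strongly reduce transport. Because carriers
of two defective alleles effectively lack hepatic OCT1 uptake, the
worldwide distribution of these alleles matters both for drug dosing across
populations and as a signal of natural selection on the transporter.

`lofscape` packages the computational side of a worldwide survey of OCT1
coding variation: 2,171 individuals from 67 populations (53 from the
enriched HGDP-CEPH panel, 14 from the 1000 Genomes Project), with coding
haplotypes grouped into star alleles (*1 to *16 plus sub-alleles) and
characterised functionally against ten transport substrates. The package
ships the population-level summary data as fixtures, implements every
statistical step of the analysis, and provides a synthetic genotype
generator so the whole pipeline can be exercised and validated end to end
without any external download.

## Data model

Three tables drive everything:

* **Allele definitions** — each star allele is a set of amino-acid
  variants; the reference allele *1 is the empty set. Sub-alleles (*1B,
  *7A, ...) add only activity-neutral variants to their parent major
  allele.
* **Activity matrix** — percent-of-reference uptake for each allele and
  each of ten substrates (MPP+, TEA+, ASP+, morphine, metformin,
  tropisetron, O-desmethyltramadol, debrisoquine, tyramine,
  monocrotaline).
* **Population panel and allele counts** — per population: world region,
  sample size, and integer chromosome counts per major allele.

The shipped allele counts were reconstructed from printed percentages; each
row sums exactly to the population's chromosome count, so frequencies are
exact rationals and the headline summaries of the published table are
reproduced to their printed precision. The activity matrix is
figure-derived and therefore approximate: values were read from bar
charts, which is why the classification rules (below) are expressed as
thresholds rather than assay-level comparisons, and why the matrix file is
flagged as figure-derived. Two pieces of the original supplementary
material are not recoverable from the running text: the exact variant
composition of the 14 sub-alleles and the per-population frequencies of the
five activity-neutral variants that segregate only on sub-alleles
(Phe160Leu, Pro341Leu, Arg342His, Met408Val, Gly414Ala). Both ship as
clearly marked *synthetic reconstructions* (files suffixed `_synthetic`):
the sub-allele compositions follow the documented combination rules, and
the neutral-variant regional frequencies were calibrated once against the
published per-region diversity summaries. Consequences: analyses that
depend only on major alleles (frequency tables, phenotype scoring, AMOVA,
F_ST) are fixture-exact, while the non-LOF diversity stratum is
reconstruction-dependent and is validated at the level of ranks and signs,
not digits.

## Classification rules

All thresholds are strict inequalities on percent-of-*1 activity and are
configurable through `analysis_config()`:

* **major vs sub-allele**: a major allele changes activity by more than
  50 % (in either direction) for at least one substrate
  (`threshold_major = 50`).
* **loss of phenotype activity**: an allele stops counting as active when
  its uptake falls below 35 % of reference for at least one substrate — a
  more than 65 % reduction (`threshold_loss = 35`). With the shipped
  matrix this leaves exactly {*1, *8, *9} active, which doubles as a
  consistency check between the rule and the configured
  `active_allele_set`.
* **activity modes**: complete substrate-wide loss when every substrate is
  at or below a 5 % floor (the floor absorbs read-off noise in a
  figure-derived matrix); substrate-specific loss when some substrate is
  below 50 % while another is retained above 90 %
  (`threshold_retained = 90`); partial substrate-wide loss otherwise;
  gain when some substrate exceeds 150 % and none falls below 50 %.
* **variant classes**: a variant is loss-of-function (LOF) when a
  single-variant allele carrying it loses more than 50 % of activity for
  at least one substrate. Cys88Arg, Arg206Cys and Gly465Arg are never
  observed without Met420del, so their class cannot be measured from the
  allele matrix; they carry explicit overrides (all LOF), as do the five
  neutral variants that appear only on sub-alleles. The resulting split is
  12 LOF and 7 non-LOF variants.

Individuals are scored by their diplotype as carriers of 2, 1 or 0 active
alleles; alleles that cannot be named (novel haplotypes) or whose
composition is unknown (*16) are scored inactive by default, with a flag.

## Haplotype phasing

The original analysis phased genotypes with PHASE v2.1. Reimplementing a
coalescent-prior Bayesian phaser is out of scope here; instead the package
uses the classical expectation-maximisation (gene-counting) estimator of
haplotype frequencies under random union of gametes, which for a single
short gene with star-shaped haplotype structure and few heterozygous sites
agrees with PHASE in practice. The protocol mirrors the original seed
design: ten independent EM runs from random starts (seeds 2, 1536, 2936,
3123, 4957, 5283, 6757, 7992, 8633, 9045), the best-likelihood run is
kept, and the fraction of individuals whose most-probable diplotype is
identical across all runs is reported. The EM log-likelihood is
non-decreasing (asserted in tests), phase-unambiguous data reduce exactly
to direct counting, and the estimator is cross-checked in the test suite
against a grid-search maximiser of the multinomial likelihood on the
haplotype-frequency simplex. Enumeration of phase configurations is exact
and limited to 25 sites per panel and 20 heterozygous sites per
individual — far above anything the single-gene data produce. Individuals
with missing genotypes are not modelled (the containers reject missing
values), matching the complete-genotype tables the pipeline consumes.

## Diversity statistics

For a stratum of segregating sites with variant counts \(c_s\) among
\(n\) chromosomes:

* nucleotide diversity
  \(\pi = \frac{n}{n-1}\sum_s 2 p_s(1-p_s) / L\) with \(p_s = c_s/n\),
  equal to the average pairwise difference per site (verified against a
  brute-force pairwise oracle on random instances);
* Watterson's estimator \(\theta_W = S/(a_1 L)\),
  \(a_1 = \sum_{i<n} 1/i\);
* Tajima's D with the standard 1989 constants.

The normalising length defaults to `coding_length_L = 1665` bp (the
554-codon coding sequence plus stop). The source text only says the values
were normalised to the coding-region length, so L is a configuration knob
and every normalised output records the L used; D is invariant to L.
Met420del, although a 3-bp deletion, is treated as one biallelic marker
throughout, and its length never enters \(\pi\) — the convention the
original analysis applies to its single segregating-variant table.

Significance of D is assessed by neutral coalescent simulation conditioned
on the observed S (Hudson's fixed-S scheme, implemented in C++): simulate
the genealogy of n tips, drop S mutations uniformly on the branches, and
recompute D. The reported p-value is the lower-tail count
\(P(D_{sim} \le D_{obs})\) with an add-one correction — the convention of
the simulation tests in the classical population-genetics packages, and
the one under which the published significance of the East Asian LOF
stratum is reproducible. The two-sided count on |D| and the upper tail are
available through the `alternative` argument; the two-sided version is
notably conservative at small S because the conditional null of D given
S = 5 has a heavy positive tail. A θ-driven (Poisson mutation) mode exists
for calibration tests: at n = 100, θ = 5 the simulated null mean of D lies
within [−0.25, 0.1] and the 1st–99th percentiles bracket zero.

Region-level strata pool the chromosomes of all non-admixed member
populations (single per-region values, as in the published stratified
table), while the frequency summary rows use unweighted arithmetic means
over member populations — the convention that reproduces the printed
region means, including the worldwide row, which is the unweighted mean
over all 67 populations.

## AMOVA, Φ statistics and F_ST

The hierarchical analysis of molecular variance follows the classical
sums-of-squared-deviations formulation from squared pairwise distances,
with the standard unequal-sample-size coefficients, at three levels
(within populations / among populations within regions / among regions) or
two. Haplotype distances are the number of differing variant sites
(used directly as the squared molecular distance); phenotype-level
analyses treat each individual as one observation with the squared
difference of the 0/1/2 active-allele codes — the documented
interpretation of the "allele frequency" input of the original software,
which does not print its exact distance convention. Negative variance
components are truncated to zero with a flag before percentages are
formed (the convention of the original software). Permutation p-values
permute chromosomes among populations (Φ_ST), chromosomes among
populations within regions (Φ_SC), and whole populations among regions
(Φ_CT); the permuted and observed statistics are compared *before*
truncation, because truncation creates an atom of ties at zero that would
make the test miscalibrated (uniformity under a true null is asserted in
the test suite). Pairwise F_ST matrices are two-level Φ_ST for every pair
of groups. The default permutation count is 10,000 and every seed is
recorded in the run manifest.

## The synthetic-data generator

`simulate_panel()` draws, per individual, two star alleles from the
population's allele-frequency vector — independently with probability
1 − F, identical by descent with probability F (default F = 0, i.e.
Hardy-Weinberg, which is the sampling assumption the worldwide analysis
itself invokes for carrier frequencies) — expands them to variant sets and
emits unphased 0/1/2 genotypes, plus a truth file with the drawn pairs and
realized allele counts. An optional symmetric per-site flip error corrupts
the emitted genotypes but never the truth. `simulate_from_fixture()`
instantiates the worldwide design: the fixture's population sizes and
allele frequencies, with composition-unknown alleles (*16) dropped and
frequencies renormalised. What the generator deliberately does **not**
model: coalescent demography, linkage to flanking variation, genotyping
missingness, and within-region substructure beyond the fixture's
population grid. Passing recovery tests on these panels therefore
demonstrates correctness of the estimators under the stated sampling
model, not robustness to artefacts real sequencing data may carry.

Default problem sizes in the tests and the acceptance script were chosen
to give stable statistics at interactive runtimes: the full fixture panel
(1,844 non-admixed individuals) for structure analyses, 500 individuals
per population for phasing recovery, 10,000 permutations and 10,000
coalescent replicates for p-values.

## Numerical and design choices worth knowing

* Exact multinomial probabilities use category probabilities exactly as
  supplied, without renormalisation — published carrier splits are rounded
  percentages (53/38/8 sums to 0.99) and renormalising would change the
  reproduced values. The point mass is the default outlier measure; an
  exact enumeration tail (sum of outcomes at most as probable) is offered
  as a conservative companion for n ≤ 20.
* The EM uses a flat restart if a random start assigns zero mass to every
  phase of some individual, and reports the likelihood of the returned
  frequencies (not the pre-update one).
* Symmetric double heterozygotes are a genuine EM saddle: uniform
  initialisation leaves the four haplotypes at 0.25 each, and the
  multi-seed agreement report flags such individuals rather than
  pretending to resolve them.
* Diplotype ties are broken lexicographically on haplotype labels and
  flagged; genotype classes with zero likelihood under the fitted
  frequencies are assigned by a uniform tie-break and flagged.
* The reference haplotype key is "." (not the empty string, which R
  cannot address by name).
* Truncated AMOVA components are reported alongside their raw values, so
  the truncation is always visible.
* `*16` is excluded from activity classification by default because its
  variant composition is unknown; it can be overridden by supplying a
  definition.

## Known limitations

* The non-LOF diversity stratum rests on the synthetic reconstruction of
  neutral-variant frequencies; its absolute values should be read as
  illustrative, its ranks and signs as the validated content.
* The stratified diversity table cannot reproduce the published values
  digit-for-digit even in principle from the shipped summaries: that would
  require the per-individual supplementary genotypes and the original
  software's indel-handling conventions.
* EM phasing reports maximum-likelihood frequencies without a coalescent
  prior; for rare haplotypes in small samples PHASE's prior would shrink
  estimates differently.
* The exact multinomial tail is limited to n ≤ 20 by design (exact
  enumeration); larger samples need a different test, not this one.
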