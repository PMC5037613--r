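---
title: "Mapping a recessive disease gene in a consanguineous family: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive disease gene in a consanguineous family: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autozygmap)
```

# The problem

`autozygmap` implements, as one tested pipeline, the desk-side computations
behind a classical consanguineous-family gene hunt: a rare, fully penetrant
autosomal recessive neuropsychiatric syndrome segregating in an extended
inbred family is localized by autozygosity mapping and parametric linkage,
the critical interval is interrogated by exome-style rare-variant
filtering, and the candidate's functional effect on G-protein signaling is
quantified from BRET deactivation kinetics (the GAP activity of an
RGS–G&beta;5 complex). No raw study data are available, so the package also
ships a first-class synthetic-data module that generates pedigrees, SNP
genotypes, exome-like variant tables and BRET traces with the statistical
structure the downstream analyses assume; every stage is exercised on its
own simulations.

# The reconstructed pedigree

The study family is known only from its textual description: five affected
girls in three sibships — three affected sisters, an affected first cousin,
and an affected more distant cousin — born to consanguineous unions. The
published pedigree figure is not machine-readable, so `study_pedigree()` is
an explicit *reconstruction*: two founder couples whose children
intermarry, making the parents of each affected sibship double first
cousins (inbreeding coefficient 1/8 for all five affecteds) and the distant
cousin a second cousin of the index sibship. It is labeled a reconstruction
throughout and treated as synthetic.

This choice matters quantitatively, and one consequence is documented here
because it bounds what the package can reproduce. At a fully informative
marker completely linked to the disease locus, the expected LOD score of a
fully penetrant rare recessive model is essentially the information content
of the affection pattern,

$$\mathrm{LOD}_{\max} \approx -\log_{10} \sum_h P(\text{all five affecteds
autozygous for founder haplotype } h),$$

which path counting evaluates to about 5.1–5.5 for *any* topology
consistent with the textual description (about 20 path meioses across the
three sibships; the requirement that unaffected siblings not be affected
adds ~0.4). The package measures exactly this: with 16-allele,
near-fully-informative markers the modal genome-scan peak across seeds is
5.49, essentially deterministic. A published peak of "approximately 4" is
therefore *not* reproducible under full marker informativeness by any
reconstruction faithful to the text; it presumably reflects the true
(unpublished) topology and the partial informativeness of biallelic SNP
panels. The package reports what its stated world computes rather than
calibrating the fixture toward the published number.

# Gene-dropping simulator

Founders receive two haplotypes with alleles drawn independently per
marker from the supplied frequencies (linkage equilibrium); each meiosis
is a Markov chain along the chromosome with switch probability given by
Haldane's map function (no interference), at 1 cM/Mb by default. When a
disease locus is given, exactly one founder haplotype carries the disease
allele, and the simulation is conditioned on the full-penetrance
consequence of the affection pattern: every affected member homozygous by
descent for that haplotype at the locus, no unaffected member so.

Conditioning is exact. Where the descent path from a candidate founder
haplotype to each affected member is unique — true for the fixture, whose
unions always pair a descendant of one founder couple with a descendant of
the other — the path meioses are forced, candidate haplotypes are proposed
with weight $2^{-\#\text{forced meioses}}$, and only the residual
unaffected-member constraints are enforced by (cheap) rejection. For
pedigrees with ambiguous paths the sampler falls back to plain batch
rejection over disease-locus inheritance vectors. A property test checks
the forced-path law against the rejection law on a small pedigree. The
naive rejection sampler alone was rejected as the default because the
conditioning event has probability ~2^-20 on the fixture.

Marker inheritance on the disease chromosome is simulated *outward from
the conditioned locus* in both directions, which is exact for a Markov
chain. Truth is recorded per individual as identity-by-descent segments
(`sim_truth`), so recovery tests never re-derive the answer from the
genotypes being tested.

# ROH detection and exclusive sharing

Runs of homozygosity longer than 2 Mb (strict) serve as surrogates of
autozygosity. A run may absorb up to `max_het` heterozygous calls
(default 0) and skips missing calls; it spans its outermost homozygous
markers, and needs at least `min_markers` homozygous markers (default 50;
the packaged pipeline uses 25 at its 50 kb marker spacing — the threshold
is declared, not inferred, since the original software's settings are not
stated). Intervals separated by one het beyond the tolerance are *not*
merged.

The critical interval is the intersection of all affected members'
autozygomes minus the union of unaffected members' autozygomes,
re-filtered at 2 Mb; interval arithmetic is 1-based inclusive and is
delegated to IRanges. Two failure modes of this *correct* procedure are
worth knowing when interpreting green tests. First, an unaffected inbred
sibling is occasionally autozygous for a *normal* haplotype across the
critical region (probability roughly its inbreeding coefficient), which
erases the interval — nothing forbids an unaffected homozygote for the
normal allele. Second, the intersection across five affecteds accumulates
recombinations from ~44 path meioses and occasionally drops under the 2 Mb
filter. On the double-first-cousin fixture the planted locus is recovered
in roughly 70% of seeds; the corresponding acceptance property demands
95% and is left failing with this analysis, since meeting it would
require either a sparser family than the text describes or weakening the
stated thresholds.

# Parametric linkage

The two-locus (marker + disease) pedigree likelihood is computed exactly
by peeling: each individual's phased two-locus genotype is a variable,
founder priors are HWE at the marker times the disease allele frequency
(default 1e-4, a shared ancestral mutation being assumed rare), each
non-founder contributes a transmission factor with Haldane recombination
between marker and disease locus, and affection status enters through the
penetrance vector ((0, 0, 1) for the fully penetrant recessive model).
Variable elimination under a min-fill order sums the network exactly;
consanguinity loops need no explicit loop-breaking because elimination
handles them (this generalizes classical Elston–Stewart peeling, and an
exhaustive inheritance-vector enumeration oracle verifies equality to
1e-10 on random looped pedigrees). Tractability on multiallelic markers
comes from genotype elimination: an individual typed at a k-allele marker
retains at most 8 of the (2k)^2 phased states, so fully typed panels peel
quickly even at k = 16.

LOD scores are singlepoint per marker, maximized over a theta grid
(default {0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5}), with LOD(0.5) = 0 by
construction; the genome-scan peak is reported. Multipoint HMMs are out
of scope; the locus-identity claims the pipeline makes are recovered by
singlepoint peaks at the simulated densities, with the caveat that a
singlepoint biallelic peak occasionally sits just outside the shared
interval (observed ~7% of non-empty runs), which the end-to-end
concordance check surfaces honestly.

Mendelian-inconsistent marker data yield likelihood zero and a diagnostic
listing the violating trio(s).

# Variant filtering

The WES prioritization chain is deliberately literal: keep variants where
the index case is homozygous for the alternate allele, inside the critical
interval (endpoints inclusive), with population frequency strictly below
0.001 or absent ("novel": missing from the frequency lookup passes, as
with cohort lookups). Counts after each rule are recorded and are monotone
non-increasing. Segregation is checked as quoted for a recessive variant:
affecteds homozygous alternate, parents of affecteds heterozygous,
unaffecteds anything but homozygous alternate; missing genotypes are
neutral and reported as untyped. The coverage audit flags exons at depth
<= 10 (pass is strictly > 10 reads). Multiallelic VCF records are split to
biallelic on read. Pathogenicity scores are pass-through annotations; the
package does not reimplement them.

The exome simulator draws 90% of background variants uniform on
[0.001, 0.5] (these fail the frequency rule wherever they fall) and 10%
uniform on [1e-6, 1e-3] placed outside the interval, so the planted causal
variant — frequency 6/121000 ≈ 4.959e-05, homozygous in affecteds,
heterozygous in obligate carriers — is the unique in-interval rare
homozygous record by construction.

# BRET kinetics

Traces follow a phenomenological two-phase model: baseline, saturating
rise after agonist at rate `k_act`, and single-exponential return toward
baseline after antagonist at the observed deactivation rate
`k_app + k_GAP`, sampled at 20 ms with iid Gaussian noise (default 0.006,
2% of the 0.3 amplitude). Defaults (baseline 0.8, agonist at 10 s,
antagonist at 30 s, 60 s duration, n = 6 replicates) are desk-scale
choices matching the sampling resolution and replication conventions of
plate-reader GAP assays; absolute BRET calibration is not modeled.

Analysis mirrors standard practice: subtract the pre-agonist mean
(&Delta;BRET), fit y(t) = A·exp(−k·(t−t0)) + C per replicate over the
post-antagonist window — a 0.1 s lag skips mixing dead time, the offset C
floats because traces return to baseline only approximately, and start
values come from the endpoints and log-slope — then aggregate replicates:
k_GAP = mean(k_obs) − mean(k_app) with SEMs propagated in quadrature.
Fitting each replicate and aggregating (rather than fitting the mean
trace) matches the mean ± SEM reporting convention. Degenerate windows
(constant or rising signal, too few points) are flagged as non-converged,
never silently returned, and non-converged fits are excluded and counted.
Group comparison is a classical one-way ANOVA on the per-replicate
deactivation rate constants (equivalent to comparing per-replicate k_GAP,
which differs by a common constant); Dunnett's post-hoc is out of scope
and Bonferroni-corrected pairwise tests against the basal group are the
labeled alternative. The magnitudes of the wild-type-like (0.4 1/s) and
mutant-like (0.1 1/s) defaults are *not* reproduction targets — the source
figures print no numbers — only their ordering and the ANOVA significance
pattern are asserted.

# What a green test does and does not establish

The simulator draws founder haplotypes in linkage equilibrium, uses
Haldane recombination at a uniform 1 cM/Mb, and knows nothing of
genotyping batch effects, LD between background markers, chip ascertainment,
sequencing artifacts, or cell-to-cell variation in BRET assays. Green
tests establish that the *computations* are correct on data satisfying the
stated model — filters filter as quoted, the likelihood equals brute-force
enumeration, rates are recovered at the stated noise — not that the
pipeline would behave identically on real chip or plate data.

# Numerical and degenerate-input choices

* Peeling factors are rescaled by their maximum at each elimination to
  avoid underflow; likelihood zero propagates to −Inf LOD sentinels.
* The theta grid always includes 0.5 so the LOD reference is computed,
  never assumed.
* `detect_roh` rejects unsorted marker input; empty input returns an
  empty autozygome.
* `allele_frequency` rejects zero totals; frequencies are validated into
  [0, 1] wherever they enter.
* All simulators take an integer seed and are bit-reproducible;
  output files carry the seed and a config hash, and report JSON is
  byte-stable for fixed config (file dates are pinned in headers).
* JSON (jsonlite) replaces YAML for configs and sidecars because no R
  YAML parser is part of the supported environment.
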