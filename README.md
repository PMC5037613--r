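# autozygmap

Autozygosity mapping, parametric linkage and GAP-kinetics analysis for
recessive gene hunts in consanguineous families — with a built-in,
fully seeded synthetic-data module so the whole pipeline is testable
without any external data.

## Who this is for

Statistical geneticists and method developers who want a small, exact,
scriptable reimplementation of the classical desk-side computations in a
consanguineous-family study of a recessive disorder:

1. **Gene-drop simulation** of SNP genotypes on looped pedigrees
   (founder haplotypes, Haldane recombination, exact conditioning on a
   fully penetrant recessive affection pattern), with recorded
   identity-by-descent truth.
2. **Run-of-homozygosity detection** (ROH > 2 Mb as surrogates of
   autozygosity) and the **exclusive-sharing interval algebra** that
   defines the critical interval: intersect affected autozygomes,
   subtract unaffected ones.
3. **Parametric LOD scores** under a fully penetrant autosomal recessive
   model: the exact two-locus pedigree likelihood is computed by
   genotype-elimination peeling (variable elimination on the pedigree's
   factor graph), which handles consanguinity loops exactly;
   LOD(θ) = log₁₀ L(θ) − log₁₀ L(0.5), maximized over a θ grid.
4. **Rare homozygous variant filtering** on VCF input: index case
   homozygous ∧ position inside the critical interval ∧ population
   frequency < 0.001 or novel, followed by a recessive segregation check
   and a strict >10-read exon coverage audit.
5. **BRET deactivation kinetics**: baseline subtraction, per-replicate
   single-exponential fits of the post-antagonist decay,
   k_GAP = mean(k_obs) − mean(k_app), and one-way ANOVA across
   conditions.

## Worked example

```r
library(autozygmap)

report <- run_mapping(mapping_config(seed = 1))
print(report)
#> Mapping report (seed 1 )
#>  exclusive shared intervals: 1
#>  critical interval: chr15:51900000-57800000 (5.9 Mb)
#>  LOD peak: 5.492 at chr15:54000000 (theta = 0.00), inside the shared interval
#>  variants surviving filter: 1 of 101
#>  segregating candidates: 1
```

Reading: on a simulated genome for the reconstructed 26-member family
(five affected girls in three sibships, double-first-cousin unions), the
five affecteds exclusively share a single 5.9 Mb autozygous interval on
chr15 that contains the planted disease locus (52.4 Mb); the parametric
LOD peak (5.49, θ = 0) falls inside it; and exactly one of 101 simulated
exome variants survives the homozygous/in-interval/MAF < 0.001 filter —
the planted causal variant, which segregates as a recessive allele
should (affecteds homozygous, parents heterozygous).

The kinetics arm:

```r
res <- run_kinetics(kinetics_config(seed = 1))
print(res$kgap[["RGS9-2+Gb5-WT"]])
#> k_GAP (RGS9-2+Gb5-WT): 0.4019 +/- 0.001785 1/s (k_obs 0.5022, k_app 0.1002, n = 6)
res$anova$p
#> [1] 1.234903e-28
```

Reading: from six simulated replicates per condition (20 ms sampling, 2%
noise), the wild-type-like RGS9-2/Gβ5 complex accelerates G-protein
deactivation by k_GAP ≈ 0.40 s⁻¹ over the basal rate k_app ≈ 0.10 s⁻¹,
recovering the simulated truth; the ANOVA across
{no-RGS, mutant-like, wild-type-like} is overwhelmingly significant.

A thin CLI wrapping these functions is installed at
`inst/cli/autozygmap` (`run-mapping`, `run-kinetics`, `simulate-bret`).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-simulates the linkage reproduction from scratch — gene-drops
near-fully informative (16-allele) markers across the critical region on
the reconstructed pedigree, conditioned on all five affecteds being
homozygous by descent, computes each seed's genome-scan peak LOD under
the fully penetrant recessive model (allele frequency 1e-4, maximized
over θ), and writes the modal peak across 200 seeds as JSON.
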