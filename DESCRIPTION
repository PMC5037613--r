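Package: autozygmap
Title: Autozygosity Mapping, Parametric Linkage and GAP Kinetics for
    Consanguineous Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping recessive disease genes in extended
    consanguineous families and for quantifying the functional impact of
    candidate variants on G-protein deactivation kinetics. Implements
    gene-dropping simulation of SNP genotypes on looped pedigrees with
    Haldane recombination, run-of-homozygosity detection and
    exclusive-sharing interval algebra (autozygosity mapping), exact
    parametric LOD scores under a fully penetrant autosomal recessive
    model via genotype-elimination peeling, interval-restricted rare
    homozygous variant filtering with segregation checks on VCF input,
    and k_GAP analysis of BRET deactivation traces (baseline correction,
    single-exponential fitting, rate subtraction, one-way ANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    methods,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    optparse
Config/testthat/edition: 3
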