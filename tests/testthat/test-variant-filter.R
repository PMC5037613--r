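test_that("allele frequency arithmetic", {
  expect_equal(signif(allele_frequency(6, 121000), 4), 4.959e-05)
  expect_equal(allele_frequency(0, 5000), 0)
  # 121/121000 = exactly 1e-3, which fails the strict < 0.001 rule
  af <- allele_frequency(121, 121000)
  expect_equal(af, 1e-3)
  expect_false(af < 0.001)
  expect_error(allele_frequency(1, 0), "total_alleles")
  expect_error(allele_frequency(7, 6), "alt_allele_count")
})

test_that("the 5-record toy table leaves exactly the two expected survivors", {
  toy <- toy_variant_table()
  rep <- filter_candidates(toy$vt, "V:1", toy$interval)
  expect_equal(rep$n_input, 5L)
  # hom-alt: records 1,2,4,5; in interval: 1,2,5; MAF rule: 1,5
  expect_equal(unname(rep$counts), c(4L, 3L, 2L))
  expect_equal(rep$survivors$variants$gene, c("G1", "G5"))
  # record 5 survives because a missing frequency means novel
  expect_true(is.na(rep$survivors$variants$af[2]))
})

test_that("empty input gives an empty report with zero counts", {
  toy <- toy_variant_table()
  empty <- variant_table(toy$vt$variants[0, ], toy$vt$geno[0, , drop = FALSE])
  rep <- filter_candidates(empty, "V:1", toy$interval)
  expect_equal(rep$n_input, 0L)
  expect_equal(unname(rep$counts), c(0L, 0L, 0L))
  expect_equal(n_variants(rep$survivors), 0L)
})

test_that("filter counts are monotone and order-independent", {
  ped <- study_pedigree()
  iv <- list(chrom = "chr15", start_bp = 47051884, end_bp = 57799765)
  for (s in 1:10) {
    vt <- simulate_exome_table(ped, iv, n_background = 60, seed = 300 + s)
    rep <- filter_candidates(vt, "V:1", iv)
    expect_true(all(diff(c(rep$n_input, unname(rep$counts))) <= 0))
    perm <- sample(n_variants(vt))
    vt_p <- variant_table(vt$variants[perm, ], vt$geno[perm, , drop = FALSE])
    rep_p <- filter_candidates(vt_p, "V:1", iv)
    expect_equal(rep_p$counts, rep$counts)
    key <- function(r) sort(paste(r$survivors$variants$chrom,
                                  r$survivors$variants$pos_bp))
    expect_equal(key(rep_p), key(rep))
  }
})

test_that("segregation check enforces the recessive pattern", {
  ped <- study_pedigree()
  iv <- list(chrom = "chr15", start_bp = 47051884, end_bp = 57799765)
  vt <- simulate_exome_table(ped, iv, n_background = 0, seed = 4)
  expect_equal(n_variants(vt), 1L)
  res <- check_segregation(vt, ped)
  expect_true(res$segregates)
  # an unaffected sibling homozygous for the variant breaks it
  vt_bad <- vt
  vt_bad$geno[1, "V:4"] <- 2L
  res_bad <- check_segregation(vt_bad, ped)
  expect_false(res_bad$segregates)
  expect_equal(nrow(res_bad$violations), 1L)
  expect_equal(res_bad$violations$individual, "V:4")
  # an affected heterozygote breaks it
  vt_het <- vt
  vt_het$geno[1, "IV:1"] <- 1L
  expect_false(check_segregation(vt_het, ped)$segregates)
  # missing genotypes are neutral but listed
  vt_na <- vt
  vt_na$geno[1, "IV:6"] <- NA
  res_na <- check_segregation(vt_na, ped)
  expect_true(res_na$segregates)
  expect_equal(res_na$untyped, "IV:6")
})

test_that("causal variant survives filtering and segregates, by construction", {
  ped <- study_pedigree()
  iv <- list(chrom = "chr15", start_bp = 47051884, end_bp = 57799765)
  for (s in 1:20) {
    vt <- simulate_exome_table(ped, iv, n_background = 100, seed = s)
    rep <- filter_candidates(vt, "V:1", iv)
    surv <- rep$survivors$variants
    expect_true("CAND1" %in% surv$gene)
    expect_equal(nrow(surv), 1L)   # unique survivor in the default world
    expect_true(check_segregation(rep$survivors, ped)$segregates)
    expect_equal(surv$af, allele_frequency(6, 121000))
  }
})

test_that("coverage audit uses the strict >10 reads rule", {
  full <- data.frame(gene = "G1", exon = 1:5, mean_depth = 81.8)
  expect_equal(nrow(coverage_gaps(full)), 0L)
  edge <- data.frame(gene = "G1", exon = 1:2, mean_depth = c(10, 10.5))
  res <- coverage_gaps(edge)
  expect_equal(res$exon, 1L)
  mixed <- data.frame(gene = rep(c("G1", "G2"), each = 4), exon = rep(1:4, 2),
                      mean_depth = c(30, 9, 50, 2, 7, 40, 60, 15))
  expect_equal(nrow(coverage_gaps(mixed)), 3L)
})

test_that("VCF output is deterministic and round-trips through readVcf", {
  skip_if_not_installed("VariantAnnotation")
  ped <- study_pedigree()
  iv <- list(chrom = "chr15", start_bp = 47051884, end_bp = 57799765)
  vt <- simulate_exome_table(ped, iv, n_background = 25, seed = 6)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.vcf"); f2 <- file.path(d, "b.vcf")
  write_variant_vcf(vt, f1, seed = 6)
  vt_again <- simulate_exome_table(ped, iv, n_background = 25, seed = 6)
  write_variant_vcf(vt_again, f2, seed = 6)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_variant_vcf(f1)
  expect_equal(back$variants$chrom, vt$variants$chrom)
  expect_equal(back$variants$pos_bp, vt$variants$pos_bp)
  expect_equal(back$variants$af, vt$variants$af, tolerance = 1e-6)
  expect_equal(unname(back$geno), unname(vt$geno))
  expect_equal(colnames(back$geno), colnames(vt$geno))
})

test_that("frequency lookup TSV overrides the af column", {
  toy <- toy_variant_table()
  d <- withr::local_tempdir()
  f <- file.path(d, "freq.tsv")
  utils::write.table(
    data.frame(chrom = "chr15", pos_bp = c(50e6, 53e6), ref = "C", alt = "T",
               af = c(0.2, 5e-6)),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  vt2 <- lookup_frequencies(toy$vt, f)
  expect_equal(vt2$variants$af, c(0.2, NA, NA, NA, 5e-6))
})
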