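mp100k <- function(n, start = 1e6) {
  marker_map(paste0("m", seq_len(n)), "chr15",
             seq(start, by = 1e5, length.out = n))
}

test_that("all-heterozygous individual yields no ROH", {
  mp <- mp100k(60)
  calls <- matrix("AB", 60, 1, dimnames = list(mp$id, "x"))
  gm <- gm_from_calls(calls, mp)
  expect_equal(nrow(detect_roh(gm, "x", min_markers = 1)), 0L)
})

test_that("boundary arithmetic of the >2 Mb rule", {
  mp <- mp100k(200)  # 1.0 Mb .. 20.9 Mb at 100 kb
  calls <- matrix("AB", 200, 1, dimnames = list(mp$id, "x"))
  # homozygous exactly from 10.0 to 15.0 Mb (markers 91..141), flanked by hets
  calls[91:141, 1] <- "AA"
  gm <- gm_from_calls(calls, mp)
  res <- detect_roh(gm, "x", min_markers = 10, max_het = 0)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start_bp, 10e6)
  expect_equal(res$end_bp, 15e6)
  expect_equal(res$n_markers, 51L)
  expect_identical(c(res$first_marker, res$last_marker), c("m91", "m141"))
  # an analogous 1.5 Mb run fails the strict >2 Mb rule...
  calls2 <- matrix("AB", 200, 1, dimnames = list(mp$id, "x"))
  calls2[91:106, 1] <- "AA"   # 10.0 -> 11.5 Mb
  expect_equal(nrow(detect_roh(gm_from_calls(calls2, mp), "x",
                               min_markers = 10)), 0L)
  # ...and exactly 2 Mb + 1 bp would be needed: a 2.0 Mb run is excluded
  calls3 <- matrix("AB", 200, 1, dimnames = list(mp$id, "x"))
  calls3[91:111, 1] <- "AA"   # 10.0 -> 12.0 Mb, length 2,000,001 > 2 Mb
  expect_equal(nrow(detect_roh(gm_from_calls(calls3, mp), "x",
                               min_markers = 10)), 1L)
})

test_that("fully homozygous chromosome gives one first-to-last interval", {
  mp <- mp100k(80)
  calls <- matrix(sample(c("AA", "BB"), 80, replace = TRUE), 80, 1,
                  dimnames = list(mp$id, "x"))
  res <- detect_roh(gm_from_calls(calls, mp), "x", min_markers = 10)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start_bp, mp$pos_bp[1])
  expect_equal(res$end_bp, mp$pos_bp[80])
})

test_that("het tolerance and missing-call handling", {
  mp <- mp100k(100)
  calls <- matrix("AA", 100, 1, dimnames = list(mp$id, "x"))
  calls[50, 1] <- "AB"
  calls[70, 1] <- "--"
  # max_het = 0: split at the het, missing call does not split
  r0 <- detect_roh(gm_from_calls(calls, mp), "x", min_markers = 5)
  expect_equal(nrow(r0), 2L)
  expect_equal(r0$end_bp[1], mp$pos_bp[49])
  expect_equal(r0$start_bp[2], mp$pos_bp[51])
  # max_het = 1: merged into a single run spanning everything
  r1 <- detect_roh(gm_from_calls(calls, mp), "x", min_markers = 5,
                   max_het = 1)
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$start_bp, r1$end_bp), range(mp$pos_bp))
})

test_that("detect_roh is stable under subsetting that keeps boundaries", {
  mp <- mp100k(100)
  calls <- matrix("AB", 100, 1, dimnames = list(mp$id, "x"))
  calls[20:80, 1] <- "AA"
  full <- detect_roh(gm_from_calls(calls, mp), "x", min_markers = 5)
  keep <- sort(unique(c(seq(1, 100, by = 2), 20, 80)))
  mp_sub <- marker_map(mp$id[keep], "chr15", mp$pos_bp[keep])
  sub <- detect_roh(gm_from_calls(calls[keep, , drop = FALSE], mp_sub),
                    "x", min_markers = 5)
  expect_equal(sub[, c("start_bp", "end_bp")],
               full[, c("start_bp", "end_bp")])
})

test_that("exclusive sharing interval algebra", {
  a1 <- az_df("a1", list("chr2", 40e6, 60e6))
  a2 <- az_df("a2", list("chr2", 47e6, 58e6))
  u1 <- az_df("u1", list("chr2", 50e6, 52e6))
  res <- exclusive_shared_intervals(list(a1, a2), list(u1),
                                    min_length_bp = 1e6)
  expect_equal(res$start_bp, c(47e6, 52000001))
  expect_equal(res$end_bp, c(49999999, 58e6))
  # single affected, no unaffected: identity up to the length filter
  solo <- exclusive_shared_intervals(list(a1), list(), min_length_bp = 1e6)
  expect_equal(solo$start_bp, 40e6)
  expect_equal(solo$end_bp, 60e6)
})

test_that("five affecteds sharing exactly the published-style interval", {
  iv <- c(47051884, 57799765)
  affs <- list(
    az_df("a1", list("chr15", iv[1], iv[2]), list("chr3", 10e6, 20e6)),
    az_df("a2", list("chr15", 40e6, 60e6), list("chr3", 12e6, 22e6)),
    az_df("a3", list("chr15", 45e6, 58e6)),
    az_df("a4", list("chr15", 47e6, 59e6), list("chr7", 5e6, 9e6)),
    az_df("a5", list("chr15", 46e6, 70e6), list("chr3", 11e6, 18e6)))
  un <- list(az_df("u1", list("chr3", 1e6, 30e6)))
  res <- exclusive_shared_intervals(affs, un, min_length_bp = 2e6)
  expect_equal(nrow(res), 1L)
  expect_equal(res$chrom, "chr15")
  expect_equal(res$start_bp, 47051884)
  expect_equal(res$end_bp, 57799765)
})

test_that("shared intervals are contained in every affected autozygome and
           disjoint from every unaffected one", {
  ped <- study_pedigree()
  mp <- marker_map(paste0("m", 1:301), "chr15", seq(40e6, 70e6, by = 1e5))
  for (s in 1:5) {
    sim <- gene_drop(ped, mp, 0.5,
                     disease_locus = list(chrom = "chr15", pos_bp = 52.4e6),
                     seed = 200 + s)
    az <- autozygomes(sim$genotypes, min_markers = 10)
    res <- exclusive_shared_intervals(az[affected_ids(ped)],
                                      az[unaffected_ids(ped)])
    if (!nrow(res)) next
    for (r in seq_len(nrow(res))) {
      for (id in affected_ids(ped)) {
        cover <- az[[id]]$chrom == res$chrom[r] &
          az[[id]]$start_bp <= res$start_bp[r] &
          az[[id]]$end_bp >= res$end_bp[r]
        expect_true(any(cover))
      }
      for (id in unaffected_ids(ped)) {
        overlap <- az[[id]]$chrom == res$chrom[r] &
          az[[id]]$start_bp <= res$end_bp[r] &
          az[[id]]$end_bp >= res$start_bp[r]
        expect_false(any(overlap))
      }
    }
    # intervals within one autozygome never overlap
    for (id in names(az)) {
      a <- az[[id]]
      if (nrow(a) < 2) next
      by_chr <- split(a, a$chrom)
      for (b in by_chr) {
        if (nrow(b) < 2) next
        expect_true(all(b$start_bp[-1] > b$end_bp[-nrow(b)]))
      }
    }
  }
})

test_that("interval writers and the interval parser", {
  iv <- parse_interval("chr15:47,051,884-57,799,765")
  expect_equal(iv$start_bp, 47051884)
  expect_equal(iv$end_bp, 57799765)
  d <- withr::local_tempdir()
  tab <- az_df("x", list("chr15", 47051884, 57799765))
  write_intervals_bed(tab, file.path(d, "x.bed"))
  bed <- readLines(file.path(d, "x.bed"))
  expect_match(bed[1], "0-based")
  expect_equal(strsplit(bed[2], "\t")[[1]][2], "47051883")
})
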