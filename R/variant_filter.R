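#' Variant tables
#'
#' A `variant_table` couples a data frame of biallelic variant sites
#' (`chrom`, `pos_bp`, `ref`, `alt`, `af` — population allele frequency,
#' `NA` meaning absent from the reference cohorts, i.e. novel — plus free
#' annotation columns such as `gene` and `effect`) with an integer
#' genotype matrix (variants x individuals) counting alternate alleles:
#' 0 = hom-ref, 1 = het, 2 = hom-alt, `NA` = missing.
#'
#' @param variants data frame of sites.
#' @param geno integer matrix of alt-allele counts, one column per
#'   individual (named).
#' @return A `variant_table`.
#' @export
variant_table <- function(variants, geno) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos_bp", "ref", "alt", "af") %in%
                  colnames(variants)),
            is.matrix(geno), nrow(geno) == nrow(variants),
            !is.null(colnames(geno)))
  ok_af <- is.na(variants$af) | (variants$af >= 0 & variants$af <= 1)
  if (!all(ok_af)) stop("population_af outside [0,1]")
  structure(list(variants = variants, geno = geno), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants x %d individuals\n",
              nrow(x$variants), ncol(x$geno)))
  invisible(x)
}

#' @rdname variant_table
#' @param vt a `variant_table`.
#' @export
n_variants <- function(vt) nrow(vt$variants)

subset_variants <- function(vt, idx) {
  variant_table(vt$variants[idx, , drop = FALSE],
                vt$geno[idx, , drop = FALSE])
}

#' Population allele frequency from allele counts
#'
#' @param alt_allele_count observed alternate allele count.
#' @param total_alleles total number of alleles genotyped (> 0).
#' @return `alt_allele_count / total_alleles`.
#' @examples
#' signif(allele_frequency(6, 121000), 4)  # 4.959e-05, the ExAC-style MAF
#' @export
allele_frequency <- function(alt_allele_count, total_alleles) {
  stopifnot(length(alt_allele_count) == length(total_alleles) ||
              length(total_alleles) == 1)
  if (any(total_alleles <= 0)) stop("total_alleles must be > 0")
  if (any(alt_allele_count < 0) || any(alt_allele_count > total_alleles)) {
    stop("alt_allele_count must be in [0, total_alleles]")
  }
  alt_allele_count / total_alleles
}

#' Interval-restricted rare homozygous variant filter
#'
#' The WES prioritization chain for a recessive disorder mapped by
#' autozygosity: keep variants where the index case is homozygous for the
#' alternate allele, the position lies within the critical autozygous
#' interval (endpoints inclusive), and the population allele frequency is
#' below `maf_threshold` (strict) or absent (novel).  Rules are applied
#' in that order and per-rule survivor counts are recorded.
#'
#' @param vt a [variant_table()].
#' @param index_id individual used for the homozygosity rule.
#' @param interval critical interval: `"chr:start-end"` string or a list
#'   with `chrom`, `start_bp`, `end_bp`.
#' @param maf_threshold strict upper bound on population frequency.
#' @return A `filter_report`: list with `n_input`, `counts` (after each
#'   rule), `n_malformed`, and `survivors` (a `variant_table`).
#' @examples
#' # see the package tests for the canonical 5-record example
#' @export
filter_candidates <- function(vt, index_id, interval, maf_threshold = 0.001) {
  stopifnot(inherits(vt, "variant_table"))
  if (!index_id %in% colnames(vt$geno)) {
    stop("index individual ", index_id, " not in genotype columns")
  }
  iv <- parse_interval(interval)
  v <- vt$variants
  malformed <- is.na(v$chrom) | is.na(v$pos_bp) | v$pos_bp < 1 |
    is.na(v$ref) | is.na(v$alt) | v$ref == "" | v$alt == ""
  if (any(malformed)) {
    warning(sum(malformed), " malformed variant record(s) skipped")
  }
  ok <- !malformed
  g <- vt$geno[, index_id]
  r1 <- ok & !is.na(g) & g == 2L
  r2 <- r1 & v$chrom == iv$chrom &
    v$pos_bp >= iv$start_bp & v$pos_bp <= iv$end_bp
  r3 <- r2 & (is.na(v$af) | v$af < maf_threshold)
  structure(list(
    n_input = nrow(v),
    n_malformed = sum(malformed),
    counts = c(zygosity = sum(r1), interval = sum(r2), frequency = sum(r3)),
    interval = iv,
    index_id = index_id,
    maf_threshold = maf_threshold,
    survivors = subset_variants(vt, which(r3))),
    class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "filter_report: %d variants in; hom-alt in %s: %d; in %s:%d-%d: %d; MAF<%g or novel: %d\n",
    x$n_input, x$index_id, x$counts["zygosity"], x$interval$chrom,
    x$interval$start_bp, x$interval$end_bp, x$counts["interval"],
    x$maf_threshold, x$counts["frequency"]))
  if (x$n_malformed) cat(" malformed records skipped:", x$n_malformed, "\n")
  invisible(x)
}

#' Write a filter report TSV
#' @param report a `filter_report`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  tab <- data.frame(
    rule = c("input", "malformed", names(report$counts)),
    count = c(report$n_input, report$n_malformed, unname(report$counts)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Co-segregation check for a recessive variant
#'
#' Tests the expected autosomal recessive segregation pattern on one
#' variant: every affected member homozygous for the alternate allele,
#' every parent of an affected heterozygous (obligate carrier), and no
#' unaffected member homozygous for the alternate allele.  Missing
#' genotypes are neutral and reported as untyped.
#'
#' @param vt a [variant_table()] (single row used).
#' @param row row index of the variant to check.
#' @param ped a [pedigree()].
#' @return list with `segregates` (logical), `violations` (data frame of
#'   individual / observed / expected) and `untyped` (ids).
#' @export
check_segregation <- function(vt, ped, row = 1L) {
  stopifnot(inherits(vt, "variant_table"))
  validate_pedigree(ped)
  g <- vt$geno[row, ]
  lab <- c(`0` = "hom-ref", `1` = "het", `2` = "hom-alt")
  viol <- list()
  untyped <- character(0)
  expect <- function(ids, pred, expected) {
    for (id in ids) {
      if (!id %in% names(g) || is.na(g[id])) {
        untyped <<- c(untyped, id)
      } else if (!pred(g[id])) {
        viol[[length(viol) + 1L]] <<- data.frame(
          individual = id, observed = lab[as.character(g[id])],
          expected = expected, stringsAsFactors = FALSE)
      }
    }
  }
  aff <- affected_ids(ped)
  parents <- unique(stats::na.omit(c(ped$father[match(aff, ped$id)],
                                     ped$mother[match(aff, ped$id)])))
  expect(aff, function(x) x == 2L, "hom-alt")
  expect(setdiff(parents, aff), function(x) x == 1L, "het")
  expect(setdiff(unaffected_ids(ped), parents),
         function(x) x != 2L, "het or hom-ref")
  viol <- if (length(viol)) do.call(rbind, viol) else
    data.frame(individual = character(0), observed = character(0),
               expected = character(0), stringsAsFactors = FALSE)
  list(segregates = nrow(viol) == 0L, violations = viol,
       untyped = unique(untyped))
}

#' Exon coverage audit
#'
#' Flags exons whose mean depth fails the strict "> `min_depth` reads"
#' rule; an empty result certifies full coverage of the interval's genes.
#'
#' @param per_exon_depth data frame with columns `gene`, `exon`,
#'   `mean_depth`.
#' @param min_depth pass rule is depth strictly greater than this.
#' @return the failing rows of `per_exon_depth`.
#' @export
coverage_gaps <- function(per_exon_depth, min_depth = 10) {
  stopifnot(all(c("gene", "exon", "mean_depth") %in%
                  colnames(per_exon_depth)),
            all(per_exon_depth$mean_depth >= 0))
  out <- per_exon_depth[per_exon_depth$mean_depth <= min_depth, ,
                        drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach population frequencies from a lookup TSV
#'
#' Matches on (chrom, pos, ref, alt); unmatched variants keep `af = NA`
#' (novel).  The lookup file needs columns `chrom`, `pos_bp`, `ref`,
#' `alt`, `af`.
#'
#' @param vt a [variant_table()].
#' @param path frequency TSV path.
#' @return the `variant_table` with `af` filled from the lookup.
#' @export
lookup_frequencies <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  # read as character: nucleotide columns like "T" must not become logical
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  key <- function(ch, pos, ref, alt) {
    paste(ch, format(as.numeric(pos), scientific = FALSE, trim = TRUE),
          ref, alt, sep = ":")
  }
  m <- match(key(vt$variants$chrom, vt$variants$pos_bp,
                 vt$variants$ref, vt$variants$alt),
             key(tab$chrom, tab$pos_bp, tab$ref, tab$alt))
  vt$variants$af <- as.numeric(tab$af)[m]
  vt
}
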