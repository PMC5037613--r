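#' Simulate an exome-like variant table for a mapped family
#'
#' Emits background variants with pedigree-consistent genotypes (each
#' variant is gene-dropped through the pedigree from founder alleles at
#' its assigned population frequency) plus one causal variant inside the
#' critical interval that follows the conditioned recessive pattern:
#' homozygous alternate in every affected member, heterozygous in
#' obligate carriers, hom-ref elsewhere.  Background frequencies are
#' drawn uniformly from `background_freq_range`; a fraction
#' `rare_fraction` is instead drawn from `rare_freq_range` and placed
#' outside the critical interval, so that rare homozygous background
#' variants never mimic the causal signal inside the interval.
#'
#' @param ped a [pedigree()].
#' @param interval critical interval (string or list, see
#'   [parse_interval()]).
#' @param n_background number of background variants (>= 0).
#' @param background_freq_range frequency range for common background
#'   variants, default (0.001, 0.5).
#' @param rare_fraction fraction of background variants drawn rare.
#' @param rare_freq_range frequency range for the rare background class.
#' @param causal_freq population frequency annotated on the causal
#'   variant (default the ExAC-style 6/121000).
#' @param causal_pos position of the causal variant (default: interval
#'   midpoint); must lie inside the interval.
#' @param truth optional `sim_truth` from [gene_drop()]; when given, the
#'   causal genotypes are taken from its disease-locus genotypes (and
#'   `causal_pos` defaults to the true locus), guaranteeing consistency
#'   with the simulated genome.
#' @param seed integer seed.
#' @return A [variant_table()] with annotation columns `gene` and
#'   `effect`; the causal record carries `gene = "CAND1"`,
#'   `effect = "missense"`.
#' @export
simulate_exome_table <- function(ped, interval, n_background = 100,
                                 background_freq_range = c(0.001, 0.5),
                                 rare_fraction = 0.1,
                                 rare_freq_range = c(1e-6, 1e-3),
                                 causal_freq = allele_frequency(6, 121000),
                                 causal_pos = NULL, truth = NULL,
                                 seed = 1L) {
  validate_pedigree(ped)
  stopifnot(n_background >= 0, causal_freq > 0, causal_freq < 1,
            background_freq_range[1] > 0, background_freq_range[2] < 1)
  set.seed(as.integer(seed))
  iv <- parse_interval(interval)
  if (is.null(causal_pos)) {
    causal_pos <- if (!is.null(truth) && !is.null(truth$disease_locus) &&
                        truth$disease_locus$chrom == iv$chrom &&
                        truth$disease_locus$pos_bp >= iv$start_bp &&
                        truth$disease_locus$pos_bp <= iv$end_bp)
      truth$disease_locus$pos_bp else round((iv$start_bp + iv$end_bp) / 2)
  }
  if (causal_pos < iv$start_bp || causal_pos > iv$end_bp) {
    stop("causal position outside the critical interval")
  }
  st <- ped_structure(ped)
  n <- nrow(ped)
  nf <- length(st$founder_idx)

  # causal genotypes: from simulation truth, or a fresh conditioned draw
  if (!is.null(truth) && !is.null(truth$disease_genotypes)) {
    causal_g <- unname(truth$disease_genotypes[ped$id])
  } else {
    cond <- sample_conditioned_locus_descent(st)
    causal_g <- as.integer((cond$origins$pat == cond$h_star) +
                             (cond$origins$mat == cond$h_star))
  }

  bases <- c("A", "C", "G", "T")
  rows <- list()
  geno <- matrix(NA_integer_, 0, n)
  if (n_background > 0) {
    rare <- stats::runif(n_background) < rare_fraction
    af <- ifelse(rare,
                 stats::runif(n_background, rare_freq_range[1],
                              rare_freq_range[2]),
                 stats::runif(n_background, background_freq_range[1],
                              background_freq_range[2]))
    chrom <- sample(paste0("chr", 1:14), n_background, replace = TRUE)
    pos <- sample.int(1e8, n_background)
    # a third of the common variants go on the interval's chromosome,
    # some inside the interval; rare ones stay off it
    on_chr <- !rare & stats::runif(n_background) < 1 / 3
    chrom[on_chr] <- iv$chrom
    # gene-drop genotypes: founder alleles at af, random transmissions
    FA <- matrix(stats::runif(2 * nf * n_background) <
                   rep(af, each = 2 * nf), 2 * nf, n_background)
    I <- matrix(sample(0:1, st$n_mei * n_background, replace = TRUE),
                nrow = max(st$n_mei, 1L))
    org <- propagate_origins_markers(st, I)
    gmat <- matrix(0L, n, n_background)
    for (b in seq_len(n_background)) {
      gmat[, b] <- FA[org$pat[, b], b] + FA[org$mat[, b], b]
    }
    ra <- t(vapply(seq_len(n_background), function(b)
      sample(bases, 2), character(2)))
    rows[[1]] <- data.frame(
      chrom = chrom, pos_bp = pos, ref = ra[, 1], alt = ra[, 2], af = af,
      gene = sprintf("GENE%04d", seq_len(n_background)),
      effect = sample(c("missense", "synonymous", "intronic"),
                      n_background, replace = TRUE),
      stringsAsFactors = FALSE)
    geno <- t(gmat)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    chrom = iv$chrom, pos_bp = causal_pos, ref = "C", alt = "T",
    af = causal_freq, gene = "CAND1", effect = "missense",
    stringsAsFactors = FALSE)
  geno <- rbind(geno, causal_g)
  colnames(geno) <- ped$id
  variants <- do.call(rbind, rows)
  ord <- order(variants$chrom, variants$pos_bp)
  rownames(variants) <- NULL
  variant_table(variants[ord, , drop = FALSE], geno[ord, , drop = FALSE])
}

#' Write a variant table as VCF v4.2
#'
#' Biallelic records with per-sample GT fields and INFO keys `AF_POP`
#' (population allele frequency; omitted when novel), `GENE` and
#' `EFFECT`.  The header date is fixed by `file_date` so identical
#' inputs give byte-identical output.
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @param file_date string written as `##fileDate` (fixed for
#'   reproducibility).
#' @param seed optional integer recorded in the header for provenance.
#' @export
write_variant_vcf <- function(vt, path, file_date = "20240101",
                              seed = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  v <- vt$variants
  samples <- colnames(vt$geno)
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##fileDate=", file_date),
    "##source=autozygmap",
    if (!is.null(seed)) paste0("##autozygmapSeed=", seed),
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    "##INFO=<ID=AF_POP,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Predicted effect\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_len(nrow(v)), function(i) {
    info <- c(
      if (!is.na(v$af[i])) sprintf("AF_POP=%.6g", v$af[i]),
      if (!is.null(v$gene)) paste0("GENE=", v$gene[i]),
      if (!is.null(v$effect)) paste0("EFFECT=", v$effect[i]))
    g <- vt$geno[i, ]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c(v$chrom[i], v$pos_bp[i],
            sprintf("var%05d", i), v$ref[i], v$alt[i], ".", "PASS",
            paste(info, collapse = ";"), "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Parsed with `VariantAnnotation::readVcf`; multiallelic sites are
#' expanded into biallelic records before conversion.  `AF_POP`, `GENE`
#' and `EFFECT` INFO keys are carried into the annotation columns when
#' present.
#'
#' @param path VCF path.
#' @return A [variant_table()].
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_variant_vcf requires the VariantAnnotation package")
  }
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  geti <- function(key, default) {
    if (key %in% colnames(info)) {
      x <- info[[key]]
      if (methods::is(x, "List")) x <- vapply(x, function(e)
        if (length(e)) as.character(e[1]) else NA_character_, character(1))
      x
    } else rep(default, length(rr))
  }
  af <- geti("AF_POP", NA_real_)
  af <- suppressWarnings(as.numeric(af))
  variants <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos_bp = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = as.character(rr$ALT),
    af = af,
    gene = as.character(geti("GENE", NA_character_)),
    effect = as.character(geti("EFFECT", NA_character_)),
    stringsAsFactors = FALSE)
  gtm <- VariantAnnotation::geno(vcf)$GT
  count_alt <- function(x) {
    ifelse(x %in% c("./.", ".", ".|."), NA_integer_,
           vapply(strsplit(x, "[/|]"), function(a)
             sum(a == "1"), integer(1)))
  }
  geno <- apply(gtm, 2, count_alt)
  if (is.null(dim(geno))) geno <- matrix(geno, nrow = 1,
                                         dimnames = list(NULL, colnames(gtm)))
  variant_table(variants, geno)
}
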