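#' Genotype matrices
#'
#' A `genotype_matrix` holds biallelic or multiallelic SNP calls for a
#' set of individuals at mapped markers.  Internally two integer allele
#' matrices (`a1 <= a2`, markers x individuals, `NA` = missing) are kept
#' together with the marker table, per-marker allele labels and (when
#' known) per-marker population allele frequencies.
#'
#' `genotype_calls()` renders calls as `"A/B"`-style strings;
#' `marker_genotypes()` extracts one marker as a named vector suitable
#' for [pedigree_likelihood()]; `set_missing()` blanks calls.
#'
#' @param gm a `genotype_matrix`.
#' @param marker a marker id.
#' @param sep separator between the two alleles (default `"/"`).
#' @name genotype_matrix
NULL

#' @rdname genotype_matrix
#' @export
genotype_calls <- function(gm, sep = "/") {
  stopifnot(inherits(gm, "genotype_matrix"))
  lab <- function(mat) {
    out <- matrix(NA_character_, nrow(mat), ncol(mat), dimnames = dimnames(mat))
    for (j in seq_len(nrow(mat))) {
      out[j, ] <- gm$alleles[[j]][mat[j, ]]
    }
    out
  }
  l1 <- lab(gm$a1); l2 <- lab(gm$a2)
  calls <- matrix(paste(l1, l2, sep = sep), nrow(gm$a1),
                  dimnames = dimnames(gm$a1))
  calls[is.na(gm$a1) | is.na(gm$a2)] <- NA_character_
  calls
}

#' @rdname genotype_matrix
#' @export
marker_genotypes <- function(gm, marker, sep = "/") {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- match(marker, gm$markers$id)
  if (is.na(j)) stop("unknown marker: ", marker)
  lab <- gm$alleles[[j]]
  g <- paste(lab[gm$a1[j, ]], lab[gm$a2[j, ]], sep = sep)
  g[is.na(gm$a1[j, ]) | is.na(gm$a2[j, ])] <- NA_character_
  stats::setNames(g, gm$individuals)
}

#' @rdname genotype_matrix
#' @param individuals,markers ids whose calls become missing.
#' @export
set_missing <- function(gm, markers, individuals) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$a1[markers, individuals] <- NA_integer_
  gm$a2[markers, individuals] <- NA_integer_
  gm
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d individuals (%s)\n",
              nrow(x$a1), ncol(x$a1),
              paste(unique(x$markers$chrom), collapse = ", ")))
  invisible(x)
}

#' Estimate per-marker allele frequencies from calls
#'
#' Simple allele counting over all typed individuals; used when
#' frequencies are not already attached (e.g. after [read_genotypes()]).
#' A small floor keeps unseen alleles at a nonzero frequency.
#'
#' @param gm a `genotype_matrix`.
#' @param floor minimum frequency assigned to an unobserved allele.
#' @return the `genotype_matrix` with its `freqs` field filled.
#' @export
estimate_allele_freqs <- function(gm, floor = 1e-3) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gm$freqs <- lapply(seq_along(gm$alleles), function(j) {
    k <- length(gm$alleles[[j]])
    cnt <- tabulate(c(gm$a1[j, ], gm$a2[j, ]), nbins = k) + floor
    cnt / sum(cnt)
  })
  gm
}

#' Read and write genotype TSV files
#'
#' Marker-by-individual table: first column `marker`, then one column per
#' individual with calls written as allele pairs (`"AB"`), `"--"` for
#' missing.  The marker map is written separately via
#' [write_marker_map()].
#'
#' @param gm a `genotype_matrix`.
#' @param path file path.
#' @param map a `marker_map` giving marker order and positions.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- genotype_calls(gm, sep = "")
  calls[is.na(calls)] <- "--"
  tab <- data.frame(marker = gm$markers$id, calls, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c("marker", gm$individuals)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, map) {
  stopifnot(inherits(map, "marker_map"))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, colClasses = "character")
  stopifnot(identical(tab$marker, map$id))
  inds <- colnames(tab)[-1]
  M <- nrow(tab)
  alleles <- lapply(seq_len(M), function(j) {
    calls <- unlist(tab[j, -1], use.names = FALSE)
    sort(unique(unlist(strsplit(calls[calls != "--"], ""))))
  })
  # guarantee at least two allele labels per marker
  alleles <- lapply(alleles, function(a) {
    if (length(a) < 2) sort(unique(c(a, c("A", "B"))))[1:2] else a
  })
  a1 <- matrix(NA_integer_, M, length(inds), dimnames = list(map$id, inds))
  a2 <- a1
  for (j in seq_len(M)) {
    calls <- unlist(tab[j, -1], use.names = FALSE)
    ok <- calls != "--"
    c1 <- match(substr(calls, 1, 1), alleles[[j]])
    c2 <- match(substr(calls, 2, 2), alleles[[j]])
    a1[j, ok] <- pmin(c1, c2)[ok]
    a2[j, ok] <- pmax(c1, c2)[ok]
  }
  gm <- structure(list(markers = as.data.frame(map), alleles = alleles,
                       freqs = NULL, a1 = a1, a2 = a2, individuals = inds),
                  cm_per_mb = attr(map, "cm_per_mb"),
                  class = "genotype_matrix")
  estimate_allele_freqs(gm)
}
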