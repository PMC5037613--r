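#' Run-of-homozygosity detection
#'
#' Scans one individual's genotype calls for maximal runs of homozygous
#' markers, used as surrogates of autozygosity.  A run may contain up to
#' `max_het` heterozygous calls; missing calls are skipped (they neither
#' extend nor break a run).  Runs are reported as intervals spanning
#' their outermost homozygous markers and kept only when longer than
#' `min_length_bp` (strict) and supported by at least `min_markers`
#' homozygous markers.
#'
#' @param gm a `genotype_matrix`.
#' @param individual id of the individual to scan.
#' @param min_length_bp minimum interval length in bp, strict; default
#'   2 Mb, the conventional surrogate threshold for autozygosity.
#' @param min_markers minimum number of homozygous markers in a run.
#' @param max_het heterozygous calls tolerated inside a run (default 0;
#'   raise to absorb genotyping error).
#' @return A data frame of class `autozygome` with columns `individual`,
#'   `chrom`, `start_bp`, `end_bp`, `length_bp`, `n_markers`,
#'   `first_marker`, `last_marker`, sorted by (chrom, start).
#' @examples
#' ped <- study_pedigree()
#' mp <- marker_map(paste0("m", 1:100), "chr15", seq(40e6, 59.8e6, by = 2e5))
#' sim <- gene_drop(ped, mp, 0.5,
#'                  disease_locus = list(chrom = "chr15", pos_bp = 52.4e6),
#'                  seed = 2)
#' detect_roh(sim$genotypes, "V:1", min_markers = 10)
#' @export
detect_roh <- function(gm, individual, min_length_bp = 2e6,
                       min_markers = 50, max_het = 0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  i <- match(individual, gm$individuals)
  if (is.na(i)) stop("unknown individual: ", individual)
  out <- list()
  for (ch in unique(gm$markers$chrom)) {
    sel <- which(gm$markers$chrom == ch)
    pos <- gm$markers$pos_bp[sel]
    if (is.unsorted(pos, strictly = TRUE)) {
      stop("markers not sorted by position on ", ch)
    }
    a1 <- gm$a1[sel, i]; a2 <- gm$a2[sel, i]
    typed <- which(!is.na(a1))
    if (!length(typed)) next
    hom <- a1[typed] == a2[typed]
    runs <- hom_runs(hom, max_het)
    for (r in runs) {
      mk <- typed[r]                       # indices into sel
      hom_mk <- mk[hom[r]]                 # homozygous markers only
      start <- pos[hom_mk[1]]
      end <- pos[hom_mk[length(hom_mk)]]
      if ((end - start + 1) > min_length_bp && length(hom_mk) >= min_markers) {
        out[[length(out) + 1L]] <- data.frame(
          individual = individual, chrom = ch,
          start_bp = start, end_bp = end,
          length_bp = end - start + 1,
          n_markers = length(hom_mk),
          first_marker = gm$markers$id[sel[hom_mk[1]]],
          last_marker = gm$markers$id[sel[hom_mk[length(hom_mk)]]],
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_autozygome()
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("autozygome", "data.frame")
  res
}

empty_autozygome <- function() {
  data.frame(individual = character(0), chrom = character(0),
             start_bp = numeric(0), end_bp = numeric(0),
             length_bp = numeric(0), n_markers = integer(0),
             first_marker = character(0), last_marker = character(0),
             stringsAsFactors = FALSE)
}

# Maximal runs over a logical homozygosity vector, tolerating up to
# max_het FALSE entries per run.  Returns a list of index ranges
# (integer vectors).  Runs both starting and ending on a TRUE.
hom_runs <- function(hom, max_het = 0) {
  n <- length(hom)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!hom[i]) { i <- i + 1L; next }
    j <- i
    hets <- 0L
    last_hom <- i
    while (j < n) {
      nxt <- j + 1L
      if (hom[nxt]) {
        j <- nxt; last_hom <- nxt
      } else if (hets < max_het) {
        hets <- hets + 1L; j <- nxt
      } else break
    }
    runs[[length(runs) + 1L]] <- i:last_hom
    i <- last_hom + 1L
  }
  runs
}

#' Autozygome of every pedigree member
#'
#' Convenience wrapper running [detect_roh()] per individual.
#' @inheritParams detect_roh
#' @param individuals ids to scan (default: all in the matrix).
#' @return Named list of `autozygome` data frames.
#' @export
autozygomes <- function(gm, individuals = gm$individuals,
                        min_length_bp = 2e6, min_markers = 50, max_het = 0) {
  stats::setNames(lapply(individuals, function(id) {
    detect_roh(gm, id, min_length_bp = min_length_bp,
               min_markers = min_markers, max_het = max_het)
  }), individuals)
}

# per-chromosome IRanges view of an autozygome (1-based inclusive);
# plain IRanges set operations avoid per-call Seqinfo merging overhead
az_to_ranges <- function(az, chroms) {
  stats::setNames(lapply(chroms, function(ch) {
    sel <- az$chrom == ch
    IRanges::IRanges(az$start_bp[sel], az$end_bp[sel])
  }), chroms)
}

#' Autozygous intervals exclusively shared by affected members
#'
#' Intersects the autozygomes of all affected members and removes every
#' region covered by any unaffected member's autozygome, keeping
#' intervals longer than `min_length_bp`.  This is the critical-interval
#' step of autozygosity mapping: the disease locus must fall in a region
#' where all affecteds, and no unaffected, are autozygous.  Interval
#' arithmetic is 1-based inclusive (set operations are delegated to
#' `GenomicRanges`).
#'
#' @param affected list of `autozygome` data frames (one per affected).
#' @param unaffected list of `autozygome` data frames (possibly empty).
#' @param min_length_bp minimum surviving interval length (strict).
#' @param gm optional `genotype_matrix`; when given, surviving intervals
#'   are annotated with marker counts and bounding marker ids.
#' @return A data frame with columns `chrom`, `start_bp`, `end_bp`,
#'   `length_bp` (plus `n_markers`, `first_marker`, `last_marker` when
#'   `gm` is supplied), sorted by position.
#' @export
exclusive_shared_intervals <- function(affected, unaffected = list(),
                                       min_length_bp = 2e6, gm = NULL) {
  if (!length(affected)) stop("at least one affected autozygome required")
  chroms <- sort(unique(unlist(lapply(c(affected, unaffected),
                                      function(a) a$chrom))))
  aff_r <- lapply(affected, az_to_ranges, chroms = chroms)
  un_r <- lapply(unaffected, az_to_ranges, chroms = chroms)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    shared <- Reduce(IRanges::intersect,
                     lapply(aff_r, function(a) a[[ch]]))
    if (length(un_r)) {
      excl <- Reduce(IRanges::union, lapply(un_r, function(a) a[[ch]]))
      shared <- IRanges::setdiff(shared, excl)
    }
    shared <- shared[IRanges::width(shared) > min_length_bp]
    data.frame(chrom = rep(ch, length(shared)),
               start_bp = IRanges::start(shared),
               end_bp = IRanges::end(shared),
               length_bp = IRanges::width(shared),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(gm) && nrow(out)) {
    out$n_markers <- NA_integer_
    out$first_marker <- NA_character_
    out$last_marker <- NA_character_
    for (r in seq_len(nrow(out))) {
      inside <- which(gm$markers$chrom == out$chrom[r] &
                        gm$markers$pos_bp >= out$start_bp[r] &
                        gm$markers$pos_bp <= out$end_bp[r])
      out$n_markers[r] <- length(inside)
      if (length(inside)) {
        out$first_marker[r] <- gm$markers$id[inside[1]]
        out$last_marker[r] <- gm$markers$id[inside[length(inside)]]
      }
    }
  }
  out
}

#' Write intervals as BED and TSV
#'
#' BED output is 0-based half-open (a comment line records the
#' conversion); the TSV keeps the 1-based inclusive coordinates and any
#' marker annotation.
#'
#' @param intervals a data frame with `chrom`, `start_bp`, `end_bp`.
#' @param path output path.
#' @export
write_intervals_bed <- function(intervals, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# BED 0-based half-open; converted from 1-based",
                   "inclusive coordinates"), con)
  if (nrow(intervals)) {
    utils::write.table(
      data.frame(intervals$chrom, intervals$start_bp - 1L, intervals$end_bp),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_intervals_bed
#' @export
write_intervals_tsv <- function(intervals, path) {
  utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse a `chr:start-end` interval string
#' @param x string like `"chr15:47051884-57799765"`, or a data frame row
#'   with `chrom`, `start_bp`, `end_bp` (returned unchanged).
#' @return list with `chrom`, `start_bp`, `end_bp` (1-based inclusive).
#' @export
parse_interval <- function(x) {
  if (is.list(x) && all(c("chrom", "start_bp", "end_bp") %in% names(x))) {
    return(list(chrom = x$chrom[1], start_bp = x$start_bp[1],
                end_bp = x$end_bp[1]))
  }
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4) stop("cannot parse interval: ", x)
  list(chrom = m[2],
       start_bp = as.numeric(gsub(",", "", m[3])),
       end_bp = as.numeric(gsub(",", "", m[4])))
}
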