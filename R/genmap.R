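#' Marker maps and the Haldane map function
#'
#' A marker map is a data frame with columns `id`, `chrom`, `pos_bp`
#' (1-based, strictly increasing within chromosome) and an attribute
#' `cm_per_mb` giving the physical-to-genetic scaling (default 1 cM/Mb).
#' Recombination between adjacent positions follows Haldane's map
#' function with no interference.
#'
#' @param id marker identifiers (unique).
#' @param chrom chromosome per marker.
#' @param pos_bp 1-based physical positions, strictly increasing within
#'   each chromosome.
#' @param cm_per_mb centimorgans per megabase (single number).
#' @return A `marker_map` data frame.
#' @examples
#' mp <- marker_map(paste0("rs", 1:5), "chr15", seq(48e6, 52e6, by = 1e6))
#' haldane_theta(100)   # -> 0.4323324
#' @export
marker_map <- function(id, chrom, pos_bp, cm_per_mb = 1) {
  id <- as.character(id)
  chrom <- rep(as.character(chrom), length.out = length(id))
  pos_bp <- as.integer(pos_bp)
  stopifnot(length(id) == length(chrom), length(chrom) == length(pos_bp),
            all(pos_bp >= 1L), cm_per_mb > 0)
  if (anyDuplicated(id)) stop("duplicated marker ids")
  m <- data.frame(id = id, chrom = chrom, pos_bp = pos_bp,
                  stringsAsFactors = FALSE)
  for (ch in unique(chrom)) {
    p <- m$pos_bp[m$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions not strictly increasing on ", ch)
    }
  }
  attr(m, "cm_per_mb") <- cm_per_mb
  class(m) <- c("marker_map", "data.frame")
  m
}

#' @rdname marker_map
#' @param d_cm genetic distance in centimorgans.
#' @export
haldane_theta <- function(d_cm) {
  0.5 * (1 - exp(-2 * d_cm / 100))
}

#' @rdname marker_map
#' @param theta recombination fraction in \[0, 0.5).
#' @export
haldane_cm <- function(theta) {
  stopifnot(all(theta >= 0), all(theta < 0.5))
  -50 * log(1 - 2 * theta)
}

# recombination fractions between adjacent bp positions on one chromosome
adjacent_thetas <- function(pos_bp, cm_per_mb = 1) {
  if (length(pos_bp) < 2L) return(numeric(0))
  haldane_theta(diff(pos_bp) / 1e6 * cm_per_mb)
}

#' Read and write marker map TSV files
#'
#' Columns `id`, `chrom`, `pos_bp`, tab-separated with a header.
#' @param map a `marker_map`.
#' @param path file path.
#' @param cm_per_mb scaling used when reading (not stored in the file).
#' @export
write_marker_map <- function(map, path) {
  stopifnot(inherits(map, "marker_map"))
  utils::write.table(as.data.frame(map)[, c("id", "chrom", "pos_bp")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path, cm_per_mb = 1) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "integer"))
  marker_map(tab$id, tab$chrom, tab$pos_bp, cm_per_mb = cm_per_mb)
}
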