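#' Gene-dropping simulation on a pedigree
#'
#' Simulates marker genotypes by dropping founder haplotypes through the
#' pedigree.  Founders receive two haplotypes with alleles drawn
#' independently per marker from the supplied frequencies; every meiosis
#' recombines between adjacent markers according to Haldane's map
#' function (no interference).  When a disease locus is supplied, exactly
#' one founder haplotype carries the (rare, fully penetrant recessive)
#' disease allele and the simulation is conditioned on the affection
#' pattern: every affected member is homozygous by descent for that
#' haplotype at the locus, and no unaffected member is.  Conditioning is
#' exact: where the descent paths from each candidate founder haplotype
#' to every affected member are unique, the path meioses are fixed and
#' only the residual constraints are enforced by rejection; otherwise a
#' plain rejection sampler over disease-locus inheritance vectors is used,
#' capped at `max_rejections` attempts.
#'
#' @param ped a [pedigree()].
#' @param map a [marker_map()].
#' @param founder_allele_freqs allele frequencies for founder haplotypes:
#'   a single number `p` (biallelic, `p` = frequency of allele "A"), a
#'   numeric vector of length k (k equifrequent-or-not alleles, same at
#'   every marker), or a list with one frequency vector per marker.
#' @param disease_locus `NULL`, or `list(chrom =, pos_bp =)` placing the
#'   disease locus on a mapped chromosome; triggers conditioning.
#' @param genotyping_error per-call probability that the recorded genotype
#'   is replaced by a uniformly random unordered genotype.
#' @param max_rejections cap on rejection attempts for the conditioning.
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   output.
#'
#' @return A list with components `genotypes` (a `genotype_matrix`) and
#'   `truth` (a `sim_truth` holding the disease haplotype, per-individual
#'   identity-by-descent segments, disease-locus genotypes and the seed).
#' @examples
#' ped <- study_pedigree()
#' mp <- marker_map(paste0("m", 1:20), "chr15", seq(45e6, 64e6, by = 1e6))
#' sim <- gene_drop(ped, mp, founder_allele_freqs = 0.5,
#'                  disease_locus = list(chrom = "chr15", pos_bp = 52.4e6),
#'                  seed = 1)
#' sim$truth$disease_genotypes[affected_ids(ped)]  # all 2 (homozygous)
#' @export
gene_drop <- function(ped, map, founder_allele_freqs = 0.5,
                      disease_locus = NULL,
                      genotyping_error = 0, max_rejections = 1e6,
                      seed = 1L) {
  validate_pedigree(ped)
  stopifnot(inherits(map, "marker_map"), genotyping_error >= 0,
            genotyping_error <= 1)
  set.seed(as.integer(seed))
  st <- ped_structure(ped)
  freqs <- normalize_freqs(founder_allele_freqs, nrow(map))

  locus <- NULL
  if (!is.null(disease_locus)) {
    locus <- list(chrom = as.character(disease_locus$chrom),
                  pos_bp = as.numeric(disease_locus$pos_bp))
    if (!locus$chrom %in% map$chrom) {
      stop("disease locus chromosome not on the marker map")
    }
    if (!any(ped$affected == "yes")) {
      stop("conditioning requires at least one affected individual")
    }
    cond <- sample_conditioned_locus_descent(st, max_rejections)
  }

  n <- nrow(ped)
  nf <- length(st$founder_idx)
  M <- nrow(map)
  a1 <- matrix(NA_integer_, M, n, dimnames = list(map$id, ped$id))
  a2 <- a1
  ibd <- stats::setNames(vector("list", n), ped$id)
  seg_acc <- lapply(seq_len(n), function(i) list())

  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    pos <- map$pos_bp[sel]
    anchored <- !is.null(locus) && ch == locus$chrom
    if (anchored) {
      loc_col <- findInterval(locus$pos_bp, pos) + 1L  # insertion index
      pos_full <- append(pos, locus$pos_bp, after = loc_col - 1L)
      I <- sim_inheritance_chain(st$n_mei, pos_full, attr(map, "cm_per_mb"),
                                 anchor_col = loc_col,
                                 anchor_vals = cond$indicators)
    } else {
      pos_full <- pos
      loc_col <- 0L
      I <- sim_inheritance_chain(st$n_mei, pos_full, attr(map, "cm_per_mb"))
    }
    org <- propagate_origins_markers(st, I)
    marker_cols <- if (anchored) setdiff(seq_along(pos_full), loc_col) else
      seq_along(pos_full)
    # founder haplotype alleles, one column per mapped marker
    FA <- matrix(NA_integer_, 2L * nf, length(sel))
    for (j in seq_along(sel)) {
      p <- freqs[[sel[j]]]
      FA[, j] <- sample.int(length(p), 2L * nf, replace = TRUE, prob = p)
    }
    op <- org$pat[, marker_cols, drop = FALSE]
    om <- org$mat[, marker_cols, drop = FALSE]
    idx1 <- t(op) + (seq_along(sel) - 1L) * (2L * nf)
    idx2 <- t(om) + (seq_along(sel) - 1L) * (2L * nf)
    x1 <- matrix(FA[idx1], length(sel), n)
    x2 <- matrix(FA[idx2], length(sel), n)
    a1[sel, ] <- pmin(x1, x2)
    a2[sel, ] <- pmax(x1, x2)
    # true IBD segments from origin-label equality (locus column retained)
    for (i in seq_len(n)) {
      auto <- org$pat[i, ] == org$mat[i, ]
      r <- rle(auto)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      seg_acc[[i]][[length(seg_acc[[i]]) + 1L]] <- data.frame(
        chrom = ch, start_bp = pos_full[starts], end_bp = pos_full[ends],
        autozygous = r$values, stringsAsFactors = FALSE)
    }
  }

  if (genotyping_error > 0) {
    k_by_marker <- vapply(freqs, length, 1L)
    err <- matrix(stats::runif(M * n) < genotyping_error, M, n)
    for (j in which(rowSums(err) > 0)) {
      k <- k_by_marker[j]
      hit <- which(err[j, ])
      g1 <- sample.int(k, length(hit), replace = TRUE)
      g2 <- sample.int(k, length(hit), replace = TRUE)
      a1[j, hit] <- pmin(g1, g2)
      a2[j, hit] <- pmax(g1, g2)
    }
  }

  gm <- structure(list(
    markers = as.data.frame(map),
    alleles = lapply(freqs, function(p) LETTERS[seq_along(p)]),
    freqs = freqs,
    a1 = a1, a2 = a2, individuals = ped$id),
    cm_per_mb = attr(map, "cm_per_mb"),
    class = "genotype_matrix")

  truth <- structure(list(
    disease_locus = locus,
    disease_hap = if (is.null(locus)) NA_integer_ else cond$h_star,
    disease_genotypes = if (is.null(locus)) NULL else {
      g <- (cond$origins$pat == cond$h_star) + (cond$origins$mat == cond$h_star)
      stats::setNames(as.integer(g), ped$id)
    },
    ibd_segments = stats::setNames(
      lapply(seg_acc, function(x) do.call(rbind, x)), ped$id),
    seed = as.integer(seed)),
    class = "sim_truth")

  list(genotypes = gm, truth = truth)
}

# ---- internal structure helpers ------------------------------------------

# Precomputed index structure: topological order, parent indices, meiosis
# ids (paternal/maternal per non-founder) and founder haplotype labels.
ped_structure <- function(ped) {
  depth <- pedigree_depth(ped)
  topo <- order(depth)
  fi <- match(ped$father, ped$id)
  mi <- match(ped$mother, ped$id)
  nonf <- which(!is.na(fi))
  mei_pat <- rep(NA_integer_, nrow(ped))
  mei_mat <- rep(NA_integer_, nrow(ped))
  mei_pat[nonf] <- seq_along(nonf) * 2L - 1L
  mei_mat[nonf] <- seq_along(nonf) * 2L
  founder_idx <- which(is.na(fi))
  founder_rank <- rep(NA_integer_, nrow(ped))
  founder_rank[founder_idx] <- seq_along(founder_idx)
  list(ped = ped, topo = topo, fi = fi, mi = mi,
       mei_pat = mei_pat, mei_mat = mei_mat,
       n_mei = 2L * length(nonf), founder_idx = founder_idx,
       founder_rank = founder_rank,
       affected = which(ped$affected == "yes"),
       unaffected = which(ped$affected == "no"))
}

normalize_freqs <- function(f, n_markers) {
  if (is.list(f)) {
    stopifnot(length(f) == n_markers)
    out <- f
  } else if (is.numeric(f) && length(f) == 1L) {
    stopifnot(f > 0, f < 1)
    out <- rep(list(c(f, 1 - f)), n_markers)
  } else if (is.numeric(f)) {
    stopifnot(all(f > 0), abs(sum(f) - 1) < 1e-8)
    out <- rep(list(f), n_markers)
  } else stop("unsupported founder_allele_freqs")
  lapply(out, function(p) {
    stopifnot(length(p) >= 2, all(p > 0), abs(sum(p) - 1) < 1e-8)
    p
  })
}

# Propagate founder-haplotype origin labels at every column of an
# inheritance-indicator matrix I (n_meioses x n_cols).
propagate_origins_markers <- function(st, I) {
  n <- nrow(st$ped)
  nc <- ncol(I)
  Opat <- matrix(0L, n, nc)
  Omat <- matrix(0L, n, nc)
  for (i in st$topo) {
    if (is.na(st$fi[i])) {
      Opat[i, ] <- 2L * st$founder_rank[i] - 1L
      Omat[i, ] <- 2L * st$founder_rank[i]
    } else {
      ip <- I[st$mei_pat[i], ]
      im <- I[st$mei_mat[i], ]
      f <- st$fi[i]; m <- st$mi[i]
      Opat[i, ] <- ifelse(ip == 0L, Opat[f, ], Omat[f, ])
      Omat[i, ] <- ifelse(im == 0L, Opat[m, ], Omat[m, ])
    }
  }
  list(pat = Opat, mat = Omat)
}

# Simulate inheritance indicators for all meioses along one chromosome.
# Columns follow `pos_bp`; the chain is a Markov process with switch
# probability = Haldane theta of the adjacent gap.  If anchored, column
# `anchor_col` is fixed to `anchor_vals` and the chain is extended
# outwards in both directions (exact for a Markov chain).
sim_inheritance_chain <- function(n_mei, pos_bp, cm_per_mb,
                                  anchor_col = 1L, anchor_vals = NULL) {
  nc <- length(pos_bp)
  I <- matrix(0L, n_mei, nc)
  if (n_mei == 0L || nc == 0L) return(I)
  th <- adjacent_thetas(pos_bp, cm_per_mb)
  if (is.null(anchor_vals)) {
    anchor_col <- 1L
    anchor_vals <- sample(0:1, n_mei, replace = TRUE)
  }
  I[, anchor_col] <- anchor_vals
  if (anchor_col < nc) {
    for (g in anchor_col:(nc - 1L)) {
      sw <- stats::runif(n_mei) < th[g]
      I[, g + 1L] <- (I[, g] + sw) %% 2L
    }
  }
  if (anchor_col > 1L) {
    for (g in (anchor_col - 1L):1L) {
      sw <- stats::runif(n_mei) < th[g]
      I[, g] <- (I[, g + 1L] + sw) %% 2L
    }
  }
  I
}

# ---- conditional sampling of disease-locus descent -----------------------

# All routes by which individual `i` can carry founder haplotype `h`:
# each route records the slot ("pat"/"mat") where h would sit and the
# forced (meiosis, indicator) pairs along the unique ancestral chain.
carrier_routes <- function(st, i, h) {
  if (is.na(st$fi[i])) {
    r <- st$founder_rank[i]
    if (2L * r - 1L == h) return(list(list(slot = 1L, mei = integer(0), val = integer(0))))
    if (2L * r == h)      return(list(list(slot = 2L, mei = integer(0), val = integer(0))))
    return(list())
  }
  out <- list()
  for (rt in carrier_routes(st, st$fi[i], h)) {
    out[[length(out) + 1L]] <- list(
      slot = 1L,
      mei = c(rt$mei, st$mei_pat[i]),
      val = c(rt$val, if (rt$slot == 1L) 0L else 1L))
  }
  for (rt in carrier_routes(st, st$mi[i], h)) {
    out[[length(out) + 1L]] <- list(
      slot = 2L,
      mei = c(rt$mei, st$mei_mat[i]),
      val = c(rt$val, if (rt$slot == 1L) 0L else 1L))
  }
  out
}

# Forced meioses for the event "every affected is homozygous by descent
# for haplotype h".  Returns NULL if h cannot reach some affected,
# the string "ambiguous" if some path is non-unique, otherwise
# list(mei=, val=) of forced indicators.
forced_paths_for_hap <- function(st, h) {
  mei <- integer(0); val <- integer(0)
  for (a in st$affected) {
    rts <- carrier_routes(st, a, h)
    pat <- Filter(function(r) r$slot == 1L, rts)
    mat <- Filter(function(r) r$slot == 2L, rts)
    if (length(pat) == 0L || length(mat) == 0L) return(NULL)
    if (length(pat) > 1L || length(mat) > 1L) return("ambiguous")
    mei <- c(mei, pat[[1]]$mei, mat[[1]]$mei)
    val <- c(val, pat[[1]]$val, mat[[1]]$val)
  }
  keep <- !duplicated(mei)
  if (any(tapply(val, mei, function(v) length(unique(v))) > 1L)) {
    return(NULL)  # conflicting requirements: event impossible
  }
  list(mei = mei[keep], val = val[keep])
}

# Check the conditioning event on one origin assignment (vectors).
locus_event_ok <- function(st, opat, omat, h) {
  ok_aff <- all(opat[st$affected] == h & omat[st$affected] == h)
  ok_un <- !any(opat[st$unaffected] == h & omat[st$unaffected] == h)
  ok_aff && ok_un
}

# Draw (disease haplotype, locus inheritance indicators) conditioned on
# the affection pattern.  Exact: forced-path proposal where descent paths
# are unique, plain batch rejection otherwise (or when forced via
# `method = "rejection"`, which the tests use as a distributional oracle).
sample_conditioned_locus_descent <- function(st, max_rejections = 1e6,
                                             method = c("auto", "rejection")) {
  method <- match.arg(method)
  nf <- length(st$founder_idx)
  haps <- seq_len(2L * nf)
  forced <- lapply(haps, function(h) forced_paths_for_hap(st, h))
  ambiguous <- any(vapply(forced, identical, TRUE, "ambiguous"))
  feasible <- !vapply(forced, is.null, TRUE)
  if (!any(feasible)) {
    stop("unsatisfiable conditioning: no founder haplotype can make all ",
         "affected individuals homozygous by descent")
  }
  if (!ambiguous && method == "auto") {
    w <- vapply(seq_along(haps), function(j) {
      if (!feasible[j]) 0 else 2^(-length(forced[[j]]$mei))
    }, 1)
    for (attempt in seq_len(10000L)) {
      h <- sample(haps, 1L, prob = w)
      I <- sample(0:1, st$n_mei, replace = TRUE)
      I[forced[[h]]$mei] <- forced[[h]]$val
      org <- propagate_origins_markers(st, matrix(I, ncol = 1L))
      if (locus_event_ok(st, org$pat[, 1], org$mat[, 1], h)) {
        return(list(h_star = h, indicators = I,
                    origins = list(pat = org$pat[, 1], mat = org$mat[, 1])))
      }
    }
    stop("unsatisfiable conditioning: unaffected-member constraint ",
         "rejected 10000 forced-path proposals")
  }
  # general fallback: batch rejection over locus inheritance vectors
  tried <- 0
  batch <- as.integer(min(2e4, max_rejections))
  while (tried < max_rejections) {
    hs <- sample(haps, batch, replace = TRUE)
    I <- matrix(sample(0:1, st$n_mei * batch, replace = TRUE),
                nrow = st$n_mei)
    org <- propagate_origins_markers(st, I)
    for (b in seq_len(batch)) {
      if (locus_event_ok(st, org$pat[, b], org$mat[, b], hs[b])) {
        return(list(h_star = hs[b], indicators = I[, b],
                    origins = list(pat = org$pat[, b], mat = org$mat[, b])))
      }
    }
    tried <- tried + batch
  }
  stop("unsatisfiable conditioning: rejection cap of ", max_rejections,
       " attempts exceeded")
}
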