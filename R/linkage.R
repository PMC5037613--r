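#' Parametric disease model
#'
#' Penetrance-based single-locus disease model.  The default is the fully
#' penetrant autosomal recessive model used throughout the mapping
#' pipeline: penetrances (0, 0, 1) for (ref/ref, ref/alt, alt/alt) and a
#' rare disease allele, reflecting homozygosity for a shared ancestral
#' mutation.
#'
#' @param disease_allele_freq population frequency of the disease allele.
#' @param penetrance length-3 vector of P(affected | 0, 1, 2 copies).
#' @return A `disease_model` object.
#' @export
disease_model <- function(disease_allele_freq = 1e-4,
                          penetrance = c(0, 0, 1)) {
  stopifnot(disease_allele_freq > 0, disease_allele_freq < 1,
            length(penetrance) == 3,
            all(penetrance >= 0), all(penetrance <= 1))
  structure(list(disease_allele_freq = disease_allele_freq,
                 penetrance = penetrance),
            class = "disease_model")
}

#' Exact pedigree likelihood for a marker linked to a disease locus
#'
#' Joint probability of the observed marker genotypes and affection
#' statuses on a pedigree, as a function of the recombination fraction
#' theta between marker and disease locus.  The sum over all phased
#' two-locus genotypes is performed by variable elimination on the
#' pedigree's factor graph (genotype-elimination peeling with a min-fill
#' elimination order), which handles consanguinity loops exactly without
#' explicit loop-breaking.  Founder haplotypes are assigned
#' linkage-equilibrium priors from the marker allele frequencies and the
#' model's disease allele frequency.
#'
#' @param ped a [pedigree()].
#' @param marker_genotypes named character vector over pedigree members,
#'   entries like `"A/B"` (unordered), `NA` for untyped members.
#' @param allele_freqs named numeric vector of marker allele frequencies
#'   (names are the allele labels used in `marker_genotypes`).
#' @param model a [disease_model()].
#' @param theta numeric vector of recombination fractions in \[0, 0.5\].
#' @return Numeric vector of natural-log likelihoods, one per `theta`.
#'   `-Inf` signals data impossible under the model; when the marker
#'   genotypes are Mendelian-inconsistent an attribute `violations`
#'   lists the offending trios.
#' @examples
#' trio <- pedigree(c("F", "M", "C"), c(NA, NA, "F"), c(NA, NA, "M"),
#'                  c("male", "female", "female"), c("no", "no", "yes"))
#' g <- c(F = "A/B", M = "A/B", C = "A/A")
#' pedigree_likelihood(trio, g, c(A = 0.5, B = 0.5), theta = c(0, 0.5))
#' @export
pedigree_likelihood <- function(ped, marker_genotypes, allele_freqs,
                                model = disease_model(), theta = 0) {
  validate_pedigree(ped)
  stopifnot(all(theta >= 0), all(theta <= 0.5), length(theta) >= 1)
  g <- marker_genotypes[ped$id]
  eng <- linkage_engine(ped, k = length(allele_freqs), theta = theta)
  ll <- eval_linkage_engine(eng, ped, g, allele_freqs, model)
  if (all(!is.finite(ll))) {
    viol <- mendelian_violations(ped, marker_genotypes)
    if (nrow(viol)) {
      attr(ll, "violations") <- viol
      warning("Mendelian-inconsistent marker data; violating trio(s): ",
              paste(viol$child, collapse = ", "))
    }
  }
  ll
}

#' LOD score curve over a marker panel
#'
#' Per-marker parametric LOD scores LOD(theta) = log10 L(theta) -
#' log10 L(0.5) on a pedigree, maximized over a theta grid, under a
#' penetrance-based disease model.  Markers are treated singlepoint; the
#' genome-wide peak is the marker/theta combination with the highest LOD.
#'
#' @param ped a [pedigree()].
#' @param gm a `genotype_matrix` covering the pedigree members (allele
#'   frequencies are taken from the matrix; run [estimate_allele_freqs()]
#'   first if absent).
#' @param model a [disease_model()].
#' @param theta_grid recombination fractions searched (0.5 is always
#'   added as the null reference).
#' @return A `linkage_result` data frame with columns `marker_id`,
#'   `chrom`, `pos_bp`, `theta_max`, `lod`; the per-theta LOD matrix is
#'   attached as attribute `"lods"` and the genome-wide peak as `"peak"`.
#' @export
lod_curve <- function(ped, gm, model = disease_model(),
                      theta_grid = c(0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)) {
  validate_pedigree(ped)
  stopifnot(inherits(gm, "genotype_matrix"), length(theta_grid) >= 1)
  if (is.null(gm$freqs)) {
    stop("genotype matrix lacks allele frequencies; run estimate_allele_freqs()")
  }
  if (!all(ped$id %in% gm$individuals)) {
    stop("genotype matrix does not cover all pedigree members")
  }
  thetas <- sort(unique(c(theta_grid, 0.5)))
  M <- nrow(gm$a1)
  lods <- matrix(NA_real_, M, length(thetas),
                 dimnames = list(gm$markers$id, format(thetas)))
  engines <- list()
  for (j in seq_len(M)) {
    k <- length(gm$freqs[[j]])
    key <- as.character(k)
    if (is.null(engines[[key]])) {
      engines[[key]] <- linkage_engine(ped, k = k, theta = thetas)
    }
    p <- stats::setNames(gm$freqs[[j]], gm$alleles[[j]])
    g <- marker_genotypes(gm, gm$markers$id[j])
    ll <- eval_linkage_engine(engines[[key]], ped, g[ped$id], p, model)
    lods[j, ] <- (ll - ll[thetas == 0.5]) / log(10)
  }
  grid_cols <- thetas %in% theta_grid
  sub <- lods[, grid_cols, drop = FALSE]
  th_sub <- thetas[grid_cols]
  imax <- apply(sub, 1, function(x) which.max(replace(x, is.na(x), -Inf)))
  out <- data.frame(marker_id = gm$markers$id,
                    chrom = gm$markers$chrom,
                    pos_bp = gm$markers$pos_bp,
                    theta_max = th_sub[imax],
                    lod = sub[cbind(seq_len(M), imax)],
                    stringsAsFactors = FALSE)
  class(out) <- c("linkage_result", "data.frame")
  attr(out, "lods") <- sub
  attr(out, "theta_grid") <- th_sub
  pk <- which.max(out$lod)
  attr(out, "peak") <- list(marker_id = out$marker_id[pk],
                            chrom = out$chrom[pk], pos_bp = out$pos_bp[pk],
                            theta = out$theta_max[pk], lod = out$lod[pk])
  out
}

#' @export
print.linkage_result <- function(x, ...) {
  pk <- attr(x, "peak")
  cat(sprintf("LOD scores at %d markers; peak %.3f at %s (%s:%d, theta=%.2f)\n",
              nrow(x), pk$lod, pk$marker_id, pk$chrom, pk$pos_bp, pk$theta))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write LOD results as TSV
#' @param x a `linkage_result`.
#' @param path file path.
#' @export
write_linkage_result <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- internal: factor-graph engine ---------------------------------------

# Phased two-locus state of one individual: ordered pair of haplotypes
# (paternal, maternal), each haplotype = (marker allele a in 1..k,
# disease allele d in 1..2).  Haplotype index h = (a-1)*2 + d; state
# index s = (hm-1)*H + hp with H = 2k (paternal haplotype fastest).

hap_amap <- function(k) rep(seq_len(k), each = 2)
hap_dmap <- function(k) rep(1:2, times = k)

# P(transmitted haplotype | parent state, theta): H x S x n_theta
build_transmission1 <- function(k, theta) {
  H <- 2L * k; S <- H * H; nt <- length(theta)
  amap <- hap_amap(k); dmap <- hap_dmap(k)
  T1 <- array(0, c(H, S, nt))
  for (s in seq_len(S)) {
    hp <- ((s - 1L) %% H) + 1L
    hm <- ((s - 1L) %/% H) + 1L
    for (x in 1:2) for (y in 1:2) {
      a <- amap[if (x == 1) hp else hm]
      d <- dmap[if (y == 1) hp else hm]
      h <- (a - 1L) * 2L + d
      w <- 0.5 * (if (x == y) 1 - theta else theta)
      T1[h, s, ] <- T1[h, s, ] + w
    }
  }
  T1
}

# Precompute everything that does not depend on the observed genotypes.
linkage_engine <- function(ped, k, theta) {
  H <- 2L * k; S <- H * H
  T1 <- build_transmission1(k, theta)
  scopes <- list()
  nonf <- which(!is.na(ped$father))
  for (i in nonf) {
    scopes[[length(scopes) + 1L]] <-
      c(ped$id[i], ped$father[i], ped$mother[i], ".theta")
  }
  elim <- elim_order_minfill(c(scopes, as.list(ped$id)), keep = ".theta")
  amap <- hap_amap(k); dmap <- hap_dmap(k)
  sp <- ((seq_len(S) - 1L) %% H) + 1L
  sm <- ((seq_len(S) - 1L) %/% H) + 1L
  list(k = k, H = H, S = S, theta = theta, T1 = T1, elim = elim,
       sp = sp, sm = sm,
       s_a1 = pmin(amap[sp], amap[sm]), s_a2 = pmax(amap[sp], amap[sm]),
       s_dg = (dmap[sp] == 2L) + (dmap[sm] == 2L))
}

# Build observation-restricted factors and peel.  Each individual's state
# domain is cut down to the states consistent with their genotype and
# (where penetrance is exactly 0 or 1) their phenotype before any factor
# is materialized -- the genotype-elimination step that keeps peeling
# tractable on looped pedigrees.
eval_linkage_engine <- function(eng, ped, g, allele_freqs, model) {
  S <- eng$S
  nt <- length(eng$theta)
  q <- model$disease_allele_freq
  pd <- c(1 - q, q)
  amap <- hap_amap(eng$k); dmap <- hap_dmap(eng$k)
  ph <- unname(allele_freqs)[amap] * pd[dmap]
  prior <- as.vector(outer(ph, ph))
  labels <- names(allele_freqs)
  n <- nrow(ped)

  dom <- vector("list", n)    # allowed state indices per individual
  wt <- vector("list", n)     # penetrance weight on the allowed states
  for (i in seq_len(n)) {
    keep <- rep(TRUE, S)
    if (!is.na(g[i])) {
      al <- match(strsplit(g[i], "/", fixed = TRUE)[[1]], labels)
      if (anyNA(al) || length(al) != 2) {
        stop("cannot parse genotype '", g[i], "' for ", ped$id[i],
             " against alleles ", paste(labels, collapse = ","))
      }
      keep <- keep & eng$s_a1 == min(al) & eng$s_a2 == max(al)
    }
    w <- rep(1, S)
    if (ped$affected[i] == "yes") {
      w <- model$penetrance[eng$s_dg + 1L]
    } else if (ped$affected[i] == "no") {
      w <- 1 - model$penetrance[eng$s_dg + 1L]
    }
    keep <- keep & w > 0
    if (!any(keep)) return(rep(-Inf, nt))
    dom[[i]] <- which(keep)
    wt[[i]] <- w[keep]
  }

  sizes <- stats::setNames(vapply(dom, length, 1L), ped$id)
  sizes[".theta"] <- nt

  factors <- list()
  add <- function(vars, arr) {
    factors[[length(factors) + 1L]] <<- list(vars = vars, arr = arr)
  }
  for (i in seq_len(n)) {
    id <- ped$id[i]
    if (is.na(ped$father[i])) {
      add(id, prior[dom[[i]]] * wt[[i]])
    } else {
      fidx <- match(ped$father[i], ped$id)
      midx <- match(ped$mother[i], ped$id)
      dc <- dom[[i]]; df <- dom[[fidx]]; dm <- dom[[midx]]
      nc <- length(dc); nf <- length(df); nm <- length(dm)
      A <- eng$T1[eng$sp[dc], df, , drop = FALSE]          # (c, f, t)
      B <- eng$T1[eng$sm[dc], dm, , drop = FALSE]          # (c, m, t)
      Ae <- aperm(array(A, c(nc, nf, nt, nm)), c(1, 2, 4, 3))
      Be <- aperm(array(B, c(nc, nm, nt, nf)), c(1, 4, 2, 3))
      add(c(id, ped$father[i], ped$mother[i], ".theta"), Ae * Be)
      add(id, wt[[i]])
    }
  }
  ve_logsum(factors, eng$elim, sizes, keep = ".theta", n_out = nt)
}

# ---- internal: dense factor algebra --------------------------------------

expand_factor <- function(f, vars, sizes) {
  if (identical(f$vars, vars)) return(f$arr)
  pres <- vars[vars %in% f$vars]
  a <- f$arr
  if (!identical(pres, f$vars)) {
    a <- aperm(array(a, sizes[f$vars]), match(pres, f$vars))
  }
  miss <- vars[!(vars %in% f$vars)]
  a <- array(a, unname(c(sizes[pres], sizes[miss])))
  if (length(miss)) a <- aperm(a, match(vars, c(pres, miss)))
  a
}

f_mul <- function(f1, f2, sizes) {
  vars <- union(f1$vars, f2$vars)
  list(vars = vars,
       arr = expand_factor(f1, vars, sizes) * expand_factor(f2, vars, sizes))
}

f_sumout <- function(f, v, sizes) {
  iv <- match(v, f$vars)
  if (length(f$vars) == 1L) {
    return(list(vars = character(0), arr = sum(f$arr)))
  }
  perm <- c(iv, seq_along(f$vars)[-iv])
  a <- aperm(array(f$arr, sizes[f$vars]), perm)
  rest <- f$vars[-iv]
  dim(a) <- c(sizes[[v]], prod(sizes[rest]))
  list(vars = rest, arr = array(colSums(a), unname(sizes[rest])))
}

# Eliminate all variables except `keep`; returns log of the resulting
# (length n_out) table, rescaling along the way to avoid underflow.
ve_logsum <- function(factors, elim_order, sizes, keep, n_out = 1L) {
  logc <- 0
  for (v in elim_order) {
    inv <- vapply(factors, function(f) v %in% f$vars, TRUE)
    if (!any(inv)) next
    fs <- factors[inv]
    factors <- factors[!inv]
    f <- Reduce(function(x, y) f_mul(x, y, sizes), fs)
    f <- f_sumout(f, v, sizes)
    mx <- max(f$arr)
    if (mx == 0) return(rep(-Inf, n_out))
    f$arr <- f$arr / mx
    logc <- logc + log(mx)
    factors[[length(factors) + 1L]] <- f
  }
  f <- Reduce(function(x, y) f_mul(x, y, sizes), factors)
  if (length(f$vars) == 0L) {
    out <- rep(logc + log(f$arr), n_out)
  } else {
    # remaining dims are exactly `keep` (the theta grid)
    out <- logc + log(as.vector(expand_factor(f, keep, sizes)))
  }
  out
}

elim_order_minfill <- function(scopes, keep = character(0)) {
  vars <- setdiff(unique(unlist(scopes)), keep)
  n <- length(vars)
  A <- matrix(FALSE, n, n, dimnames = list(vars, vars))
  for (sc in scopes) {
    sc <- setdiff(sc, keep)
    A[sc, sc] <- TRUE
  }
  diag(A) <- FALSE
  alive <- stats::setNames(rep(TRUE, n), vars)
  ord <- character(n)
  for (step in seq_len(n)) {
    best <- NA_character_; best_fill <- Inf; best_deg <- Inf
    for (v in vars[alive[vars]]) {
      nb <- vars[alive[vars] & A[v, vars]]
      deg <- length(nb)
      fill <- if (deg < 2L) 0L else {
        sub <- A[nb, nb, drop = FALSE]
        sum(!sub[upper.tri(sub)])
      }
      if (fill < best_fill || (fill == best_fill && deg < best_deg)) {
        best <- v; best_fill <- fill; best_deg <- deg
      }
    }
    nb <- vars[alive[vars] & A[best, vars]]
    if (length(nb) > 1L) A[nb, nb] <- TRUE
    diag(A) <- FALSE
    alive[best] <- FALSE
    ord[step] <- best
  }
  ord
}

# ---- internal: Mendelian trio check --------------------------------------

mendelian_violations <- function(ped, g) {
  g <- g[ped$id]
  split2 <- function(x) strsplit(x, "/", fixed = TRUE)
  out <- list()
  for (i in which(!is.na(ped$father))) {
    gi <- g[ped$id[i]]; gf <- g[ped$father[i]]; gm <- g[ped$mother[i]]
    if (is.na(gi) || is.na(gf) || is.na(gm)) next
    ci <- split2(gi)[[1]]; cf <- split2(gf)[[1]]; cm <- split2(gm)[[1]]
    ok <- any(vapply(1:2, function(x) {
      (ci[x] %in% cf) && (ci[3 - x] %in% cm)
    }, TRUE))
    if (!ok) {
      out[[length(out) + 1L]] <- data.frame(
        child = ped$id[i], father = ped$father[i], mother = ped$mother[i],
        child_gt = gi, father_gt = gf, mother_gt = gm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(child = character(0), father = character(0),
               mother = character(0), child_gt = character(0),
               father_gt = character(0), mother_gt = character(0))
}
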