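# Independent brute-force oracle for the two-locus pedigree likelihood:
# exhaustive enumeration over marker-locus and disease-locus inheritance
# vectors (2 bits per meiosis) with founder-allele enumeration per locus.
# Deliberately shares no code with the package's peeling engine.
#
# Requires the pedigree rows to be topologically ordered (parents before
# children), which all fixtures here satisfy.

oracle_two_locus_loglik <- function(ped, g, allele_freqs, q, theta,
                                    penetrance = c(0, 0, 1)) {
  ids <- ped$id
  n <- length(ids)
  fi <- match(ped$father, ids)
  mi <- match(ped$mother, ids)
  stopifnot(all(is.na(fi) | fi < seq_len(n)),
            all(is.na(mi) | mi < seq_len(n)))
  founders <- which(is.na(fi))
  nonf <- which(!is.na(fi))
  m <- 2L * length(nonf)
  k <- length(allele_freqs)
  labels <- names(allele_freqs)

  # meiosis index: paternal of nonf[j] -> 2j-1, maternal -> 2j
  mei_of <- matrix(NA_integer_, n, 2)
  mei_of[nonf, 1] <- seq_along(nonf) * 2L - 1L
  mei_of[nonf, 2] <- seq_along(nonf) * 2L

  # founder slot ranks: founder f's slots are 2r-1, 2r
  frank <- rep(NA_integer_, n)
  frank[founders] <- seq_along(founders)
  nslot <- 2L * length(founders)

  # origin of each individual's two slots given one inheritance vector
  slot_origin <- function(bits) {
    org <- matrix(NA_integer_, n, 2)
    for (i in seq_len(n)) {
      if (is.na(fi[i])) {
        org[i, ] <- c(2L * frank[i] - 1L, 2L * frank[i])
      } else {
        org[i, 1] <- org[fi[i], 1L + bits[mei_of[i, 1]]]
        org[i, 2] <- org[mi[i], 1L + bits[mei_of[i, 2]]]
      }
    }
    org
  }

  bits_table <- function(m) {
    if (m == 0) return(matrix(integer(0), 1, 0))
    as.matrix(expand.grid(rep(list(0:1), m)))
  }
  B <- bits_table(m)                       # 2^m x m

  row_prods <- function(cfg, p) {
    Reduce(`*`, lapply(seq_len(ncol(cfg)), function(j) p[cfg[, j]]))
  }

  # P(marker observations | inheritance vector), all vectors
  cfgM <- as.matrix(expand.grid(rep(list(seq_len(k)), nslot)))
  wM <- row_prods(cfgM, unname(allele_freqs))
  gsplit <- lapply(g, function(x)
    if (is.na(x)) NULL else sort(strsplit(x, "/", fixed = TRUE)[[1]]))
  a_marker <- apply(B, 1, function(bits) {
    org <- slot_origin(bits)
    keep <- rep(TRUE, nrow(cfgM))
    for (i in seq_len(n)) {
      if (is.null(gsplit[[i]])) next
      al1 <- labels[cfgM[, org[i, 1]]]
      al2 <- labels[cfgM[, org[i, 2]]]
      obs <- gsplit[[i]]
      keep <- keep & ((al1 == obs[1] & al2 == obs[2]) |
                        (al1 == obs[2] & al2 == obs[1]))
    }
    sum(wM[keep])
  })

  # P(affection statuses | inheritance vector) at the disease locus
  cfgD <- as.matrix(expand.grid(rep(list(1:2), nslot)))
  wD <- row_prods(cfgD, c(1 - q, q))
  b_disease <- apply(B, 1, function(bits) {
    org <- slot_origin(bits)
    lik <- rep(1, nrow(cfgD))
    for (i in seq_len(n)) {
      dg <- (cfgD[, org[i, 1]] == 2L) + (cfgD[, org[i, 2]] == 2L)
      if (ped$affected[i] == "yes") {
        lik <- lik * penetrance[dg + 1L]
      } else if (ped$affected[i] == "no") {
        lik <- lik * (1 - penetrance[dg + 1L])
      }
    }
    sum(wD * lik)
  })

  # combine over pairs of vectors; per meiosis P = 0.5 * theta^(differ)
  vapply(theta, function(th) {
    if (m == 0) return(log(a_marker[1] * b_disease[1]))
    D <- B %*% t(1 - B) + (1 - B) %*% t(B)   # pairwise Hamming distances
    W <- 0.5^m * th^D * (1 - th)^(m - D)
    log(drop(a_marker %*% W %*% b_disease))
  }, 1)
}

# Permutation reference for the one-way ANOVA F statistic.
oracle_permutation_p <- function(groups, n_perm = 1e4, seed = 1) {
  set.seed(seed)
  x <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, 1L)
  f_stat <- function(x) {
    g <- rep(seq_along(sizes), sizes)
    means <- tapply(x, g, mean)
    ssb <- sum(sizes * (means - mean(x))^2)
    ssw <- sum((x - means[g])^2)
    (ssb / (length(sizes) - 1)) / (ssw / (length(x) - length(sizes)))
  }
  f0 <- f_stat(x)
  hits <- sum(vapply(seq_len(n_perm), function(i)
    f_stat(sample(x)) >= f0, TRUE))
  (hits + 1) / (n_perm + 1)
}
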