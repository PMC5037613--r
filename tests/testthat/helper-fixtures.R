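# Shared fixtures built in code.

# grandparental couple -> two sibs married out -> first cousins marry,
# one affected child, two unaffected sibs
first_cousin_pedigree <- function(affected_child = "yes") {
  pedigree(
    id = c("gp1", "gp2", "u1", "u2", "w1", "h2", "c1", "c2", "kid",
           "sib1", "sib2"),
    father = c(NA, NA, "gp1", "gp1", NA, NA, "u1", "h2", "c1", "c1", "c1"),
    mother = c(NA, NA, "gp2", "gp2", NA, NA, "w1", "u2", "c2", "c2", "c2"),
    sex = c("male", "female", "male", "female", "female", "male",
            "male", "female", "female", "male", "female"),
    affected = c(rep("no", 8), affected_child, "no", "no"),
    name = "FC")
}

# small random pedigree with parents preceding children; monogamous
# couples (as in real study pedigrees) keep the peeling cliques small,
# and sizes are tuned so the enumeration oracle stays cheap
# (<= 10 meioses, <= 3 founders)
random_small_pedigree <- function(seed) {
  set.seed(seed)
  nf <- sample(2:3, 1)
  id <- paste0("F", seq_len(nf))
  sex <- c("male", "female",
           if (nf == 3) sample(c("male", "female"), 1))
  father <- mother <- rep(NA_character_, nf)
  couples <- list(c("F1", "F2"))
  unpaired <- if (nf == 3) id[3] else character(0)
  n_child <- sample(2:5, 1)
  for (j in seq_len(n_child)) {
    cpl <- couples[[sample(length(couples), 1)]]
    kid <- paste0("C", j)
    kid_sex <- sample(c("male", "female"), 1)
    id <- c(id, kid)
    sex <- c(sex, kid_sex)
    father <- c(father, cpl[1])
    mother <- c(mother, cpl[2])
    # pair the new child with an unpaired opposite-sex member (this is
    # what creates consanguineous loops), or leave it unpaired
    mate_ok <- unpaired[match(unpaired, id) > 0 &
                          sex[match(unpaired, id)] != kid_sex]
    if (length(mate_ok) && stats::runif(1) < 0.6) {
      mate <- sample(c(mate_ok, mate_ok), 1)  # guard length-1 sample()
      unpaired <- setdiff(unpaired, mate)
      couples[[length(couples) + 1L]] <-
        if (kid_sex == "male") c(kid, mate) else c(mate, kid)
    } else {
      unpaired <- c(unpaired, kid)
    }
  }
  pedigree(id, father, mother, sex, affected = rep("unknown", length(id)),
           name = paste0("RND", seed))
}

# independent mini gene-drop used to produce Mendelian-consistent marker
# genotypes and affection statuses for the oracle comparisons
random_ped_data <- function(ped, k = 2, q_sim = 0.3, miss = 0.2,
                            seed = 1) {
  set.seed(seed)
  ids <- ped$id
  n <- length(ids)
  fi <- match(ped$father, ids)
  mi <- match(ped$mother, ids)
  labels <- LETTERS[seq_len(k)]
  al <- matrix(NA_integer_, n, 2)
  dis <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      al[i, ] <- sample.int(k, 2, replace = TRUE)
      dis[i, ] <- sample(1:2, 2, replace = TRUE, prob = c(1 - q_sim, q_sim))
    } else {
      al[i, 1] <- al[fi[i], sample(1:2, 1)]
      al[i, 2] <- al[mi[i], sample(1:2, 1)]
      dis[i, 1] <- dis[fi[i], sample(1:2, 1)]
      dis[i, 2] <- dis[mi[i], sample(1:2, 1)]
    }
  }
  g <- paste(labels[pmin(al[, 1], al[, 2])],
             labels[pmax(al[, 1], al[, 2])], sep = "/")
  g[stats::runif(n) < miss] <- NA
  ped$affected <- ifelse(rowSums(dis == 2L) == 2L, "yes", "no")
  freqs <- stats::setNames(rep(1 / k, k), labels)
  list(ped = ped, g = stats::setNames(g, ids), freqs = freqs)
}

# genotype_matrix built from call strings ("AA", "AB", "--", NA)
gm_from_calls <- function(calls, map) {
  stopifnot(nrow(calls) == nrow(map))
  a1 <- matrix(NA_integer_, nrow(calls), ncol(calls),
               dimnames = list(map$id, colnames(calls)))
  a2 <- a1
  for (j in seq_len(nrow(calls))) {
    x <- calls[j, ]
    ok <- !is.na(x) & x != "--"
    c1 <- match(substr(x, 1, 1), c("A", "B"))
    c2 <- match(substr(x, 2, 2), c("A", "B"))
    a1[j, ok] <- pmin(c1, c2)[ok]
    a2[j, ok] <- pmax(c1, c2)[ok]
  }
  structure(list(markers = as.data.frame(map),
                 alleles = rep(list(c("A", "B")), nrow(map)),
                 freqs = rep(list(c(0.5, 0.5)), nrow(map)),
                 a1 = a1, a2 = a2, individuals = colnames(calls)),
            cm_per_mb = attr(map, "cm_per_mb"),
            class = "genotype_matrix")
}

# autozygome data frame from (chrom, start, end) triples
az_df <- function(individual, ...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r) data.frame(
    individual = individual, chrom = r[[1]],
    start_bp = as.numeric(r[[2]]), end_bp = as.numeric(r[[3]]),
    length_bp = as.numeric(r[[3]]) - as.numeric(r[[2]]) + 1,
    n_markers = NA_integer_, first_marker = NA_character_,
    last_marker = NA_character_, stringsAsFactors = FALSE)))
  class(out) <- c("autozygome", "data.frame")
  out
}

# the hand-constructed 5-record filter example
toy_variant_table <- function() {
  iv <- list(chrom = "chr15", start_bp = 47051884, end_bp = 57799765)
  variants <- data.frame(
    chrom = c("chr15", "chr15", "chr15", "chr15", "chr15"),
    pos_bp = c(50e6, 51e6, 52e6, 60e6, 53e6),
    ref = "C", alt = "T",
    af = c(1e-5, 0.01, 1e-5, 1e-5, NA),
    gene = paste0("G", 1:5), effect = "missense",
    stringsAsFactors = FALSE)
  geno <- matrix(c(2L, 2L, 1L, 2L, 2L), ncol = 1,
                 dimnames = list(NULL, "V:1"))
  list(vt = variant_table(variants, geno), interval = iv)
}

# noise-free exponential decay packaged as a baseline-corrected trace
decay_trace <- function(k, A = 0.3, C = 0, t_end = 30, dt = 0.02) {
  t <- seq(0, t_end, by = dt)
  structure(list(time_s = t, bret_ratio = A * exp(-k * t) + C,
                 t_agonist = -2, t_antagonist = 0,
                 condition = "synthetic"),
            class = "bret_trace")
}
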