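test_that("likelihood matches exhaustive enumeration on small pedigrees", {
  # a representative batch here; the full 100-pedigree sweep runs in
  # test-acceptance.R
  for (s in 1:20) {
    dat <- random_ped_data(random_small_pedigree(s), k = sample(2:3, 1),
                           seed = s)
    model <- disease_model(disease_allele_freq = 0.01)
    th <- c(0, 0.1, 0.3, 0.5)
    ll <- pedigree_likelihood(dat$ped, dat$g, dat$freqs, model, theta = th)
    oracle <- oracle_two_locus_loglik(dat$ped, dat$g, dat$freqs,
                                      q = 0.01, theta = th)
    expect_equal(as.numeric(ll), oracle, tolerance = 1e-10)
  }
})

test_that("fully informative 4-allele marker on the first-cousin pedigree
           matches enumeration at complete linkage", {
  # 9-member core of the first-cousin pedigree (10 meioses) keeps the
  # enumeration oracle affordable
  fc <- pedigree(
    id = c("gp1", "gp2", "u1", "u2", "w1", "h2", "c1", "c2", "kid"),
    father = c(NA, NA, "gp1", "gp1", NA, NA, "u1", "h2", "c1"),
    mother = c(NA, NA, "gp2", "gp2", NA, NA, "w1", "u2", "c2"),
    sex = c("male", "female", "male", "female", "female", "male",
            "male", "female", "female"),
    affected = c(rep("no", 8), "yes"), name = "FC9")
  # grandparents carry four distinct alleles; descent fully traceable
  g <- c(gp1 = "A/B", gp2 = "C/D", u1 = "A/C", u2 = "A/C",
         w1 = "B/D", h2 = "B/D", c1 = "A/B", c2 = "A/D",
         kid = "A/A")
  freqs <- c(A = 0.25, B = 0.25, C = 0.25, D = 0.25)
  model <- disease_model(1e-4)
  ll <- pedigree_likelihood(fc, g, freqs, model, theta = c(0, 0.5))
  oracle <- oracle_two_locus_loglik(fc, g, freqs, q = 1e-4,
                                    theta = c(0, 0.5))
  expect_equal(as.numeric(ll), oracle, tolerance = 1e-10)
  expect_gt(ll[1], ll[2])   # complete linkage fits the autozygous child
})

test_that("theta = 0.5 factorizes into marker-only x disease-only", {
  for (s in c(3, 7)) {
    dat <- random_ped_data(random_small_pedigree(s), seed = s + 50)
    model <- disease_model(0.01)
    joint <- pedigree_likelihood(dat$ped, dat$g, dat$freqs, model, 0.5)
    ped_u <- dat$ped
    ped_u$affected <- rep("unknown", nrow(ped_u))
    marker_only <- pedigree_likelihood(ped_u, dat$g, dat$freqs, model, 0.5)
    disease_only <- pedigree_likelihood(
      dat$ped, stats::setNames(rep(NA_character_, nrow(dat$ped)),
                               dat$ped$id),
      dat$freqs, model, 0.5)
    expect_equal(as.numeric(joint),
                 as.numeric(marker_only + disease_only), tolerance = 1e-10)
    # all-missing marker: likelihood reduces to the disease-only part
    all_na <- pedigree_likelihood(
      dat$ped, stats::setNames(rep(NA_character_, nrow(dat$ped)),
                               dat$ped$id),
      dat$freqs, model, c(0, 0.2, 0.5))
    expect_equal(diff(range(all_na)), 0)
  }
})

test_that("LOD at theta = 0.5 is exactly zero, for every marker", {
  ped <- study_pedigree()
  mp <- marker_map(paste0("m", 1:6), "chr15", seq(48e6, 53e6, by = 1e6))
  sim <- gene_drop(ped, mp, 0.5,
                   disease_locus = list(chrom = "chr15", pos_bp = 50e6),
                   seed = 5)
  lr <- lod_curve(ped, sim$genotypes, theta_grid = c(0, 0.1, 0.5))
  lods <- attr(lr, "lods")
  expect_true(all(lods[, ncol(lods)] == 0))
})

test_that("uninformative duo gives LOD 0 at all theta", {
  # a duo needs both parents present; model it as a trio with an untyped,
  # phenotype-unknown mother, which marginalizes to the duo
  trio <- pedigree(c("p", "m", "kid"), c(NA, NA, "p"), c(NA, NA, "m"),
                   c("male", "female", "female"),
                   c("no", "unknown", "unknown"))
  g <- c(p = "A/A", m = NA, kid = "A/A")
  th <- c(0, 0.1, 0.3, 0.5)
  ll <- pedigree_likelihood(trio, g, c(A = 0.3, B = 0.7),
                            disease_model(1e-3), theta = th)
  lod <- (ll - ll[4]) / log(10)
  expect_equal(as.numeric(lod), rep(0, 4), tolerance = 1e-12)
})

test_that("likelihood is invariant to allele relabeling", {
  dat <- random_ped_data(random_small_pedigree(9), k = 3, seed = 99)
  model <- disease_model(0.05)
  ll1 <- pedigree_likelihood(dat$ped, dat$g, dat$freqs, model, c(0, 0.2))
  swap <- c(A = "C", B = "A", C = "B")
  g2 <- vapply(dat$g, function(x) {
    if (is.na(x)) return(NA_character_)
    al <- sort(swap[strsplit(x, "/", fixed = TRUE)[[1]]])
    paste(al, collapse = "/")
  }, character(1))
  freqs2 <- stats::setNames(dat$freqs, swap[names(dat$freqs)])
  freqs2 <- freqs2[order(names(freqs2))]
  ll2 <- pedigree_likelihood(dat$ped, g2, freqs2, model, c(0, 0.2))
  expect_equal(as.numeric(ll1), as.numeric(ll2), tolerance = 1e-12)
})

test_that("Mendelian inconsistency gives -Inf with a trio diagnostic", {
  trio <- pedigree(c("f", "m", "c"), c(NA, NA, "f"), c(NA, NA, "m"),
                   c("male", "female", "male"), c("no", "no", "no"))
  g <- c(f = "A/A", m = "A/A", c = "B/B")
  expect_warning(
    ll <- pedigree_likelihood(trio, g, c(A = 0.5, B = 0.5),
                              disease_model(), theta = c(0, 0.5)),
    "Mendelian")
  expect_true(all(ll == -Inf))
  expect_equal(attr(ll, "violations")$child, "c")
})

test_that("an all-missing extra marker never changes the peak LOD", {
  ped <- study_pedigree()
  mp <- marker_map(paste0("m", 1:6), "chr15", seq(48e6, 53e6, by = 1e6))
  sim <- gene_drop(ped, mp, 0.5,
                   disease_locus = list(chrom = "chr15", pos_bp = 50e6),
                   seed = 8)
  lr1 <- lod_curve(ped, sim$genotypes)
  mp2 <- marker_map(c(paste0("m", 1:6), "mx"), "chr15",
                    c(seq(48e6, 53e6, by = 1e6), 54e6))
  gm2 <- sim$genotypes
  gm2$markers <- rbind(gm2$markers, data.frame(id = "mx", chrom = "chr15",
                                               pos_bp = 54e6))
  gm2$alleles <- c(gm2$alleles, list(c("A", "B")))
  gm2$freqs <- c(gm2$freqs, list(c(0.5, 0.5)))
  gm2$a1 <- rbind(gm2$a1, mx = NA_integer_)
  gm2$a2 <- rbind(gm2$a2, mx = NA_integer_)
  lr2 <- lod_curve(ped, gm2)
  expect_equal(attr(lr2, "peak")$lod, attr(lr1, "peak")$lod)
})
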