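test_that("simulated traces follow the stated two-phase model", {
  tr <- simulate_bret_traces(k_act = 0.3, k_app = 0.1, k_gap = 0.4,
                             noise_sd = 0, n_replicates = 1, seed = 1)[[1]]
  expect_length(tr$time_s, 3001)          # 60 s at 20 ms
  # pre-agonist baseline
  expect_equal(tr$bret_ratio[tr$time_s < 10], rep(0.8, 500))
  # half-life check: k_app + k_gap = 0.5/s, value at t_ant + ln2/0.5
  a_decay <- 0.3 * (1 - exp(-0.3 * 20))
  t_half <- 30 + log(2) / 0.5
  idx <- which.min(abs(tr$time_s - t_half))
  expect_equal(tr$bret_ratio[idx], 0.8 + a_decay / 2, tolerance = 1e-3)
  # long after the antagonist the trace returns to baseline
  expect_equal(tr$bret_ratio[3001], 0.8, tolerance = 1e-4)
  # determinism
  tr2 <- simulate_bret_traces(k_act = 0.3, k_app = 0.1, k_gap = 0.4,
                              noise_sd = 0, n_replicates = 1, seed = 1)[[1]]
  expect_identical(tr, tr2)
})

test_that("baseline correction zeroes the pre-agonist window", {
  tr <- simulate_bret_traces(noise_sd = 0, n_replicates = 1, seed = 2)[[1]]
  bc <- baseline_correct(tr)
  expect_lt(abs(mean(bc$bret_ratio[bc$time_s < bc$t_agonist])), 1e-12)
  expect_equal(bc$baseline, 0.8)
  # constant trace maps to all-zero
  flat <- tr
  flat$bret_ratio <- rep(0.55, length(tr$time_s))
  expect_equal(baseline_correct(flat)$bret_ratio,
               rep(0, length(tr$time_s)))
  # noisy trace: post-agonist plateau close to the simulated amplitude
  nz <- simulate_bret_traces(k_act = 0.5, noise_sd = 0.006,
                             n_replicates = 1, seed = 3)[[1]]
  bcn <- baseline_correct(nz)
  plateau <- mean(bcn$bret_ratio[bcn$time_s > 25 & bcn$time_s < 30])
  expect_equal(plateau, 0.3, tolerance = 0.02)
  # insufficient pre-agonist data is an error
  short <- tr
  short$t_agonist <- 0.05
  expect_error(baseline_correct(short), "pre-agonist")
})

test_that("noise-free exponential fits recover k to 1e-6 relative error", {
  for (k in c(0.05, 0.1, 0.5, 1, 2)) {
    fit <- fit_deactivation(decay_trace(k, t_end = 30), window = c(0, 30))
    expect_true(fit$converged)
    expect_lt(abs(fit$k - k) / k, 1e-6)
    expect_equal(fit$tau, 1 / fit$k)
  }
  # via the simulator: baseline-correct then fit, same recovery
  for (k_tot in c(0.05, 0.5, 2)) {
    tr <- simulate_bret_traces(k_app = k_tot, k_gap = 0, noise_sd = 0,
                               n_replicates = 1, duration = 90,
                               seed = 1)[[1]]
    fit <- fit_deactivation(baseline_correct(tr), lag = 0)
    expect_lt(abs(fit$k - k_tot) / k_tot, 1e-6)
  }
})

test_that("fit diagnostics flag degenerate inputs instead of guessing", {
  flat <- decay_trace(0)      # constant at A + C
  f1 <- fit_deactivation(flat, window = c(0, 30))
  expect_false(f1$converged)
  rising <- decay_trace(0.5)
  rising$bret_ratio <- rev(rising$bret_ratio)
  f2 <- fit_deactivation(rising, window = c(0, 30))
  expect_false(f2$converged)
  tiny <- decay_trace(0.5, t_end = 0.1)
  f3 <- fit_deactivation(tiny, window = c(0, 0.1))
  expect_false(f3$converged)
  expect_match(f3$reason, "10 points")
})

test_that("fitted k is invariant to vertical scaling and noisy replicates
           recover the rate", {
  tr <- simulate_bret_traces(k_app = 0.1, k_gap = 0.4, noise_sd = 0.006,
                             n_replicates = 1, seed = 9)[[1]]
  bc <- baseline_correct(tr)
  f1 <- fit_deactivation(bc)
  sc <- bc
  sc$bret_ratio <- sc$bret_ratio * 7.5
  f2 <- fit_deactivation(sc)
  expect_equal(f1$k, f2$k, tolerance = 1e-6)
  # 6 replicates at 2% noise: mean k within 5% of truth (0.5/s)
  fits <- lapply(simulate_bret_traces(k_app = 0.1, k_gap = 0.4,
                                      noise_sd = 0.006, n_replicates = 6,
                                      seed = 10),
                 function(x) fit_deactivation(baseline_correct(x)))
  ks <- vapply(fits, `[[`, 1, "k")
  expect_lt(abs(mean(ks) - 0.5) / 0.5, 0.05)
})

test_that("k_GAP subtraction, antisymmetry and recovery", {
  sim_fits <- function(k_gap, seed, n = 6) {
    lapply(simulate_bret_traces(k_app = 0.1, k_gap = k_gap,
                                noise_sd = 0.006, n_replicates = n,
                                seed = seed,
                                condition = paste0("kgap", k_gap)),
           function(x) fit_deactivation(baseline_correct(x)))
  }
  basal <- sim_fits(0, 21)
  cond <- sim_fits(0.4, 22)
  r <- compute_kgap(cond, basal)
  expect_equal(r$k_gap, r$k_obs - r$k_app)
  expect_equal(r$k_gap, 0.4, tolerance = 3 * r$k_gap_sem + 0.01)
  # identical groups give exactly zero
  r0 <- compute_kgap(basal, basal)
  expect_equal(r0$k_gap, 0)
  # swapping condition and basal negates k_gap
  rs <- compute_kgap(basal, cond)
  expect_equal(rs$k_gap, -r$k_gap)
  expect_equal(rs$k_gap_sem, r$k_gap_sem)
  # non-converged fits are excluded and counted
  broken <- c(cond, list(fit_deactivation(decay_trace(0), c(0, 30))))
  rb <- compute_kgap(broken, basal)
  expect_equal(rb$n_excluded, 1L)
  expect_equal(rb$k_gap, r$k_gap)
  expect_error(compute_kgap(list(fit_deactivation(decay_trace(0), c(0, 30))),
                            basal), "converged")
})

test_that("one-way ANOVA matches stats::oneway.test and a permutation
           reference", {
  set.seed(31)
  groups <- list(a = rnorm(10), b = rnorm(10, 0.8), c = rnorm(10, 0.4))
  res <- anova_oneway(groups)
  ref <- stats::oneway.test(
    values ~ g,
    data = data.frame(values = unlist(groups),
                      g = rep(names(groups), each = 10)),
    var.equal = TRUE)
  expect_equal(res$F, unname(ref$statistic))
  expect_equal(res$p, unname(ref$p.value))
  p_perm <- oracle_permutation_p(groups, n_perm = 1e4, seed = 5)
  expect_lt(abs(res$p - p_perm), 0.02)
  # two groups: F equals the square of the pooled t statistic
  g2 <- groups[1:2]
  t2 <- stats::t.test(g2$a, g2$b, var.equal = TRUE)$statistic
  expect_equal(anova_oneway(g2)$F, unname(t2^2), tolerance = 1e-12)
  # degenerate: identical constants
  expect_equal(anova_oneway(list(x = c(1, 1), y = c(1, 1)))$p, 1)
  expect_equal(anova_oneway(list(x = c(1, 1), y = c(1, 1)))$F, 0)
  expect_equal(anova_oneway(list(x = c(1, 1), y = c(2, 2)))$p, 0)
  expect_error(anova_oneway(list(x = 1:3)), "length")
})

test_that("trace TSV round-trip with JSON sidecar", {
  tr <- simulate_bret_traces(n_replicates = 3, seed = 12,
                             condition = "RGS9-2+Gb5-WT")
  d <- withr::local_tempdir()
  f <- file.path(d, "traces.tsv")
  write_bret_traces(tr, f)
  back <- read_bret_traces(f)
  expect_length(back, 3)
  expect_equal(back[[2]]$bret_ratio, tr[[2]]$bret_ratio, tolerance = 1e-9)
  expect_equal(back[[1]]$t_antagonist, 30)
  expect_equal(back[[1]]$condition, "RGS9-2+Gb5-WT")
})
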