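#' Simulate BRET traces of G-protein activation and deactivation
#'
#' Phenomenological two-phase model of the free-Gbetagamma BRET reporter:
#' flat baseline before agonist addition, saturating rise
#' `amplitude * (1 - exp(-k_act * (t - t_agonist)))` between agonist and
#' antagonist, then single-exponential decay back towards baseline at the
#' observed deactivation rate `k_app + k_gap` after the antagonist.
#' Points are sampled on a fixed grid (default 20 ms, matching
#' plate-reader resolution) with iid Gaussian noise.
#'
#' @param k_act activation rate constant (1/s).
#' @param k_app basal deactivation rate constant (1/s), i.e. without
#'   exogenous RGS GAP complex.
#' @param k_gap GAP-attributable additional deactivation rate (1/s).
#' @param baseline BRET ratio before agonist.
#' @param amplitude asymptotic agonist-driven rise of the BRET ratio.
#' @param t_agonist,t_antagonist,duration event times and total length
#'   (s); require `0 <= t_agonist < t_antagonist < duration`.
#' @param dt sampling interval (s), default 0.02.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param n_replicates number of independent traces.
#' @param condition label attached to each trace.
#' @param seed integer seed.
#' @return List of `bret_trace` objects: each has `time_s`, `bret_ratio`,
#'   `t_agonist`, `t_antagonist`, `condition`.
#' @examples
#' tr <- simulate_bret_traces(k_gap = 0.4, noise_sd = 0, n_replicates = 1)
#' length(tr[[1]]$time_s)  # 3001 samples for 60 s at 20 ms
#' @export
simulate_bret_traces <- function(k_act = 0.3, k_app = 0.1, k_gap = 0,
                                 baseline = 0.8, amplitude = 0.3,
                                 t_agonist = 10, t_antagonist = 30,
                                 duration = 60, dt = 0.02,
                                 noise_sd = 0.006, n_replicates = 6,
                                 condition = "condition", seed = 1L) {
  stopifnot(t_agonist >= 0, t_agonist < t_antagonist,
            t_antagonist < duration, dt > 0, duration > 0,
            k_act >= 0, k_app >= 0, k_gap >= 0, noise_sd >= 0,
            n_replicates >= 1)
  set.seed(as.integer(seed))
  t <- seq(0, duration, by = dt)
  mu <- rep(baseline, length(t))
  rise <- t >= t_agonist & t < t_antagonist
  mu[rise] <- baseline + amplitude * (1 - exp(-k_act * (t[rise] - t_agonist)))
  a_decay <- amplitude * (1 - exp(-k_act * (t_antagonist - t_agonist)))
  fall <- t >= t_antagonist
  mu[fall] <- baseline +
    a_decay * exp(-(k_app + k_gap) * (t[fall] - t_antagonist))
  lapply(seq_len(n_replicates), function(r) {
    structure(list(
      time_s = t,
      bret_ratio = mu + stats::rnorm(length(t), 0, noise_sd),
      t_agonist = t_agonist, t_antagonist = t_antagonist,
      condition = condition),
      class = "bret_trace")
  })
}

#' @export
print.bret_trace <- function(x, ...) {
  cat(sprintf(
    "bret_trace '%s': %d samples, %.3g-%.3g s (agonist %.3g s, antagonist %.3g s)\n",
    x$condition, length(x$time_s), min(x$time_s), max(x$time_s),
    x$t_agonist, x$t_antagonist))
  invisible(x)
}

#' Read and write BRET trace TSV files
#'
#' The TSV holds `time_s` plus one column per replicate; a JSON sidecar
#' (`<path>.json`) records the event times and condition label.
#'
#' @param traces list of `bret_trace` objects sharing a time grid.
#' @param path TSV path (sidecar written next to it).
#' @export
write_bret_traces <- function(traces, path) {
  stopifnot(length(traces) >= 1)
  t <- traces[[1]]$time_s
  tab <- data.frame(time_s = t)
  for (i in seq_along(traces)) {
    stopifnot(identical(traces[[i]]$time_s, t))
    tab[[paste0("rep", i)]] <- traces[[i]]$bret_ratio
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(t_agonist = traces[[1]]$t_agonist,
         t_antagonist = traces[[1]]$t_antagonist,
         condition = traces[[1]]$condition),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bret_traces
#' @export
read_bret_traces <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lapply(setdiff(colnames(tab), "time_s"), function(cn) {
    structure(list(time_s = tab$time_s, bret_ratio = tab[[cn]],
                   t_agonist = meta$t_agonist,
                   t_antagonist = meta$t_antagonist,
                   condition = meta$condition),
              class = "bret_trace")
  })
}
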