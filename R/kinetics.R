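#' Baseline correction of a BRET trace
#'
#' Subtracts the mean of the pre-agonist window from the whole trace,
#' yielding the deltaBRET ratio conventionally plotted and fitted.  At
#' least 5 samples before the agonist are required.
#'
#' @param trace a `bret_trace`.
#' @return the trace with `bret_ratio` replaced by deltaBRET and a
#'   `baseline` field recording the subtracted value.
#' @export
baseline_correct <- function(trace) {
  stopifnot(inherits(trace, "bret_trace"))
  pre <- trace$time_s < trace$t_agonist
  if (sum(pre) < 5) {
    stop("need at least 5 pre-agonist samples for baseline correction")
  }
  b <- mean(trace$bret_ratio[pre])
  trace$bret_ratio <- trace$bret_ratio - b
  trace$baseline <- b
  trace
}

#' Single-exponential fit of the deactivation phase
#'
#' Least-squares fit of `y(t) = A * exp(-k * (t - t0)) + C` over the
#' post-antagonist window, returning the deactivation rate constant
#' `k = 1/tau`.  The window defaults to (t_antagonist + lag, end of
#' trace); the short lag skips mixing dead-time artifacts.  Start values
#' come from the window endpoints and the log-linear slope; fitting uses
#' `nls` (port algorithm, k bounded below by 0).  Degenerate windows
#' (constant or rising signal) and optimizer failures are flagged via
#' `converged = FALSE` rather than returning a spurious rate.
#'
#' @param trace a baseline-corrected `bret_trace`.
#' @param window numeric `(start_s, end_s)` overriding the default.
#' @param lag seconds skipped after the antagonist (default 0.1).
#' @return An `exponential_fit`: list with `k`, `tau`, `A`, `C`, `rss`,
#'   `n_points`, `converged`, `reason`.
#' @export
fit_deactivation <- function(trace, window = NULL, lag = 0.1) {
  stopifnot(inherits(trace, "bret_trace"))
  if (is.null(window)) {
    window <- c(trace$t_antagonist + lag, max(trace$time_s))
  }
  sel <- trace$time_s >= window[1] & trace$time_s <= window[2]
  t <- trace$time_s[sel]
  y <- trace$bret_ratio[sel]
  fail <- function(reason) {
    structure(list(k = NA_real_, tau = NA_real_, A = NA_real_,
                   C = NA_real_, rss = NA_real_, n_points = length(t),
                   converged = FALSE, reason = reason,
                   condition = trace$condition),
              class = "exponential_fit")
  }
  if (length(t) < 10) return(fail("fewer than 10 points in window"))
  if (stats::sd(y) == 0) return(fail("constant signal in window"))
  t0 <- t[1]
  n_tail <- max(5L, round(length(y) * 0.1))
  C0 <- mean(y[(length(y) - n_tail + 1):length(y)])
  A0 <- mean(y[1:min(5L, length(y))]) - C0
  if (A0 <= 0) return(fail("signal does not decay in window"))
  pos <- which(y - C0 > A0 * 0.05)
  k0 <- if (length(pos) > 5) {
    sl <- stats::coef(stats::lm(log(y[pos] - C0) ~ t[pos]))[2]
    max(1e-3, -sl)
  } else 0.5
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-k * (t - t0)) + C,
               start = list(A = A0, k = k0, C = C0),
               algorithm = "port",
               lower = c(A = 0, k = 0, C = -Inf),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nls did not converge"))
  cf <- stats::coef(fit)
  structure(list(k = unname(cf["k"]), tau = 1 / unname(cf["k"]),
                 A = unname(cf["A"]), C = unname(cf["C"]),
                 rss = sum(stats::resid(fit)^2), n_points = length(t),
                 converged = TRUE, reason = NA_character_,
                 condition = trace$condition),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("exponential_fit: k = %.4g 1/s (tau = %.4g s), n = %d\n",
                x$k, x$tau, x$n_points))
  } else {
    cat("exponential_fit: not converged (", x$reason, ")\n")
  }
  invisible(x)
}

#' GAP activity from deactivation rate constants
#'
#' k_GAP quantifies the catalytic effect of an RGS-Gbeta5 complex on
#' G-protein deactivation: the mean deactivation rate measured with the
#' complex minus the mean basal rate (k_app) measured without it.
#' Replicates are fitted individually and aggregated here; the SEM of
#' the difference is propagated as sqrt(SEM_obs^2 + SEM_app^2).
#' Non-converged fits are excluded and counted.
#'
#' @param fits_condition list of `exponential_fit` for the RGS condition.
#' @param fits_basal list of `exponential_fit` for the basal (no-RGS)
#'   condition.
#' @param condition label for the result (default taken from the fits).
#' @return A `kgap_result`: list with `condition`, `k_obs`, `k_app`,
#'   `k_gap`, `sem`, `n`, `n_excluded`, and the per-replicate rates.
#' @export
compute_kgap <- function(fits_condition, fits_basal, condition = NULL) {
  keep <- function(fits) {
    ks <- vapply(fits, function(f) if (isTRUE(f$converged)) f$k else NA_real_,
                 1)
    ks[!is.na(ks)]
  }
  k_obs <- keep(fits_condition)
  k_app <- keep(fits_basal)
  if (!length(k_obs) || !length(k_app)) {
    stop("need at least one converged fit in each group")
  }
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  if (is.null(condition)) {
    condition <- fits_condition[[1]]$condition
    if (is.null(condition)) condition <- "condition"
  }
  structure(list(
    condition = condition,
    k_obs = mean(k_obs), k_obs_sem = sem(k_obs),
    k_app = mean(k_app), k_app_sem = sem(k_app),
    k_gap = mean(k_obs) - mean(k_app),
    k_gap_sem = sqrt(sem(k_obs)^2 + sem(k_app)^2),
    k_obs_replicates = k_obs, k_app_replicates = k_app,
    n = length(k_obs),
    n_excluded = length(fits_condition) + length(fits_basal) -
      length(k_obs) - length(k_app)),
    class = "kgap_result")
}

#' @export
print.kgap_result <- function(x, ...) {
  cat(sprintf("k_GAP (%s): %.4g +/- %.4g 1/s (k_obs %.4g, k_app %.4g, n = %d)\n",
              x$condition, x$k_gap, x$k_gap_sem, x$k_obs, x$k_app, x$n))
  invisible(x)
}

#' Classical one-way ANOVA
#'
#' F = MS_between / MS_within with an F-distribution p-value, across two
#' or more groups of (typically) per-replicate k_GAP values.  The fully
#' degenerate case — zero between-group and zero within-group variance —
#' is reported as F = 0, p = 1; zero within-group variance with distinct
#' means gives F = Inf, p = 0.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return list with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 1L))
  n <- length(x)
  k <- length(groups)
  gm <- mean(x)
  means <- tapply(x, g, mean)
  ssb <- sum(tabulate(g) * (means - gm)^2)
  ssw <- sum((x - means[g])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (ssw == 0 && ssb == 0) return(list(F = 0, p = 1,
                                        df_between = df1, df_within = df2))
  if (ssw == 0) return(list(F = Inf, p = 0,
                            df_between = df1, df_within = df2))
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2)
}

#' Pairwise comparisons against a control group
#'
#' Welch two-sample t-tests of every group against the named control,
#' with Bonferroni correction.  Provided as the package's labeled
#' alternative to Dunnett's post-hoc test (which needs multivariate-t
#' critical values and is out of scope).
#'
#' @param groups named list of numeric vectors.
#' @param control name of the control group.
#' @return data frame with `group`, `estimate` (difference of means),
#'   `p_raw`, `p_bonferroni`.
#' @export
pairwise_vs_basal <- function(groups, control) {
  stopifnot(control %in% names(groups))
  others <- setdiff(names(groups), control)
  res <- do.call(rbind, lapply(others, function(nm) {
    tt <- stats::t.test(groups[[nm]], groups[[control]])
    data.frame(group = nm,
               estimate = mean(groups[[nm]]) - mean(groups[[control]]),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  }))
  res$p_bonferroni <- pmin(1, res$p_raw * length(others))
  res
}

#' Write per-replicate fits and k_GAP results as TSV
#' @param fits list of `exponential_fit`.
#' @param results list of `kgap_result`.
#' @param path output path.
#' @export
write_fits_tsv <- function(fits, path) {
  tab <- do.call(rbind, lapply(fits, function(f) data.frame(
    condition = if (is.null(f$condition)) NA_character_ else f$condition,
    k = f$k, tau = f$tau, A = f$A, C = f$C, rss = f$rss,
    n_points = f$n_points, converged = f$converged,
    stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fits_tsv
#' @export
write_kgap_tsv <- function(results, path) {
  tab <- do.call(rbind, lapply(results, function(r) data.frame(
    condition = r$condition, k_obs = r$k_obs, k_obs_sem = r$k_obs_sem,
    k_app = r$k_app, k_app_sem = r$k_app_sem,
    k_gap = r$k_gap, k_gap_sem = r$k_gap_sem, n = r$n,
    n_excluded = r$n_excluded, stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
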