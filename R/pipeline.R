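#' Default configuration for the mapping pipeline
#'
#' The packaged "study design": the reconstructed consanguineous family,
#' a biallelic SNP panel at 50 kb spacing on the disease chromosome
#' (chr15, 40-70 Mb) plus two 30 Mb background chromosomes at 100 kb,
#' a fully penetrant rare recessive disease model, ROH thresholds
#' (>2 Mb, >=25 homozygous markers, no het tolerance), and an exome of
#' 100 background variants around one causal variant at the disease
#' locus.  Every entry can be overridden via `...`.
#'
#' @param seed integer seed driving all randomness of a run.
#' @param ... named overrides of any default entry.
#' @return A named list (class `run_config`).
#' @export
mapping_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    disease_chrom = "chr15",
    disease_pos_bp = 52400000,
    chr15_range_bp = c(40e6, 70e6),
    chr15_spacing_bp = 50000,
    background_chroms = c("chr1", "chr2"),
    background_length_bp = 30e6,
    background_spacing_bp = 100000,
    founder_allele_freq = 0.5,
    cm_per_mb = 1,
    genotyping_error = 0,
    roh_min_length_bp = 2e6,
    roh_min_markers = 25,
    roh_max_het = 0,
    disease_allele_freq = 1e-4,
    theta_grid = c(0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
    linkage_marker_stride = 20,
    exome_n_background = 100,
    causal_freq = allele_frequency(6, 121000),
    index_id = "V:1",
    maf_threshold = 0.001,
    file_date = "20240101")
  override_config(cfg, list(...))
}

#' Load a configuration from a JSON file
#' @param path JSON file with configuration entries.
#' @param seed optional seed overriding the file's.
#' @return A `run_config` list.
#' @export
read_config <- function(path, seed = NULL) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- override_config(mapping_config(), cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

# whole-entry override (utils::modifyList would merge nested lists
# element-wise and silently skip unnamed ones, e.g. condition lists)
override_config <- function(cfg, overrides) {
  stopifnot(is.list(overrides))
  if (length(overrides)) {
    stopifnot(!is.null(names(overrides)), all(names(overrides) != ""))
    for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  }
  cfg
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg[order(names(cfg))], f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full gene-mapping pipeline
#'
#' Executes the mapping stages in the study's order on a simulated
#' dataset: gene-drop simulation of SNP genotypes conditioned on the
#' affection pattern, per-individual ROH detection, exclusive-sharing
#' interval analysis, parametric LOD scores on a thinned marker panel,
#' exome simulation inside the critical interval, the rare-homozygous
#' variant filter, and the segregation check.  A concordance check
#' asserts that the LOD peak lies inside the exclusive shared interval.
#'
#' @param config a [mapping_config()] list.
#' @return A `mapping_report`: list with `candidate_intervals`,
#'   `linkage` (`linkage_result`), `peak`, `concordant`, `filter`
#'   (a `filter_report`), `segregation`, `truth` and `provenance`.
#' @export
run_mapping <- function(config = mapping_config()) {
  cfg <- config
  ped <- if (is.null(cfg$pedigree)) study_pedigree() else cfg$pedigree
  validate_pedigree(ped)
  if (!any(ped$affected == "yes")) {
    stop("configuration invalid: no affected individuals in the pedigree")
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    message(sprintf("[%s] done in %.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  map <- stage("map", {
    p15 <- seq(cfg$chr15_range_bp[1], cfg$chr15_range_bp[2],
               by = cfg$chr15_spacing_bp)
    pos <- c(list(p15), lapply(cfg$background_chroms, function(ch)
      seq(1e6, 1e6 + cfg$background_length_bp,
          by = cfg$background_spacing_bp)))
    chroms <- c(cfg$disease_chrom, cfg$background_chroms)
    marker_map(
      id = unlist(lapply(seq_along(pos), function(i)
        sprintf("%s_m%04d", chroms[i], seq_along(pos[[i]])))),
      chrom = rep(chroms, lengths(pos)),
      pos_bp = unlist(pos), cm_per_mb = cfg$cm_per_mb)
  })

  sim <- stage("simulate", gene_drop(
    ped, map, founder_allele_freqs = cfg$founder_allele_freq,
    disease_locus = list(chrom = cfg$disease_chrom,
                         pos_bp = cfg$disease_pos_bp),
    genotyping_error = cfg$genotyping_error, seed = cfg$seed))

  az <- stage("roh", autozygomes(
    sim$genotypes, min_length_bp = cfg$roh_min_length_bp,
    min_markers = cfg$roh_min_markers, max_het = cfg$roh_max_het))

  shared <- stage("shared", exclusive_shared_intervals(
    az[affected_ids(ped)], az[unaffected_ids(ped)],
    min_length_bp = cfg$roh_min_length_bp, gm = sim$genotypes))

  linkage <- stage("linkage", {
    keep <- unlist(lapply(split(seq_len(nrow(map)), map$chrom), function(ix)
      ix[seq(1, length(ix), by = cfg$linkage_marker_stride)]))
    gm_thin <- sim$genotypes
    gm_thin$markers <- gm_thin$markers[keep, , drop = FALSE]
    gm_thin$alleles <- gm_thin$alleles[keep]
    gm_thin$freqs <- gm_thin$freqs[keep]
    gm_thin$a1 <- gm_thin$a1[keep, , drop = FALSE]
    gm_thin$a2 <- gm_thin$a2[keep, , drop = FALSE]
    lod_curve(ped, gm_thin,
              model = disease_model(cfg$disease_allele_freq),
              theta_grid = cfg$theta_grid)
  })
  peak <- attr(linkage, "peak")

  in_interval <- nrow(shared) > 0 &
    shared$chrom == peak$chrom &
    shared$start_bp <= peak$pos_bp & shared$end_bp >= peak$pos_bp
  concordant <- any(in_interval)
  critical <- if (concordant) {
    shared[which(in_interval)[1], ]
  } else if (nrow(shared)) {
    shared[which.max(shared$length_bp), ]
  } else NULL

  filter <- segregation <- NULL
  if (!is.null(critical)) {
    exome <- stage("exome", simulate_exome_table(
      ped, critical, n_background = cfg$exome_n_background,
      causal_freq = cfg$causal_freq,
      causal_pos = if (critical$start_bp <= cfg$disease_pos_bp &&
                         critical$end_bp >= cfg$disease_pos_bp)
        cfg$disease_pos_bp else NULL,
      truth = sim$truth, seed = cfg$seed))
    filter <- stage("filter", filter_candidates(
      exome, index_id = cfg$index_id, interval = critical,
      maf_threshold = cfg$maf_threshold))
    segregation <- stage("segregation", lapply(
      seq_len(n_variants(filter$survivors)), function(i)
        check_segregation(filter$survivors, ped, row = i)))
  }

  structure(list(
    candidate_intervals = shared,
    critical_interval = critical,
    linkage = linkage,
    peak = peak,
    concordant = concordant,
    filter = filter,
    segregation = segregation,
    truth = sim$truth,
    genotypes = sim$genotypes,
    provenance = list(seed = cfg$seed, config = cfg,
                      config_hash = config_hash(cfg),
                      package_version =
                        as.character(utils::packageVersion("autozygmap")))),
    class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("Mapping report (seed", x$provenance$seed, ")\n")
  cat(sprintf(" exclusive shared intervals: %d\n",
              nrow(x$candidate_intervals)))
  if (!is.null(x$critical_interval)) {
    ci <- x$critical_interval
    cat(sprintf(" critical interval: %s:%d-%d (%.1f Mb)\n", ci$chrom,
                ci$start_bp, ci$end_bp, ci$length_bp / 1e6))
  }
  cat(sprintf(" LOD peak: %.3f at %s:%d (theta = %.2f)%s\n", x$peak$lod,
              x$peak$chrom, x$peak$pos_bp, x$peak$theta,
              if (x$concordant) ", inside the shared interval" else ""))
  if (!is.null(x$filter)) {
    cat(sprintf(" variants surviving filter: %d of %d\n",
                x$filter$counts["frequency"], x$filter$n_input))
    seg <- vapply(x$segregation, function(s) s$segregates, TRUE)
    cat(sprintf(" segregating candidates: %d\n", sum(seg)))
  }
  invisible(x)
}

#' Serialize and reload a mapping report
#'
#' JSON round-trip of the report's tabular content and provenance (the
#' simulated genotype matrix itself is not serialized).
#'
#' @param report a `mapping_report`.
#' @param path JSON path.
#' @export
write_mapping_report <- function(report, path) {
  seg <- lapply(report$segregation, function(s) list(
    segregates = s$segregates, violations = s$violations,
    untyped = s$untyped))
  out <- list(
    candidate_intervals = report$candidate_intervals,
    critical_interval = report$critical_interval,
    linkage = as.data.frame(report$linkage),
    peak = report$peak,
    concordant = report$concordant,
    filter = if (!is.null(report$filter)) list(
      n_input = report$filter$n_input,
      n_malformed = report$filter$n_malformed,
      counts = as.list(report$filter$counts),
      survivors = report$filter$survivors$variants,
      survivor_geno = as.data.frame(report$filter$survivors$geno)),
    segregation = seg,
    provenance = report$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_mapping_report
#' @export
read_mapping_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Default configuration for the kinetics workflow
#'
#' Three default conditions at paper-scale replication (n = 6): a basal
#' (no exogenous RGS) group, a strong wild-type-like GAP (k_GAP = 0.4/s)
#' and a weak mutant-like GAP (k_GAP = 0.1/s), on a 60 s, 20 ms grid
#' with 2%-of-amplitude Gaussian noise.
#'
#' @param seed integer seed.
#' @param ... named overrides.
#' @return A named list.
#' @export
kinetics_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    k_act = 0.3, k_app = 0.1,
    baseline = 0.8, amplitude = 0.3,
    t_agonist = 10, t_antagonist = 30, duration = 60, dt = 0.02,
    noise_sd = 0.006, n_replicates = 6,
    lag = 0.1,
    conditions = list(
      list(name = "no-RGS", k_gap = 0, basal = TRUE),
      list(name = "RGS9-2+Gb5-S81L", k_gap = 0.1, basal = FALSE),
      list(name = "RGS9-2+Gb5-WT", k_gap = 0.4, basal = FALSE)))
  override_config(cfg, list(...))
}

#' Run the kinetics workflow
#'
#' Simulates (or accepts) BRET traces per condition, baseline-corrects
#' and fits each replicate's deactivation phase, computes k_GAP per
#' condition against the basal group, and compares conditions with a
#' one-way ANOVA on the per-replicate deactivation rate constants.
#'
#' @param config a [kinetics_config()] list.
#' @param traces optional named list of trace lists (one entry per
#'   condition name) replacing simulation.
#' @return list with `kgap` (named list of `kgap_result`), `fits`,
#'   `anova`, and `provenance`.
#' @export
run_kinetics <- function(config = kinetics_config(), traces = NULL) {
  cfg <- config
  conds <- cfg$conditions
  basal_idx <- which(vapply(conds, function(cn) isTRUE(cn$basal), TRUE))
  if (length(basal_idx) != 1) {
    stop("exactly one basal (no-RGS) condition is required")
  }
  if (length(conds) < 2) stop("need at least two conditions")
  if (is.null(traces)) {
    traces <- stats::setNames(lapply(seq_along(conds), function(i) {
      simulate_bret_traces(
        k_act = cfg$k_act, k_app = cfg$k_app, k_gap = conds[[i]]$k_gap,
        baseline = cfg$baseline, amplitude = cfg$amplitude,
        t_agonist = cfg$t_agonist, t_antagonist = cfg$t_antagonist,
        duration = cfg$duration, dt = cfg$dt, noise_sd = cfg$noise_sd,
        n_replicates = cfg$n_replicates, condition = conds[[i]]$name,
        seed = cfg$seed + i)
    }), vapply(conds, function(cn) cn$name, ""))
  }
  fits <- lapply(traces, function(tr) lapply(tr, function(x)
    fit_deactivation(baseline_correct(x), lag = cfg$lag)))
  basal_name <- conds[[basal_idx]]$name
  kgap <- stats::setNames(lapply(names(fits), function(nm)
    compute_kgap(fits[[nm]], fits[[basal_name]], condition = nm)),
    names(fits))
  groups <- lapply(fits, function(fs) {
    ks <- vapply(fs, function(f) if (isTRUE(f$converged)) f$k else NA_real_, 1)
    ks[!is.na(ks)]
  })
  list(kgap = kgap, fits = fits, anova = anova_oneway(groups),
       pairwise = pairwise_vs_basal(groups, basal_name),
       provenance = list(seed = cfg$seed, config_hash = config_hash(cfg),
                         package_version =
                           as.character(utils::packageVersion("autozygmap"))))
}
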