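#' Default pipeline configuration
#'
#' Returns the full nested configuration used by [run_bsa_pipeline()],
#' mirroring the simulator and scan defaults. A YAML file (or list)
#' passed to the pipeline is merged over these defaults, so a config
#' needs to state only what it changes.
#'
#' @return Nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    mode = "simulate+map",
    seed = NULL,
    out_dir = NULL,
    vcf = NULL,
    low_sample = "low_bulk",
    high_sample = "high_bulk",
    genome = NULL,
    cross = list(n_rils = 116, selfing_generations = 10),
    phenotype = list(baseline = 12, animal_sd = 1.5, animals_per_line = 80),
    design = list(n_low = 22, n_high = 24),
    reads = list(mean_depth = 25, base_error = 0.001, gq_value = 60,
                 low_gq_fraction = 0),
    filter = list(gq_min = 40, depth_min_low = 22, depth_min_high = 24),
    map = list(window = 300000, alpha = 0.05, null = "exact",
               trials = 1e6, clamp = 0.5, gap = 0),
    truth_tolerance = 2e6
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' @param path Path to a YAML file whose keys mirror
#'   [default_run_config()].
#' @return The merged configuration list.
#' @export
read_run_config <- function(path) {
  merge_config(default_run_config(), yaml::read_yaml(path))
}

#' Run the simulate/map pipeline end to end
#'
#' Orchestrates the four stages behind one entry point. Modes:
#' `"simulate"` (generate a RIL cross and write its two-bulk VCF,
#' phenotype table and planted-QTL truth), `"map"` (scan an existing VCF),
#' `"simulate+map"` (both, plus a truth-vs-called comparison) and
#' `"calibrate"` (null thresholds only). With `out_dir` set, artifacts are
#' written as plain TSV/BED/VCF; identical seeds give byte-identical
#' outputs.
#'
#' @param config A configuration list (see [default_run_config()]), or a
#'   path to a YAML file.
#' @return An object of class `bsa_report` carrying reconciled record
#'   counts, thresholds, the window and QTL tables, and (in simulation
#'   modes) the truth comparison.
#' @examples
#' \donttest{
#' rep <- run_bsa_pipeline(list(mode = "simulate+map", seed = 1))
#' rep$truth_comparison
#' }
#' @export
run_bsa_pipeline <- function(config = list()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- merge_config(default_run_config(), config)
  mode <- match.arg(cfg$mode, c("simulate", "map", "simulate+map",
                                "calibrate"))
  stochastic <- mode != "map" || identical(cfg$map$null, "mc")
  if (stochastic && is.null(cfg$seed))
    stop("config error: a seed is required for mode '", mode, "'")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(name, writer, obj) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
  }

  design <- bulk_design(cfg$design$n_low, cfg$design$n_high)
  report <- list(mode = mode, seed = cfg$seed, config = cfg)

  if (mode == "calibrate") {
    nd <- if (identical(cfg$map$null, "mc")) {
      null_threshold_mc(design, alpha = cfg$map$alpha,
                        trials = cfg$map$trials, clamp = cfg$map$clamp,
                        seed = cfg$seed)
    } else {
      null_threshold_exact(design, alpha = cfg$map$alpha,
                           clamp = cfg$map$clamp)
    }
    report$null <- nd
    emit("thresholds.tsv", write_tsv,
         data.frame(alpha = nd$alpha, source = nd$source,
                    threshold_low = nd$threshold_low,
                    threshold_high = nd$threshold_high,
                    p_low = nd$p_low, p_high = nd$p_high))
    return(structure(report, class = "bsa_report"))
  }

  sim <- NULL
  if (mode %in% c("simulate", "simulate+map")) {
    map <- if (is.null(cfg$genome)) genome_map() else
      do.call(genome_map, cfg$genome)
    sim <- sim_bsa_cross(
      map = map,
      cross = cross_config(cfg$cross$n_rils, cfg$cross$selfing_generations,
                           forced_regions =
                             if (is.null(cfg$cross$forced_regions))
                               default_forced_regions()
                             else as.data.frame(cfg$cross$forced_regions)),
      model = phenotype_model(cfg$phenotype$baseline,
                              qtls = if (is.null(cfg$phenotype$qtls))
                                default_qtls()
                              else as.data.frame(cfg$phenotype$qtls),
                              animal_sd = cfg$phenotype$animal_sd,
                              animals_per_line =
                                cfg$phenotype$animals_per_line),
      design = design,
      reads = read_sim_config(cfg$reads$mean_depth, cfg$reads$base_error,
                              cfg$reads$gq_value,
                              cfg$reads$low_gq_fraction),
      seed = cfg$seed
    )
    records <- sim$records
    report$truth <- sim$truth
    report$het_before_resolution <- sim$het_before_resolution
    if (!is.null(out_dir)) {
      write_bulk_vcf(records, file.path(out_dir, "bulks.vcf"),
                     cfg$low_sample, cfg$high_sample, map = sim$map)
      write_tsv(sim$phenotypes, file.path(out_dir, "phenotypes.tsv"))
      write_tsv(sim$truth, file.path(out_dir, "truth_qtls.tsv"))
    }
    skip_counts <- c(multiallelic_or_indel = 0L, malformed_ad = 0L,
                     missing_gq = 0L)
  } else {
    if (is.null(cfg$vcf)) stop("config error: mode 'map' needs a vcf path")
    records <- read_bulk_vcf(cfg$vcf, cfg$low_sample, cfg$high_sample)
    skip_counts <- attr(records, "skip_counts")
  }

  if (mode == "simulate") {
    report$counts <- c(n_records = nrow(records))
    return(structure(report, class = "bsa_report"))
  }

  fit <- bsa_scan(records, design = design,
                  filter = filter_config(cfg$filter$gq_min,
                                         cfg$filter$depth_min_low,
                                         cfg$filter$depth_min_high),
                  window = cfg$map$window, alpha = cfg$map$alpha,
                  null = cfg$map$null, trials = cfg$map$trials,
                  clamp = cfg$map$clamp, gap = cfg$map$gap,
                  seed = cfg$seed)
  report$scan <- fit
  report$null <- fit$null
  report$qtls <- fit$qtls
  fc <- fit$filter_counts
  report$counts <- c(
    n_read = fc[["n_in"]] + sum(skip_counts[c("multiallelic_or_indel",
                                              "malformed_ad")]),
    n_skipped = sum(skip_counts[c("multiallelic_or_indel",
                                  "malformed_ad")]),
    n_filtered = fc[["n_in"]] - fc[["n_kept"]],
    n_kept = fc[["n_kept"]]
  )

  if (!is.null(out_dir)) {
    write_tsv(fit$windows, file.path(out_dir, "window_stats.tsv"))
    write_tsv(data.frame(alpha = fit$null$alpha, source = fit$null$source,
                         threshold_low = fit$null$threshold_low,
                         threshold_high = fit$null$threshold_high),
              file.path(out_dir, "thresholds.tsv"))
    write_tsv(fit$qtls, file.path(out_dir, "qtl_intervals.tsv"))
    write_qtl_bed(fit$qtls, file.path(out_dir, "qtl_intervals.bed"))
  }

  if (!is.null(sim) && nrow(sim$truth)) {
    report$truth_comparison <- compare_to_truth(fit$qtls, sim$truth,
                                                tolerance =
                                                  cfg$truth_tolerance)
    emit("truth_comparison.tsv", write_tsv, report$truth_comparison)
  }
  structure(report, class = "bsa_report")
}

#' Score called QTLs against planted truth
#'
#' A planted QTL is a hit when some called interval has the matching sign
#' (+1 for a positive effect: the CB4856 allele raises the phenotype, so
#' the high bulk is CB4856-enriched there) and its peak-window midpoint
#' lies within `tolerance` of the planted position.
#'
#' @param called data.frame from [call_qtls()].
#' @param truth data.frame with columns `chrom`, `pos`, `effect`.
#' @param tolerance Maximum peak-to-truth distance in bp.
#' @return `truth` with added columns `expected_sign`, `hit`,
#'   `peak_distance` (bp, NA when missed).
#' @export
compare_to_truth <- function(called, truth, tolerance = 2e6) {
  truth$expected_sign <- ifelse(truth$effect > 0, 1L, -1L)
  truth$hit <- FALSE
  truth$peak_distance <- NA_real_
  for (i in seq_len(nrow(truth))) {
    cand <- called[called$chrom == truth$chrom[i] &
                     called$sign == truth$expected_sign[i], , drop = FALSE]
    if (!nrow(cand)) next
    peak_mid <- (cand$peak_start + cand$peak_end - 1) / 2
    d <- abs(peak_mid - truth$pos[i])
    if (min(d) <= tolerance) {
      truth$hit[i] <- TRUE
      truth$peak_distance[i] <- min(d)
    }
  }
  truth
}

#' @export
print.bsa_report <- function(x, ...) {
  cat("bulkscan pipeline report — mode:", x$mode,
      if (!is.null(x$seed)) paste(" seed:", x$seed) else "", "\n")
  if (!is.null(x$counts)) {
    cat("  counts:",
        paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$null))
    cat(sprintf("  thresholds: [%.4f, %.4f] (%s, alpha = %g)\n",
                x$null$threshold_low, x$null$threshold_high,
                x$null$source, x$null$alpha))
  if (!is.null(x$qtls)) {
    if (nrow(x$qtls)) {
      cat("  called QTL intervals:\n")
      print(x$qtls, row.names = FALSE, digits = 4)
    } else cat("  called QTL intervals: none\n")
  }
  if (!is.null(x$truth_comparison)) {
    cat("  truth comparison (", sum(x$truth_comparison$hit), "of",
        nrow(x$truth_comparison), "planted QTLs recovered):\n")
    print(x$truth_comparison, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
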