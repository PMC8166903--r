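#' Configuration objects for the RIL cross simulator
#'
#' `cross_config()` describes the construction of the recombinant inbred
#' line (RIL) panel: 116 lines by default, each derived from a single F1
#' heterozygote by `selfing_generations` successive generations of selfing
#' (the first of which produces the F2), so the expected genome fraction
#' still heterozygous before the final coin-flip resolution is
#' `(1/2)^selfing_generations`. `forced_regions` are genomic tracts fixed
#' for one parental ancestry in every line, emulating introgressed markers
#' and incompatibility regions that are invisible to mapping: by default the
#' left arm of I (a parental-incompatibility element), the left arm of IV
#' (the introgressed mutation the cross phenotypes), and the centre of V
#' (the scoring transgene), all fixed for N2.
#'
#' @param n_rils Number of RILs to derive.
#' @param selfing_generations Generations of selfing from the F1.
#' @param forced_regions `NULL`, or a data.frame with columns `chrom`,
#'   `start`, `end`, `ancestry` ("N2" or "CB4856"); the tract (closed
#'   interval, bp) is overwritten in every line.
#' @return A list of class `cross_config`.
#' @export
cross_config <- function(n_rils = 116,
                         selfing_generations = 10,
                         forced_regions = default_forced_regions()) {
  stopifnot(n_rils > 0, selfing_generations >= 1)
  if (!is.null(forced_regions)) {
    stopifnot(all(c("chrom", "start", "end", "ancestry") %in%
                    names(forced_regions)))
    if (any(forced_regions$start < 1) ||
        any(forced_regions$end < forced_regions$start))
      stop("invalid forced region coordinates")
  }
  structure(list(n_rils = as.integer(n_rils),
                 selfing_generations = as.integer(selfing_generations),
                 forced_regions = forced_regions),
            class = "cross_config")
}

#' @rdname cross_config
#' @export
default_forced_regions <- function() {
  data.frame(
    chrom = c("I", "IV", "V"),
    start = c(1, 1, 5e6),
    end = c(3e6, 5e6, 15e6),
    ancestry = "N2",
    stringsAsFactors = FALSE
  )
}

#' Phenotype architecture of the mapped trait
#'
#' The mapped trait is a per-line mean count (seam cell number, SCN). A
#' line's genetic value is `baseline` plus the summed effects of the QTLs
#' whose position the line inherits from CB4856; the observed line mean
#' averages `animals_per_line` animals, each with independent Gaussian
#' noise `animal_sd`. Defaults plant four QTLs on chromosomes II, III, V
#' and X with effects +0.8, +0.8, -0.5 and +0.4 cells, so the favourable
#' alleles (II + III + X) sum to the ~2-cell gap between the parental
#' backgrounds, and the V allele acts in the opposite direction
#' (transgressive segregation).
#'
#' @param baseline Mean SCN of an all-N2 line.
#' @param qtls data.frame with columns `chrom`, `pos`, `effect` (cells added
#'   when the CB4856 allele is present; may be negative).
#' @param animal_sd Per-animal phenotype SD, in cells.
#' @param animals_per_line Animals scored per line (80, the panel's scoring
#'   depth).
#' @return A list of class `phenotype_model`.
#' @export
phenotype_model <- function(baseline = 12,
                            qtls = default_qtls(),
                            animal_sd = 1.5,
                            animals_per_line = 80) {
  stopifnot(animal_sd >= 0, animals_per_line >= 1)
  if (!is.null(qtls))
    stopifnot(all(c("chrom", "pos", "effect") %in% names(qtls)))
  structure(list(baseline = baseline,
                 qtls = qtls,
                 animal_sd = animal_sd,
                 animals_per_line = as.integer(animals_per_line)),
            class = "phenotype_model")
}

#' @rdname phenotype_model
#' @export
default_qtls <- function() {
  data.frame(
    chrom = c("II", "III", "V", "X"),
    pos = c(11.5e6, 10e6, 17.5e6, 5e6),
    effect = c(0.8, 0.8, -0.5, 0.4),
    stringsAsFactors = FALSE
  )
}

#' Bulk design: how many lines enter each phenotypic extreme
#'
#' @param n_low Lines pooled in the low-phenotype bulk (22).
#' @param n_high Lines pooled in the high-phenotype bulk (24).
#' @return A list of class `bulk_design`.
#' @export
bulk_design <- function(n_low = 22, n_high = 24) {
  stopifnot(n_low > 0, n_high > 0)
  structure(list(n_low = as.integer(n_low), n_high = as.integer(n_high)),
            class = "bulk_design")
}

#' Pooled-sequencing read-count model
#'
#' Per SNP and bulk, sequencing depth is Poisson with mean `mean_depth`
#' (25x, the study's target coverage) and the CB4856-allele read count is
#' binomial in the bulk's true CB4856 line fraction, perturbed by a
#' symmetric per-base error `base_error`. Genotype quality is a constant
#' `gq_value` except for a `low_gq_fraction` of SNPs, which draw a low GQ
#' uniformly from `gq_low_range` to exercise the quality filter.
#'
#' @param mean_depth Mean sequencing depth per SNP per bulk.
#' @param base_error Probability a read reports the wrong allele.
#' @param gq_value GQ assigned to well-genotyped SNPs.
#' @param low_gq_fraction Fraction of SNPs given a low GQ instead.
#' @param gq_low_range Integer range (inclusive) for low GQ draws.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(mean_depth = 25,
                            base_error = 0.001,
                            gq_value = 60,
                            low_gq_fraction = 0,
                            gq_low_range = c(0, 39)) {
  stopifnot(mean_depth > 0, base_error >= 0, base_error < 0.5,
            low_gq_fraction >= 0, low_gq_fraction <= 1)
  structure(list(mean_depth = mean_depth, base_error = base_error,
                 gq_value = gq_value, low_gq_fraction = low_gq_fraction,
                 gq_low_range = gq_low_range),
            class = "read_sim_config")
}

# ---------------------------------------------------------------------------

#' Derive a panel of recombinant inbred lines
#'
#' Each line descends from its own F1 heterozygote between the two parents
#' and is carried through `selfing_generations` generations of single-
#' individual selfing (the first meiosis producing the F2). Any interval
#' still heterozygous after the last generation is fixed to one parental
#' ancestry by a fair coin per maximal interval, and `forced_regions` are
#' then overwritten in every line. The realised genome fraction that was
#' heterozygous immediately before resolution is recorded in the
#' `"het_before_resolution"` attribute (averaged over lines).
#'
#' @param config A [cross_config()].
#' @param map A [genome_map()].
#' @return A list of `ril_genome` objects, each `list(line_id, segments)`
#'   where `segments` is a named list (per chromosome) of data.frames with
#'   columns `start`, `end`, `ancestry` partitioning `[1, length]`.
#' @examples
#' map <- genome_map(chrom = "I", length = 1e6)
#' set.seed(1)
#' rils <- make_rils(cross_config(n_rils = 3, forced_regions = NULL), map)
#' rils[[1]]$segments$I
#' @export
make_rils <- function(config = cross_config(), map = genome_map()) {
  stopifnot(inherits(config, "cross_config"), inherits(map, "genome_map"))
  chroms <- map$chromosomes$chrom
  if (!is.null(config$forced_regions)) {
    fr <- config$forced_regions
    for (k in seq_len(nrow(fr))) {
      if (fr$end[k] > chrom_length(map, fr$chrom[k]))
        stop("forced region beyond chromosome ", fr$chrom[k])
    }
  }

  pure <- function(code) {
    h <- lapply(map$chromosomes$length, new_hap, anc = code)
    names(h) <- chroms
    h
  }

  lines <- vector("list", config$n_rils)
  het_frac <- numeric(config$n_rils)
  genome_size <- sum(map$chromosomes$length)

  for (i in seq_len(config$n_rils)) {
    ind <- list(hap1 = pure(ANC_N2), hap2 = pure(ANC_CB))
    for (g in seq_len(config$selfing_generations)) {
      ind <- list(hap1 = simulate_gamete(ind, map),
                  hap2 = simulate_gamete(ind, map))
    }
    het_frac[i] <- sum(vapply(chroms, function(ch) {
      diplotype_het_length(ind$hap1[[ch]], ind$hap2[[ch]])
    }, numeric(1))) / genome_size

    haps <- lapply(chroms, function(ch) {
      resolve_diplotype(ind$hap1[[ch]], ind$hap2[[ch]])
    })
    names(haps) <- chroms

    if (!is.null(config$forced_regions)) {
      fr <- config$forced_regions
      for (k in seq_len(nrow(fr))) {
        haps[[fr$chrom[k]]] <- hap_force(haps[[fr$chrom[k]]],
                                         fr$start[k], fr$end[k],
                                         anc_code(fr$ancestry[k]))
      }
    }

    segs <- lapply(haps, function(h) {
      data.frame(start = c(1, h$end[-length(h$end)] + 1),
                 end = h$end,
                 ancestry = anc_label(h$anc),
                 stringsAsFactors = FALSE)
    })
    lines[[i]] <- structure(list(line_id = i, segments = segs),
                            class = "ril_genome")
  }
  structure(lines, het_before_resolution = mean(het_frac))
}

# overwrite ancestry over the closed interval [from, to]
hap_force <- function(h, from, to, code) {
  L <- h$end[length(h$end)]
  ends <- NULL; ancs <- NULL
  if (from > 1) {
    left <- hap_slice(h, 1, from - 1)
    ends <- left$end; ancs <- left$anc
  }
  ends <- c(ends, to); ancs <- c(ancs, code)
  if (to < L) {
    right <- hap_slice(h, to + 1, L)
    ends <- c(ends, right$end); ancs <- c(ancs, right$anc)
  }
  hap_merge(list(end = ends, anc = ancs))
}

#' Ancestry of a RIL at a position
#'
#' @param line A `ril_genome` from [make_rils()].
#' @param chrom Chromosome name.
#' @param pos 1-based position; must lie within the chromosome.
#' @return `"N2"` or `"CB4856"`.
#' @export
ancestry_at <- function(line, chrom, pos) {
  segs <- line$segments[[chrom]]
  if (is.null(segs)) stop("unknown chromosome: ", chrom)
  L <- segs$end[nrow(segs)]
  if (any(pos < 1 | pos > L)) stop("position outside [1, ", L, "]")
  segs$ancestry[findInterval(pos - 1, segs$end) + 1L]
}

#' Simulate per-line mean phenotypes
#'
#' Each line's mean is the average of `animals_per_line` animal scores,
#' each `baseline + sum(QTL effects carried) + N(0, animal_sd)`.
#'
#' @param lines List of `ril_genome` objects.
#' @param model A [phenotype_model()].
#' @return data.frame with columns `line_id`, `mean_scn`.
#' @export
sim_phenotypes <- function(lines, model = phenotype_model()) {
  stopifnot(inherits(model, "phenotype_model"))
  qtls <- model$qtls
  out <- data.frame(
    line_id = vapply(lines, function(l) l$line_id, numeric(1)),
    mean_scn = NA_real_
  )
  for (i in seq_along(lines)) {
    g <- model$baseline
    if (!is.null(qtls) && nrow(qtls)) {
      carries <- vapply(seq_len(nrow(qtls)), function(k) {
        ancestry_at(lines[[i]], qtls$chrom[k], qtls$pos[k]) == "CB4856"
      }, logical(1))
      g <- g + sum(qtls$effect[carries])
    }
    out$mean_scn[i] <-
      mean(g + stats::rnorm(model$animals_per_line, 0, model$animal_sd))
  }
  out
}

#' Select the phenotypic extreme bulks
#'
#' The `n_low` lines with the smallest means form the low bulk and the
#' `n_high` largest the high bulk; ties are broken by ascending line id, so
#' selection is deterministic given the phenotypes.
#'
#' @param phenotypes data.frame with columns `line_id`, `mean_scn`.
#' @param design A [bulk_design()].
#' @return `list(low = <ids>, high = <ids>)`, disjoint.
#' @export
select_bulks <- function(phenotypes, design = bulk_design()) {
  stopifnot(inherits(design, "bulk_design"))
  n <- nrow(phenotypes)
  if (n < design$n_low + design$n_high)
    stop("need at least n_low + n_high = ", design$n_low + design$n_high,
         " lines, got ", n)
  ord <- order(phenotypes$mean_scn, phenotypes$line_id)
  list(low = phenotypes$line_id[ord[seq_len(design$n_low)]],
       high = phenotypes$line_id[ord[seq(n - design$n_high + 1L, n)]])
}

#' Simulate pooled sequencing read counts for one bulk
#'
#' For each SNP of the map, `q` is the fraction of bulk lines carrying the
#' CB4856 allele; depth is Poisson(`mean_depth`), the CB4856 (alt) read
#' count is binomial with success probability
#' `q (1 - base_error) + (1 - q) base_error`, and GQ follows the configured
#' sampler.
#'
#' @param lines List of `ril_genome` objects pooled in the bulk.
#' @param map A [genome_map()].
#' @param cfg A [read_sim_config()].
#' @return data.frame with columns `chrom`, `pos`, `ref_count`, `alt_count`,
#'   `depth`, `gq`.
#' @export
simulate_bulk_reads <- function(lines, map = genome_map(),
                                cfg = read_sim_config()) {
  if (!length(lines)) stop("empty bulk")
  stopifnot(inherits(cfg, "read_sim_config"))
  chroms <- map$chromosomes$chrom
  res <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    pos <- map$snps[[ch]]
    if (!length(pos)) next
    cb <- rowMeans(vapply(lines, function(l) {
      segs <- l$segments[[ch]]
      segs$ancestry[findInterval(pos - 1, segs$end) + 1L] == "CB4856"
    }, logical(length(pos))))
    n <- length(pos)
    depth <- stats::rpois(n, cfg$mean_depth)
    p <- cb * (1 - cfg$base_error) + (1 - cb) * cfg$base_error
    alt <- stats::rbinom(n, depth, p)
    gq <- rep.int(as.numeric(cfg$gq_value), n)
    if (cfg$low_gq_fraction > 0) {
      lo <- stats::runif(n) < cfg$low_gq_fraction
      gq[lo] <- sample(seq(cfg$gq_low_range[1], cfg$gq_low_range[2]),
                       sum(lo), replace = TRUE)
    }
    res[[ci]] <- data.frame(chrom = ch, pos = pos,
                            ref_count = depth - alt, alt_count = alt,
                            depth = depth, gq = gq,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Simulate a complete bulked-segregant experiment
#'
#' Runs the full generative model: derive the RIL panel, score phenotypes,
#' pick the extreme bulks, and sequence each bulk's pooled DNA. The result
#' bundles the two-bulk SNP table (the input to [bsa_scan()]), the per-line
#' phenotypes with bulk membership, and the planted QTLs as ground truth.
#'
#' @param map A [genome_map()].
#' @param cross A [cross_config()].
#' @param model A [phenotype_model()].
#' @param design A [bulk_design()].
#' @param reads A [read_sim_config()].
#' @param seed Integer seed; required for a reproducible run.
#' @return An object of class `bsa_sim`: list with elements `records`
#'   (two-bulk SNP data.frame as documented in [read_bulk_vcf()]),
#'   `phenotypes` (`line_id`, `mean_scn`, `bulk`), `bulks`, `truth`
#'   (planted QTLs), `lines`, `map`, and `het_before_resolution`.
#' @examples
#' \donttest{
#' sim <- sim_bsa_cross(seed = 1)
#' head(sim$records)
#' }
#' @export
sim_bsa_cross <- function(map = genome_map(),
                          cross = cross_config(),
                          model = phenotype_model(),
                          design = bulk_design(),
                          reads = read_sim_config(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cross$n_rils < design$n_low + design$n_high)
    stop("cross produces fewer lines than the bulk design needs")
  lines <- make_rils(cross, map)
  phen <- sim_phenotypes(lines, model)
  bulks <- select_bulks(phen, design)
  phen$bulk <- "none"
  phen$bulk[phen$line_id %in% bulks$low] <- "low"
  phen$bulk[phen$line_id %in% bulks$high] <- "high"

  low_reads <- simulate_bulk_reads(lines[match(bulks$low, phen$line_id)],
                                   map, reads)
  high_reads <- simulate_bulk_reads(lines[match(bulks$high, phen$line_id)],
                                    map, reads)
  records <- data.frame(
    chrom = low_reads$chrom, pos = low_reads$pos,
    ref = "A", alt = "T",
    ref_low = low_reads$ref_count, alt_low = low_reads$alt_count,
    depth_low = low_reads$depth, gq_low = low_reads$gq,
    ref_high = high_reads$ref_count, alt_high = high_reads$alt_count,
    depth_high = high_reads$depth, gq_high = high_reads$gq,
    stringsAsFactors = FALSE
  )
  truth <- model$qtls
  if (is.null(truth)) truth <- data.frame(chrom = character(),
                                          pos = numeric(),
                                          effect = numeric())
  structure(list(records = records, phenotypes = phen, bulks = bulks,
                 truth = truth, lines = lines, map = map,
                 het_before_resolution =
                   attr(lines, "het_before_resolution"),
                 seed = seed),
            class = "bsa_sim")
}

#' @export
print.bsa_sim <- function(x, ...) {
  cat("Simulated bulked-segregant experiment\n")
  cat("  lines:", length(x$lines),
      " bulks:", length(x$bulks$low), "low /", length(x$bulks$high), "high\n")
  cat("  SNP records:", nrow(x$records), "\n")
  if (nrow(x$truth)) {
    cat("  planted QTLs:\n")
    print(x$truth, row.names = FALSE)
  } else cat("  planted QTLs: none\n")
  invisible(x)
}
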