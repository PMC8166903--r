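# Small in-code fixtures shared across the test files.

# a two-chromosome toy map with sparse markers, for fast cross simulations
toy_map <- function(genetic_length = 50, snp_spacing = 1e5) {
  genome_map(chrom = c("A", "B"), length = c(2e6, 1e6),
             genetic_length = genetic_length, snp_spacing = snp_spacing)
}

# a RIL genome that is a single ancestry block per chromosome
make_line <- function(map, ancestry, line_id = 1L) {
  ancestry <- rep_len(ancestry, nrow(map$chromosomes))
  segs <- lapply(seq_len(nrow(map$chromosomes)), function(i) {
    data.frame(start = 1, end = map$chromosomes$length[i],
               ancestry = ancestry[i], stringsAsFactors = FALSE)
  })
  names(segs) <- map$chromosomes$chrom
  structure(list(line_id = line_id, segments = segs), class = "ril_genome")
}

# deterministic two-bulk SNP record table with a known mix of GQ and depth
# violations, used by the filter and VCF round-trip tests
fixture_records <- function(n = 100, seed = 404) {
  set.seed(seed)
  depth_low <- rpois(n, 30)
  depth_high <- rpois(n, 30)
  alt_low <- rbinom(n, depth_low, 0.5)
  alt_high <- rbinom(n, depth_high, 0.5)
  rec <- data.frame(
    chrom = rep(c("A", "B"), each = n / 2),
    pos = rep(seq(1e4, by = 1e4, length.out = n / 2), 2),
    ref = "A", alt = "T",
    ref_low = depth_low - alt_low, alt_low = alt_low,
    depth_low = depth_low, gq_low = sample(c(60, 45, 39, 10), n, TRUE),
    ref_high = depth_high - alt_high, alt_high = alt_high,
    depth_high = depth_high, gq_high = sample(c(60, 45, 39, 10), n, TRUE),
    stringsAsFactors = FALSE
  )
  # plant some depth violations
  k <- min(20L, ceiling(n / 5))
  low_idx <- sample(n, k)
  rec$depth_low[low_idx] <- sample(0:21, k, TRUE)
  rec$alt_low[low_idx] <- pmin(rec$alt_low[low_idx], rec$depth_low[low_idx])
  rec$ref_low[low_idx] <- rec$depth_low[low_idx] - rec$alt_low[low_idx]
  high_idx <- sample(n, k)
  rec$depth_high[high_idx] <- sample(0:23, k, TRUE)
  rec$alt_high[high_idx] <- pmin(rec$alt_high[high_idx],
                                 rec$depth_high[high_idx])
  rec$ref_high[high_idx] <- rec$depth_high[high_idx] - rec$alt_high[high_idx]
  rec
}

# brute-force filter recount, written independently of filter_snps()
brute_force_survivors <- function(rec, gq_min = 40, dmin_l = 22,
                                  dmin_h = 24) {
  n <- 0L
  for (i in seq_len(nrow(rec))) {
    if (rec$gq_low[i] >= gq_min && rec$gq_high[i] >= gq_min &&
        rec$depth_low[i] >= dmin_l && rec$depth_high[i] >= dmin_h)
      n <- n + 1L
  }
  n
}
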