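# Internal haplotype mosaic machinery.
#
# A haplotype for one chromosome is a run-length mosaic stored as
#   list(end = <integer vector of segment end positions, ascending,
#               last element = chromosome length>,
#        anc = <integer vector, 0 = N2, 1 = CB4856>)
# Segments are closed intervals: segment i covers (end[i-1], end[i]],
# i.e. positions end[i-1]+1 .. end[i]; the first starts at 1.

ANC_N2 <- 0L
ANC_CB <- 1L

anc_label <- function(code) c("N2", "CB4856")[code + 1L]
anc_code <- function(label) {
  code <- match(label, c("N2", "CB4856")) - 1L
  if (anyNA(code)) stop("ancestry must be 'N2' or 'CB4856'")
  code
}

new_hap <- function(L, anc) list(end = as.numeric(L), anc = as.integer(anc))

# collapse adjacent runs with equal ancestry
hap_merge <- function(h) {
  if (length(h$anc) <= 1L) return(h)
  keep <- c(h$anc[-1L] != h$anc[-length(h$anc)], TRUE)
  list(end = h$end[keep], anc = h$anc[keep])
}

# ancestry code at position pos (1-based); pos must lie in [1, L]
hap_at <- function(h, pos) {
  h$anc[findInterval(pos - 1L, h$end) + 1L]
}

# sub-mosaic covering positions [from, to], as (end, anc) runs
hap_slice <- function(h, from, to) {
  i <- findInterval(from - 1L, h$end) + 1L
  j <- findInterval(to - 1L, h$end) + 1L
  end <- h$end[i:j]
  end[length(end)] <- to
  list(end = end, anc = h$anc[i:j])
}

# recombine two haplotypes at integer cut positions: positions <= cuts[1]
# come from the haplotype selected by `first` (1 or 2), then the source
# alternates after every cut. cuts must be sorted, unique, in [1, L-1].
hap_recombine <- function(hapA, hapB, cuts, first) {
  L <- hapA$end[length(hapA$end)]
  if (!length(cuts)) return(if (first == 1L) hapA else hapB)
  src <- list(hapA, hapB)
  bounds <- c(0, cuts, L)
  ends <- NULL
  ancs <- NULL
  cur <- first
  for (k in seq_len(length(bounds) - 1L)) {
    piece <- hap_slice(src[[cur]], bounds[k] + 1L, bounds[k + 1L])
    ends <- c(ends, piece$end)
    ancs <- c(ancs, piece$anc)
    cur <- 3L - cur
  }
  hap_merge(list(end = ends, anc = ancs))
}

# genome fraction where the two haplotypes of a diplotype differ
diplotype_het_length <- function(hap1, hap2) {
  ends <- sort(unique(c(hap1$end, hap2$end)))
  starts <- c(0, ends[-length(ends)])
  a1 <- hap_at(hap1, starts + 1L)
  a2 <- hap_at(hap2, starts + 1L)
  sum((ends - starts)[a1 != a2])
}

# collapse a diplotype into a single homozygous mosaic: homozygous runs keep
# their ancestry; each maximal heterozygous run is fixed by a fair coin.
resolve_diplotype <- function(hap1, hap2) {
  ends <- sort(unique(c(hap1$end, hap2$end)))
  starts <- c(0, ends[-length(ends)])
  a1 <- hap_at(hap1, starts + 1L)
  a2 <- hap_at(hap2, starts + 1L)
  het <- a1 != a2
  anc <- a1
  if (any(het)) {
    # identify maximal runs of heterozygous intervals
    r <- rle(het)
    idx_end <- cumsum(r$lengths)
    idx_start <- idx_end - r$lengths + 1L
    for (k in which(r$values)) {
      anc[idx_start[k]:idx_end[k]] <-
        if (stats::runif(1) < 0.5) ANC_N2 else ANC_CB
    }
  }
  hap_merge(list(end = ends, anc = anc))
}

#' Simulate one gamete from a heterozygous individual
#'
#' Performs one meiosis per chromosome under a no-interference crossover
#' model: the number of crossovers is Poisson with mean equal to the genetic
#' length in Morgans (cM/100), and breakpoints are placed uniformly on the
#' genetic map, projected to physical coordinates (the default map is
#' uniform, so breakpoints are uniform in bp).
#'
#' @param diplotype A list with elements `hap1` and `hap2`, each a named
#'   list (one element per chromosome) of internal haplotype mosaics, as
#'   produced by [make_rils()] internals.
#' @param map A [genome_map()].
#' @return A named list of haplotype mosaics, one per chromosome of `map`.
#' @keywords internal
simulate_gamete <- function(diplotype, map) {
  chroms <- map$chromosomes$chrom
  if (!all(chroms %in% names(diplotype$hap1)) ||
      !all(chroms %in% names(diplotype$hap2)))
    stop("diplotype does not cover all chromosomes of the map")
  out <- vector("list", length(chroms))
  names(out) <- chroms
  for (i in seq_along(chroms)) {
    ch <- chroms[i]
    L <- map$chromosomes$length[i]
    morgans <- map$chromosomes$genetic_length[i] / 100
    n_x <- stats::rpois(1L, morgans)
    first <- if (stats::runif(1) < 0.5) 1L else 2L
    if (n_x == 0L) {
      out[[i]] <- if (first == 1L) diplotype$hap1[[ch]] else diplotype$hap2[[ch]]
    } else {
      cuts <- sort(unique(floor(stats::runif(n_x, min = 1, max = L))))
      cuts <- cuts[cuts >= 1 & cuts < L]
      out[[i]] <- hap_recombine(diplotype$hap1[[ch]], diplotype$hap2[[ch]],
                                cuts, first)
    }
  }
  out
}
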