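#' Genome map for a two-parent cross
#'
#' Describes the chromosomes of the cross (physical length in bp, genetic
#' length in cM) and the positions of the SNPs that distinguish the two
#' parental strains. The default map approximates the six *C. elegans*
#' chromosomes with one diagnostic SNP every 10 kb, the marker density at
#' which an N2 x CB4856 cross is typically scored.
#'
#' @param chrom Character vector of chromosome names.
#' @param length Numeric vector of physical lengths in bp (same order).
#' @param genetic_length Numeric vector of genetic lengths in cM. Recycled if
#'   length 1.
#' @param snp_positions Optional named list (one element per chromosome) of
#'   strictly increasing 1-based SNP positions. If `NULL`, positions are laid
#'   out every `snp_spacing` bp.
#' @param snp_spacing Spacing in bp used to generate default SNP positions.
#'
#' @return An object of class `genome_map`: a list with elements
#'   `chromosomes` (data.frame with columns `chrom`, `length`, `genetic_length`)
#'   and `snps` (named list of integer position vectors).
#' @examples
#' map <- genome_map()
#' map$chromosomes
#' @export
genome_map <- function(chrom = c("I", "II", "III", "IV", "V", "X"),
                       length = c(15.1e6, 15.3e6, 13.8e6, 17.5e6, 20.9e6, 17.7e6),
                       genetic_length = 50,
                       snp_positions = NULL,
                       snp_spacing = 10000) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("duplicated chromosome names")
  if (length(length) != length(chrom))
    stop("'length' must have one entry per chromosome")
  genetic_length <- rep_len(genetic_length, length(chrom))
  if (any(length <= 0)) stop("physical lengths must be > 0")
  if (any(genetic_length < 0)) stop("genetic lengths must be >= 0")

  if (is.null(snp_positions)) {
    snp_positions <- lapply(length, function(L) {
      as.integer(seq(snp_spacing, floor(L), by = snp_spacing))
    })
    names(snp_positions) <- chrom
  } else {
    if (!all(chrom %in% names(snp_positions)))
      stop("'snp_positions' must have an entry for every chromosome")
    snp_positions <- snp_positions[chrom]
  }

  map <- structure(
    list(
      chromosomes = data.frame(
        chrom = chrom,
        length = as.numeric(length),
        genetic_length = as.numeric(genetic_length),
        stringsAsFactors = FALSE
      ),
      snps = snp_positions
    ),
    class = "genome_map"
  )
  validate_genome_map(map)
  map
}

validate_genome_map <- function(map) {
  stopifnot(inherits(map, "genome_map"))
  chr <- map$chromosomes
  for (i in seq_len(nrow(chr))) {
    p <- map$snps[[chr$chrom[i]]]
    if (length(p)) {
      if (any(diff(p) <= 0))
        stop("SNP positions on chromosome ", chr$chrom[i],
             " are not strictly increasing")
      if (p[1] < 1 || p[length(p)] > chr$length[i])
        stop("SNP positions on chromosome ", chr$chrom[i],
             " fall outside [1, length]")
    }
  }
  invisible(map)
}

chrom_length <- function(map, chrom) {
  i <- match(chrom, map$chromosomes$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  map$chromosomes$length[i]
}

#' @export
print.genome_map <- function(x, ...) {
  cat("Genome map:", nrow(x$chromosomes), "chromosomes,",
      sum(lengths(x$snps)), "SNPs\n")
  df <- x$chromosomes
  df$n_snps <- lengths(x$snps)[df$chrom]
  print(df, row.names = FALSE)
  invisible(x)
}
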