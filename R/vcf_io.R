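# Two-bulk SNP tables move through the package as a plain data.frame with
# columns: chrom, pos, ref, alt, ref_low, alt_low, depth_low, gq_low,
# ref_high, alt_high, depth_high, gq_high. The alt allele is the
# CB4856-specific allele; VCFs supplied in real mode must already be
# polarised that way.

#' Read a two-bulk VCF into a SNP record table
#'
#' Parses a VCF whose two sample columns are the pooled low- and
#' high-phenotype bulks, keeping only biallelic SNPs genotyped in both
#' samples. Per-bulk depth is recomputed as the sum of that sample's AD
#' (allelic depth) entries — the same quantity whose ratio gives the allele
#' frequency — rather than taken from DP. Records missing GQ in a sample
#' are kept with GQ 0, so the standard quality filter removes them;
#' multiallelic, indel and malformed-AD records are skipped and counted.
#'
#' @param path Path to a VCF (plain text or gzipped).
#' @param low_sample,high_sample Sample column names for the two bulks.
#' @return data.frame of SNP records in (chrom, pos) order, with a
#'   `"skip_counts"` attribute (`multiallelic_or_indel`, `malformed_ad`,
#'   `missing_gq`).
#' @export
read_bulk_vcf <- function(path, low_sample = "low_bulk",
                          high_sample = "high_bulk") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  empty <- data.frame(chrom = character(), pos = numeric(),
                      ref = character(), alt = character(),
                      ref_low = numeric(), alt_low = numeric(),
                      depth_low = numeric(), gq_low = numeric(),
                      ref_high = numeric(), alt_high = numeric(),
                      depth_high = numeric(), gq_high = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0) {
    attr(empty, "skip_counts") <- c(multiallelic_or_indel = 0L,
                                    malformed_ad = 0L, missing_gq = 0L)
    return(empty)
  }
  samples <- colnames(vcf@gt)[-1]
  if (!all(c(low_sample, high_sample) %in% samples))
    stop("sample(s) not found in VCF: ",
         paste(setdiff(c(low_sample, high_sample), samples), collapse = ", "))

  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  biallelic_snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_multi <- sum(!biallelic_snp)

  ad <- vcfR::extract.gt(vcf, element = "AD")
  gq <- suppressWarnings(vcfR::extract.gt(vcf, element = "GQ",
                                          as.numeric = TRUE))

  parse_ad <- function(x) {
    # returns matrix with rows (ref, alt, depth); NA row where malformed
    parts <- strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
    t(vapply(parts, function(p) {
      v <- suppressWarnings(as.numeric(p))
      if (length(v) < 2 || anyNA(v)) return(c(NA_real_, NA_real_, NA_real_))
      c(v[1], v[2], sum(v))
    }, numeric(3)))
  }
  ad_low <- parse_ad(ad[, low_sample])
  ad_high <- parse_ad(ad[, high_sample])
  ok_ad <- !is.na(ad_low[, 1]) & !is.na(ad_high[, 1])
  n_bad_ad <- sum(biallelic_snp & !ok_ad)
  if (n_bad_ad > 0)
    warning(n_bad_ad, " record(s) skipped for malformed AD")

  gq_low <- gq[, low_sample]; gq_high <- gq[, high_sample]
  n_missing_gq <- sum(biallelic_snp & ok_ad &
                        (is.na(gq_low) | is.na(gq_high)))
  gq_low[is.na(gq_low)] <- 0
  gq_high[is.na(gq_high)] <- 0

  keep <- biallelic_snp & ok_ad
  out <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.numeric(fix[keep, "POS"]),
    ref = ref[keep], alt = alt[keep],
    ref_low = ad_low[keep, 1], alt_low = ad_low[keep, 2],
    depth_low = ad_low[keep, 3], gq_low = gq_low[keep],
    ref_high = ad_high[keep, 1], alt_high = ad_high[keep, 2],
    depth_high = ad_high[keep, 3], gq_high = gq_high[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(match(out$chrom, unique(out$chrom)), out$pos), ]
  rownames(out) <- NULL
  attr(out, "skip_counts") <- c(multiallelic_or_indel = n_multi,
                                malformed_ad = n_bad_ad,
                                missing_gq = n_missing_gq)
  out
}

#' Write a two-bulk SNP record table as VCF 4.2
#'
#' Emits one body line per record with FORMAT `GT:AD:DP:GQ`. The GT field
#' carries diploid missing-or-homozygous calls consistent with the pooled
#' counts (`0/0` when only reference reads, `1/1` when only alternate,
#' `./.` for a mixed or empty pool — a pooled bulk has no meaningful
#' diploid genotype). Contig header lines come from `map` when supplied,
#' otherwise from the largest position seen per chromosome.
#'
#' @param records SNP record table sorted by (chrom, pos).
#' @param path Output path.
#' @param low_sample,high_sample Sample column names.
#' @param map Optional [genome_map()] supplying contig lengths.
#' @return `path`, invisibly.
#' @export
write_bulk_vcf <- function(records, path, low_sample = "low_bulk",
                           high_sample = "high_bulk", map = NULL) {
  if (nrow(records)) {
    o <- order(match(records$chrom, unique(records$chrom)), records$pos)
    if (is.unsorted(o)) stop("records must be sorted by (chrom, pos)")
  }
  if (!is.null(map)) {
    contigs <- sprintf("##contig=<ID=%s,length=%d>",
                       map$chromosomes$chrom,
                       as.integer(map$chromosomes$length))
  } else if (nrow(records)) {
    lens <- tapply(records$pos, factor(records$chrom,
                                       levels = unique(records$chrom)), max)
    contigs <- sprintf("##contig=<ID=%s,length=%d>",
                       names(lens), as.integer(lens))
  } else contigs <- character()

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bulkscan",
    contigs,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", low_sample, high_sample, sep = "\t")
  )
  body <- character()
  if (nrow(records)) {
    gt_call <- function(ref_n, alt_n) {
      ifelse(ref_n > 0 & alt_n == 0, "0/0",
             ifelse(alt_n > 0 & ref_n == 0, "1/1", "./."))
    }
    fmt <- function(ref_n, alt_n, gq) {
      sprintf("%s:%d,%d:%d:%d", gt_call(ref_n, alt_n),
              as.integer(ref_n), as.integer(alt_n),
              as.integer(ref_n + alt_n), as.integer(gq))
    }
    body <- paste(records$chrom, format(records$pos, scientific = FALSE,
                                        trim = TRUE),
                  ".", records$ref, records$alt, ".", ".", ".",
                  "GT:AD:DP:GQ",
                  fmt(records$ref_low, records$alt_low, records$gq_low),
                  fmt(records$ref_high, records$alt_high, records$gq_high),
                  sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write called QTL intervals as BED6
#'
#' Coordinates follow the BED convention (0-based, half-open): the BED
#' start is the 1-based interval start minus one. The name field is
#' `chrom:sign`, the score scales the peak absolute log-odds (250 units
#' per log10, capped at 1000), and the strand encodes the sign.
#'
#' @param intervals data.frame from [call_qtls()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qtl_bed <- function(intervals, path) {
  lines <- character()
  if (nrow(intervals)) {
    lines <- paste(
      intervals$chrom,
      format(intervals$start - 1, scientific = FALSE, trim = TRUE),
      format(intervals$end - 1, scientific = FALSE, trim = TRUE),
      paste0(intervals$chrom, ":", ifelse(intervals$sign > 0, "+", "-")),
      pmin(1000L, as.integer(round(250 * abs(intervals$peak_log_odds)))),
      ifelse(intervals$sign > 0, "+", "-"),
      sep = "\t"
    )
  }
  writeLines(lines, path, sep = if (length(lines)) "\n" else "")
  invisible(path)
}

# plain TSV writer shared by the pipeline artifacts
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
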