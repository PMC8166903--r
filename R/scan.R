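#' Bulked-segregant QTL scan
#'
#' The package's central fit: from a two-bulk SNP record table it (i)
#' discards low-quality and low-depth SNPs, (ii) computes per-SNP CB4856
#' allele frequencies in each bulk, (iii) averages them in non-overlapping
#' 300-kb windows and evaluates the bulk-scaled [log_odds()] statistic,
#' (iv) derives the genome-wide two-tailed significance thresholds from
#' the Bernoulli null (exactly enumerated by default, or by Monte-Carlo
#' simulation), and (v) merges runs of significant windows into QTL
#' intervals. Positive log-odds means the high bulk is CB4856-enriched at
#' that window; negative means the low bulk is.
#'
#' @param records Two-bulk SNP data.frame as returned by [read_bulk_vcf()]
#'   or found in `sim_bsa_cross()$records`.
#' @param design A [bulk_design()] giving the pooled line counts.
#' @param filter A [filter_config()].
#' @param window Window size in bp.
#' @param alpha Two-tailed genome-wide significance level.
#' @param null `"exact"` (enumeration) or `"mc"` (Monte-Carlo, the
#'   procedure's original form); both use the same clamped statistic and
#'   agree to within Monte-Carlo error.
#' @param trials Monte-Carlo trials when `null = "mc"`.
#' @param clamp Boundary clamp of the statistic, in line-equivalents.
#' @param gap Allowed non-significant windows inside one QTL interval.
#' @param seed Seed for the Monte-Carlo null (ignored for `"exact"`).
#' @return An object of class `bsa_scan` with components `windows`
#'   (windowed statistics), `null` (thresholds), `qtls` (called
#'   intervals), `freq` (per-SNP frequencies), `filter_counts`, `design`,
#'   and the call parameters.
#' @examples
#' \donttest{
#' sim <- sim_bsa_cross(seed = 1)
#' fit <- bsa_scan(sim$records)
#' summary(fit)
#' }
#' @seealso [sim_bsa_cross()] to generate input, [compare_to_truth()] to
#'   score recovery of planted QTLs.
#' @export
bsa_scan <- function(records,
                     design = bulk_design(),
                     filter = filter_config(),
                     window = 300000,
                     alpha = 0.05,
                     null = c("exact", "mc"),
                     trials = 1e6,
                     clamp = 0.5,
                     gap = 0,
                     seed = NULL) {
  null <- match.arg(null)
  kept <- filter_snps(records, filter)
  counts <- attr(kept, "filter_counts")
  freq <- cb_allele_frequency(kept)
  windows <- window_stats(freq, window = window, design = design,
                          clamp = clamp)
  nd <- if (null == "exact") {
    null_threshold_exact(design, alpha = alpha, clamp = clamp)
  } else {
    null_threshold_mc(design, alpha = alpha, trials = trials,
                      clamp = clamp, seed = seed)
  }
  qtls <- call_qtls(windows, nd, gap = gap)
  structure(list(windows = windows, null = nd, qtls = qtls, freq = freq,
                 filter_counts = counts, design = design,
                 window = window, alpha = alpha, clamp = clamp,
                 gap = gap, call = match.call()),
            class = "bsa_scan")
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat("Bulked-segregant QTL scan\n")
  cat(sprintf("  SNPs: %d in, %d kept after GQ/depth filters\n",
              x$filter_counts[["n_in"]], x$filter_counts[["n_kept"]]))
  cat(sprintf("  windows: %d of %g kb (bulks: %d low, %d high)\n",
              nrow(x$windows), x$window / 1000,
              x$design$n_low, x$design$n_high))
  cat(sprintf("  thresholds (alpha = %g, %s null): [%.4f, %.4f]\n",
              x$alpha, x$null$source,
              x$null$threshold_low, x$null$threshold_high))
  if (nrow(x$qtls)) {
    cat("  QTL intervals:\n")
    print(x$qtls, row.names = FALSE, digits = 4)
  } else cat("  QTL intervals: none\n")
  invisible(x)
}

#' @export
summary.bsa_scan <- function(object, ...) {
  w <- object$windows
  per_chrom <- do.call(rbind, lapply(split(w, factor(w$chrom,
                                                     unique(w$chrom))),
                                     function(d) {
    data.frame(chrom = d$chrom[1], n_windows = nrow(d),
               n_snps = sum(d$n_snps),
               max_log_odds = max(d$log_odds),
               min_log_odds = min(d$log_odds),
               n_significant = sum(d$log_odds > object$null$threshold_high |
                                     d$log_odds < object$null$threshold_low),
               stringsAsFactors = FALSE)
  }))
  rownames(per_chrom) <- NULL
  structure(list(scan = object, per_chrom = per_chrom),
            class = "summary.bsa_scan")
}

#' @export
print.summary.bsa_scan <- function(x, ...) {
  print(x$scan)
  cat("\nPer-chromosome window summary:\n")
  print(x$per_chrom, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.bsa_scan <- function(x, ...) x$windows

#' Plot a bulked-segregant scan
#'
#' Draws either the windowed log-odds track with the genome-wide
#' significance thresholds (`type = "logodds"`) or the per-SNP bulk allele
#' frequencies with LOESS-smoothed curves (`type = "freq"`), one panel per
#' chromosome, base graphics.
#'
#' @param x A `bsa_scan`.
#' @param type `"logodds"` or `"freq"`.
#' @param chrom Chromosomes to draw (default: all present).
#' @param span LOESS span for `type = "freq"`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bsa_scan <- function(x, type = c("logodds", "freq"), chrom = NULL,
                          span = 0.1, ...) {
  type <- match.arg(type)
  chroms <- unique(x$windows$chrom)
  if (!is.null(chrom)) chroms <- intersect(chroms, chrom)
  if (!length(chroms)) stop("no chromosomes to plot")
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(chroms)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (ch in chroms) {
    if (type == "logodds") {
      w <- x$windows[x$windows$chrom == ch, ]
      mid <- (w$start + w$end - 1) / 2 / 1e6
      ylim <- range(c(w$log_odds, x$null$threshold_low,
                      x$null$threshold_high))
      graphics::plot(mid, w$log_odds, type = "l",
                     xlab = "position (Mb)", ylab = "log-odds",
                     main = ch, ylim = ylim, ...)
      graphics::abline(h = c(x$null$threshold_low, x$null$threshold_high),
                       lty = 2, col = "blue")
      graphics::abline(h = 0, col = "grey")
      q <- x$qtls[x$qtls$chrom == ch, ]
      if (nrow(q))
        graphics::rect((q$start - 1) / 1e6, ylim[1], (q$end - 1) / 1e6,
                       ylim[2], col = grDevices::adjustcolor("red", 0.15),
                       border = NA)
    } else {
      f <- x$freq[x$freq$chrom == ch, ]
      graphics::plot(f$pos / 1e6, f$freq_low, pch = ".", col = "darkgreen",
                     ylim = c(0, 1), xlab = "position (Mb)",
                     ylab = "CB4856 allele frequency", main = ch, ...)
      graphics::points(f$pos / 1e6, f$freq_high, pch = ".", col = "orange")
      if (nrow(f) >= 10 && span * nrow(f) >= 3) {
        graphics::lines(f$pos / 1e6, loess_curve(f$pos, f$freq_low, span),
                        col = "darkgreen", lwd = 2)
        graphics::lines(f$pos / 1e6, loess_curve(f$pos, f$freq_high, span),
                        col = "orange", lwd = 2)
      }
      graphics::abline(h = 0.5, col = "grey")
    }
  }
  invisible(x)
}
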