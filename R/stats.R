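#' Quality and depth filter settings
#'
#' SNPs are discarded when either bulk's genotype quality falls below
#' `gq_min` (phred scale, default 40) or a bulk's total read depth falls
#' below its bulk-specific minimum (defaults 22 for the low bulk and 24 for
#' the high bulk, i.e. one read per pooled line). Equality passes: the
#' cutoffs discard values strictly below the minimum.
#'
#' @param gq_min Minimum GQ required in both bulks.
#' @param depth_min_low,depth_min_high Minimum read depth per bulk.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(gq_min = 40, depth_min_low = 22,
                          depth_min_high = 24) {
  stopifnot(gq_min >= 0, depth_min_low >= 0, depth_min_high >= 0)
  structure(list(gq_min = gq_min, depth_min_low = depth_min_low,
                 depth_min_high = depth_min_high),
            class = "filter_config")
}

#' Filter SNP records on genotype quality and depth
#'
#' Keeps exactly the records with `gq_low >= gq_min`, `gq_high >= gq_min`,
#' `depth_low >= depth_min_low` and `depth_high >= depth_min_high`,
#' preserving order. Per-criterion failure counts (not mutually exclusive)
#' are attached as the `"filter_counts"` attribute.
#'
#' @param records Two-bulk SNP data.frame (see [read_bulk_vcf()]).
#' @param cfg A [filter_config()].
#' @return The surviving rows, with a `filter_counts` attribute.
#' @export
filter_snps <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  fail_gq <- records$gq_low < cfg$gq_min | records$gq_high < cfg$gq_min
  fail_dl <- records$depth_low < cfg$depth_min_low
  fail_dh <- records$depth_high < cfg$depth_min_high
  keep <- !(fail_gq | fail_dl | fail_dh)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(
    n_in = nrow(records),
    fail_gq = sum(fail_gq),
    fail_depth_low = sum(fail_dl),
    fail_depth_high = sum(fail_dh),
    n_kept = sum(keep)
  )
  out
}

#' Per-SNP CB4856 allele frequencies in each bulk
#'
#' The frequency in a bulk is the CB4856 (alt) read count divided by the
#' total read count at that SNP in that bulk.
#'
#' @param records Filtered two-bulk SNP data.frame.
#' @return data.frame with columns `chrom`, `pos`, `freq_low`, `freq_high`.
#' @export
cb_allele_frequency <- function(records) {
  tot_low <- records$alt_low + records$ref_low
  tot_high <- records$alt_high + records$ref_high
  if (any(tot_low == 0) || any(tot_high == 0))
    stop("zero total read count in a bulk; filter records on depth first")
  data.frame(chrom = records$chrom, pos = records$pos,
             freq_low = records$alt_low / tot_low,
             freq_high = records$alt_high / tot_high,
             stringsAsFactors = FALSE)
}

#' Bulk-scaled log-odds statistic
#'
#' The mapping statistic compares CB4856 allele frequencies between the two
#' bulks on the scale of pooled lines. With `l` and `h` the window-mean
#' frequencies multiplied by the bulk sizes `n_l` and `n_h`
#' (line-equivalents), the statistic is
#' \deqn{\log_{10}\left(\frac{h/(n_h - h)}{l/(n_l - l)}\right)}
#' positive when the high bulk is CB4856-enriched. Because the raw formula
#' diverges at the boundaries (`l` or `h` equal to 0 or the bulk size),
#' `l` and `h` are clamped `clamp` line-equivalents away from the
#' boundaries before evaluation; interior values are untouched, so the
#' statistic equals the raw formula wherever that is finite.
#'
#' @param l,h Scaled line-equivalents, vectors of equal length.
#' @param n_l,n_h Bulk sizes (lines).
#' @param clamp Boundary clamp in line-equivalents.
#' @return Numeric vector of log10 odds ratios, always finite.
#' @examples
#' log_odds(0.25 * 22, 0.75 * 24)  # log10(9)
#' @export
log_odds <- function(l, h, n_l = 22, n_h = 24, clamp = 0.5) {
  if (n_l <= 2 * clamp || n_h <= 2 * clamp)
    stop("bulk sizes must exceed twice the clamp")
  if (any(l < 0 | l > n_l) || any(h < 0 | h > n_h))
    stop("l must lie in [0, n_l] and h in [0, n_h]")
  lc <- pmin(pmax(l, clamp), n_l - clamp)
  hc <- pmin(pmax(h, clamp), n_h - clamp)
  log10((hc / (n_h - hc)) / (lc / (n_l - lc)))
}

#' Windowed bulk-frequency statistics
#'
#' Tiles each chromosome with non-overlapping windows of `window` bp
#' anchored at position 1 (window k covers `[1 + k w, 1 + (k+1) w)`),
#' averages the per-SNP bulk frequencies within each window (unweighted),
#' scales the means by the bulk sizes, and evaluates the [log_odds()]
#' statistic. Windows containing no SNPs are omitted.
#'
#' @param points data.frame from [cb_allele_frequency()], sorted by
#'   chromosome then position.
#' @param window Window size in bp.
#' @param design A [bulk_design()].
#' @param clamp Boundary clamp passed to [log_odds()].
#' @return data.frame with columns `chrom`, `start`, `end` (half-open),
#'   `n_snps`, `mean_freq_low`, `mean_freq_high`, `l`, `h`, `log_odds`.
#' @export
window_stats <- function(points, window = 300000, design = bulk_design(),
                         clamp = 0.5) {
  stopifnot(inherits(design, "bulk_design"), window > 0)
  if (!nrow(points))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      mean_freq_low = numeric(), mean_freq_high = numeric(),
                      l = numeric(), h = numeric(), log_odds = numeric(),
                      stringsAsFactors = FALSE))
  chrom_f <- factor(points$chrom, levels = unique(points$chrom))
  if (is.unsorted(order(as.integer(chrom_f), points$pos)))
    stop("points must be sorted by (chrom, pos)")
  k <- (points$pos - 1) %/% window
  key <- interaction(chrom_f, k, drop = TRUE, lex.order = TRUE)
  agg <- data.frame(
    chrom = as.character(tapply(as.character(points$chrom), key, `[`, 1)),
    k = as.numeric(tapply(k, key, `[`, 1)),
    n_snps = as.integer(tapply(points$pos, key, length)),
    mean_freq_low = as.numeric(tapply(points$freq_low, key, mean)),
    mean_freq_high = as.numeric(tapply(points$freq_high, key, mean)),
    stringsAsFactors = FALSE
  )
  agg <- agg[order(match(agg$chrom, levels(chrom_f)), agg$k), ]
  out <- data.frame(
    chrom = agg$chrom,
    start = 1 + agg$k * window,
    end = 1 + (agg$k + 1) * window,
    n_snps = agg$n_snps,
    mean_freq_low = agg$mean_freq_low,
    mean_freq_high = agg$mean_freq_high,
    stringsAsFactors = FALSE
  )
  out$l <- out$mean_freq_low * design$n_low
  out$h <- out$mean_freq_high * design$n_high
  out$log_odds <- log_odds(out$l, out$h, design$n_low, design$n_high, clamp)
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------

new_bsa_null <- function(source, threshold_low, threshold_high, alpha,
                         p_low, p_high, ...) {
  structure(list(source = source,
                 threshold_low = threshold_low,
                 threshold_high = threshold_high,
                 alpha = alpha, p_low = p_low, p_high = p_high, ...),
            class = "bsa_null")
}

#' Monte-Carlo genome-wide significance threshold
#'
#' Simulates the null hypothesis of no frequency difference between bulks:
#' per trial, `l ~ Binomial(n_l, 1/2)` and `h ~ Binomial(n_h, 1/2)`
#' independently (one fair Bernoulli per pooled line), and the clamped
#' [log_odds()] statistic is evaluated. The two-tailed genome-wide
#' thresholds at level `alpha` are the order statistics
#' `ceiling(alpha/2 * trials)` from each tail, so the empirical mass
#' strictly beyond each threshold is at most `alpha/2`.
#'
#' @param design A [bulk_design()].
#' @param alpha Two-tailed significance level.
#' @param trials Number of simulated null windows (one million, the
#'   procedure's standard).
#' @param clamp Boundary clamp passed to [log_odds()].
#' @param seed Optional integer seed.
#' @return An object of class `bsa_null` with elements `threshold_low`,
#'   `threshold_high`, `alpha`, `p_low`/`p_high` (empirical tail mass
#'   strictly beyond each threshold), `trials`, `seed`.
#' @export
null_threshold_mc <- function(design = bulk_design(), alpha = 0.05,
                              trials = 1e6, clamp = 0.5, seed = NULL) {
  stopifnot(trials >= 1000, alpha > 0, alpha <= 1)
  if (!is.null(seed)) set.seed(seed)
  l <- stats::rbinom(trials, design$n_low, 0.5)
  h <- stats::rbinom(trials, design$n_high, 0.5)
  stat <- sort(log_odds(l, h, design$n_low, design$n_high, clamp))
  k <- ceiling(alpha / 2 * trials)
  threshold_low <- stat[k]
  threshold_high <- stat[trials - k + 1L]
  new_bsa_null("monte_carlo", threshold_low, threshold_high, alpha,
               p_low = mean(stat < threshold_low),
               p_high = mean(stat > threshold_high),
               trials = trials, seed = seed, design = design, clamp = clamp)
}

#' Exact genome-wide significance threshold by enumeration
#'
#' The null statistic takes finitely many values: `l` ranges over
#' `0..n_l` and `h` over `0..n_h`, with independent Binomial(n, 1/2)
#' probabilities, so the full null pmf of the clamped [log_odds()]
#' statistic can be enumerated. Thresholds are conservative: the smallest
#' statistic value whose strict upper tail mass is at most `alpha/2` (and
#' symmetrically for the lower tail).
#'
#' @inheritParams null_threshold_mc
#' @return An object of class `bsa_null` with the exact pmf in `values` /
#'   `probs` and exact strict tail masses `p_low`, `p_high`.
#' @export
null_threshold_exact <- function(design = bulk_design(), alpha = 0.05,
                                 clamp = 0.5) {
  stopifnot(alpha > 0, alpha <= 1)
  n_l <- design$n_low; n_h <- design$n_high
  l <- 0:n_l; h <- 0:n_h
  pl <- stats::dbinom(l, n_l, 0.5)
  ph <- stats::dbinom(h, n_h, 0.5)
  stat <- outer(h, l, function(hh, ll) log_odds(ll, hh, n_l, n_h, clamp))
  prob <- outer(ph, pl)
  o <- order(stat)
  v <- as.vector(stat)[o]
  p <- as.vector(prob)[o]
  grp <- cumsum(!duplicated(signif(v, 12)))
  values <- tapply(v, grp, `[`, 1)
  probs <- tapply(p, grp, sum)
  values <- as.numeric(values); probs <- as.numeric(probs)

  upper <- rev(cumsum(rev(probs))) - probs   # P(stat > values[i])
  lower <- cumsum(probs) - probs             # P(stat < values[i])
  i_hi <- which(upper <= alpha / 2)[1]
  i_lo <- max(which(lower <= alpha / 2))
  new_bsa_null("exact",
               threshold_low = values[i_lo], threshold_high = values[i_hi],
               alpha = alpha,
               p_low = lower[i_lo], p_high = upper[i_hi],
               values = values, probs = probs, design = design,
               clamp = clamp)
}

#' @export
print.bsa_null <- function(x, ...) {
  cat("Null distribution of the bulk log-odds statistic (",
      x$source, ")\n", sep = "")
  cat(sprintf("  two-tailed alpha = %g thresholds: [%.6f, %.6f]\n",
              x$alpha, x$threshold_low, x$threshold_high))
  cat(sprintf("  tail mass beyond thresholds: %.6f (low) + %.6f (high)\n",
              x$p_low, x$p_high))
  if (identical(x$source, "monte_carlo"))
    cat("  trials:", format(x$trials, big.mark = ","),
        if (!is.null(x$seed)) paste(" seed:", x$seed) else "", "\n")
  invisible(x)
}

#' Call QTL intervals from windowed statistics
#'
#' A window is significant with sign +1 when its log-odds exceeds the upper
#' threshold (high bulk CB4856-enriched) and sign -1 when it falls below
#' the lower threshold. Maximal runs of same-sign significant windows are
#' merged into one interval; a run tolerates at most `gap` intervening
#' non-significant windows (default 0; windows omitted for containing no
#' SNPs never break a run). The peak is the member window with the largest
#' absolute log-odds, ties going to the leftmost.
#'
#' @param stats Windowed statistics from [window_stats()], sorted by
#'   chromosome then start.
#' @param null A `bsa_null` from [null_threshold_mc()] or
#'   [null_threshold_exact()].
#' @param gap Allowed number of intervening non-significant windows.
#' @return data.frame with columns `chrom`, `start`, `end`, `sign`,
#'   `n_windows` (significant member windows), `peak_start`, `peak_end`,
#'   `peak_log_odds`.
#' @export
call_qtls <- function(stats, null, gap = 0) {
  stopifnot(inherits(null, "bsa_null"))
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), sign = integer(),
                      n_windows = integer(), peak_start = numeric(),
                      peak_end = numeric(), peak_log_odds = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(stats)) return(empty)
  sgn <- integer(nrow(stats))
  sgn[stats$log_odds > null$threshold_high] <- 1L
  sgn[stats$log_odds < null$threshold_low] <- -1L

  out <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    m <- cur$rows
    peak <- m[which.max(abs(stats$log_odds[m]))]
    data.frame(chrom = stats$chrom[m[1]],
               start = stats$start[m[1]],
               end = stats$end[m[length(m)]],
               sign = cur$sign,
               n_windows = length(m),
               peak_start = stats$start[peak],
               peak_end = stats$end[peak],
               peak_log_odds = stats$log_odds[peak],
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(stats))) {
    if (!is.null(cur) && stats$chrom[i] != cur$chrom) {
      out[[length(out) + 1L]] <- flush(cur); cur <- NULL
    }
    if (sgn[i] == 0L) {
      if (!is.null(cur)) {
        cur$gaps <- cur$gaps + 1L
        if (cur$gaps > gap) { out[[length(out) + 1L]] <- flush(cur); cur <- NULL }
      }
    } else if (is.null(cur)) {
      cur <- list(chrom = stats$chrom[i], sign = sgn[i], rows = i, gaps = 0L)
    } else if (sgn[i] == cur$sign) {
      cur$rows <- c(cur$rows, i); cur$gaps <- 0L
    } else {
      out[[length(out) + 1L]] <- flush(cur)
      cur <- list(chrom = stats$chrom[i], sign = sgn[i], rows = i, gaps = 0L)
    }
  }
  out[[length(out) + 1L]] <- flush(cur)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' LOESS-smoothed allele-frequency curve
#'
#' Fits a locally weighted linear regression (tricube weights, span 0.1 of
#' the points) of frequency on position and returns the fitted value at
#' every input position. Used for frequency-track reporting and plots,
#' never for QTL inference.
#'
#' @param pos Numeric vector of SNP positions (one chromosome).
#' @param freq Allele frequencies at those positions (one bulk).
#' @param span LOESS span (fraction of points in each local fit).
#' @return Numeric vector of fitted frequencies, same length as `pos`.
#' @export
loess_curve <- function(pos, freq, span = 0.1) {
  n <- length(pos)
  if (n != length(freq)) stop("pos and freq lengths differ")
  if (n < 10) stop("need at least 10 points to smooth")
  if (span * n < 3) stop("span * n must be at least 3")
  fit <- stats::loess(freq ~ pos, span = span, degree = 1,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  as.numeric(stats::predict(fit, data.frame(pos = pos)))
}
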