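test_that("the GQ/depth filter applies the study cutoffs at their boundaries", {
  rec <- fixture_records(4)
  rec$gq_low <- c(39, 60, 60, 60)
  rec$gq_high <- c(60, 40, 60, 60)
  rec$depth_low <- c(30, 30, 22, 21)
  rec$depth_high <- c(30, 30, 24, 30)
  kept <- filter_snps(rec)
  # GQ 39 removed (< 40 discarded); GQ 40 and depth 22/24 equality kept
  expect_equal(kept$pos, rec$pos[2:3])
  counts <- attr(kept, "filter_counts")
  expect_equal(counts[["n_in"]], 4)
  expect_equal(counts[["n_kept"]], 2)
  expect_equal(counts[["fail_gq"]], 1)
  expect_equal(counts[["fail_depth_low"]], 1)
})

test_that("filter survivors match a brute-force recount and are monotone in thresholds", {
  rec <- fixture_records(100)
  kept <- filter_snps(rec)
  expect_equal(nrow(kept), brute_force_survivors(rec))
  expect_equal(attr(kept, "filter_counts")[["n_kept"]], nrow(kept))
  # raising any threshold never increases survivors
  base <- nrow(kept)
  for (gq in c(40, 45, 50, 61)) {
    for (dl in c(22, 25, 31)) {
      for (dh in c(24, 26, 31)) {
        n <- nrow(filter_snps(rec, filter_config(gq, dl, dh)))
        expect_equal(n, brute_force_survivors(rec, gq, dl, dh))
        expect_lte(n, base)
      }
    }
  }
  surv_gq <- vapply(c(0, 10, 39, 40, 41, 60, 61),
                    function(g) nrow(filter_snps(rec, filter_config(gq_min = g))),
                    numeric(1))
  expect_true(all(diff(surv_gq) <= 0))
})

test_that("bulk allele frequency is the CB read fraction", {
  rec <- fixture_records(4)
  rec$ref_low <- c(30, 25, 12, 0); rec$alt_low <- c(10, 0, 13, 10)
  rec$ref_high <- c(10, 10, 12, 5); rec$alt_high <- c(10, 10, 13, 15)
  fp <- cb_allele_frequency(rec)
  expect_equal(fp$freq_low, c(0.25, 0, 0.52, 1))
  expect_equal(fp$freq_high, c(0.5, 0.5, 0.52, 0.75))
  rec$alt_high[1] <- 0; rec$ref_high[1] <- 0
  expect_error(cb_allele_frequency(rec), "zero total")
})

test_that("the log-odds statistic matches its closed form and is antisymmetric", {
  # worked value: window means 0.25 and 0.75 give log10(9)
  expect_equal(log_odds(0.25 * 22, 0.75 * 24), log10(9), tolerance = 1e-12)
  # equal window means give exactly zero
  expect_identical(log_odds(0.5 * 22, 0.5 * 24), 0)
  # antisymmetry: swapping the bulks negates the statistic
  set.seed(50)
  l <- runif(200, 0, 22); h <- runif(200, 0, 24)
  expect_equal(log_odds(l, h, 22, 24), -log_odds(h, l, 24, 22))
  # boundary values are clamped, never infinite, and match the clamped form
  expect_equal(log_odds(0, 24, 22, 24),
               log10((23.5 / 0.5) / (0.5 / 21.5)))
  expect_true(all(is.finite(log_odds(c(0, 22), c(0, 24)))))
  # interior values are untouched by the clamp
  expect_equal(log_odds(5.5, 18), log10((18 / 6) / (5.5 / 16.5)))
  expect_error(log_odds(0.2, 0.2, n_l = 1, n_h = 24), "clamp")
})

test_that("window statistics tile from position 1 and average in-window SNPs", {
  pts <- data.frame(chrom = "A", pos = c(1e5, 2.5e5, 4e5),
                    freq_low = c(0.2, 0.4, 0.9),
                    freq_high = c(0.6, 0.8, 0.1), stringsAsFactors = FALSE)
  w <- window_stats(pts)
  expect_equal(nrow(w), 2)
  expect_equal(w$start, c(1, 300001))
  expect_equal(w$end, c(300001, 600001))
  expect_equal(w$n_snps, c(2L, 1L))
  expect_equal(w$mean_freq_low, c(0.3, 0.9))
  expect_equal(w$mean_freq_high, c(0.7, 0.1))
  expect_equal(w$l, w$mean_freq_low * 22)
  expect_equal(w$h, w$mean_freq_high * 24)

  # symmetric frequencies give l = 11, h = 12, log-odds 0
  sym <- data.frame(chrom = "A", pos = 1e5, freq_low = 0.5, freq_high = 0.5)
  ws <- window_stats(sym)
  expect_equal(ws$l, 11)
  expect_equal(ws$h, 12)
  expect_identical(ws$log_odds, 0)

  expect_error(window_stats(pts[c(3, 1, 2), ]), "sorted")
})

test_that("window means equal a brute-force recount on a random fixture", {
  set.seed(51)
  pts <- data.frame(
    chrom = rep(c("A", "B"), c(120, 80)),
    pos = c(sort(sample(1e6, 120)), sort(sample(7e5, 80))),
    freq_low = runif(200), freq_high = runif(200),
    stringsAsFactors = FALSE
  )
  w <- window_stats(pts, window = 1e5)
  for (i in seq_len(nrow(w))) {
    in_w <- pts$chrom == w$chrom[i] & pts$pos >= w$start[i] &
      pts$pos < w$end[i]
    expect_equal(w$n_snps[i], sum(in_w))
    expect_equal(w$mean_freq_low[i], mean(pts$freq_low[in_w]))
    expect_equal(w$mean_freq_high[i], mean(pts$freq_high[in_w]))
    expect_equal(w$log_odds[i], log_odds(w$l[i], w$h[i]))
  }
  # every SNP lands in exactly one emitted window
  expect_equal(sum(w$n_snps), nrow(pts))
})

test_that("the exact null enumeration is a normalised pmf with conservative thresholds", {
  nd <- null_threshold_exact()
  expect_equal(sum(nd$probs), 1, tolerance = 1e-12)
  expect_lte(nd$threshold_low, 0)
  expect_gte(nd$threshold_high, 0)
  # strict tail mass beyond each threshold is at most alpha/2 ...
  expect_lte(sum(nd$probs[nd$values > nd$threshold_high]), 0.025)
  expect_lte(sum(nd$probs[nd$values < nd$threshold_low]), 0.025)
  expect_equal(sum(nd$probs[nd$values > nd$threshold_high]), nd$p_high)
  # ... and the next atom inwards would violate it
  below <- max(nd$values[nd$values < nd$threshold_high])
  expect_gt(sum(nd$probs[nd$values > below]), 0.025)
})

test_that("the exact null for two-line bulks matches a hand enumeration", {
  nd <- null_threshold_exact(bulk_design(2, 2), alpha = 0.5)
  # independent oracle: loop over all (l, h) outcomes directly
  vals <- c(); probs <- c()
  for (l in 0:2) {
    for (h in 0:2) {
      lc <- min(max(l, 0.5), 1.5); hc <- min(max(h, 0.5), 1.5)
      vals <- c(vals, log10((hc / (2 - hc)) / (lc / (2 - lc))))
      probs <- c(probs, dbinom(l, 2, 0.5) * dbinom(h, 2, 0.5))
    }
  }
  o <- order(vals)
  agg <- tapply(probs[o], cumsum(!duplicated(round(vals[o], 9))), sum)
  uv <- vals[o][!duplicated(round(vals[o], 9))]
  expect_equal(nd$values, unname(uv), tolerance = 1e-9)
  expect_equal(nd$probs, unname(as.numeric(agg)), tolerance = 1e-12)
  # conservative threshold reproduced from the hand pmf
  upper <- vapply(uv, function(v) sum(probs[vals > v + 1e-12]), numeric(1))
  expect_equal(nd$threshold_high, min(uv[upper <= 0.25]), tolerance = 1e-9)
})

test_that("Monte-Carlo thresholds are symmetric and reproducible", {
  a <- null_threshold_mc(trials = 5e4, seed = 60)
  b <- null_threshold_mc(trials = 5e4, seed = 60)
  expect_identical(a$threshold_low, b$threshold_low)
  expect_identical(a$threshold_high, b$threshold_high)
  # the null statistic is symmetric about zero
  expect_lt(abs(a$threshold_low + a$threshold_high), 0.05)
  expect_lte(a$p_low, 0.025)
  expect_lte(a$p_high, 0.025)
  # degenerate level: both thresholds collapse to the median
  m <- null_threshold_mc(alpha = 1, trials = 5e4, seed = 61)
  expect_lt(abs(m$threshold_low), 0.06)
  expect_lt(abs(m$threshold_high), 0.06)
  expect_lte(m$threshold_low, m$threshold_high)
})

test_that("QTL calling merges same-sign runs and splits on sign or gaps", {
  nd <- list(threshold_low = -1, threshold_high = 1, alpha = 0.05,
             source = "exact", p_low = 0.02, p_high = 0.02)
  class(nd) <- "bsa_null"
  mkw <- function(chrom, k, lod) {
    data.frame(chrom = chrom, start = 1 + k * 3e5, end = 1 + (k + 1) * 3e5,
               n_snps = 10L, mean_freq_low = 0.5, mean_freq_high = 0.5,
               l = 11, h = 12, log_odds = lod, stringsAsFactors = FALSE)
  }
  # nothing beyond thresholds: empty call set
  w0 <- do.call(rbind, lapply(0:4, function(k) mkw("III", k, 0.5)))
  expect_equal(nrow(call_qtls(w0, nd)), 0)

  # windows 3..5 significant, same sign: one interval with the max peak
  lods <- c(0.2, 0.1, 0.2, 1.5, 2.0, 1.4, 0.3)
  w1 <- do.call(rbind, lapply(0:6, function(k) mkw("III", k, lods[k + 1])))
  q1 <- call_qtls(w1, nd)
  expect_equal(nrow(q1), 1)
  expect_equal(q1$start, w1$start[4])
  expect_equal(q1$end, w1$end[6])
  expect_equal(q1$n_windows, 3L)
  expect_equal(q1$peak_start, w1$start[5])
  expect_equal(q1$peak_log_odds, 2.0)
  expect_equal(q1$sign, 1L)

  # adjacent opposite-sign significant windows are separate intervals
  w2 <- rbind(mkw("V", 0, 1.5), mkw("V", 1, -1.5))
  q2 <- call_qtls(w2, nd)
  expect_equal(q2$sign, c(1L, -1L))
  expect_equal(nrow(q2), 2)

  # a single non-significant window breaks a run unless gap allows it
  w3 <- rbind(mkw("X", 0, 1.5), mkw("X", 1, 0.2), mkw("X", 2, 1.5))
  expect_equal(nrow(call_qtls(w3, nd, gap = 0)), 2)
  q3 <- call_qtls(w3, nd, gap = 1)
  expect_equal(nrow(q3), 1)
  expect_equal(q3$n_windows, 2L)

  # runs never merge across chromosomes
  w4 <- rbind(mkw("II", 0, 1.5), mkw("III", 0, 1.5))
  expect_equal(nrow(call_qtls(w4, nd)), 2)

  # peak ties go to the leftmost window
  w5 <- rbind(mkw("IV", 0, 1.5), mkw("IV", 1, 1.5))
  expect_equal(call_qtls(w5, nd)$peak_start, w5$start[1])
})

test_that("LOESS smoothing reproduces constants and exact lines", {
  pos <- seq(1e4, 1e6, by = 1e4)
  # constant input is reproduced
  fit <- loess_curve(pos, rep(0.4, length(pos)), span = 0.1)
  expect_equal(fit, rep(0.4, length(pos)), tolerance = 1e-9)
  # collinear input: the local linear fit is exact
  y <- 0.1 + 3e-7 * pos
  expect_equal(loess_curve(pos, y, span = 0.2), y, tolerance = 1e-8)
  # deterministic: identical calls give identical output
  set.seed(70)
  yr <- y + rnorm(length(pos), 0, 0.05)
  expect_identical(loess_curve(pos, yr), loess_curve(pos, yr))
  expect_error(loess_curve(1:5, rnorm(5)), "at least 10")
  expect_error(loess_curve(1:20, rnorm(20), span = 0.05), "span")
})
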