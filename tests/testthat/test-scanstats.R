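# helper: a freq_table built directly from frequency/count matrices
mk_freqs <- function(p_hp, p_lp, n_hp, n_lp, pos = NULL, chrom = NULL,
                     chrom_len = NULL) {
  S <- length(p_hp)
  pos <- pos %||% (seq_len(S) * 100L)
  chrom <- chrom %||% rep("chr1", S)
  k <- cbind(HP = p_hp * n_hp, LP = p_lp * n_lp)
  structure(list(p = cbind(HP = p_hp, LP = p_lp),
                 n = cbind(HP = rep(n_hp, S), LP = rep(n_lp, S)), k = k,
                 chrom = chrom, pos = as.integer(pos), pops = c("HP", "LP"),
                 chrom_len = chrom_len %||% c(chr1 = max(pos))),
            class = "freq_table")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

mk_windows <- function(freqs, width = 1000) {
  hap <- toy_hap(matrix(0:1, 2, length(freqs$pos)), pos = freqs$pos,
                 chrom = freqs$chrom,
                 chrom_len = freqs$chrom_len)
  make_windows(hap, "tile", width = width)
}

test_that("per-SNP AFD matches its definition and endpoints", {
  expect_equal(afd(0.9, 0.1), 0.8)
  expect_equal(afd(0.5, 0.5), 0)
  expect_equal(afd(1, 0), 1)
  expect_equal(afd(0, 1), 1)
  set.seed(1)
  p1 <- runif(200); p2 <- runif(200)
  expect_equal(afd(p1, p2), afd_bf(p1, p2), tolerance = 1e-12)
})

test_that("window_afd filters low-SNP windows and caps the cutoff at 0.5", {
  # 10 windows of 10 SNPs, one window with only 5 river-variant SNPs
  set.seed(2)
  p_hp <- runif(100, 0.2, 0.8)
  p_lp <- runif(100, 0.2, 0.8)
  p_hp[41:45] <- 0; p_lp[41:45] <- 0          # invariants in window 5
  p_hp[46:50] <- 0.9; p_lp[46:50] <- 0.1      # 5 variant SNPs remain
  fr <- mk_freqs(p_hp, p_lp, 40, 40)
  w <- mk_windows(fr)
  res <- window_afd(fr, w, "HP", "LP", min_snps = 6L)
  expect_equal(res$n_var[5], 5)
  expect_false(res$eligible[5])
  expect_false(res$outlier[5])                # never flagged despite AFD 0.8
  expect_equal(res$median_afd[5], 0.8)
  # cutoff is min(q95, 0.5)
  thr <- attr(res, "threshold")
  expect_lte(thr, 0.5)
  q95 <- quantile(res$median_afd[res$eligible], 0.95, names = FALSE)
  expect_equal(thr, min(q95, 0.5))
})

test_that("windowed Hudson FST matches a site-by-site oracle", {
  set.seed(3)
  S <- 20L
  p1 <- runif(S, 0.05, 0.95); p2 <- runif(S, 0.05, 0.95)
  fr <- mk_freqs(p1, p2, 20, 20, pos = seq_len(S) * 10L)
  w <- mk_windows(fr, width = 1000)
  expect_equal(nrow(w), 1L)
  res <- hudson_fst(fr, w, "HP", "LP")
  oracle <- hudson_bf(p1, p2, rep(20, S), rep(20, S))
  expect_equal(res$fst[1], oracle$ratio, tolerance = 1e-12)
})

test_that("Hudson FST endpoints behave", {
  # no differentiation, large n: per-window value near 0
  fr <- mk_freqs(rep(0.5, 50), rep(0.5, 50), 100, 100)
  w <- mk_windows(fr, width = 10000)
  res <- hudson_fst(fr, w, "HP", "LP")
  expect_lt(abs(res$fst[1]), 0.05)
  # fixed difference: exactly 1
  fr2 <- mk_freqs(rep(1, 10), rep(0, 10), 20, 20)
  res2 <- hudson_fst(fr2, mk_windows(fr2, width = 10000), "HP", "LP")
  expect_equal(res2$fst[1], 1)
})

test_that("pod_threshold honours quantile contracts and determinism", {
  set.seed(4)
  p1 <- runif(400, 0.1, 0.9); p2 <- pmin(pmax(p1 + rnorm(400, 0, 0.1), 0), 1)
  fr <- mk_freqs(p1, p2, 30, 30)
  w <- mk_windows(fr)
  f <- hudson_fst(fr, w, "HP", "LP")
  expect_error(pod_threshold(f, n_pod = 50), ">= 100")
  t1 <- pod_threshold(f, n_pod = 2000, seed = 5)
  t2 <- pod_threshold(f, n_pod = 2000, seed = 5)
  expect_identical(as.numeric(t1), as.numeric(t2))
  # q = 1 gives the POD maximum; threshold is monotone in q
  t_max <- pod_threshold(f, n_pod = 2000, q = 1, seed = 6)
  expect_equal(as.numeric(t_max), max(attr(t_max, "pod")))
  qs <- c(0.5, 0.8, 0.95, 1)
  ts <- vapply(qs, function(q) as.numeric(pod_threshold(f, 2000, q, seed = 7)), 0)
  expect_true(all(diff(ts) >= 0))
})

test_that("EHH equals exhaustive haplotype-class enumeration", {
  # 4 haplotypes splitting into two classes of 2 one site from the core
  geno <- rbind(c(0L, 0L, 0L), c(0L, 0L, 0L), c(0L, 1L, 1L), c(0L, 1L, 0L))
  hap <- toy_hap(geno, pos = c(100, 200, 300))
  curve <- ehh(hap, core = 1, cutoff = 0)
  expect_equal(curve$ehh[curve$side == "core"], 1)
  expect_equal(curve$ehh[curve$pos == 200], 1 / 3)  # (C(2,2)+C(2,2))/C(4,2)
  # random fixtures against the brute-force enumerator
  set.seed(8)
  for (rep in 1:20) {
    g <- matrix(rbinom(8 * 12, 1, 0.5), 8, 12)
    h <- toy_hap(g, pos = sort(sample(1e4, 12)))
    core <- sample(2:11, 1)
    cv <- ehh(h, core, cutoff = 0)
    for (x in c(core - 1, core + 1, 12)) {
      expect_equal(cv$ehh[cv$pos == h$pos[x]], ehh_bf(g, core, x),
                   tolerance = 1e-12)
    }
    expect_true(all(diff(cv$ehh[cv$side == "right"]) <= 1e-12))
    expect_true(all(diff(rev(cv$ehh[cv$side == "left"])) <= 1e-12))
  }
})

test_that("XP-EHH normalisation is standard normal by construction", {
  sim <- river_scenario(81, sweep = FALSE, chrom_len = c(chr1 = 2e5))
  hap <- filter_sites(sim$hap, sim$popmap, maf = 0.05)
  w <- make_windows(hap, "tile", width = 10000)
  x <- xpehh(hap, sim$popmap, "R1", w)
  sc <- attr(x, "scores")
  z <- sc$z[!is.na(sc$z)]
  expect_gt(length(z), 50)
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(sd(z) - 1), 0.01)
})

test_that("candidate windows need at least two scan flags", {
  df <- data.frame(afd_outlier = c(TRUE, TRUE, FALSE, TRUE, FALSE),
                   fst_outlier = c(TRUE, FALSE, FALSE, TRUE, FALSE),
                   xpehh_outlier = c(FALSE, FALSE, TRUE, TRUE, FALSE))
  out <- call_candidates(df)
  expect_equal(out$candidate, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("association aggregation flags exactly the top window at q=0.999", {
  S <- 1000L
  pos <- seq_len(S) * 10L
  hap <- toy_hap(matrix(0:1, 2, S), pos = pos, chrom_len = c(chr1 = 1e4))
  w <- make_windows(hap, "tile", width = 10)   # one site per window
  scores <- seq_len(S) / S
  res <- aggregate_association(scores, w, q = 0.999)
  expect_equal(sum(res$outlier), 1L)
  expect_equal(which(res$outlier), which.max(res$score_mean))
})
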