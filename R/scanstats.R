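#' Absolute allele frequency difference (AFD)
#'
#' For biallelic sites, half the summed per-allele absolute frequency
#' difference, i.e. `|p1 - p2|`: 0 for identical frequencies, 1 for a fixed
#' difference, linear in between.
#'
#' @param p1,p2 ALT allele frequencies (vectors recycle).
#' @return AFD values in `[0, 1]`.
#' @export
afd <- function(p1, p2) {
  (abs(p1 - p2) + abs((1 - p1) - (1 - p2))) / 2
}

# sites variant within the river (pooled HP+LP allele count not 0 or total)
river_variant <- function(freqs, hp, lp) {
  ktot <- freqs$k[, hp] + freqs$k[, lp]
  ntot <- freqs$n[, hp] + freqs$n[, lp]
  !is.na(ktot) & ntot > 0 & ktot > 0 & ktot < ntot
}

#' Windowed median AFD with outlier calling
#'
#' Per window: sites invariant within the river are removed, the median
#' per-SNP AFD is taken, and windows with fewer than `min_snps` river-variant
#' SNPs are excluded from outlier calling (their median is still reported).
#' The outlier cutoff is the 0.95 genome quantile of eligible window medians,
#' capped at 0.5 (an AFD of 0.5 is the smallest change that flips the major
#' allele, so the cutoff never exceeds it).
#'
#' @param freqs A `freq_table` from [allele_freqs()].
#' @param windows A `window_index` from [make_windows()].
#' @param hp,lp HP and LP population ids of the river.
#' @param min_snps Minimum river-variant SNPs for outlier eligibility
#'   (default 6).
#' @param q Quantile for the cutoff (default 0.95).
#' @return Data frame: window coordinates, `median_afd`, `n_var` (river-
#'   variant SNPs), `eligible`, `outlier`; the cutoff used is in attribute
#'   `threshold`.
#' @export
window_afd <- function(freqs, windows, hp, lp, min_snps = 6L, q = 0.95) {
  vars <- river_variant(freqs, hp, lp)
  site_afd <- afd(freqs$p[, hp], freqs$p[, lp])
  med <- n_var <- numeric(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    s <- windows$sites[[w]]
    s <- s[vars[s]]
    n_var[w] <- length(s)
    med[w] <- if (length(s)) median(site_afd[s]) else NA_real_
  }
  eligible <- n_var >= min_snps
  thr <- if (any(eligible)) min(quantile(med[eligible], q, names = FALSE), 0.5)
         else NA_real_
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, median_afd = med, n_var = n_var,
                    eligible = eligible,
                    outlier = eligible & !is.na(med) & med > thr)
  attr(out, "threshold") <- thr
  out
}

# per-site Hudson FST components; NA where undefined
hudson_components <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  bad <- is.na(p1) | is.na(p2) | n1 < 2 | n2 < 2
  num[bad] <- NA_real_
  den[bad] <- NA_real_
  list(num = num, den = den)
}

#' Windowed Hudson FST (ratio of averages)
#'
#' Per-SNP numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; the window value is the ratio of their
#' sums over river-variant sites. Windows whose denominator sum is zero are
#' undefined (`NA`).
#'
#' @inheritParams window_afd
#' @return Data frame with window coordinates, `fst` and `n_var`; per-site
#'   components are in attributes `num` and `den` (used by the POD null).
#' @export
hudson_fst <- function(freqs, windows, hp, lp) {
  comp <- hudson_components(freqs$p[, hp], freqs$p[, lp],
                            freqs$n[, hp], freqs$n[, lp])
  vars <- river_variant(freqs, hp, lp) & !is.na(comp$num)
  fst <- n_var <- numeric(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    s <- windows$sites[[w]]
    s <- s[vars[s]]
    n_var[w] <- length(s)
    dsum <- sum(comp$den[s])
    fst[w] <- if (length(s) && dsum > 0) sum(comp$num[s]) / dsum else NA_real_
  }
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, fst = fst, n_var = n_var)
  attr(out, "num") <- ifelse(vars, comp$num, NA_real_)
  attr(out, "den") <- ifelse(vars, comp$den, NA_real_)
  out
}

#' Neutral differentiation threshold from pseudo-observed data (POD)
#'
#' Builds a null distribution of windowed Hudson FST from pseudo-observed
#' windows: contiguous blocks of observed per-SNP numerator/denominator
#' components, with block sizes drawn from the observed distribution of
#' window SNP counts and start points drawn uniformly over the genome-wide
#' SNP ordering. Contiguous blocks preserve the local linkage that makes
#' neutral window statistics overdispersed relative to independent SNPs,
#' while random placement destroys the alignment between windows and any
#' locus-specific signal, so the q-quantile of the POD distribution is an
#' empirical neutral cutoff for the windowed scan.
#'
#' @param fst_result Result of [hudson_fst()] (carries per-SNP components).
#' @param n_pod Number of POD SNPs to consume (default 10000; >= 100).
#' @param q Quantile of the POD window distribution (default 0.95).
#' @param seed Optional seed; the threshold is deterministic under it.
#' @return The threshold (numeric scalar), with the POD window statistics in
#'   attribute `pod`.
#' @export
pod_threshold <- function(fst_result, n_pod = 10000L, q = 0.95, seed = NULL) {
  if (n_pod < 100L) stop("n_pod must be >= 100 (quantile would be unstable)")
  if (!is.null(seed)) set.seed(seed)
  num <- attr(fst_result, "num")
  den <- attr(fst_result, "den")
  ok <- which(!is.na(num))
  if (!length(ok)) stop("no usable SNPs for the POD null")
  num <- num[ok]; den <- den[ok]
  S <- length(num)
  sizes_pool <- fst_result$n_var[fst_result$n_var > 0]
  stats <- numeric(0)
  used <- 0L
  while (used < n_pod) {
    w <- min(sample(sizes_pool, 1L), S)
    s0 <- sample.int(S - w + 1L, 1L)
    s <- s0:(s0 + w - 1L)
    dsum <- sum(den[s])
    if (dsum > 0) stats <- c(stats, sum(num[s]) / dsum)
    used <- used + w
  }
  thr <- quantile(stats, q, names = FALSE)
  attr(thr, "pod") <- stats
  thr
}

#' Extended haplotype homozygosity curve from a core site
#'
#' EHH at distance x is the probability that two haplotypes drawn without
#' replacement are identical over the span from the core to x (the core site
#' itself spans zero sequence, so EHH at the core is 1). Haplotypes with a
#' missing allele inside the current span are dropped. iHH is the trapezoid
#' integral of EHH over physical distance, accumulated until EHH drops below
#' `cutoff` or the matrix ends.
#'
#' @param hap A [hap_matrix()] restricted to one chromosome (typically one
#'   population's haplotypes).
#' @param core Site index of the core.
#' @param cutoff EHH truncation value (default 0.05).
#' @return An `ehh_curve`: data frame of `pos`, `ehh`, `side`, plus
#'   attributes `ihh_left`, `ihh_right`, `ihh`.
#' @export
ehh <- function(hap, core, cutoff = 0.05) {
  stopifnot(length(unique(hap$chrom)) == 1L, core >= 1, core <= n_sites(hap))
  res <- ehh_curve_cpp(hap$geno, as.double(hap$pos), as.integer(core - 1L),
                       cutoff)
  out <- data.frame(
    pos = c(rev(res$pos_left), hap$pos[core], res$pos_right),
    ehh = c(rev(res$ehh_left), 1, res$ehh_right),
    side = c(rep("left", length(res$ehh_left)), "core",
             rep("right", length(res$ehh_right))))
  attr(out, "ihh_left") <- res$ihh_left
  attr(out, "ihh_right") <- res$ihh_right
  attr(out, "ihh") <- res$ihh_left + res$ihh_right
  class(out) <- c("ehh_curve", "data.frame")
  out
}

#' Cross-population EHH scan (XP-EHH) in windows
#'
#' Per core SNP, `ln(iHH_HP / iHH_LP)`; scores are z-normalised genome-wide,
#' averaged within each window, and a window is an outlier when the absolute
#' mean normalised score exceeds `z_cut` (elevated haplotype homozygosity in
#' either population). Cores where either population's iHH is zero are
#' skipped.
#'
#' @param hap A [hap_matrix()].
#' @param popmap A [pop_map()].
#' @param river River id (scanned HP vs LP).
#' @param windows A `window_index` over `hap`.
#' @param cutoff EHH truncation (default 0.05).
#' @param z_cut Outlier threshold on `|mean z|` (default 2).
#' @return Data frame: window coordinates, `xpehh_mean` (signed mean z),
#'   `xpehh_abs`, `n_cores`, `outlier`; per-core scores in attribute
#'   `scores`.
#' @export
xpehh <- function(hap, popmap, river, windows, cutoff = 0.05, z_cut = 2) {
  pair <- river_pair(popmap, river)
  freqs <- allele_freqs(hap, popmap)
  vars <- river_variant(freqs, pair$HP, pair$LP)
  raw <- rep(NA_real_, n_sites(hap))
  for (cc in unique(hap$chrom)) {
    idx <- which(hap$chrom == cc)
    sub_hp <- subset_hap(hap, sites = idx, samples = pop_samples(popmap, pair$HP))
    sub_lp <- subset_hap(hap, sites = idx, samples = pop_samples(popmap, pair$LP))
    cores <- which(vars[idx])
    if (!length(cores)) next
    ihh_hp <- ihh_all_cpp(sub_hp$geno, as.double(sub_hp$pos),
                          as.integer(cores - 1L), cutoff)
    ihh_lp <- ihh_all_cpp(sub_lp$geno, as.double(sub_lp$pos),
                          as.integer(cores - 1L), cutoff)
    ok <- ihh_hp > 0 & ihh_lp > 0
    raw[idx[cores[ok]]] <- log(ihh_hp[ok] / ihh_lp[ok])
  }
  mu <- mean(raw, na.rm = TRUE)
  sdv <- sd(raw, na.rm = TRUE)
  z <- (raw - mu) / sdv
  wmean <- n_cores <- numeric(nrow(windows))
  for (w in seq_len(nrow(windows))) {
    s <- windows$sites[[w]]
    zz <- z[s]
    zz <- zz[!is.na(zz)]
    n_cores[w] <- length(zz)
    wmean[w] <- if (length(zz)) mean(zz) else NA_real_
  }
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, xpehh_mean = wmean,
                    xpehh_abs = abs(wmean), n_cores = n_cores,
                    outlier = !is.na(wmean) & abs(wmean) > z_cut)
  attr(out, "scores") <- data.frame(chrom = hap$chrom, pos = hap$pos,
                                    raw = raw, z = z)
  out
}

#' Run all three selection scans for one river
#'
#' Computes windowed AFD, Hudson FST with a POD-derived neutral threshold,
#' and XP-EHH on a common window index, and intersects the per-scan outlier
#' flags into candidate windows (outliers in at least two scans).
#'
#' @param hap A [hap_matrix()] (filtered).
#' @param popmap A [pop_map()].
#' @param river River id.
#' @param windows Optional `window_index` (default: 10kb tiling).
#' @param min_snps AFD SNP-count filter (default 6).
#' @param n_pod POD SNPs for the FST threshold (default 10000).
#' @param seed Seed for the POD resampling.
#' @param xpehh_cutoff,z_cut XP-EHH parameters.
#' @return A `scan_result` data frame: window coordinates, `n_snps`,
#'   `median_afd`, `fst`, `xpehh_mean`, per-scan outlier flags, `candidate`;
#'   thresholds in attribute `thresholds`.
#' @export
scan_river <- function(hap, popmap, river, windows = NULL, min_snps = 6L,
                       n_pod = 10000L, seed = NULL, xpehh_cutoff = 0.05,
                       z_cut = 2) {
  pair <- river_pair(popmap, river)
  windows <- windows %||% make_windows(hap, "tile", width = 10000)
  freqs <- allele_freqs(hap, popmap)
  a <- window_afd(freqs, windows, pair$HP, pair$LP, min_snps = min_snps)
  f <- hudson_fst(freqs, windows, pair$HP, pair$LP)
  thr_fst <- pod_threshold(f, n_pod = n_pod, seed = seed)
  x <- xpehh(hap, popmap, river, windows, cutoff = xpehh_cutoff, z_cut = z_cut)
  out <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, n_snps = windows$n_snps,
                    median_afd = a$median_afd, fst = f$fst,
                    xpehh_mean = x$xpehh_mean,
                    afd_outlier = a$outlier,
                    fst_outlier = !is.na(f$fst) & f$fst > as.numeric(thr_fst),
                    xpehh_outlier = x$outlier)
  out$candidate <- rowSums(out[c("afd_outlier", "fst_outlier",
                                 "xpehh_outlier")]) >= 2L
  attr(out, "thresholds") <- c(afd = attr(a, "threshold"),
                               fst = as.numeric(thr_fst), xpehh = z_cut)
  attr(out, "river") <- river
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Intersect per-scan outlier flags into candidate windows
#'
#' A window is a candidate when flagged by at least two of the three scans.
#'
#' @param scan A `scan_result` (or data frame with the three flag columns).
#' @return The input with its `candidate` column recomputed.
#' @export
call_candidates <- function(scan) {
  need <- c("afd_outlier", "fst_outlier", "xpehh_outlier")
  stopifnot(all(need %in% names(scan)))
  scan$candidate <- rowSums(scan[need]) >= 2L
  scan
}

#' Aggregate per-SNP association scores into outlier windows
#'
#' Window means of an externally supplied per-SNP score; outliers are the
#' windows above the `q` quantile of window means.
#'
#' @param scores Numeric per-SNP scores, one per site of the matrix the
#'   windows were built on.
#' @param windows A `window_index`.
#' @param q Outlier quantile (default 0.999).
#' @return Data frame with window coordinates, `score_mean`, `outlier`.
#' @export
aggregate_association <- function(scores, windows, q = 0.999) {
  if (length(scores) < max(unlist(windows$sites), 0L)) {
    stop("scores shorter than the site index of the windows")
  }
  m <- vapply(windows$sites, function(s) {
    v <- scores[s]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, 0)
  thr <- quantile(m, q, na.rm = TRUE, names = FALSE)
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             score_mean = m, outlier = !is.na(m) & m > thr)
}
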