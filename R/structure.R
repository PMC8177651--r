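#' Genome-wide PCA with per-population centroid drift
#'
#' PCA of the centered (optionally frequency-scaled) diploid dosage matrix.
#' Because the data are centered, the global centroid is the origin, and each
#' population's drift from the common ancestral state is summarised as the
#' distance of its centroid from the origin in the top `npc` axes; founding
#' bottlenecks inflate this distance for derived populations.
#'
#' @param hap A [hap_matrix()] (typically LD-pruned).
#' @param popmap A [pop_map()].
#' @param scale Scale sites by `sqrt(p(1-p))` (default FALSE).
#' @param npc Number of axes for centroid distances (default 2).
#' @return List: `coords` (samples x PCs), `varexp` (fraction of variance per
#'   PC), `centroid` (data frame: population, distance), `rank`.
#' @export
global_pca <- function(hap, popmap, scale = FALSE, npc = 2L) {
  stopifnot(n_samples(hap) >= 2, n_sites(hap) >= 2)
  d <- dosage(hap)
  # mean-impute missing calls so PCA is defined
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  praw <- colMeans(d, na.rm = TRUE) / 2
  d <- scale(d, center = TRUE, scale = FALSE)
  if (scale) {
    sc <- sqrt(pmax(praw * (1 - praw), .Machine$double.eps))
    d <- sweep(d, 2, sc, "/")
  }
  pc <- prcomp(d, center = FALSE, scale. = FALSE)
  varexp <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > 1e-9)
  npc_eff <- min(npc, max(rank, 1L))
  coords <- pc$x
  rownames(coords) <- hap$samples
  pops <- unique(popmap$population)
  cent <- vapply(pops, function(pp) {
    rows <- match(pop_samples(popmap, pp), hap$samples)
    cm <- colMeans(coords[rows, seq_len(npc_eff), drop = FALSE])
    sqrt(sum(cm^2))
  }, 0)
  list(coords = coords, varexp = varexp,
       centroid = data.frame(population = pops, distance = unname(cent),
                             stringsAsFactors = FALSE),
       rank = rank)
}

#' Hypergeometric projection of one site to a smaller sample size
#'
#' Distribution of the derived-allele count after drawing `m` of `n`
#' chromosomes without replacement when `k` carry the derived allele:
#' `P(j) = C(k,j) C(n-k, m-j) / C(n,m)`.
#'
#' @param k Derived-allele count (0..n).
#' @param n Chromosomes sampled at the site.
#' @param m Projection size (m <= n).
#' @return Numeric vector of probabilities over counts `0..m`.
#' @export
project_site <- function(k, n, m) {
  stopifnot(k >= 0, k <= n, m >= 1, m <= n)
  j <- 0:m
  w <- exp(lchoose(k, j) + lchoose(n - k, m - j) - lchoose(n, m))
  w[j > k | (m - j) > (n - k)] <- 0
  w
}

#' Folded two-dimensional site frequency spectrum with projection
#'
#' Each site contributes its hypergeometric projection mass to an
#' `(m1+1) x (m2+1)` grid of joint allele counts; sites with fewer called
#' chromosomes than the projection in either population are skipped and
#' counted. Folding orients cells to the joint minor allele: the mass of any
#' cell whose joint count exceeds `(m1+m2)/2` is added to its complementary
#' cell, and complementary pairs exactly on the fold are combined into the
#' cell with the smaller first index, so no mass remains above the fold.
#'
#' @param freqs A `freq_table` from [allele_freqs()].
#' @param pops Character vector of two population ids.
#' @param m1,m2 Projection sizes (chromosomes).
#' @param folded Fold to minor-allele orientation (default TRUE).
#' @return An `sfs2d`: list with `sfs` (matrix, rows = population 1 counts
#'   0..m1), `m1`, `m2`, `folded`, `n_sites` (contributing), `n_skipped`.
#' @export
build_2dsfs <- function(freqs, pops, m1, m2, folded = TRUE) {
  stopifnot(length(pops) == 2L, all(pops %in% freqs$pops))
  k1 <- freqs$k[, pops[1]]; n1 <- freqs$n[, pops[1]]
  k2 <- freqs$k[, pops[2]]; n2 <- freqs$n[, pops[2]]
  usable <- !is.na(k1) & !is.na(k2) & n1 >= m1 & n2 >= m2
  sfs <- matrix(0, m1 + 1L, m2 + 1L,
                dimnames = list(0:m1, 0:m2))
  for (s in which(usable)) {
    w1 <- project_site(k1[s], n1[s], m1)
    w2 <- project_site(k2[s], n2[s], m2)
    sfs <- sfs + outer(w1, w2)
  }
  if (folded) sfs <- fold_sfs2d(sfs, m1, m2)
  structure(list(sfs = sfs, m1 = m1, m2 = m2, folded = folded,
                 n_sites = sum(usable), n_skipped = sum(!usable)),
            class = "sfs2d")
}

fold_sfs2d <- function(sfs, m1, m2) {
  tot <- m1 + m2
  out <- matrix(0, m1 + 1L, m2 + 1L, dimnames = dimnames(sfs))
  for (i in 0:m1) for (j in 0:m2) {
    v <- sfs[i + 1L, j + 1L]
    if (v == 0) next
    ci <- m1 - i; cj <- m2 - j
    if (i + j < tot / 2) {
      out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + v
    } else if (i + j > tot / 2) {
      out[ci + 1L, cj + 1L] <- out[ci + 1L, cj + 1L] + v
    } else {
      # exactly on the fold: combine complementary pairs deterministically
      if (i < ci || (i == ci && j <= cj)) {
        out[i + 1L, j + 1L] <- out[i + 1L, j + 1L] + v
      } else {
        out[ci + 1L, cj + 1L] <- out[ci + 1L, cj + 1L] + v
      }
    }
  }
  out
}

#' Choose the projection maximising expected segregating sites
#'
#' Over a grid of projection sizes, picks the `(m1, m2)` pair maximising the
#' expected number of sites that remain variable after projection,
#' `sum over usable sites of [1 - P(projected monomorphic)]`; larger
#' projections keep more variation per site but skip more sites with missing
#' calls.
#'
#' @param freqs A `freq_table`.
#' @param pops Two population ids.
#' @param min_m Smallest projection considered (default 2).
#' @return List `m1`, `m2`, `expected_segregating`, and the full `grid`.
#' @export
choose_projection <- function(freqs, pops, min_m = 2L) {
  k1 <- freqs$k[, pops[1]]; n1 <- freqs$n[, pops[1]]
  k2 <- freqs$k[, pops[2]]; n2 <- freqs$n[, pops[2]]
  ok <- !is.na(k1) & !is.na(k2)
  max1 <- max(n1[ok]); max2 <- max(n2[ok])
  grid <- expand.grid(m1 = seq(min_m, max1), m2 = seq(min_m, max2))
  # P(monomorphic) = P(both project to 0) + P(both project to all-derived)
  p_zero <- function(k, n, m) exp(lchoose(n - k, m) - lchoose(n, m))
  p_full <- function(k, n, m) exp(lchoose(k, m) - lchoose(n, m))
  grid$expected_segregating <- vapply(seq_len(nrow(grid)), function(r) {
    m1 <- grid$m1[r]; m2 <- grid$m2[r]
    use <- ok & n1 >= m1 & n2 >= m2
    if (!any(use)) return(0)
    pz <- p_zero(k1[use], n1[use], m1) * p_zero(k2[use], n2[use], m2)
    pf <- p_full(k1[use], n1[use], m1) * p_full(k2[use], n2[use], m2)
    sum(1 - pz - pf)
  }, 0)
  best <- which.max(grid$expected_segregating)
  list(m1 = grid$m1[best], m2 = grid$m2[best],
       expected_segregating = grid$expected_segregating[best], grid = grid)
}

# f4 statistic: mean over sites of (pA - pB)(pC - pD)
f4_stat <- function(pa, pb, pc, pd) {
  v <- (pa - pb) * (pc - pd)
  mean(v[!is.na(v)])
}

#' Patterson's D and f4-ratio for one trio plus outgroup
#'
#' ABBA/BABA imbalance: per site `ABBA = (1-p1) p2 p3 (1-p4)` and
#' `BABA = p1 (1-p2) p3 (1-p4)`; `D = sum(ABBA-BABA) / sum(ABBA+BABA)`.
#' Significance comes from a delete-one block jackknife over contiguous bp
#' blocks. The f4-ratio (admixture-fraction estimate for gene flow from P3
#' into P2) splits P3's haplotypes into random halves a/b once under the
#' seed: `f4(P1, P2; P3a, O) / f4(P1, P3b; P3a, O)`.
#'
#' @param hap A [hap_matrix()].
#' @param popmap A [pop_map()].
#' @param p1,p2,p3 Population ids of the trio.
#' @param outgroup Outgroup population id.
#' @param block_size Jackknife block size in bp (default 1e5).
#' @param seed Seed for the P3 half-split.
#' @return A `dstat_result`: list with `D`, `se`, `Z`, `p` (two-sided
#'   normal), `f4_ratio`, `n_blocks`, `abba`, `baba`, `n_sites`.
#' @export
patterson_d <- function(hap, popmap, p1, p2, p3, outgroup,
                        block_size = 1e5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  freqs <- allele_freqs(hap, popmap)
  need <- c(p1, p2, p3, outgroup)
  stopifnot(all(need %in% freqs$pops))
  f1 <- freqs$p[, p1]; f2 <- freqs$p[, p2]
  f3 <- freqs$p[, p3]; f4 <- freqs$p[, outgroup]
  ok <- !(is.na(f1) | is.na(f2) | is.na(f3) | is.na(f4))
  abba <- (1 - f1) * f2 * f3 * (1 - f4)
  baba <- f1 * (1 - f2) * f3 * (1 - f4)
  abba[!ok] <- NA; baba[!ok] <- NA
  tot_num <- sum(abba - baba, na.rm = TRUE)
  tot_den <- sum(abba + baba, na.rm = TRUE)
  if (tot_den == 0) stop("no ABBA/BABA informative sites; D undefined")
  D <- tot_num / tot_den
  gp <- global_pos(hap$chrom, hap$pos, hap$chrom_len)
  block <- floor(gp / block_size)
  blocks <- unique(block[ok])
  g <- length(blocks)
  if (g < 20L) stop("need >= 20 jackknife blocks (", g, " available); ",
                    "reduce block_size")
  d_jack <- vapply(blocks, function(b) {
    keep <- ok & block != b
    sum(abba[keep] - baba[keep]) / sum(abba[keep] + baba[keep])
  }, 0)
  se <- sqrt((g - 1) / g * sum((d_jack - mean(d_jack))^2))
  Z <- if (se > 0) D / se else NA_real_
  # f4-ratio with a random half-split of P3
  s3 <- pop_samples(popmap, p3)
  rows3 <- hap_rows(hap, s3)
  half <- sample(rows3, floor(length(rows3) / 2))
  other <- setdiff(rows3, half)
  p3a <- colMeans(hap$geno[half, , drop = FALSE], na.rm = TRUE)
  p3b <- colMeans(hap$geno[other, , drop = FALSE], na.rm = TRUE)
  num <- f4_stat(f1[ok], f2[ok], p3a[ok], f4[ok])
  den <- f4_stat(f1[ok], p3b[ok], p3a[ok], f4[ok])
  f4r <- if (abs(den) > 0) num / den else NA_real_
  structure(list(trio = c(P1 = p1, P2 = p2, P3 = p3, outgroup = outgroup),
                 D = D, se = se, Z = Z,
                 p = if (is.na(Z)) NA_real_ else 2 * pnorm(-abs(Z)),
                 f4_ratio = f4r, n_blocks = g,
                 abba = sum(abba, na.rm = TRUE),
                 baba = sum(baba, na.rm = TRUE), n_sites = sum(ok)),
            class = "dstat_result")
}

#' @export
print.dstat_result <- function(x, ...) {
  cat(sprintf("D(%s, %s; %s | %s) = %.4f  Z = %.2f  f4-ratio = %.4f (%d blocks)\n",
              x$trio[1], x$trio[2], x$trio[3], x$trio[4],
              x$D, x$Z, x$f4_ratio, x$n_blocks))
  invisible(x)
}

#' Screen trios for introgression candidates
#'
#' The screening rule keeps trios with Bonferroni-significant D and an
#' f4-ratio above `f4_min`.
#'
#' @param results List of `dstat_result`s.
#' @param alpha Corrected significance level (default 0.001).
#' @param f4_min Minimum f4-ratio (default 0.05).
#' @return Data frame, one row per trio, with `D`, `Z`, `p`, `p_bonf`,
#'   `f4_ratio` and the `candidate` flag.
#' @export
screen_introgression <- function(results, alpha = 0.001, f4_min = 0.05) {
  n <- length(results)
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(P1 = r$trio[1], P2 = r$trio[2], P3 = r$trio[3],
               outgroup = r$trio[4], D = r$D, Z = r$Z, p = r$p,
               f4_ratio = r$f4_ratio, stringsAsFactors = FALSE)
  }))
  df$p_bonf <- pmin(1, df$p * n)
  df$candidate <- !is.na(df$p_bonf) & df$p_bonf < alpha &
    !is.na(df$f4_ratio) & df$f4_ratio > f4_min
  rownames(df) <- NULL
  df
}
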