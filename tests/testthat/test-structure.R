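test_that("PCA separates diverged populations and centers degenerate data", {
  # two populations fixed for opposite alleles at half the sites
  n <- 10L
  geno <- rbind(matrix(0L, 2 * n, 40),
                cbind(matrix(1L, 2 * n, 20), matrix(0L, 2 * n, 20)))
  # add a little noise so within-population variance is nonzero
  set.seed(12)
  flip <- matrix(rbinom(4 * n * 40, 1, 0.02), 4 * n, 40)
  geno <- abs(geno - flip)
  hap <- toy_hap(geno)
  pm <- toy_popmap(paste0("s", 1:(2 * n)), rep(c("A", "B"), each = n),
                   predation = c(A = "HP", B = "LP"))
  pca <- global_pca(hap, pm)
  expect_gt(pca$varexp[1], 0.5)
  pc1 <- pca$coords[, 1]
  expect_true(max(pc1[1:n]) < min(pc1[(n + 1):(2 * n)]) ||
                min(pc1[1:n]) > max(pc1[(n + 1):(2 * n)]))
  # all samples identical: zero variance, zero coordinates
  geno2 <- matrix(rep(c(0L, 1L), 20), 4, 10)   # every sample is 0|1
  hap2 <- toy_hap(geno2)
  pm2 <- toy_popmap(c("s1", "s2"), c("A", "A"), predation = c(A = "HP"))
  pca2 <- global_pca(hap2, pm2)
  expect_equal(pca2$rank, 0L)
  expect_equal(max(abs(pca2$coords)), 0)
})

test_that("project_site is hypergeometric and matches oracles", {
  expect_equal(project_site(1, 4, 2), c(0.5, 0.5, 0))
  # identity projection: point mass at k
  expect_equal(project_site(3, 7, 7), c(0, 0, 0, 1, 0, 0, 0, 0))
  set.seed(13)
  for (rep in 1:50) {
    n <- sample(4:20, 1); k <- sample(0:n, 1); m <- sample(2:n, 1)
    w <- project_site(k, n, m)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_equal(w, project_bf(k, n, m), tolerance = 1e-12)
    expect_equal(w, dhyper(0:m, k, n - k, m), tolerance = 1e-12)
  }
})

test_that("2dSFS conserves mass, folds below the diagonal, keeps margins", {
  set.seed(14)
  sim <- river_scenario(91, sweep = FALSE, chrom_len = c(chr1 = 1e5))
  fr <- allele_freqs(sim$hap, sim$popmap)
  sfs <- build_2dsfs(fr, c("LP", "HP"), m1 = 10, m2 = 12, folded = FALSE)
  expect_equal(sum(sfs$sfs), sfs$n_sites, tolerance = 1e-6)
  f <- build_2dsfs(fr, c("LP", "HP"), m1 = 10, m2 = 12, folded = TRUE)
  expect_equal(sum(f$sfs), f$n_sites, tolerance = 1e-6)
  idx <- which(outer(0:10, 0:12, "+") > 11, arr.ind = TRUE)
  expect_equal(max(f$sfs[idx]), 0)
  # a site monomorphic in LP contributes only to the first row (count 0)
  fr0 <- fr
  fr0$k[, "LP"] <- 0
  s0 <- build_2dsfs(fr0, c("LP", "HP"), m1 = 6, m2 = 6, folded = FALSE)
  expect_equal(sum(s0$sfs[-1, ]), 0, tolerance = 1e-9)
})

test_that("choose_projection equals exhaustive brute force", {
  sim <- river_scenario(92, sweep = FALSE, chrom_len = c(chr1 = 5e4))
  fr <- allele_freqs(sim$hap, sim$popmap)
  got <- choose_projection(fr, c("LP", "HP"))
  # brute force: project every site explicitly over the full grid
  k1 <- fr$k[, "LP"]; n1 <- fr$n[, "LP"]
  k2 <- fr$k[, "HP"]; n2 <- fr$n[, "HP"]
  best <- c(NA, NA); best_v <- -1
  for (m1 in 2:max(n1)) for (m2 in 2:max(n2)) {
    tot <- 0
    for (s in seq_along(k1)) {
      if (n1[s] < m1 || n2[s] < m2) next
      w1 <- project_bf(k1[s], n1[s], m1)
      w2 <- project_bf(k2[s], n2[s], m2)
      tot <- tot + (1 - w1[1] * w2[1] - w1[m1 + 1] * w2[m2 + 1])
    }
    if (tot > best_v) { best_v <- tot; best <- c(m1, m2) }
  }
  expect_equal(c(got$m1, got$m2), best)
  expect_equal(got$expected_segregating, best_v, tolerance = 1e-9)
})

test_that("D is exactly 1 on pure-ABBA data and antisymmetric in P1/P2", {
  # every informative site: p1=0, p2=1, p3=1, outgroup=0 -> all ABBA
  n <- 8L
  block <- function(x) matrix(x, 2 * n, 60)
  geno <- rbind(block(0L), block(1L), block(1L), block(0L))
  # add outgroup-fixed private noise to avoid zero variance elsewhere
  hap <- toy_hap(geno, pos = seq_len(60) * 2000,
                 chrom_len = c(chr1 = 1.3e5))
  pm <- toy_popmap(paste0("s", 1:(4 * n)),
                   rep(c("P1", "P2", "P3", "OUT"), each = n),
                   rivers = rep(c("R1", "R1", "R2", "R2"), each = n),
                   predation = c(P1 = "HP", P2 = "LP", P3 = "HP", OUT = "LP"))
  d <- patterson_d(hap, pm, "P1", "P2", "P3", "OUT", block_size = 3000,
                   seed = 15)
  expect_equal(d$D, 1)
  sim <- quad_scenario(93)
  d1 <- patterson_d(sim$hap, sim$popmap, "P1", "P2", "P3", "OUT",
                    block_size = 2e4, seed = 16)
  d2 <- patterson_d(sim$hap, sim$popmap, "P2", "P1", "P3", "OUT",
                    block_size = 2e4, seed = 16)
  expect_equal(d1$D, -d2$D, tolerance = 1e-12)
  expect_gte(d1$n_blocks, 20)
})

test_that("degenerate trios and screening rules are handled", {
  n <- 4L
  geno <- matrix(0L, 8 * n, 30)
  geno[1:(2 * n), ] <- 1L   # only P1 variable -> no ABBA/BABA pattern
  hap <- toy_hap(geno, pos = seq_len(30) * 100)
  pm <- toy_popmap(paste0("s", 1:(4 * n)),
                   rep(c("P1", "P2", "P3", "OUT"), each = n),
                   rivers = rep(c("R1", "R1", "R2", "R2"), each = n),
                   predation = c(P1 = "HP", P2 = "LP", P3 = "HP", OUT = "LP"))
  expect_error(patterson_d(hap, pm, "P1", "P2", "P3", "OUT",
                           block_size = 100, seed = 1),
               "undefined|blocks")
  fake <- function(D, Z, f4) {
    structure(list(trio = c(P1 = "a", P2 = "b", P3 = "c", outgroup = "o"),
                   D = D, se = abs(D / Z), Z = Z, p = 2 * pnorm(-abs(Z)),
                   f4_ratio = f4, n_blocks = 25), class = "dstat_result")
  }
  scr <- screen_introgression(list(fake(0.3, 8, 0.2), fake(0.3, 8, 0.01),
                                   fake(0.05, 1, 0.4)))
  expect_equal(scr$candidate, c(TRUE, FALSE, FALSE))
})
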