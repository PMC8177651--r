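test_that("demography_config rejects inconsistent inputs", {
  pops <- data.frame(pop = c("A", "B"), river = "R1", drainage = "D1",
                     predation = c("HP", "LP"), Ne = c(50L, 50L),
                     sample_n = c(10L, 10L), founded_at = c(0L, 10L),
                     source = c(NA, "A"))
  cl <- c(chr1 = 1e5)
  expect_s3_class(demography_config(pops, NULL, cl, 1e-6, total_gens = 20L),
                  "demography_config")
  bad <- pops; bad$founded_at <- c(0L, 0L)   # founded with its source
  expect_error(demography_config(bad, NULL, cl, 1e-6, total_gens = 20L),
               "founded before")
  bad <- pops; bad$source <- c(NA, "Z")
  expect_error(demography_config(bad, NULL, cl, 1e-6, total_gens = 20L),
               "unknown source")
  bad <- pops; bad$sample_n <- c(60L, 10L)
  expect_error(demography_config(bad, NULL, cl, 1e-6, total_gens = 20L),
               "sample size exceeds")
  bad <- pops; bad$Ne <- c(1L, 50L)
  expect_error(demography_config(bad, NULL, cl, 1e-6, total_gens = 20L),
               ">= 2")
  m <- matrix(c(0, 0.6, 0.7, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_silent(demography_config(pops, m, cl, 1e-6, total_gens = 20L))
  m2 <- matrix(c(0, 1.2, 0, 0), 2, 2, dimnames = dimnames(m))
  expect_error(demography_config(pops, m2, cl, 1e-6, total_gens = 20L),
               "\\[0, 1\\)")
})

test_that("fixed seed reproduces byte-identical VCF output", {
  pops <- data.frame(pop = c("A", "B"), river = "R1", drainage = "D1",
                     predation = c("HP", "LP"), Ne = c(30L, 30L),
                     sample_n = c(8L, 8L), founded_at = c(0L, 20L),
                     source = c(NA, "A"))
  cfg <- demography_config(pops, NULL, c(chr1 = 1e5, chr2 = 1e5), 2e-6,
                           xo_per_chrom = 1, total_gens = 60L)
  s1 <- simulate_demography(cfg, seed = 11)
  s2 <- simulate_demography(cfg, seed = 11)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(s1$hap, f1); write_vcf(s2$hap, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- simulate_demography(cfg, seed = 12)
  expect_false(identical(s1$hap$geno, s3$hap$geno))
})

test_that("drift is mean-zero over one generation (martingale)", {
  pops <- data.frame(pop = "A", river = "R1", drainage = "D1",
                     predation = "HP", Ne = 50L, sample_n = 50L,
                     founded_at = 0L, source = NA)
  cfg <- demography_config(pops, NULL, c(chr1 = 1e6), mu = 0,
                           xo_per_chrom = 0, total_gens = 1L,
                           init_freq = 0.5, init_sites = 1200L)
  sim <- simulate_demography(cfg, seed = 21)
  p <- colMeans(sim$hap$geno)
  # starting at p = 0.5 with 100 chromosomes, loss/fixation in one
  # generation has probability ~2^-99, so no sites are dropped
  expect_length(p, 1200L)
  se <- sqrt(0.5 * 0.5 / 100 / 1200)  # Var(p') = p(1-p)/2N per locus
  expect_lt(abs(mean(p) - 0.5), 3 * se)
})

test_that("simulated diversity scales with population size", {
  mk <- function(ne) {
    pops <- data.frame(pop = "A", river = "R1", drainage = "D1",
                       predation = "HP", Ne = ne, sample_n = 15L,
                       founded_at = 0L, source = NA)
    demography_config(pops, NULL, c(chr1 = 4e5), mu = 2e-6,
                      xo_per_chrom = 1, total_gens = 100L)
  }
  s_small <- simulate_demography(mk(25L), seed = 5)
  s_big <- simulate_demography(mk(150L), seed = 5)
  het <- function(s) {
    p <- colMeans(s$hap$geno)
    sum(2 * p * (1 - p))
  }
  expect_gt(het(s_big), het(s_small))
})

test_that("plant_sweep hits target frequencies and leaves the rest alone", {
  sim <- river_scenario(31, sweep = FALSE)
  hap0 <- sim$hap
  sp <- sweep_spec("chr1", 2e5, 2.5e5, c(LP = 0.9, HP = 0.3),
                   ancestral = TRUE)
  hap1 <- plant_sweep(hap0, sim$popmap, sp, seed = 32)
  carriers <- attr(hap1, "sweep_carriers")
  in_iv <- which(hap1$chrom == "chr1" & hap1$pos > 2e5 & hap1$pos <= 2.5e5)
  out_iv <- setdiff(seq_len(n_sites(hap1)), in_iv)
  # outside the interval nothing changes
  expect_identical(hap1$geno[, out_iv], hap0$geno[, out_iv])
  # realized carrier frequency within 1/n_hap of target
  for (pp in c("LP", "HP")) {
    rows <- riverscan:::hap_rows(hap1, sim$popmap$sample[sim$popmap$population == pp])
    f <- length(carriers[[pp]]) / length(rows)
    expect_lt(abs(f - sp$targets[[pp]]), 1 / length(rows) + 1e-9)
    # carriers are byte-identical over the interval
    if (length(carriers[[pp]]) > 1) {
      blk <- hap1$geno[carriers[[pp]], in_iv, drop = FALSE]
      expect_true(all(blk == rep(blk[1, ], each = nrow(blk))))
    }
  }
})

test_that("full fixation makes every carrier haplotype identical with EHH 1", {
  sim <- river_scenario(41, sweep = FALSE)
  sp <- sweep_spec("chr1", 2e5, 2.6e5, c(LP = 1.0))
  hap <- plant_sweep(sim$hap, sim$popmap, sp, seed = 42)
  lp <- subset_hap(hap, samples = sim$popmap$sample[sim$popmap$population == "LP"])
  in_iv <- which(lp$chrom == "chr1" & lp$pos > 2e5 & lp$pos <= 2.6e5)
  blk <- lp$geno[, in_iv, drop = FALSE]
  expect_true(all(blk == rep(blk[1, ], each = nrow(blk))))
  core <- in_iv[ceiling(length(in_iv) / 2)]
  curve <- ehh(lp, core)
  inside <- curve$pos > 2e5 & curve$pos <= 2.6e5
  expect_true(all(curve$ehh[inside] == 1))
})

test_that("zero-frequency target is a no-op and bad intervals error", {
  sim <- river_scenario(51, sweep = FALSE)
  sp <- sweep_spec("chr1", 2e5, 2.5e5, c(LP = 0))
  hap <- plant_sweep(sim$hap, sim$popmap, sp, seed = 52)
  expect_identical(hap$geno, sim$hap$geno)
  expect_error(plant_sweep(sim$hap, sim$popmap,
                           sweep_spec("chr1", 4e5, 9e5, c(LP = 0.5)), 1),
               "outside chromosome bounds")
  expect_error(sweep_spec("chr1", 100, 100, c(LP = 0.5)), "empty")
  expect_error(plant_sweep(sim$hap, sim$popmap,
                           sweep_spec("chr9", 0, 100, c(LP = 0.5)), 1),
               "not in the matrix")
})

test_that("emit_annotations builds a consistent pathway map", {
  cl <- c(chr1 = 5e5, chr2 = 5e5)
  ann <- emit_annotations(100L, c(pw1 = 10L), cl, seed = 7, gene_len = 2000)
  expect_equal(length(ann$background), 100L)
  # background proportion K/N of the single pathway
  K <- sum(ann$pathways$pathway == "pw1")
  expect_equal(K / 100, 0.10)
  # genes are placed inside the genome, non-overlapping per chromosome
  g <- ann$genes
  expect_true(all(g$start >= 0 & g$end <= cl[g$chrom]))
  for (cc in names(cl)) {
    gg <- g[g$chrom == cc, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1) expect_true(all(diff(gg$start) >= 2000))
  }
  # determinism under the seed
  ann2 <- emit_annotations(100L, c(pw1 = 10L), cl, seed = 7, gene_len = 2000)
  expect_identical(ann, ann2)
  # focal co-location honoured
  iv <- list(R1 = list(chrom = "chr1", start = 1e5, end = 1.5e5))
  ann3 <- emit_annotations(50L, c(focal = 5L, other = 10L), cl, seed = 8,
                           gene_len = 2000, sweeps = iv, focal = "focal",
                           focal_per_river = 2L)
  fg <- ann3$truth$focal_genes$R1
  expect_length(fg, 2L)
  rows <- ann3$genes[match(fg, ann3$genes$gene), ]
  expect_true(all(rows$chrom == "chr1" & rows$start >= 1e5 & rows$end <= 1.5e5))
  expect_true(all(fg %in% ann3$pathways$gene[ann3$pathways$pathway == "focal"]))
})

test_that("per-call dropout introduces the configured missingness", {
  pops <- data.frame(pop = "A", river = "R1", drainage = "D1",
                     predation = "HP", Ne = 40L, sample_n = 20L,
                     founded_at = 0L, source = NA)
  cfg <- demography_config(pops, NULL, c(chr1 = 2e5), mu = 2e-6,
                           xo_per_chrom = 1, total_gens = 40L,
                           dropout = 0.1)
  sim <- simulate_demography(cfg, seed = 77)
  d <- dosage(sim$hap)
  miss <- mean(is.na(d))
  expect_gt(miss, 0.05)
  expect_lt(miss, 0.15)
  # both haplotypes of a dropped genotype are missing together
  g <- sim$hap$geno
  odd <- g[seq(1, nrow(g), 2), ]
  even <- g[seq(2, nrow(g), 2), ]
  expect_identical(is.na(odd), is.na(even))
})

test_that("bottlenecked founding reduces diversity and leaves private alleles", {
  sim <- river_scenario(61, sweep = FALSE)
  fr <- allele_freqs(sim$hap, sim$popmap)
  het <- function(pp) mean(2 * fr$p[, pp] * (1 - fr$p[, pp]), na.rm = TRUE)
  expect_lt(het("LP"), het("HP"))
  poly_hp <- fr$p[, "HP"] > 0 & fr$p[, "HP"] < 1
  poly_lp <- fr$p[, "LP"] > 0 & fr$p[, "LP"] < 1
  expect_gt(sum(poly_hp & !poly_lp), sum(poly_lp & !poly_hp))
})
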