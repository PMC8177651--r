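make_vcf_fixture <- function(path) {
  # 3 samples x 4 sites, plus one multiallelic record that must be skipped
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t101\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0",
    "chr1\t202\t.\tC\tG\t.\tPASS\t.\tGT\t0|0\t0|1\t1|0",
    "chr1\t303\t.\tG\tA\t.\tPASS\t.\tGT\t1|1\t0|0\t0|1",
    "chr1\t350\t.\tT\tA,C\t.\tPASS\t.\tGT\t1|2\t0|0\t0|1",
    "chr2\t50\t.\tT\tC\t.\tPASS\t.\tGT\t0|0\t1|1\t0|1")
  writeLines(lines, path)
  path
}

fixture_popmap <- function(samples = c("s1", "s2", "s3")) {
  toy_popmap(samples, rep("P1", length(samples)),
             predation = c(P1 = "HP"))
}

test_that("read_vcf parses a handcrafted fixture exactly", {
  f <- make_vcf_fixture(tempfile(fileext = ".vcf"))
  expect_message(out <- read_vcf(f, fixture_popmap()), "multiallelic")
  hap <- out$hap
  expect_equal(dim(hap$geno), c(6L, 4L))
  expect_equal(hap$pos, c(101L, 202L, 303L, 50L))
  # s1 = haplotypes 1,2; site 1 is 0|1
  expect_equal(unname(hap$geno[, 1]), c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(unname(hap$geno[, 4]), c(0L, 0L, 1L, 1L, 0L, 1L))
})

test_that("VCF round-trip is lossless for genotypes and coordinates", {
  sim <- river_scenario(71, sweep = FALSE, chrom_len = c(chr1 = 1e5))
  f <- tempfile(fileext = ".vcf")
  write_vcf(sim$hap, f)
  back <- read_vcf(f, sim$popmap)
  expect_identical(unname(back$hap$geno), unname(sim$hap$geno))
  expect_identical(back$hap$pos, sim$hap$pos)
  expect_identical(back$hap$chrom, sim$hap$chrom)
})

test_that("read_vcf enforces the popmap and phasing contracts", {
  f <- make_vcf_fixture(tempfile(fileext = ".vcf"))
  expect_error(suppressMessages(read_vcf(f, fixture_popmap(c("s1", "s2")))),
               "s3")
  f2 <- tempfile(fileext = ".vcf")
  txt <- readLines(f)
  txt[4] <- sub("0\\|1", "0/1", txt[4])
  writeLines(txt, f2)
  expect_error(suppressMessages(read_vcf(f2, fixture_popmap())),
               "unphased.*chr1:101.*s1")
})

test_that("filter_sites applies MAF and per-population missingness rules", {
  # 10 diploids in each of two populations
  n <- 20L
  geno <- matrix(0L, 2 * n, 3)
  geno[1, 1] <- 1L                      # site 1: global MAF 1/80 = 0.0125
  geno[1:28, 2] <- 1L                   # site 2: common, no missingness
  geno[1:28, 3] <- 1L                   # site 3: missing in 60% of pop 1
  pm <- toy_popmap(paste0("s", 1:n), rep(c("A", "B"), each = 10),
                   predation = c(A = "HP", B = "LP"))
  hap <- toy_hap(geno)
  hap$geno[1:12, 3] <- NA_integer_      # samples s1..s6 of pop A missing
  out <- filter_sites(hap, pm, maf = 0.05, max_missing_per_pop = 0.5)
  expect_equal(n_sites(out), 1L)
  expect_equal(out$pos, hap$pos[2])
  # idempotent
  out2 <- filter_sites(out, pm)
  expect_identical(out2$geno, out$geno)
})

test_that("ld_prune keeps one of a perfectly duplicated site and respects r2", {
  set.seed(9)
  n <- 30L
  base <- matrix(rbinom(2 * n * 40, 1, 0.4), 2 * n, 40)
  geno <- cbind(base[, 1], base[, 1], base[, -1])  # duplicate first site
  hap <- toy_hap(geno)
  keep <- ld_prune(hap, window = 50, step = 5, r2 = 0.2)
  expect_true(xor(1 %in% keep, 2 %in% keep))
  d <- dosage(subset_hap(hap, sites = keep))
  cm <- suppressWarnings(cor(d))
  cm[is.na(cm)] <- 0
  diag(cm) <- 0
  expect_lt(max(cm^2), 0.2 + 1e-12)
})

test_that("ld_prune retains nearly all independent sites", {
  set.seed(10)
  n <- 120L   # sampling noise in r2 shrinks as 1/n; independence needs n large
  geno <- matrix(rbinom(2 * n * 120, 1, 0.5), 2 * n, 120)
  hap <- toy_hap(geno)
  keep <- ld_prune(hap)
  expect_gte(length(keep) / 120, 0.95)
})

test_that("thin_sites applies the greedy spacing rule", {
  hap <- toy_hap(matrix(rep(c(0L, 1L), 3 * 2), 4, 3), pos = c(1, 15000, 25000))
  expect_equal(thin_sites(hap, 20000), c(1L, 3L))
  hap2 <- toy_hap(matrix(rep(c(0L, 1L), 3 * 2), 4, 3),
                  pos = c(1, 25000, 50000))
  expect_equal(thin_sites(hap2, 20000), 1:3)
  # dense grid over 100kb: survivors at 0,20k,...,100k
  pos <- seq(100, 100100, by = 100)
  geno <- matrix(rep(c(0L, 1L), length(pos)), 2, length(pos))
  hap3 <- toy_hap(geno, pos = pos)
  expect_equal(hap3$pos[thin_sites(hap3, 20000)],
               c(100, 20100, 40100, 60100, 80100, 100100))
})

test_that("make_windows tiles, slides and counts SNPs as specified", {
  pos <- c(500, 9500, 12000, 24000)
  hap <- toy_hap(matrix(rep(c(0L, 1L), length(pos)), 2, length(pos)),
                 pos = pos, chrom_len = c(chr1 = 25000))
  w <- make_windows(hap, "tile", width = 10000)
  expect_equal(w$start, c(0, 10000, 20000))
  expect_equal(w$end, c(10000, 20000, 25000))
  expect_equal(w$n_snps, c(2L, 1L, 1L))
  expect_true(w$partial[3])
  # sliding 100kb/50kb over 300kb: 5 full windows
  hap2 <- toy_hap(matrix(rep(c(0L, 1L), 2), 2, 2), pos = c(1, 2.9e5),
                  chrom_len = c(chr1 = 3e5))
  w2 <- make_windows(hap2, "slide", width = 1e5, step = 5e4)
  expect_equal(w2$start, c(0, 5e4, 1e5, 1.5e5, 2e5))
  # SNP-count windows: terminal partial flagged
  pos3 <- seq(100, 2500, by = 100)
  hap3 <- toy_hap(matrix(rep(c(0L, 1L), length(pos3)), 2, length(pos3)),
                  pos = pos3)
  w3 <- make_windows(hap3, "snp", snp_count = 10L)
  expect_equal(w3$n_snps, c(10L, 10L, 5L))
  expect_equal(w3$partial, c(FALSE, FALSE, TRUE))
})

test_that("allele_freqs counts alleles over called chromosomes", {
  # 2 diploids genotyped 0|1 and 1|1 -> p = 0.75, n = 4
  geno <- matrix(c(0L, 1L, 1L, 1L), 4, 1)
  hap <- toy_hap(geno)
  pm <- toy_popmap(c("s1", "s2"), c("A", "A"), predation = c(A = "HP"))
  fr <- allele_freqs(hap, pm)
  expect_equal(unname(fr$p[1, "A"]), 0.75)
  expect_equal(unname(fr$n[1, "A"]), 4)
  # zero called chromosomes flagged missing
  hap$geno[, 1] <- NA_integer_
  fr2 <- allele_freqs(hap, pm)
  expect_true(is.na(fr2$p[1, "A"]))
})
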