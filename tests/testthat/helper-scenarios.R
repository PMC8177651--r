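# Reduced simulation scenarios reused across tests. Sizes are desk-scale:
# tens of diploids, a few hundred kb, a few hundred generations.

# single HP/LP river pair, optionally with a planted sweep
river_scenario <- function(seed, sweep = TRUE, chrom_len = c(chr1 = 5e5),
                           lp_target = 0.95, hp_target = 0.25) {
  pops <- data.frame(pop = c("HP", "LP"), river = "R1", drainage = "D1",
                     predation = c("HP", "LP"), Ne = c(100L, 50L),
                     sample_n = c(20L, 20L), founded_at = c(0L, 60L),
                     source = c(NA, "HP"), founder_n = c(NA, 10L),
                     bottleneck_gens = c(0L, 5L))
  mig <- matrix(c(0, 0.005, 0.02, 0), 2, 2,
                dimnames = list(c("HP", "LP"), c("HP", "LP")))
  cfg <- demography_config(pops, mig, chrom_len = chrom_len, mu = 1.2e-6,
                           xo_per_chrom = 1, total_gens = 160L)
  sim <- simulate_demography(cfg, seed = seed)
  if (sweep) {
    span <- as.double(chrom_len[[1]])
    sp <- sweep_spec("chr1", round(span * 0.4), round(span * 0.48),
                     c(LP = lp_target, HP = hp_target),
                     ancestral = FALSE, extra_snps = 15L)
    sim$hap <- plant_sweep(sim$hap, sim$popmap, sp, seed = seed + 1000L)
    sim$sweep <- sp
  }
  sim
}

# large divergent ancestral haplotype fixed in LP, polymorphic in HP
cl_scenario <- function(seed, hp_target = 0.45) {
  pops <- data.frame(pop = c("HP", "LP"), river = "R1", drainage = "D1",
                     predation = c("HP", "LP"), Ne = c(100L, 50L),
                     sample_n = c(19L, 18L), founded_at = c(0L, 60L),
                     source = c(NA, "HP"), founder_n = c(NA, 8L),
                     bottleneck_gens = c(0L, 5L))
  mig <- matrix(c(0, 0.005, 0.02, 0), 2, 2,
                dimnames = list(c("HP", "LP"), c("HP", "LP")))
  cfg <- demography_config(pops, mig, chrom_len = c(chr1 = 1e6), mu = 1.2e-6,
                           xo_per_chrom = 1.5, total_gens = 160L)
  sim <- simulate_demography(cfg, seed = seed)
  sp <- sweep_spec("chr1", 1e5, 2.5e5, c(LP = 1.0, HP = hp_target),
                   ancestral = TRUE, extra_snps = 150L)
  sim$hap <- plant_sweep(sim$hap, sim$popmap, sp, seed = seed + 999L)
  sim$region <- list(chrom = "chr1", start = 1e5, end = 2.5e5)
  sim$carriers <- attr(sim$hap, "sweep_carriers")
  sim
}

# (((P1,P2),P3),OUT) topology for D/f4; optional planted admixture P3 -> P2
quad_scenario <- function(seed, alpha = 0) {
  pops <- data.frame(pop = c("OUT", "P3", "P1", "P2"),
                     river = c("R0", "R0", "R1", "R1"), drainage = "D1",
                     predation = c("HP", "LP", "HP", "LP"),
                     Ne = 50L, sample_n = c(12L, 16L, 12L, 12L),
                     founded_at = c(0L, 60L, 110L, 150L),
                     source = c(NA, "OUT", "P3", "P1"),
                     founder_n = c(NA, 40L, 40L, 40L), bottleneck_gens = 0L)
  cfg <- demography_config(pops, NULL,
                           chrom_len = setNames(rep(2e5, 3), paste0("chr", 1:3)),
                           mu = 1.2e-6, xo_per_chrom = 2, total_gens = 200L)
  sim <- simulate_demography(cfg, seed = seed)
  if (alpha > 0) {
    set.seed(seed + 5000L)
    h2 <- riverscan:::hap_rows(sim$hap, sim$popmap$sample[sim$popmap$population == "P2"])
    h3 <- riverscan:::hap_rows(sim$hap, sim$popmap$sample[sim$popmap$population == "P3"])
    k <- round(alpha * length(h2))
    sim$hap$geno[sample(h2, k), ] <- sim$hap$geno[sample(h3, k), ]
  }
  sim
}

# reduced five-river design with per-river sweeps and a co-located focal
# pathway; used for the end-to-end enrichment power check
mini_five_rivers <- function(seed) {
  rivers <- c("Guanapo", "Oropouche", "Madamas", "Tacarigua", "Aripo")
  hp <- c("GHP", "OHP", "MADHP", "TACHP", "APHP")
  lp <- c("GLP", "OLP", "MADLP", "TACLP", "APLP")
  pops <- data.frame(
    pop = c(hp, lp), river = rep(rivers, 2),
    drainage = rep(c("Caroni", "Oropouche", "Northern", "Caroni", "Caroni"), 2),
    predation = rep(c("HP", "LP"), each = 5),
    Ne = c(rep(50L, 5), rep(36L, 5)),
    sample_n = 16L,
    founded_at = c(0L, 10L, 15L, 20L, 25L, rep(60L, 5)),
    source = c(NA, "GHP", "OHP", "GHP", "GHP", hp),
    founder_n = c(NA, rep(30L, 4), rep(10L, 5)),
    bottleneck_gens = c(rep(0L, 5), rep(5L, 5)))
  # downstream-biased within-river migration keeps HP-LP drift moderate
  mig <- matrix(0, 10, 10, dimnames = list(pops$pop, pops$pop))
  for (i in 1:5) {
    mig[hp[i], lp[i]] <- 0.005
    mig[lp[i], hp[i]] <- 0.02
  }
  chrom_len <- setNames(rep(4e5, 2), c("chr1", "chr2"))
  cfg <- demography_config(pops, mig, chrom_len = chrom_len, mu = 1.2e-6,
                           xo_per_chrom = 1, total_gens = 120L)
  sim <- simulate_demography(cfg, seed = seed)
  iv <- list(Guanapo   = list(chrom = "chr1", start = 4e4, end = 8e4),
             Oropouche = list(chrom = "chr1", start = 1.8e5, end = 2.2e5),
             Madamas   = list(chrom = "chr1", start = 3.2e5, end = 3.6e5),
             Tacarigua = list(chrom = "chr2", start = 4e4, end = 8e4),
             Aripo     = list(chrom = "chr2", start = 2.4e5, end = 2.8e5))
  for (i in seq_along(rivers)) {
    tg <- setNames(c(0.97, 0.15), c(lp[i], hp[i]))
    sp <- sweep_spec(iv[[i]]$chrom, iv[[i]]$start, iv[[i]]$end, tg,
                     ancestral = FALSE, extra_snps = 28L)
    sim$hap <- plant_sweep(sim$hap, sim$popmap, sp, seed = seed + 100L + i)
  }
  ann <- emit_annotations(n_genes = 250L,
                          pathways = c(focal = 25L, pwA = 30L, pwB = 45L),
                          chrom_len = chrom_len, seed = seed + 77L,
                          gene_len = 2000, sweeps = iv, focal = "focal",
                          focal_per_river = 5L)
  sim$annotation <- ann
  sim$sweep_iv <- iv
  sim
}

# fast two-scan candidate windows (AFD + POD-thresholded FST) for one river
two_scan_candidates <- function(hap, popmap, river, seed, n_pod = 4000L) {
  pair <- river_pair(popmap, river)
  windows <- make_windows(hap, "tile", width = 10000)
  freqs <- allele_freqs(hap, popmap)
  a <- window_afd(freqs, windows, pair$HP, pair$LP)
  f <- hudson_fst(freqs, windows, pair$HP, pair$LP)
  thr <- pod_threshold(f, n_pod = n_pod, seed = seed)
  cand <- a$outlier & !is.na(f$fst) & f$fst > as.numeric(thr)
  windows[cand, c("chrom", "start", "end")]
}

# outgroup + HP + bottlenecked LP; used for the founding-bottleneck
# diversity-loss and centroid-drift calibration
bottleneck_scenario <- function(seed) {
  pops <- data.frame(pop = c("OUT", "HP", "LP"), river = c("R0", "R1", "R1"),
                     drainage = "D1", predation = c("HP", "HP", "LP"),
                     Ne = c(80L, 80L, 40L), sample_n = c(16L, 16L, 16L),
                     founded_at = c(0L, 10L, 100L), source = c(NA, "OUT", "HP"),
                     founder_n = c(NA, 40L, 4L), bottleneck_gens = c(0L, 0L, 10L))
  cfg <- demography_config(pops, NULL,
                           chrom_len = setNames(rep(1.5e5, 4), paste0("chr", 1:4)),
                           mu = 1e-6, xo_per_chrom = 2, total_gens = 150L)
  simulate_demography(cfg, seed = seed)
}

# compact quad for the introgression calibration loops: shallower history,
# smaller genome, more jackknife blocks per bp
quad_small <- function(seed, alpha = 0) {
  pops <- data.frame(pop = c("OUT", "P3", "P1", "P2"),
                     river = c("R0", "R0", "R1", "R1"), drainage = "D1",
                     predation = c("HP", "LP", "HP", "LP"),
                     Ne = 50L, sample_n = c(12L, 16L, 12L, 12L),
                     founded_at = c(0L, 50L, 90L, 120L),
                     source = c(NA, "OUT", "P3", "P1"),
                     founder_n = c(NA, 40L, 40L, 40L), bottleneck_gens = 0L)
  cfg <- demography_config(pops, NULL,
                           chrom_len = setNames(rep(1.5e5, 2), c("chr1", "chr2")),
                           mu = 1.5e-6, xo_per_chrom = 2, total_gens = 160L)
  sim <- simulate_demography(cfg, seed = seed)
  if (alpha > 0) {
    set.seed(seed + 5000L)
    h2 <- riverscan:::hap_rows(sim$hap, sim$popmap$sample[sim$popmap$population == "P2"])
    h3 <- riverscan:::hap_rows(sim$hap, sim$popmap$sample[sim$popmap$population == "P3"])
    k <- round(alpha * length(h2))
    sim$hap$geno[sample(h2, k), ] <- sim$hap$geno[sample(h3, k), ]
  }
  sim
}
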