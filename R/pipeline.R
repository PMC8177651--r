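#' Default run configuration
#'
#' Effective parameters of every stage, with the scan, permutation and
#' window defaults used throughout. Unknown keys in a user configuration are
#' rejected.
#'
#' @return Nested list of stage parameters.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "riverscan_out",
    paths = list(vcf = NULL, popmap = NULL, genes = NULL, pathways = NULL),
    simulate = list(n_chrom = 3L, chrom_size = 8e5),
    filter = list(maf = 0.05, max_missing_per_pop = 0.5),
    scan = list(window = 10000, min_snps = 6L, n_pod = 10000L,
                xpehh_cutoff = 0.05, z_cut = 2),
    converge = list(cluster_width = 1e5, cluster_step = 5e4,
                    n_perm = 10000L),
    enrich = list(rule = "all", any_k = 4L, n_perm = 10000L),
    structure = list(ld_window = 50L, ld_step = 5L, ld_r2 = 0.2, npc = 2L,
                     block_size = 1e5),
    haplo = list(win_snps = 100L, k = 2L, npc = 2L, tree_width = 1e5)
  )
}

merge_config <- function(user, defaults) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) stop("unknown configuration key(s): ",
                            paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(user[[nm]], defaults[[nm]])
    } else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Run the full analysis pipeline
#'
#' Stage order: simulate (or load the input files named in `paths`), filter,
#' scan each river, convergence summaries, pathway enrichment, genome-wide
#' structure (PCA, 2dSFS, D statistics), and the haplotype-region follow-up.
#' Every stage draws its randomness from a seed derived from the global seed
#' and the stage name, and all effective parameters are echoed to a
#' machine-readable manifest, so a rerun with the same configuration
#' reproduces identical outputs.
#'
#' @param config A list (see [default_run_config()]), or a path to a YAML
#'   file with the same structure. Unknown keys are rejected.
#' @return Invisibly, a list with the stage results and the manifest (also
#'   written to `outdir`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config, default_run_config())
  seed <- as.integer(cfg$seed)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "riverscan",
                   version = as.character(packageVersion("riverscan")),
                   config = cfg, config_hash = config_hash(cfg),
                   seed = seed, stages = list())
  stage_seed <- function(nm) {
    s <- derive_seed(seed, nm)
    manifest$stages[[nm]] <<- list(seed = s)
    s
  }
  res <- list()

  # -- simulate / load ------------------------------------------------------
  if (!is.null(cfg$paths$vcf)) {
    inp <- read_vcf(cfg$paths$vcf, cfg$paths$popmap)
    hap <- inp$hap; popmap <- inp$popmap
    genes <- read.table(cfg$paths$genes, sep = "\t",
                        col.names = c("chrom", "start", "end", "gene"),
                        stringsAsFactors = FALSE)[c("gene", "chrom", "start", "end")]
    memb <- read.table(cfg$paths$pathways, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    ann <- list(genes = genes, pathways = memb, background = genes$gene,
                focal = NULL)
    truth <- NULL
  } else {
    scen <- default_scenario(n_chrom = cfg$simulate$n_chrom,
                             chrom_size = cfg$simulate$chrom_size)
    ds <- generate_dataset(scen, seed = stage_seed("simulate"))
    write_dataset(ds, file.path(cfg$outdir, "data"))
    hap <- ds$hap; popmap <- ds$popmap; ann <- ds$annotation
    truth <- ds$truth
  }
  res$popmap <- popmap

  # -- filter ---------------------------------------------------------------
  hap_f <- filter_sites(hap, popmap, maf = cfg$filter$maf,
                        max_missing_per_pop = cfg$filter$max_missing_per_pop)
  res$n_sites <- c(raw = n_sites(hap), filtered = n_sites(hap_f))

  # -- scans ----------------------------------------------------------------
  rivers <- unique(popmap$river)
  windows <- make_windows(hap_f, "tile", width = cfg$scan$window)
  scans <- list()
  for (rv in rivers) {
    scans[[rv]] <- scan_river(hap_f, popmap, rv, windows = windows,
                              min_snps = cfg$scan$min_snps,
                              n_pod = cfg$scan$n_pod,
                              seed = stage_seed(paste0("scan_", rv)),
                              xpehh_cutoff = cfg$scan$xpehh_cutoff,
                              z_cut = cfg$scan$z_cut)
    write.table(scans[[rv]], file.path(cfg$outdir, paste0("scan_", rv, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res$scans <- scans

  # -- convergence ----------------------------------------------------------
  cand_sets <- lapply(scans, function(s) window_id(s[s$candidate, ]))
  res$overlap <- overlap_sets(cand_sets)
  all_cand <- do.call(rbind, lapply(scans, function(s)
    s[s$candidate, c("chrom", "start", "end")]))
  res$clusters <- cluster_sliding(unique(all_cand), hap_f$chrom_len,
                                  width = cfg$converge$cluster_width,
                                  step = cfg$converge$cluster_step)
  multi <- unique(unlist(cand_sets))
  if (length(multi)) {
    res$snp_count_test <- snp_count_permutation(
      multi, windows, n_perm = cfg$converge$n_perm,
      seed = stage_seed("converge"))
  }
  write.table(res$overlap, file.path(cfg$outdir, "overlap.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # -- enrichment -----------------------------------------------------------
  outlier_genes <- lapply(scans, function(s)
    genes_in_windows(s[s$candidate, ], ann$genes))
  usable <- vapply(outlier_genes, length, 1L) > 0
  res$outlier_genes <- outlier_genes
  if (all(usable) && !is.null(ann$focal)) {
    pw <- ann$pathways$gene[ann$pathways$pathway == ann$focal]
    res$enrichment <- multi_river_permutation(
      outlier_genes, pw, ann$background, rule = cfg$enrich$rule,
      any_k = cfg$enrich$any_k, n_perm = cfg$enrich$n_perm,
      seed = stage_seed("enrich"))
  }

  # -- structure ------------------------------------------------------------
  keep <- ld_prune(hap_f, window = cfg$structure$ld_window,
                   step = cfg$structure$ld_step, r2 = cfg$structure$ld_r2)
  res$pca <- global_pca(subset_hap(hap_f, sites = keep), popmap,
                        npc = cfg$structure$npc)
  freqs <- allele_freqs(hap_f, popmap)
  sfs_list <- list()
  for (rv in rivers) {
    pair <- river_pair(popmap, rv)
    pr <- choose_projection(freqs, c(pair$LP, pair$HP))
    sfs_list[[rv]] <- build_2dsfs(freqs, c(pair$LP, pair$HP), pr$m1, pr$m2)
  }
  res$sfs <- sfs_list

  # -- haplotype-region follow-up (needs the planted truth) -----------------
  if (!is.null(truth) && "CL" %in% names(truth$sweeps)) {
    sw <- truth$sweeps$CL
    region <- list(chrom = sw$chrom, start = sw$start, end = sw$end)
    carrier_hp <- names(sw$targets)[grepl("HP", names(sw$targets))][1]
    hp_samples <- pop_samples(popmap, carrier_hp)
    loc_hap <- subset_hap(hap_f, sites = which(hap_f$chrom == sw$chrom),
                          samples = hp_samples)
    res$local_pca <- tryCatch(
      local_pca_mds(loc_hap, win = cfg$haplo$win_snps, k = cfg$haplo$k,
                    npc = cfg$haplo$npc),
      error = function(e) NULL)
    res$haplogroups <- tryCatch(call_haplogroups(hap_f, region),
                                error = function(e) NULL)
    ap_pair <- river_pair(popmap, "Aripo")
    res$branch_contrast <- tryCatch(
      window_branch_contrast(hap_f, popmap, ap_pair$HP, ap_pair$LP, region,
                             width = cfg$haplo$tree_width),
      error = function(e) NULL)
  }
  res$manifest <- manifest
  jsonlite::write_json(list(package = manifest$package,
                            version = manifest$version,
                            config_hash = manifest$config_hash,
                            seed = manifest$seed,
                            stages = manifest$stages),
                       file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
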