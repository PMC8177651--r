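# Coordinate conventions: sites carry 1-based bp positions (as in VCF);
# windows and gene intervals are 0-based half-open (as in BED). A site at
# 1-based position p falls in window [a, b) iff a < p <= b.

#' Read a popmap TSV
#'
#' @param path TSV with header columns sample, population, river, drainage,
#'   predation.
#' @return A [pop_map()].
#' @export
read_popmap <- function(path) {
  pop_map(read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE))
}

#' Read phased genotypes from a VCF
#'
#' Requires phased GT ("|" separator) for every sample; multiallelic records
#' are skipped with a message. Every VCF sample must appear in the popmap.
#'
#' @param path VCF file (plain text or gzipped).
#' @param popmap_path Popmap TSV path (or an existing [pop_map()]).
#' @return List with `hap` ([hap_matrix()]) and `popmap` ([pop_map()]).
#' @export
read_vcf <- function(path, popmap_path) {
  popmap <- if (inherits(popmap_path, "pop_map")) popmap_path
            else read_popmap(popmap_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message(sum(multi), " multiallelic record(s) skipped")
    v <- v[!multi, ]
    fix <- vcfR::getFIX(v)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  missing <- setdiff(samples, popmap$sample)
  if (length(missing)) {
    stop("samples absent from popmap: ", paste(missing, collapse = ", "))
  }
  unphased <- which(grepl("/", gt, fixed = TRUE) & !is.na(gt))
  if (length(unphased)) {
    rc <- arrayInd(unphased[1], dim(gt))
    stop("unphased genotype at ", fix[rc[1], "CHROM"], ":", fix[rc[1], "POS"],
         " sample ", samples[rc[2]], " (phased GT required)")
  }
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  code <- function(a) {
    out <- rep(NA_integer_, length(a))
    out[a == "0"] <- 0L
    out[a == "1"] <- 1L
    out
  }
  S <- nrow(gt); n <- length(samples)
  geno <- matrix(NA_integer_, 2L * n, S)
  geno[seq(1, 2 * n, by = 2), ] <- t(matrix(code(a1), S, n))
  geno[seq(2, 2 * n, by = 2), ] <- t(matrix(code(a2), S, n))
  hap <- hap_matrix(geno, fix[, "CHROM"], as.integer(fix[, "POS"]), samples,
                    ref = fix[, "REF"], alt = fix[, "ALT"])
  list(hap = hap, popmap = popmap[match(samples, popmap$sample), ])
}

#' Write a haplotype matrix as a phased VCF 4.2
#'
#' @param hap A [hap_matrix()].
#' @param path Output path (plain text).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(hap, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=riverscan", as.character(packageVersion("riverscan"))),
               sprintf("##contig=<ID=%s,length=%d>", names(hap$chrom_len),
                       as.integer(hap$chrom_len)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", hap$samples), collapse = "\t")), con)
  n <- length(hap$samples)
  g1 <- hap$geno[seq(1, 2 * n, by = 2), , drop = FALSE]
  g2 <- hap$geno[seq(2, 2 * n, by = 2), , drop = FALSE]
  c1 <- ifelse(is.na(g1), ".", g1)
  c2 <- ifelse(is.na(g2), ".", g2)
  gtmat <- matrix(paste0(c1, "|", c2), nrow = n)
  body <- apply(gtmat, 2, paste, collapse = "\t")
  lines <- paste(hap$chrom, hap$pos, ".", hap$ref, hap$alt, ".", "PASS", ".",
                 "GT", body, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Site-level filters: minor allele frequency and per-population missingness
#'
#' Retains sites that are polymorphic across all samples, have minor allele
#' frequency (computed over all called chromosomes of all individuals)
#' at least `maf`, and are missing in at most `max_missing_per_pop` of the
#' individuals of every population. Idempotent.
#'
#' @param hap A [hap_matrix()].
#' @param popmap A [pop_map()].
#' @param maf Minimum global minor allele frequency (default 0.05).
#' @param max_missing_per_pop Maximum fraction of individuals with a missing
#'   genotype within any one population (default 0.5).
#' @return A filtered `hap_matrix` (possibly with zero sites).
#' @export
filter_sites <- function(hap, popmap, maf = 0.05, max_missing_per_pop = 0.5) {
  stopifnot(n_sites(hap) > 0)
  g <- hap$geno
  called <- colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  p <- ifelse(called > 0, alt / called, NA)
  keep <- !is.na(p) & pmin(p, 1 - p) >= maf & p > 0 & p < 1
  d <- dosage(hap)
  for (pp in unique(popmap$population)) {
    rows <- match(pop_samples(popmap, pp), hap$samples)
    miss <- colMeans(is.na(d[rows, , drop = FALSE]))
    keep <- keep & miss <= max_missing_per_pop
  }
  if (!any(keep)) message("filter_sites: no sites retained")
  subset_hap(hap, sites = which(keep))
}

#' Greedy LD pruning (plink indep-pairwise convention)
#'
#' Slides a window of `window` SNPs advancing by `step` over the retained
#' set; within a window, for every pair with squared dosage correlation above
#' `r2` the later site is removed. Passes repeat until no window of the
#' retained set contains an offending pair, so the result satisfies the
#' pairwise bound within every 50-SNP window of the retained sites.
#' Monomorphic sites have undefined r2 and are always retained.
#'
#' @param hap A [hap_matrix()].
#' @param window Window size in SNPs (default 50).
#' @param step Window increment in SNPs (default 5).
#' @param r2 Maximum allowed squared correlation (default 0.2).
#' @return Integer vector of retained site indices (increasing).
#' @export
ld_prune <- function(hap, window = 50L, step = 5L, r2 = 0.2) {
  S <- n_sites(hap)
  if (S < 2L) return(seq_len(S))
  d <- dosage(hap)
  v <- apply(d, 2, var, na.rm = TRUE)
  poly <- !is.na(v) & v > 0
  keep <- rep(TRUE, S)
  repeat {
    removed <- FALSE
    for (cc in unique(hap$chrom)) {
      on_c <- which(hap$chrom == cc & keep)
      if (length(on_c) < 2L) next
      starts <- seq(1L, max(1L, length(on_c) - 1L), by = step)
      for (ws in starts) {
        idx <- on_c[seq(ws, min(ws + window - 1L, length(on_c)))]
        idx <- idx[keep[idx] & poly[idx]]
        if (length(idx) < 2L) next
        cm <- suppressWarnings(cor(d[, idx, drop = FALSE],
                                   use = "pairwise.complete.obs"))
        cm[is.na(cm)] <- 0
        for (i in seq_len(length(idx) - 1L)) {
          if (!keep[idx[i]]) next
          for (j in seq((i + 1L), length(idx))) {
            if (keep[idx[j]] && cm[i, j]^2 > r2) {
              keep[idx[j]] <- FALSE
              removed <- TRUE
            }
          }
        }
      }
    }
    if (!removed) break
  }
  which(keep)
}

#' Thin sites to a minimum bp spacing
#'
#' Greedy per chromosome: the first site is kept, then every site at least
#' `interval` bp from the last kept site.
#'
#' @param hap A [hap_matrix()].
#' @param interval Minimum spacing in bp (default 20000).
#' @return Integer vector of retained site indices.
#' @export
thin_sites <- function(hap, interval = 20000) {
  keep <- integer(0)
  for (cc in unique(hap$chrom)) {
    idx <- which(hap$chrom == cc)
    last <- -Inf
    for (i in idx) {
      if (hap$pos[i] - last >= interval) {
        keep <- c(keep, i)
        last <- hap$pos[i]
      }
    }
  }
  keep
}

#' Build a window index over the sites of a haplotype matrix
#'
#' Three tiling modes: `"tile"` (non-overlapping windows of `width` bp,
#' exhaustive over `[0, chrom_len)`, terminal window truncated), `"slide"`
#' (windows of `width` advancing by `step`, full windows only), and `"snp"`
#' (consecutive blocks of `snp_count` sites; the terminal block may be
#' partial and is flagged).
#'
#' @param hap A [hap_matrix()].
#' @param mode One of "tile", "slide", "snp".
#' @param width,step Window geometry in bp (tile/slide).
#' @param snp_count Sites per window (snp mode).
#' @return A data frame of class `window_index`: `chrom`, `start`, `end`
#'   (0-based half-open), `n_snps`, `partial`, and a list column `sites` of
#'   site indices.
#' @export
make_windows <- function(hap, mode = c("tile", "slide", "snp"),
                         width = 10000, step = width / 2, snp_count = 100L) {
  mode <- match.arg(mode)
  rows <- list()
  for (cc in unique(hap$chrom)) {
    idx <- which(hap$chrom == cc)
    len <- as.double(hap$chrom_len[[cc]])
    if (mode == "snp") {
      grp <- ceiling(seq_along(idx) / snp_count)
      for (g in unique(grp)) {
        gi <- idx[grp == g]
        rows[[length(rows) + 1L]] <- list(
          chrom = cc, start = hap$pos[gi[1]] - 1, end = hap$pos[gi[length(gi)]],
          n_snps = length(gi), partial = length(gi) < snp_count, sites = gi)
      }
    } else {
      starts <- if (mode == "tile") seq(0, max(0, len - 1), by = width)
                else if (len >= width) seq(0, len - width, by = step)
                else numeric(0)
      for (s in starts) {
        e <- if (mode == "tile") min(s + width, len) else s + width
        gi <- idx[hap$pos[idx] > s & hap$pos[idx] <= e]
        rows[[length(rows) + 1L]] <- list(
          chrom = cc, start = s, end = e, n_snps = length(gi),
          partial = (e - s) < width, sites = gi)
      }
    }
  }
  out <- data.frame(chrom = vapply(rows, `[[`, "", "chrom"),
                    start = vapply(rows, `[[`, 0, "start"),
                    end = vapply(rows, `[[`, 0, "end"),
                    n_snps = vapply(rows, function(r) as.integer(r$n_snps), 1L),
                    partial = vapply(rows, `[[`, TRUE, "partial"),
                    stringsAsFactors = FALSE)
  out$sites <- lapply(rows, `[[`, "sites")
  class(out) <- c("window_index", "data.frame")
  out
}

#' Per-site, per-population allele frequencies and call counts
#'
#' @param hap A [hap_matrix()].
#' @param popmap A [pop_map()].
#' @return A `freq_table`: list with matrices `p` (ALT frequency), `n`
#'   (called chromosomes) and `k` (ALT allele count), sites in rows and
#'   populations in columns, plus `chrom`/`pos`. A population with zero
#'   called chromosomes at a site gets `p = NA`.
#' @export
allele_freqs <- function(hap, popmap) {
  pops <- unique(popmap$population)
  S <- n_sites(hap)
  p <- n <- k <- matrix(NA_real_, S, length(pops),
                        dimnames = list(NULL, pops))
  for (pp in pops) {
    rows <- hap_rows(hap, pop_samples(popmap, pp))
    g <- hap$geno[rows, , drop = FALSE]
    n[, pp] <- colSums(!is.na(g))
    k[, pp] <- colSums(g, na.rm = TRUE)
    p[, pp] <- ifelse(n[, pp] > 0, k[, pp] / n[, pp], NA)
  }
  structure(list(p = p, n = n, k = k, chrom = hap$chrom, pos = hap$pos,
                 pops = pops, chrom_len = hap$chrom_len),
            class = "freq_table")
}
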