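#' Phased haplotype matrix
#'
#' The universal substrate of the pipeline: phased biallelic alleles for H
#' haplotypes at S sites. Haplotypes `2i-1` and `2i` belong to diploid sample
#' `i`. Sites are strictly ordered by position within chromosome.
#'
#' @param geno Integer matrix, haplotypes in rows, sites in columns; entries
#'   0 (REF), 1 (ALT) or `NA` (missing call).
#' @param chrom Character vector of chromosome ids, one per site.
#' @param pos Integer vector of 1-based bp positions (1-based internally at
#'   the site level; window/interval arithmetic is 0-based half-open).
#' @param samples Character vector of sample ids, `nrow(geno)/2` long.
#' @param ref,alt Optional allele labels per site (default "A"/"T").
#' @param chrom_len Optional named vector of chromosome lengths (bp); used by
#'   window tiling. Defaults to the maximum observed position per chromosome.
#' @return An object of class `hap_matrix`.
#' @export
hap_matrix <- function(geno, chrom, pos, samples, ref = NULL, alt = NULL,
                       chrom_len = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  S <- ncol(geno)
  if (nrow(geno) %% 2L != 0L) stop("haplotype count must be even")
  if (length(samples) * 2L != nrow(geno)) {
    stop("need exactly 2 haplotypes per sample")
  }
  if (length(chrom) != S || length(pos) != S) {
    stop("chrom/pos length must match site count")
  }
  if (S > 0 && !all(geno == 0L | geno == 1L, na.rm = TRUE)) {
    stop("alleles must be 0, 1 or NA (biallelic)")
  }
  o <- order(match(chrom, unique(chrom)), pos)
  geno <- geno[, o, drop = FALSE]
  chrom <- chrom[o]
  pos <- as.integer(pos[o])
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (anyDuplicated(p)) stop("duplicate positions on ", cc)
  }
  if (is.null(chrom_len)) {
    chrom_len <- tapply(pos, chrom, max)
    chrom_len <- setNames(as.double(chrom_len), names(chrom_len))
    chrom_len <- chrom_len[unique(chrom)]
  }
  structure(list(
    geno = geno, chrom = chrom, pos = pos,
    ref = ref %||% rep("A", S), alt = alt %||% rep("T", S),
    samples = as.character(samples),
    chrom_len = chrom_len
  ), class = "hap_matrix")
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d haplotypes (%d samples) x %d sites on %d chromosome(s)\n",
              nrow(x$geno), length(x$samples), ncol(x$geno),
              length(unique(x$chrom))))
  invisible(x)
}

#' Number of sites / samples in a haplotype matrix
#' @param x A `hap_matrix`.
#' @return Integer count.
#' @export
n_sites <- function(x) ncol(x$geno)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

#' Subset a haplotype matrix by site index and/or samples
#'
#' @param x A `hap_matrix`.
#' @param sites Integer site indices to keep (default all).
#' @param samples Character sample ids to keep (default all).
#' @return A `hap_matrix`.
#' @export
subset_hap <- function(x, sites = NULL, samples = NULL) {
  sites <- sites %||% seq_len(n_sites(x))
  keep_s <- x$samples
  if (!is.null(samples)) {
    missing <- setdiff(samples, x$samples)
    if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
    keep_s <- x$samples[x$samples %in% samples]
  }
  hrows <- as.vector(rbind(2L * match(keep_s, x$samples) - 1L,
                           2L * match(keep_s, x$samples)))
  hap_matrix(x$geno[hrows, sites, drop = FALSE], x$chrom[sites], x$pos[sites],
             keep_s, x$ref[sites], x$alt[sites], chrom_len = x$chrom_len)
}

#' Diploid dosage matrix (samples x sites)
#'
#' Counts of the ALT allele per genotype (0/1/2); `NA` if either haplotype is
#' missing.
#'
#' @param x A `hap_matrix`.
#' @return Numeric matrix, samples in rows.
#' @export
dosage <- function(x) {
  g <- x$geno
  n <- length(x$samples)
  d <- g[seq(1, 2 * n, by = 2), , drop = FALSE] +
    g[seq(2, 2 * n, by = 2), , drop = FALSE]
  rownames(d) <- x$samples
  d
}

# haplotype row indices of a set of samples
hap_rows <- function(x, samples) {
  idx <- match(samples, x$samples)
  if (anyNA(idx)) stop("unknown samples: ",
                       paste(samples[is.na(idx)], collapse = ", "))
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

#' Population map
#'
#' Sample-to-population hierarchy with predation labels. Each sample maps to
#' exactly one population, each population to one river and drainage.
#'
#' @param df Data frame with columns `sample`, `population`, `river`,
#'   `drainage`, `predation` (values "HP"/"LP").
#' @return A `pop_map` (validated data frame).
#' @export
pop_map <- function(df) {
  need <- c("sample", "population", "river", "drainage", "predation")
  if (!all(need %in% names(df))) {
    stop("popmap needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  for (cc in need) df[[cc]] <- as.character(df[[cc]])
  if (anyDuplicated(df$sample)) stop("duplicated sample ids in popmap")
  if (!all(df$predation %in% c("HP", "LP"))) {
    stop("predation must be 'HP' or 'LP'")
  }
  per_pop <- unique(df[c("population", "river", "drainage", "predation")])
  if (anyDuplicated(per_pop$population)) {
    stop("inconsistent river/drainage/predation within a population")
  }
  class(df) <- c("pop_map", "data.frame")
  df
}

#' Check the paired HP/LP design of a river
#'
#' Every scanned river must have exactly one HP and one LP population.
#'
#' @param popmap A `pop_map`.
#' @param river River id.
#' @return Named list with elements `HP` and `LP` (population ids).
#' @export
river_pair <- function(popmap, river) {
  sub <- unique(popmap[popmap$river == river, c("population", "predation")])
  hp <- sub$population[sub$predation == "HP"]
  lp <- sub$population[sub$predation == "LP"]
  if (length(hp) != 1L || length(lp) != 1L) {
    stop("river '", river, "' must have exactly one HP and one LP population")
  }
  list(HP = hp, LP = lp)
}

pop_samples <- function(popmap, pop) popmap$sample[popmap$population == pop]
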