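#' Local PCA across SNP windows with MDS embedding
#'
#' Summarises each window of `win` SNPs by the rank-`k` eigen-approximation
#' of its sample-covariance matrix (eigenvalues normalised by the window's
#' total variance, so the summary is scale-free and invariant to eigenvector
#' sign or rotation within ties). Windows are compared by the Frobenius
#' distance between these reconstructions and embedded with classical
#' (Torgerson) MDS; windows of deviant local ancestry (inversions, large
#' divergent haplotypes) separate on the leading axes.
#'
#' @param hap A [hap_matrix()] for one chromosome (typically one
#'   population's samples). Sites invariant among the given samples are
#'   removed before windowing.
#' @param win Window size in SNPs (default 100).
#' @param k Eigenvectors retained per window (default 2).
#' @param npc MDS axes returned (default 2).
#' @return A `local_pca_result`: list with `windows` (chrom/start/end/
#'   n_snps/rank), `mds` (windows x npc), `dist` (window distance matrix).
#' @export
local_pca_mds <- function(hap, win = 100L, k = 2L, npc = 2L) {
  stopifnot(length(unique(hap$chrom)) == 1L)
  d <- dosage(hap)
  v <- apply(d, 2, var, na.rm = TRUE)
  poly <- which(!is.na(v) & v > 0)
  sub <- subset_hap(hap, sites = poly)
  S <- n_sites(sub)
  n_win <- S %/% win
  if (n_win < 3L) stop("need at least 3 full windows of ", win, " SNPs")
  d <- dosage(sub)
  recon <- vector("list", n_win)
  meta <- data.frame(chrom = character(n_win), start = numeric(n_win),
                     end = numeric(n_win), n_snps = integer(n_win),
                     rank = integer(n_win), stringsAsFactors = FALSE)
  for (w in seq_len(n_win)) {
    s <- ((w - 1L) * win + 1L):(w * win)
    X <- scale(d[, s, drop = FALSE], center = TRUE, scale = FALSE)
    X[is.na(X)] <- 0
    C <- tcrossprod(X) / (length(s) - 1L)
    ev <- eigen(C, symmetric = TRUE)
    tot <- sum(pmax(ev$values, 0))
    kk <- min(k, sum(ev$values > 1e-12))
    R <- matrix(0, nrow(C), ncol(C))
    for (i in seq_len(kk)) {
      R <- R + (ev$values[i] / tot) * tcrossprod(ev$vectors[, i])
    }
    recon[[w]] <- R
    meta$chrom[w] <- sub$chrom[s[1]]
    meta$start[w] <- sub$pos[s[1]] - 1
    meta$end[w] <- sub$pos[s[length(s)]]
    meta$n_snps[w] <- length(s)
    meta$rank[w] <- kk
  }
  dm <- matrix(0, n_win, n_win)
  for (i in seq_len(n_win - 1L)) for (j in (i + 1L):n_win) {
    dm[i, j] <- dm[j, i] <- sqrt(sum((recon[[i]] - recon[[j]])^2))
  }
  mds <- cmdscale(dm, k = min(npc, n_win - 1L))
  structure(list(windows = meta, mds = mds, dist = dm),
            class = "local_pca_result")
}

#' Call haplogroups from regional PC1 clusters
#'
#' PCA over the region's dosages; PC1 is clustered into at most three groups
#' by 1-D k-means with deterministic initialisation at the PC1 minimum,
#' median and maximum. Clusters are ordered along PC1; homozygote labels are
#' assigned by mean regional dosage, so the heterozygote cluster always lies
#' between the two homozygote clusters.
#'
#' @param hap A [hap_matrix()].
#' @param region List or data frame row with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param min_snps Minimum polymorphic sites required (default 10).
#' @return A `haplogroup_call`: data frame (sample, pc1, cluster, group with
#'   levels hom_ref/het/hom_alt) plus attributes `n_clusters`, `flagged`,
#'   `pc1_varexp`.
#' @export
call_haplogroups <- function(hap, region, min_snps = 10L) {
  idx <- which(hap$chrom == region$chrom & hap$pos > region$start &
                 hap$pos <= region$end)
  if (length(idx) < min_snps) stop("region has fewer than ", min_snps,
                                   " polymorphic sites")
  d <- dosage(hap)[, idx, drop = FALSE]
  v <- apply(d, 2, var, na.rm = TRUE)
  d <- d[, !is.na(v) & v > 0, drop = FALSE]
  if (ncol(d) == 0L) {
    # all individuals identical over the region: one degenerate cluster
    out <- data.frame(sample = hap$samples, pc1 = 0,
                      cluster = 1L, group = "single",
                      stringsAsFactors = FALSE)
    attr(out, "n_clusters") <- 1L
    attr(out, "flagged") <- TRUE
    attr(out, "pc1_varexp") <- NA_real_
    class(out) <- c("haplogroup_call", "data.frame")
    return(out)
  }
  if (ncol(d) < min_snps) stop("region has fewer than ", min_snps,
                               " polymorphic sites")
  X <- scale(d, center = TRUE, scale = FALSE)
  X[is.na(X)] <- 0
  pc <- prcomp(X, center = FALSE)
  pc1 <- pc$x[, 1]
  varexp <- pc$sdev[1]^2 / sum(pc$sdev^2)
  uq <- sort(unique(round(pc1, 10)))
  n_cl <- min(3L, length(uq))
  flagged <- n_cl < 3L
  if (n_cl == 1L) {
    cl <- rep(1L, length(pc1))
    centers <- mean(pc1)
  } else {
    mid <- median(pc1)
    # the median collapses onto an extreme when one cluster holds most
    # samples; fall back to the midpoint so the init stays distinct
    if (mid <= min(pc1) || mid >= max(pc1)) mid <- (min(pc1) + max(pc1)) / 2
    init <- matrix(c(min(pc1), if (n_cl == 3L) mid, max(pc1)), ncol = 1)
    km <- kmeans(matrix(pc1, ncol = 1), centers = init)
    ord <- order(km$centers[, 1])
    cl <- match(km$cluster, ord)
    centers <- sort(km$centers[, 1])
  }
  mean_dos <- tapply(rowMeans(d, na.rm = TRUE), cl, mean)
  ord_dos <- order(mean_dos)   # ascending dosage: hom_ref, (het), hom_alt
  labels <- rep(NA_character_, n_cl)
  if (n_cl == 3L) labels[ord_dos] <- c("hom_ref", "het", "hom_alt")
  if (n_cl == 2L) labels[ord_dos] <- c("hom_ref", "hom_alt")
  if (n_cl == 1L) labels <- "single"
  out <- data.frame(sample = hap$samples, pc1 = pc1,
                    cluster = cl, group = labels[cl],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_clusters") <- n_cl
  attr(out, "flagged") <- flagged
  attr(out, "pc1_varexp") <- varexp
  attr(out, "centers") <- centers
  class(out) <- c("haplogroup_call", "data.frame")
  out
}

#' Nei's standard genetic distance between two frequency profiles
#'
#' `D = -ln( Jxy / sqrt(Jx Jy) )` with `Jx` the mean across loci of the
#' summed squared allele frequencies and `Jxy` the mean cross-product.
#' Profiles are per-locus ALT frequencies (diploid individuals: dosage/2).
#' A zero normalised identity gives an infinite distance, which is returned
#' as `Inf` with attribute `infinite = TRUE`.
#'
#' @param x,y Numeric vectors of ALT allele frequencies over shared loci.
#' @return Nei's distance (>= 0, possibly `Inf`).
#' @export
nei_distance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  if (!length(x)) stop("no shared loci")
  jx <- mean(x^2 + (1 - x)^2)
  jy <- mean(y^2 + (1 - y)^2)
  jxy <- mean(x * y + (1 - x) * (1 - y))
  if (jxy <= 0) {
    out <- Inf
    attr(out, "infinite") <- TRUE
    return(out)
  }
  max(0, -log(jxy / sqrt(jx * jy)))
}

# pairwise Nei distance matrix between individuals (rows of a dosage matrix);
# J_xy for all pairs at once via cross-products of the frequency profiles
nei_dist_matrix <- function(dos) {
  prof <- dos / 2
  if (anyNA(prof)) return(nei_dist_matrix_slow(prof))
  L <- ncol(prof)
  jxy <- (tcrossprod(prof) + tcrossprod(1 - prof)) / L
  jd <- diag(jxy)
  dm <- -log(jxy / sqrt(outer(jd, jd)))
  dm[jxy <= 0] <- Inf
  dm <- pmax(dm, 0)
  diag(dm) <- 0
  dimnames(dm) <- list(rownames(prof), rownames(prof))
  dm
}

nei_dist_matrix_slow <- function(prof) {
  n <- nrow(prof)
  dm <- matrix(0, n, n, dimnames = list(rownames(prof), rownames(prof)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dm[i, j] <- dm[j, i] <- nei_distance(prof[i, ], prof[j, ])
  }
  dm
}

#' BIONJ tree from a distance matrix
#'
#' Variance-weighted neighbor joining (BIONJ); negative branch lengths are
#' clamped to zero with the total deficit recorded. On additive distances
#' BIONJ recovers the tree exactly.
#'
#' @param d Distance matrix (or `dist`).
#' @return An `ape::phylo` tree with attribute `clamped` (sum of clamped
#'   negative length).
#' @export
bionj_tree <- function(d) {
  dm <- as.matrix(d)
  if (any(!is.finite(dm))) stop("distances must be finite for tree building")
  tr <- ape::bionj(as.dist(dm))
  neg <- tr$edge.length < 0
  clamped <- -sum(tr$edge.length[neg])
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Windowed between-population branch-length contrast
#'
#' In each window of `width` bp along the focal chromosome, a BIONJ tree is
#' built from pairwise Nei distances between the individuals of both
#' populations, and the mean tree-path distance over all between-population
#' pairs is taken. The focal region's value is then located as a percentile
#' of the chromosome-wide window distribution; an old divergent haplotype
#' segregating between the populations puts the focal region in the upper
#' tail. Windows with infinite Nei distances or fewer than `min_snps` sites
#' are dropped (logged in `n_dropped`).
#'
#' @param hap A [hap_matrix()].
#' @param popmap A [pop_map()].
#' @param pop_a,pop_b Population ids contrasted.
#' @param focal List with `chrom`, `start`, `end` (0-based half-open).
#' @param width Window width in bp (default 1e5).
#' @param min_snps Minimum polymorphic sites per window (default 5).
#' @return A `tree_window_result`: list with `windows` (chrom/start/end/
#'   mean_dist), `focal_dist`, `percentile` (0-100), `n_dropped`.
#' @export
window_branch_contrast <- function(hap, popmap, pop_a, pop_b, focal,
                                   width = 1e5, min_snps = 5L) {
  samples <- c(pop_samples(popmap, pop_a), pop_samples(popmap, pop_b))
  sub <- subset_hap(hap, sites = which(hap$chrom == focal$chrom),
                    samples = samples)
  is_a <- sub$samples %in% pop_samples(popmap, pop_a)
  len <- as.double(sub$chrom_len[[focal$chrom]])
  starts <- seq(0, max(0, len - 1), by = width)
  mean_pair_dist <- function(site_idx) {
    if (length(site_idx) < min_snps) return(NA_real_)
    dos <- dosage(subset_hap(sub, sites = site_idx))
    v <- apply(dos, 2, var, na.rm = TRUE)
    dos <- dos[, !is.na(v) & v > 0, drop = FALSE]
    if (ncol(dos) < min_snps) return(NA_real_)
    dm <- nei_dist_matrix(dos)
    if (any(!is.finite(dm))) return(NA_real_)
    tr <- bionj_tree(dm)
    pd <- ape::cophenetic.phylo(tr)[sub$samples, sub$samples]
    mean(pd[is_a, !is_a])
  }
  vals <- vapply(starts, function(s) {
    mean_pair_dist(which(sub$pos > s & sub$pos <= min(s + width, len)))
  }, 0)
  # background = windows not overlapping the focal region, so the focal
  # value is contrasted against the rest of the chromosome
  overlaps <- starts < focal$end & (starts + width) > focal$start
  usable <- !is.na(vals) & !overlaps
  if (sum(usable) < 3L) stop("fewer than 3 usable background windows on the chromosome")
  focal_idx <- which(sub$pos > focal$start & sub$pos <= focal$end)
  focal_dist <- mean_pair_dist(focal_idx)
  if (is.na(focal_dist)) stop("focal region has no usable distance")
  percentile <- 100 * mean(vals[usable] <= focal_dist)
  structure(list(windows = data.frame(chrom = focal$chrom, start = starts,
                                      end = pmin(starts + width, len),
                                      mean_dist = vals),
                 focal_dist = focal_dist, percentile = percentile,
                 n_dropped = sum(!usable)),
            class = "tree_window_result")
}
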