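#' Genes overlapping a set of windows
#'
#' A gene is included when it overlaps any window by at least 1 bp. Both gene
#' intervals and windows are 0-based half-open, so a gene starting exactly at
#' a window's end does not overlap it.
#'
#' @param windows Data frame of windows (`chrom`, `start`, `end`).
#' @param genes Data frame of gene intervals (`gene`, `chrom`, `start`,
#'   `end`).
#' @return Character vector of overlapping gene ids (sorted, unique).
#' @export
genes_in_windows <- function(windows, genes) {
  hit <- logical(nrow(genes))
  for (cc in unique(windows$chrom)) {
    w <- windows[windows$chrom == cc, , drop = FALSE]
    gi <- which(genes$chrom == cc)
    if (!length(gi) || !nrow(w)) next
    for (i in gi) {
      hit[i] <- any(genes$start[i] < w$end & genes$end[i] > w$start)
    }
  }
  sort(unique(genes$gene[hit]))
}

#' Fold enrichment of a pathway among outlier genes
#'
#' The standard over-representation ratio `FE = (k/n) / (K/N)`: the share of
#' outlier genes in the pathway relative to the pathway's share of the
#' background.
#'
#' @param outlier_genes Character vector of outlier genes (must be a subset
#'   of the background).
#' @param pathway_genes Character vector of the pathway's genes.
#' @param background Character vector of all background genes.
#' @return Numeric FE; 0 when no outlier genes are given (flagged with
#'   attribute `empty_outliers`).
#' @export
fold_enrichment <- function(outlier_genes, pathway_genes, background) {
  N <- length(unique(background))
  K <- length(intersect(pathway_genes, background))
  if (K == 0) stop("pathway has no background genes; FE undefined")
  n <- length(unique(outlier_genes))
  if (n == 0) {
    out <- 0
    attr(out, "empty_outliers") <- TRUE
    return(out)
  }
  k <- length(intersect(outlier_genes, pathway_genes))
  (k / n) / (K / N)
}

#' Multi-river permutation test for pathway-level convergence
#'
#' The tested pattern is cross-river convergence: fold enrichment of the
#' pathway exceeds 1 in all rivers ("all") or in at least `any_k` rivers
#' ("any_k"). The null draws, for each river independently, a random outlier
#' set of the observed size uniformly without replacement from the
#' background; pathway-size weighting arises implicitly because larger
#' pathways capture proportionally more random genes. The reported `p` is the
#' +1-corrected Monte-Carlo probability that a null permutation shows at
#' least as many FE > 1 rivers as observed (so a pathway equal to the whole
#' background, where FE is identically 1, gets p = 1). Under uniform
#' sampling the pathway hit count is exactly hypergeometric, so null draws
#' use `rhyper()` directly (`sampler = "uniform"`); `sampler = "stratified"`
#' materialises gene sets with per-gene weights proportional to
#' pathway-membership counts.
#'
#' @param outlier_sets Named list: river -> character vector of outlier
#'   genes.
#' @param pathway_genes The focal pathway's genes.
#' @param background All background genes.
#' @param rule "all" or "any_k".
#' @param any_k Rivers required under "any_k" (default 4).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @param sampler "uniform" (hypergeometric) or "stratified".
#' @param memberships Data frame (`gene`, `pathway`) needed for the
#'   stratified sampler.
#' @return An `enrichment_result`: list with per-river `fe`, `k`, `n`, `K`,
#'   `N`, the rule, `t_obs` (rivers with FE > 1), `observed_met`, `p` (the
#'   Monte-Carlo probability, +1-corrected, of a null permutation matching or
#'   exceeding the observed number of FE > 1 rivers), `p_rule` (probability
#'   of a null permutation satisfying the rule itself), `n_perm`, `seed`.
#' @export
multi_river_permutation <- function(outlier_sets, pathway_genes, background,
                                    rule = c("all", "any_k"), any_k = 4L,
                                    n_perm = 10000L, seed = NULL,
                                    sampler = c("uniform", "stratified"),
                                    memberships = NULL) {
  rule <- match.arg(rule)
  sampler <- match.arg(sampler)
  if (!is.null(seed)) set.seed(seed)
  background <- unique(background)
  N <- length(background)
  pw <- intersect(unique(pathway_genes), background)
  K <- length(pw)
  if (K == 0) stop("pathway has no background genes")
  sizes <- vapply(outlier_sets, function(s) length(unique(s)), 1L)
  if (any(sizes > N)) stop("an outlier set exceeds the background size")
  if (any(sizes == 0)) stop("every river needs >= 1 outlier gene")
  fe <- ks <- numeric(length(outlier_sets))
  for (i in seq_along(outlier_sets)) {
    ks[i] <- length(intersect(outlier_sets[[i]], pw))
    fe[i] <- (ks[i] / sizes[i]) / (K / N)
  }
  need <- if (rule == "all") length(outlier_sets) else any_k
  t_obs <- sum(fe > 1)
  observed_met <- t_obs >= need
  crit <- K / N * sizes  # k/n > K/N  <=>  k > K/N * n
  if (sampler == "uniform") {
    hits <- matrix(rhyper(n_perm * length(sizes), K, N - K,
                          rep(sizes, each = n_perm)),
                   nrow = n_perm)
    t_null <- rowSums(sweep(hits, 2, crit, ">"))
  } else {
    if (is.null(memberships)) stop("stratified sampler needs 'memberships'")
    wts <- table(factor(memberships$gene, levels = background))
    wts <- as.numeric(wts) + 1  # +1 so unannotated genes remain drawable
    t_null <- integer(n_perm)
    for (b in seq_len(n_perm)) {
      t_null[b] <- sum(vapply(seq_along(sizes), function(i) {
        draw <- sample(background, sizes[i], prob = wts)
        length(intersect(draw, pw)) > crit[i]
      }, TRUE))
    }
  }
  structure(list(fe = setNames(fe, names(outlier_sets)),
                 k = setNames(ks, names(outlier_sets)),
                 n = setNames(sizes, names(outlier_sets)), K = K, N = N,
                 rule = rule, any_k = any_k, t_obs = t_obs,
                 observed_met = observed_met,
                 p = (1 + sum(t_null >= t_obs)) / (n_perm + 1),
                 p_rule = (1 + sum(t_null >= need)) / (n_perm + 1),
                 n_perm = n_perm, seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("pathway enrichment (%s rule): FE > 1 in %d/%d rivers; p = %.4g\n",
              x$rule, sum(x$fe > 1), length(x$fe), x$p))
  invisible(x)
}
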