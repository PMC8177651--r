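# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles along a different code path than the package
# (explicit loops, per-allele sums, factorials), so agreement is evidence of
# correctness rather than repetition.

# AFD via the general per-allele definition: sum over both alleles of
# |p1a - p2a| / 2
afd_bf <- function(p1, p2) {
  mapply(function(a, b) {
    (abs(a - b) + abs((1 - a) - (1 - b))) / 2
  }, p1, p2)
}

# Hudson FST components, scalar arithmetic
hudson_bf <- function(p1, p2, n1, n2) {
  num <- den <- numeric(length(p1))
  for (i in seq_along(p1)) {
    num[i] <- (p1[i] - p2[i])^2 -
      p1[i] * (1 - p1[i]) / (n1[i] - 1) -
      p2[i] * (1 - p2[i]) / (n2[i] - 1)
    den[i] <- p1[i] * (1 - p2[i]) + p2[i] * (1 - p1[i])
  }
  list(num = num, den = den, ratio = sum(num) / sum(den))
}

# Nei's distance step by step from per-locus identities
nei_bf <- function(x, y) {
  jx <- jy <- jxy <- 0
  L <- length(x)
  for (l in seq_len(L)) {
    jx <- jx + x[l]^2 + (1 - x[l])^2
    jy <- jy + y[l]^2 + (1 - y[l])^2
    jxy <- jxy + x[l] * y[l] + (1 - x[l]) * (1 - y[l])
  }
  -log((jxy / L) / sqrt((jx / L) * (jy / L)))
}

# fold enrichment from the 2x2 contingency construction
fe_bf <- function(outliers, pathway, background) {
  k <- sum(outliers %in% pathway)
  n <- length(outliers)
  K <- sum(background %in% pathway)
  N <- length(background)
  (k / n) / (K / N)
}

# exact-subset overlap by per-window membership tabulation
overlap_bf <- function(sets) {
  u <- unique(unlist(sets))
  out <- list()
  for (w in u) {
    members <- names(sets)[vapply(sets, function(s) w %in% s, TRUE)]
    key <- paste(members, collapse = "+")
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# hypergeometric projection via explicit factorials
project_bf <- function(k, n, m) {
  ch <- function(a, b) {
    if (b < 0 || b > a) return(0)
    factorial(a) / (factorial(b) * factorial(a - b))
  }
  vapply(0:m, function(j) ch(k, j) * ch(n - k, m - j) / ch(n, m), 0)
}

# EHH by exhaustive haplotype-class enumeration over the span (core, x]
ehh_bf <- function(geno, core, x) {
  n <- nrow(geno)
  if (x == core) return(1)
  span <- if (x > core) (core + 1):x else x:(core - 1)
  keys <- apply(geno[, span, drop = FALSE], 1, paste, collapse = "")
  cnt <- table(keys)
  sum(choose(cnt, 2)) / choose(n, 2)
}

# f4 via explicit site loop
f4_bf <- function(pa, pb, pc, pd) {
  tot <- 0
  for (i in seq_along(pa)) tot <- tot + (pa[i] - pb[i]) * (pc[i] - pd[i])
  tot / length(pa)
}

# build a tiny hap_matrix by hand
toy_hap <- function(geno, pos = NULL, chrom = NULL, chrom_len = NULL) {
  S <- ncol(geno)
  hap_matrix(geno, chrom %||% rep("chr1", S), pos %||% (seq_len(S) * 100),
             samples = paste0("s", seq_len(nrow(geno) / 2)),
             chrom_len = chrom_len)
}

toy_popmap <- function(samples, pops, rivers = NULL, predation = NULL) {
  upop <- unique(pops)
  pred_by_pop <- predation %||%
    setNames(rep(c("HP", "LP"), length.out = length(upop)), upop)
  pop_map(data.frame(sample = samples, population = pops,
                     river = rivers %||% "R1", drainage = "D1",
                     predation = unname(pred_by_pop[pops])))
}
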