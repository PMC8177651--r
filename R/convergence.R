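#' Exact-subset overlap tabulation of per-river candidate windows
#'
#' Partitions the union of all rivers' candidate windows by the exact subset
#' of rivers sharing each window (the cells of an upset plot / Venn diagram).
#'
#' @param sets Named list: river -> character vector of window ids (any
#'   stable id; `window_id()` builds "chrom:start-end").
#' @return An `overlap_summary`: data frame with `subset` (river names joined
#'   by "+", in input order), `degree` (number of rivers) and `count`; set
#'   sizes in attribute `set_sizes`. Subset counts sum to the size of the
#'   union.
#' @export
overlap_sets <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  rivers <- names(sets)
  all_w <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) all_w %in% s, logical(length(all_w)))
  if (length(all_w) == 1L) memb <- matrix(memb, nrow = 1,
                                          dimnames = list(NULL, rivers))
  key <- apply(memb, 1, function(r) paste(rivers[r], collapse = "+"))
  tab <- table(key)
  # enumerate every nonempty subset so zero cells are explicit
  subsets <- unlist(lapply(seq_along(rivers), function(k) {
    combn(rivers, k, paste, collapse = "+", simplify = TRUE)
  }))
  out <- data.frame(subset = subsets,
                    degree = lengths(strsplit(subsets, "+", fixed = TRUE)),
                    count = as.integer(tab[subsets]),
                    stringsAsFactors = FALSE)
  out$count[is.na(out$count)] <- 0L
  attr(out, "set_sizes") <- vapply(sets, function(s) length(unique(s)), 1L)
  attr(out, "union_size") <- length(all_w)
  class(out) <- c("overlap_summary", "data.frame")
  out
}

#' Window id strings for overlap tabulation
#' @param windows A data frame with `chrom`, `start`, `end`.
#' @return Character vector "chrom:start-end".
#' @export
window_id <- function(windows) {
  sprintf("%s:%.0f-%.0f", windows$chrom, windows$start, windows$end)
}

#' Cluster candidate windows into larger regions with sliding windows
#'
#' Slides `width` windows in `step` increments over each chromosome, counts
#' the candidate windows contained in each, and merges maximal runs of
#' consecutive sliding windows containing at least one candidate into
#' regions.
#'
#' @param candidates Data frame of candidate windows (`chrom`, `start`,
#'   `end`), 0-based half-open.
#' @param chrom_len Named chromosome lengths.
#' @param width Sliding window width in bp (default 1e5).
#' @param step Increment in bp (default 5e4).
#' @return List with `sliding` (all sliding windows and their contained
#'   candidate counts) and `regions` (merged regions, `chrom`/`start`/`end`/
#'   `n_candidates`).
#' @export
cluster_sliding <- function(candidates, chrom_len, width = 1e5, step = 5e4) {
  slid <- list(); regions <- list()
  for (cc in names(chrom_len)) {
    len <- as.double(chrom_len[[cc]])
    starts <- if (len >= width) seq(0, len - width, by = step) else 0
    cand <- candidates[candidates$chrom == cc, , drop = FALSE]
    counts <- vapply(starts, function(s) {
      sum(cand$start >= s & cand$end <= s + width)
    }, 0)
    slid[[cc]] <- data.frame(chrom = cc, start = starts,
                             end = pmin(starts + width, len), count = counts)
    hit <- counts > 0
    if (any(hit)) {
      r <- rle(hit)
      ends_i <- cumsum(r$lengths)
      starts_i <- ends_i - r$lengths + 1L
      for (j in which(r$values)) {
        s <- starts[starts_i[j]]
        e <- min(starts[ends_i[j]] + width, len)
        inside <- cand$start >= s & cand$end <= e
        regions[[length(regions) + 1L]] <-
          data.frame(chrom = cc, start = s, end = e,
                     n_candidates = sum(inside))
      }
    }
  }
  list(sliding = do.call(rbind, slid),
       regions = if (length(regions)) do.call(rbind, regions)
                 else data.frame(chrom = character(0), start = numeric(0),
                                 end = numeric(0), n_candidates = integer(0)))
}

#' Permutation check of SNP counts in outlier windows
#'
#' Low-SNP windows have noisier statistics; this test asks whether outlier
#' windows carry unusually many (or few) SNPs. The observed median SNP count
#' of the outlier windows is compared with medians of equally many windows
#' drawn at random (without replacement) from the genome-wide window set.
#' P-values carry the +1 Monte-Carlo correction, so they are never 0 and
#' never exceed 1.
#'
#' @param outlier_ids Window ids of the outlier set (subset of
#'   `window_id(all_windows)`).
#' @param all_windows Data frame of all windows with `chrom`, `start`, `end`,
#'   `n_snps`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed.
#' @return List: `observed_median`, `p_more` (one-tailed, outliers have more
#'   SNPs), `p_less`, `null_median_mean`, `n_perm`.
#' @export
snp_count_permutation <- function(outlier_ids, all_windows, n_perm = 10000L,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- window_id(all_windows)
  if (!all(outlier_ids %in% ids)) {
    stop("outlier windows not a subset of all windows")
  }
  if (!length(outlier_ids)) stop("need at least one outlier window")
  counts <- all_windows$n_snps
  n_out <- length(unique(outlier_ids))
  obs <- median(counts[ids %in% outlier_ids])
  null <- vapply(seq_len(n_perm), function(i) {
    median(counts[sample.int(length(counts), n_out)])
  }, 0)
  list(observed_median = obs,
       p_more = (1 + sum(null >= obs)) / (n_perm + 1),
       p_less = (1 + sum(null <= obs)) / (n_perm + 1),
       null_median_mean = mean(null),
       n_perm = n_perm)
}
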