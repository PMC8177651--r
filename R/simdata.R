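#' Demography configuration for the forward Wright-Fisher simulator
#'
#' Describes a metapopulation of demes connected by a founding topology and a
#' migration matrix, simulated forward in time with haploid-gamete resampling,
#' diploid pairing, recombination and infinite-sites-style mutation on a
#' finite bp grid. Effective sizes are intended to be desk-scale reductions of
#' field estimates (roughly 100x smaller, with migration scaled up to conserve
#' the product N*m).
#'
#' @param pops Data frame with one row per deme and columns: `pop`, `river`,
#'   `drainage`, `predation` ("HP"/"LP"), `Ne` (diploid size), `sample_n`
#'   (diploids sampled at the end; 0 for unsampled demes), `founded_at`
#'   (generation, forward time, at which the deme appears; the single root has
#'   0 and `source = NA`), `source` (parent deme), `founder_n` (diploid size
#'   during the founding bottleneck; defaults to `Ne`) and `bottleneck_gens`
#'   (duration of the founding bottleneck).
#' @param migration Square matrix over demes; `migration[i, j]` is the
#'   probability that a gamete of an offspring born in deme `j` is drawn from
#'   deme `i` in one generation. Off-diagonal entries must lie in `[0, 1)` and
#'   each column's off-diagonal sum must be < 1. `NULL` means no migration.
#' @param chrom_len Named vector of chromosome lengths in bp.
#' @param mu Mutation rate per site per generation.
#' @param xo_per_chrom Expected crossovers per gamete per chromosome.
#' @param total_gens Number of generations simulated after the root is seeded.
#' @param init_freq Either `NULL` (derived counts drawn from the neutral
#'   frequency spectrum, P(count = c) proportional to 1/c) or a single number
#'   in (0,1): all seeded sites start at exactly that frequency (rounded to a
#'   whole derived-allele count), which gives a clean closed-form target for
#'   drift-decay checks.
#' @param init_sites `NULL` (Watterson-expected count for the root deme) or an
#'   integer number of standing-variation sites seeded at generation 0 in
#'   linkage equilibrium.
#' @param dropout Per-genotype missing-call probability applied to the sampled
#'   output (default 0).
#' @return A `demography_config`.
#' @export
demography_config <- function(pops, migration = NULL, chrom_len, mu,
                              xo_per_chrom = 1, total_gens,
                              init_freq = NULL, init_sites = NULL,
                              dropout = 0) {
  pops <- as.data.frame(pops)
  need <- c("pop", "river", "drainage", "predation", "Ne", "sample_n",
            "founded_at", "source")
  miss <- setdiff(need, names(pops))
  if (length(miss)) stop("pops is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(pops$founder_n)) pops$founder_n <- pops$Ne
  pops$founder_n <- ifelse(is.na(pops$founder_n), pops$Ne, pops$founder_n)
  if (is.null(pops$bottleneck_gens)) pops$bottleneck_gens <- 0L
  pops$bottleneck_gens[is.na(pops$bottleneck_gens)] <- 0L
  if (any(pops$Ne < 2) || any(pops$founder_n < 2)) {
    stop("all deme sizes must be >= 2 diploids")
  }
  if (any(pops$sample_n > pops$Ne)) {
    stop("sample size exceeds deme size for: ",
         paste(pops$pop[pops$sample_n > pops$Ne], collapse = ", "))
  }
  root <- pops$pop[is.na(pops$source)]
  if (length(root) != 1L) stop("exactly one root deme (source = NA) required")
  if (pops$founded_at[is.na(pops$source)] != 0) stop("root deme must have founded_at = 0")
  for (i in seq_len(nrow(pops))) {
    src <- pops$source[i]
    if (is.na(src)) next
    j <- match(src, pops$pop)
    if (is.na(j)) stop("unknown source deme '", src, "'")
    if (pops$founded_at[i] <= pops$founded_at[j]) {
      stop("deme '", pops$pop[i], "' founded before its source exists")
    }
    if (pops$founded_at[i] > total_gens) {
      stop("deme '", pops$pop[i], "' founded after the simulation ends")
    }
  }
  P <- nrow(pops)
  if (is.null(migration)) migration <- matrix(0, P, P)
  migration <- as.matrix(migration)
  if (!all(dim(migration) == P)) stop("migration must be ", P, "x", P)
  if (is.null(rownames(migration))) {
    rownames(migration) <- colnames(migration) <- pops$pop
  }
  migration <- migration[pops$pop, pops$pop, drop = FALSE]
  diag(migration) <- 0
  if (any(migration < 0) || any(migration >= 1)) {
    stop("migration rates must lie in [0, 1)")
  }
  if (any(colSums(migration) >= 1)) {
    stop("per-deme migrant inflow must sum to < 1")
  }
  if (is.null(names(chrom_len))) {
    names(chrom_len) <- paste0("chr", seq_along(chrom_len))
  }
  xo <- rep_len(xo_per_chrom, length(chrom_len))
  structure(list(pops = pops, migration = migration,
                 chrom_len = chrom_len, mu = mu, xo_per_chrom = xo,
                 total_gens = as.integer(total_gens),
                 init_freq = init_freq, init_sites = init_sites,
                 dropout = dropout),
            class = "demography_config")
}

#' @export
print.demography_config <- function(x, ...) {
  cat(sprintf(
    "demography_config: %d demes, genome %.0f bp on %d chromosome(s), %d generations\n",
    nrow(x$pops), sum(x$chrom_len), length(x$chrom_len), x$total_gens))
  invisible(x)
}

# draw n random site positions (global coordinate), uniform over the genome
draw_positions <- function(n, chrom_len) {
  off <- chrom_offsets(chrom_len)
  C <- length(chrom_len)
  cc <- if (C == 1L) rep(1L, n) else {
    sample.int(C, n, replace = TRUE, prob = chrom_len / sum(chrom_len))
  }
  off[cc] + ceiling(runif(n) * chrom_len[cc])
}

# seed standing variation in the root deme: derived counts from the neutral
# spectrum (or a fixed frequency), alleles assigned in linkage equilibrium
seed_root <- function(config, H0) {
  G <- sum(config$chrom_len)
  if (is.null(config$init_sites)) {
    theta_l <- 2 * H0 * config$mu * G          # 4 N mu G with H0 = 2N
    S0 <- max(1L, rpois(1, theta_l * sum(1 / seq_len(H0 - 1))))
  } else S0 <- as.integer(config$init_sites)
  if (is.null(config$init_freq)) {
    counts <- sample.int(H0 - 1L, S0, replace = TRUE,
                         prob = 1 / seq_len(H0 - 1L))
  } else {
    counts <- rep(max(1L, min(H0 - 1L, round(config$init_freq * H0))), S0)
  }
  gpos <- sort(unique(draw_positions(S0, config$chrom_len)))
  counts <- counts[seq_along(gpos)]
  geno <- matrix(0L, length(gpos), H0)   # sites x haplotypes
  for (s in seq_along(gpos)) geno[s, sample.int(H0, counts[s])] <- 1L
  list(geno = geno, gpos = as.double(gpos))
}

# map global coordinates back to (chrom, pos)
split_gpos <- function(gpos, chrom_len) {
  off <- chrom_offsets(chrom_len)
  idx <- findInterval(gpos, c(off, Inf))
  idx[idx > length(off)] <- length(off)
  list(chrom = names(chrom_len)[idx], pos = as.integer(round(gpos - off[idx])))
}

# per-gamete strand-switch points: Poisson crossovers within each chromosome
# plus an independent 1/2 flip at the start of every chromosome after the
# first (independent assortment); returned flattened (0-based offsets plus
# values sorted within gamete) for the C++ gamete assembler
draw_switches <- function(n_gam, chrom_len, xo) {
  off <- chrom_offsets(chrom_len)
  C <- length(chrom_len)
  gam <- integer(0); val <- double(0)
  for (cc in seq_len(C)) {
    k <- rpois(n_gam, xo[cc])
    tot <- sum(k)
    if (tot > 0) {
      gam <- c(gam, rep.int(seq_len(n_gam), k))
      val <- c(val, off[cc] + runif(tot) * chrom_len[cc])
    }
    if (cc > 1L) {
      flip <- which(runif(n_gam) < 0.5)
      gam <- c(gam, flip)
      val <- c(val, rep.int(off[cc] - 0.5, length(flip)))
    }
  }
  o <- order(gam, val)
  gam <- gam[o]; val <- val[o]
  counts <- tabulate(gam, nbins = n_gam)
  list(off = c(0L, cumsum(counts)), val = val)
}

#' Simulate the metapopulation demography
#'
#' Discrete-generation forward Wright-Fisher simulation: every generation each
#' deme's offspring draw each gamete from a (possibly migrant) parental
#' diploid, gametes recombine with Poisson crossovers, and new mutations are
#' placed at unoccupied integer bp (a drawn position that is already occupied
#' is skipped, which guarantees biallelic sites). Founding events copy
#' `founder_n` diploids from the source deme; during `bottleneck_gens` the new
#' deme stays at its founder size, then jumps to `Ne`.
#'
#' @param config A [demography_config()].
#' @param seed Integer seed; fixed seed gives identical output.
#' @return List with `hap` (a [hap_matrix()] of the sampled individuals,
#'   restricted to sites segregating in the sample) and `popmap` (a
#'   [pop_map()]).
#' @export
simulate_demography <- function(config, seed = NULL) {
  stopifnot(inherits(config, "demography_config"))
  if (!is.null(seed)) set.seed(seed)
  pops <- config$pops
  P <- nrow(pops)
  root_i <- which(is.na(pops$source))
  chrom_len <- config$chrom_len
  G <- sum(chrom_len)
  mu <- config$mu

  H0 <- 2L * pops$Ne[root_i]
  st <- seed_root(config, H0)
  geno <- st$geno
  gpos <- st$gpos
  n_sorted <- length(gpos)
  hap_pop <- rep(root_i, H0)

  prune_every <- 20L
  for (g in seq_len(config$total_gens)) {
    # founding events: copy founder haplotypes from the source deme
    newly <- which(pops$founded_at == g)
    for (i in newly) {
      src_cols <- which(hap_pop == match(pops$source[i], pops$pop))
      n_src <- length(src_cols) / 2L
      fn <- pops$founder_n[i]
      if (fn > n_src) stop("founder size exceeds source deme for '", pops$pop[i], "'")
      founders <- sample.int(n_src, fn)
      cols <- src_cols[as.vector(rbind(2L * founders - 1L, 2L * founders))]
      geno <- cbind(geno, geno[, cols, drop = FALSE])
      hap_pop <- c(hap_pop, rep(i, 2L * fn))
    }
    active <- sort(unique(hap_pop))
    # current deme sizes under the bottleneck schedule
    size_now <- integer(P)
    for (i in active) {
      age <- g - pops$founded_at[i]
      size_now[i] <- if (age <= pops$bottleneck_gens[i] && !is.na(pops$source[i]))
        pops$founder_n[i] else pops$Ne[i]
    }
    rows_of <- lapply(seq_len(P), function(i) which(hap_pop == i))
    # offspring gamete specs for all active demes at once
    hapA <- integer(0); hapB <- integer(0); new_pop <- integer(0)
    for (i in active) {
      n_gam <- 2L * size_now[i]
      m_in <- config$migration[, i]
      m_in[setdiff(seq_len(P), active)] <- 0   # absent demes send no migrants
      p_src <- m_in; p_src[i] <- p_src[i] + max(0, 1 - sum(m_in))
      src <- sample.int(P, n_gam, replace = TRUE, prob = p_src)
      for (sp in unique(src)) {
        sel <- src == sp
        n_par <- length(rows_of[[sp]]) / 2L
        par <- sample.int(n_par, sum(sel), replace = TRUE)
        a <- rows_of[[sp]][2L * par - 1L]
        b <- rows_of[[sp]][2L * par]
        hapA <- c(hapA, a); hapB <- c(hapB, b)
        new_pop <- c(new_pop, rep(i, sum(sel)))
      }
    }
    n_gam <- length(hapA)
    start <- sample(0:1, n_gam, replace = TRUE)
    sw <- draw_switches(n_gam, chrom_len, config$xo_per_chrom)
    # this generation's new mutations: unoccupied positions, one carrier each;
    # they are appended as an unsorted tail and sorted in at prune points
    n_mut <- rpois(1, mu * G * n_gam)
    cand <- if (n_mut > 0) {
      cc <- draw_positions(n_mut, chrom_len)
      unique(cc[!(cc %in% gpos)])
    } else double(0)
    geno <- make_gametes_cpp(geno, gpos, hapA - 1L, hapB - 1L, start,
                             sw$off, sw$val, n_sorted, length(cand))
    hap_pop <- new_pop
    if (length(cand)) {
      S_old <- length(gpos)
      geno[cbind(S_old + seq_along(cand),
                 sample.int(n_gam, length(cand), replace = TRUE))] <- 1L
      gpos <- c(gpos, as.double(cand))
    }
    if (g %% prune_every == 0L || g == config$total_gens) {
      rs <- rowSums(geno)
      keep <- which(rs > 0L & rs < ncol(geno))
      keep <- keep[order(gpos[keep])]
      geno <- geno[keep, , drop = FALSE]
      gpos <- gpos[keep]
      n_sorted <- length(gpos)
    }
  }

  # sample individuals
  samples <- character(0); spop <- character(0); cols <- integer(0)
  for (i in seq_len(P)) {
    if (pops$sample_n[i] == 0L) next
    pc <- which(hap_pop == i)
    n_i <- length(pc) / 2L
    if (pops$sample_n[i] > n_i) stop("sample size exceeds deme size for '", pops$pop[i], "'")
    pick <- sort(sample.int(n_i, pops$sample_n[i]))
    cols <- c(cols, pc[as.vector(rbind(2L * pick - 1L, 2L * pick))])
    ids <- sprintf("%s_%02d", pops$pop[i], seq_len(pops$sample_n[i]))
    samples <- c(samples, ids)
    spop <- c(spop, rep(pops$pop[i], pops$sample_n[i]))
  }
  geno <- t(geno[, cols, drop = FALSE])   # back to haplotypes x sites
  cs <- colSums(geno)
  keep <- cs > 0L & cs < nrow(geno)
  geno <- geno[, keep, drop = FALSE]
  gpos <- gpos[keep]
  if (config$dropout > 0 && length(gpos)) {
    n_ind <- length(samples)
    drop <- matrix(runif(n_ind * length(gpos)) < config$dropout, n_ind)
    hdrop <- drop[rep(seq_len(n_ind), each = 2L), , drop = FALSE]
    geno[hdrop] <- NA_integer_
  }
  cp <- split_gpos(gpos, chrom_len)
  hap <- hap_matrix(geno, cp$chrom, cp$pos, samples, chrom_len = chrom_len)
  idx <- match(spop, pops$pop)
  popmap <- pop_map(data.frame(sample = samples,
                               population = spop,
                               river = pops$river[idx],
                               drainage = pops$drainage[idx],
                               predation = pops$predation[idx]))
  list(hap = hap, popmap = popmap)
}

#' Specification of a planted sweep haplotype
#'
#' A sweep is imposed (not evolved): a donor haplotype drawn from the first
#' carrier population is copied over the interval into randomly chosen
#' recipient haplotypes of each carrier population until the target frequency
#' is reached. With `ancestral = TRUE` the same donor is shared by all carrier
#' populations (an ancestrally shared haplotype, as for a large LP haplotype
#' segregating across a drainage); otherwise each population receives its own
#' donor. `extra_snps` adds that many new derived sites inside the interval,
#' carried only by the donor lineage, which gives the planted haplotype the
#' sequence divergence an old haplotype would have accumulated.
#'
#' @param chrom Chromosome id.
#' @param start,end 0-based half-open bp interval of the swept haplotype.
#' @param targets Named numeric vector: carrier population -> target
#'   derived-haplotype frequency in `[0, 1]`.
#' @param ancestral Logical; share one donor across carrier populations.
#' @param extra_snps Number of divergence SNPs to add on the donor haplotype.
#' @return A `sweep_spec`.
#' @export
sweep_spec <- function(chrom, start, end, targets, ancestral = TRUE,
                       extra_snps = 0L) {
  if (end <= start) stop("sweep interval is empty")
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop("targets must be named by carrier population")
  }
  if (any(targets < 0 | targets > 1)) stop("target frequencies must lie in [0, 1]")
  structure(list(chrom = chrom, start = start, end = end,
                 targets = targets, ancestral = ancestral,
                 extra_snps = as.integer(extra_snps)),
            class = "sweep_spec")
}

#' Plant a sweep haplotype into a haplotype matrix
#'
#' @param hap A [hap_matrix()].
#' @param popmap A [pop_map()] for the samples of `hap`.
#' @param spec A [sweep_spec()].
#' @param seed Optional integer seed (donor and recipient choice).
#' @return A `hap_matrix` with the sweep planted. Attribute
#'   `sweep_carriers` records, per carrier population, which haplotype rows
#'   received the donor haplotype (the planted truth used by power tests).
#' @export
plant_sweep <- function(hap, popmap, spec, seed = NULL) {
  stopifnot(inherits(hap, "hap_matrix"), inherits(spec, "sweep_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (!spec$chrom %in% names(hap$chrom_len)) {
    stop("sweep chromosome '", spec$chrom, "' not in the matrix")
  }
  if (spec$start < 0 || spec$end > hap$chrom_len[spec$chrom]) {
    stop("sweep interval outside chromosome bounds")
  }
  pops <- names(spec$targets)
  missing <- setdiff(pops, popmap$population)
  if (length(missing)) stop("carrier populations absent: ",
                            paste(missing, collapse = ", "))
  # optional divergence SNPs: new sites inside the interval, derived only on
  # the (future) donor lineage; inserted before recipients are chosen
  if (spec$extra_snps > 0L) {
    occupied <- hap$pos[hap$chrom == spec$chrom]
    cand <- setdiff(seq.int(spec$start + 1L, spec$end), occupied)
    k <- min(spec$extra_snps, length(cand))
    newp <- sort(sample(cand, k))
    add <- matrix(0L, nrow(hap$geno), k)
    hap <- hap_matrix(cbind(hap$geno, add), c(hap$chrom, rep(spec$chrom, k)),
                      c(hap$pos, newp), hap$samples,
                      c(hap$ref, rep("A", k)), c(hap$alt, rep("T", k)),
                      chrom_len = hap$chrom_len)
  }
  in_iv <- which(hap$chrom == spec$chrom & hap$pos > spec$start &
                   hap$pos <= spec$end)
  if (!length(in_iv)) stop("no sites inside the sweep interval")
  new_sites <- if (spec$extra_snps > 0L) {
    in_iv[hap$geno[1L, in_iv] == 0L & colSums(hap$geno[, in_iv, drop = FALSE]) == 0L]
  } else integer(0)

  donor_for <- function(p) {
    rows_p <- hap_rows(hap, pop_samples(popmap, p))
    rows_p[sample.int(length(rows_p), 1L)]
  }
  shared_donor <- if (spec$ancestral) donor_for(pops[1L]) else NA_integer_
  carriers <- list()
  for (p in pops) {
    f <- spec$targets[[p]]
    rows_p <- hap_rows(hap, pop_samples(popmap, p))
    n <- length(rows_p)
    k <- round(f * n)
    if (k == 0L) { carriers[[p]] <- integer(0); next }
    donor <- if (spec$ancestral) shared_donor else donor_for(p)
    if (donor %in% rows_p && k >= 1L) {
      rec <- c(donor, sample(setdiff(rows_p, donor), k - 1L))
    } else {
      rec <- sample(rows_p, k)
    }
    donor_hap <- hap$geno[donor, in_iv]
    donor_hap[match(new_sites, in_iv)] <- 1L      # divergence SNPs ride along
    hap$geno[rec, in_iv] <- rep(donor_hap, each = length(rec))
    carriers[[p]] <- sort(rec)
  }
  # divergence SNPs must not remain monomorphic (nobody received them)
  if (length(new_sites)) {
    cs <- colSums(hap$geno[, new_sites, drop = FALSE])
    dead <- new_sites[cs == 0L | cs == nrow(hap$geno)]
    if (length(dead)) {
      # haplotype row indices are unaffected by dropping site columns
      hap <- subset_hap(hap, sites = setdiff(seq_len(n_sites(hap)), dead))
    }
  }
  attr(hap, "sweep_carriers") <- carriers
  hap
}

#' Generate gene annotations and a pathway map
#'
#' Genes are placed uniformly and non-overlapping on the genome; pathways
#' receive uniformly sampled member genes. When sweep intervals are supplied,
#' the focal pathway gets `focal_per_river` of its genes placed inside each
#' river's sweep interval, emulating a functional pathway repeatedly hit by
#' selection in every river.
#'
#' @param n_genes Number of genes.
#' @param pathways Named integer vector: pathway id -> member count.
#' @param chrom_len Named chromosome lengths (bp).
#' @param seed Integer seed.
#' @param gene_len Gene length in bp (default 4000).
#' @param sweeps Optional named list: river -> list(chrom, start, end) sweep
#'   interval in which focal genes are co-located.
#' @param focal Name of the focal pathway (must appear in `pathways`).
#' @param focal_per_river Number of focal-pathway genes placed inside each
#'   river's sweep interval.
#' @return List with `genes` (data frame: gene, chrom, start, end; 0-based
#'   half-open), `pathways` (data frame: gene, pathway), `background`
#'   (character vector of all genes), `focal`, and `truth` (sweep intervals
#'   and planted focal genes per river).
#' @export
emit_annotations <- function(n_genes, pathways, chrom_len, seed = NULL,
                             gene_len = 4000, sweeps = NULL, focal = NULL,
                             focal_per_river = 2L) {
  if (!is.null(seed)) set.seed(seed)
  if (sum(pathways) > n_genes * length(pathways)) {
    stop("not enough genes for the requested pathway memberships")
  }
  if (!is.null(focal) && !focal %in% names(pathways)) {
    stop("focal pathway missing from 'pathways'")
  }
  genes <- data.frame(gene = sprintf("gene%04d", seq_len(n_genes)),
                      chrom = NA_character_, start = NA_real_, end = NA_real_,
                      stringsAsFactors = FALSE)
  placed <- lapply(names(chrom_len), function(x) cbind(numeric(0), numeric(0)))
  names(placed) <- names(chrom_len)
  place_one <- function(chrom, lo, hi) {
    # place uniformly over the free gaps of [lo, hi) that can hold a gene
    if (hi - gene_len <= lo) stop("interval too small for a gene")
    ov <- placed[[chrom]]
    ov <- ov[ov[, 2] > lo & ov[, 1] < hi, , drop = FALSE]
    if (nrow(ov)) {
      ov[, 1] <- pmax(ov[, 1], lo)
      ov[, 2] <- pmin(ov[, 2], hi)
    }
    ov <- ov[order(ov[, 1]), , drop = FALSE]
    bounds <- c(lo, t(ov), hi)
    gap_lo <- bounds[seq(1, length(bounds), by = 2)]
    gap_hi <- bounds[seq(2, length(bounds), by = 2)]
    room <- pmax(0, (gap_hi - gap_lo) - gene_len)
    ok <- which(room > 0)
    if (!length(ok)) stop("genome too small to place non-overlapping genes")
    g <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = room[ok])
    s <- floor(runif(1, gap_lo[g], gap_hi[g] - gene_len))
    e <- s + gene_len
    placed[[chrom]] <<- rbind(placed[[chrom]], c(s, e))
    c(s, e)
  }
  gi <- 1L
  truth_genes <- list()
  if (!is.null(sweeps) && !is.null(focal)) {
    for (rv in names(sweeps)) {
      iv <- sweeps[[rv]]
      for (j in seq_len(focal_per_river)) {
        se <- place_one(iv$chrom, iv$start, iv$end)
        genes$chrom[gi] <- iv$chrom
        genes$start[gi] <- se[1]; genes$end[gi] <- se[2]
        truth_genes[[rv]] <- c(truth_genes[[rv]], genes$gene[gi])
        gi <- gi + 1L
      }
    }
  }
  if (gi > n_genes) stop("n_genes too small for the co-located focal genes")
  for (i in seq(gi, n_genes)) {
    cc <- sample(names(chrom_len), 1L, prob = chrom_len / sum(chrom_len))
    se <- place_one(cc, 0, chrom_len[[cc]])
    genes$chrom[i] <- cc; genes$start[i] <- se[1]; genes$end[i] <- se[2]
  }
  memb <- data.frame(gene = character(0), pathway = character(0),
                     stringsAsFactors = FALSE)
  planted <- unique(unlist(truth_genes))
  for (pw in names(pathways)) {
    size <- pathways[[pw]]
    if (!is.null(focal) && pw == focal) {
      extra <- size - length(planted)
      members <- c(planted,
                   if (extra > 0) sample(setdiff(genes$gene, planted), extra))
    } else {
      members <- sample(genes$gene, size)
    }
    memb <- rbind(memb, data.frame(gene = members, pathway = pw,
                                   stringsAsFactors = FALSE))
  }
  list(genes = genes, pathways = memb, background = genes$gene, focal = focal,
       truth = list(sweeps = sweeps, focal_genes = truth_genes))
}

#' The default five-river study scenario
#'
#' Three drainages, five rivers, ten populations with the field design's
#' sample sizes. Effective sizes are ~100x desk-scale reductions of the
#' rivers' demographic estimates (clamped to `[25, 120]` diploids), within-
#' river migration is scaled up 100x (capped at 0.1) to conserve N*m, and
#' every LP deme is founded from its HP deme through a founding bottleneck.
#' One large ancestral haplotype is planted near-fixed in the LP populations
#' of the Caroni-analog drainage, plus one smaller sweep per river, and a
#' focal pathway's genes are co-located with the per-river sweeps.
#'
#' @param n_chrom Number of chromosomes (default 3).
#' @param chrom_size Chromosome length in bp (default 6e5).
#' @return List with `config` (a [demography_config()]), `sweeps` (list of
#'   [sweep_spec()]), and `annotation` (arguments for [emit_annotations()]).
#' @export
default_scenario <- function(n_chrom = 3, chrom_size = 6e5) {
  chrom_len <- setNames(rep(chrom_size, n_chrom), paste0("chr", seq_len(n_chrom)))
  pops <- data.frame(
    pop        = c("GHP", "OHP", "MADHP", "TACHP", "APHP",
                   "TACLP", "GLP", "APLP", "OLP", "MADLP"),
    river      = c("Guanapo", "Oropouche", "Madamas", "Tacarigua", "Aripo",
                   "Tacarigua", "Guanapo", "Aripo", "Oropouche", "Madamas"),
    drainage   = c("Caroni", "Oropouche", "Northern", "Caroni", "Caroni",
                   "Caroni", "Caroni", "Caroni", "Oropouche", "Northern"),
    predation  = c(rep("HP", 5), rep("LP", 5)),
    Ne         = c(120L, 45L, 25L, 35L, 120L, 25L, 25L, 61L, 37L, 25L),
    sample_n   = c(19L, 19L, 20L, 12L, 19L, 14L, 18L, 19L, 20L, 16L),
    founded_at = c(0L, 150L, 200L, 230L, 260L, 340L, 350L, 350L, 360L, 400L),
    source     = c(NA, "GHP", "OHP", "GHP", "GHP",
                   "TACHP", "GHP", "APHP", "OHP", "MADHP"),
    founder_n  = c(NA, 30L, 20L, 25L, 40L, 4L, 3L, 5L, 20L, 5L),
    bottleneck_gens = c(0L, 0L, 0L, 0L, 0L, 10L, 10L, 10L, 0L, 10L),
    stringsAsFactors = FALSE
  )
  # within-river migration, downstream-biased (LP -> HP stronger). Rates are
  # the field per-generation probabilities multiplied by each river's time
  # compression factor (true LP size / scaled LP size, the faster-drifting
  # deme sets the scaled clock), capped at 0.1. Scaling both directions by
  # one factor preserves the ratio of migration lag to LP drift time, so
  # poorly connected pairs (Tacarigua, Guanapo) stay strongly drifted while
  # well-connected pairs (Aripo, Oropouche) stay weakly differentiated.
  mig <- matrix(0, 10, 10, dimnames = list(pops$pop, pops$pop))
  set_m <- function(from, to, m) mig[from, to] <<- min(m, 0.1)
  set_m("TACHP", "TACLP", 9.1e-4);  set_m("TACLP", "TACHP", 2.9e-3)
  set_m("GHP", "GLP", 2.4e-5);      set_m("GLP", "GHP", 5.2e-3)
  set_m("APHP", "APLP", 2.1e-2);    set_m("APLP", "APHP", 3.3e-2)
  set_m("OHP", "OLP", 2.5e-2);      set_m("OLP", "OHP", 0.1)
  set_m("MADHP", "MADLP", 8.6e-3);  set_m("MADLP", "MADHP", 4.8e-2)
  config <- demography_config(pops, mig, chrom_len, mu = 8e-7,
                              xo_per_chrom = 0.6, total_gens = 460L)
  # sweep coordinates scale with chromosome size so reduced-size runs of the
  # same scenario stay valid
  fr <- function(a, b) c(round(chrom_size * a), round(chrom_size * b))
  cl <- fr(0.05, 0.40)
  per_river <- list(
    Guanapo   = list(chrom = "chr1", start = fr(0.125, 0.1875)[1], end = fr(0.125, 0.1875)[2]),
    Tacarigua = list(chrom = "chr1", start = fr(0.5, 0.5625)[1], end = fr(0.5, 0.5625)[2]),
    Aripo     = list(chrom = "chr2", start = fr(0.125, 0.1875)[1], end = fr(0.125, 0.1875)[2]),
    Oropouche = list(chrom = "chr2", start = fr(0.5, 0.5625)[1], end = fr(0.5, 0.5625)[2]),
    Madamas   = list(chrom = "chr1", start = fr(0.8125, 0.875)[1], end = fr(0.8125, 0.875)[2])
  )
  mk <- function(rv, tg) sweep_spec(per_river[[rv]]$chrom, per_river[[rv]]$start,
                                    per_river[[rv]]$end, tg, FALSE, 20L)
  sweeps <- list(
    # large ancestral LP haplotype of the Caroni-analog drainage, polymorphic
    # in carrier HP demes, near-fixed in their LP demes
    CL = sweep_spec(paste0("chr", n_chrom), cl[1], cl[2],
                    targets = c(GLP = 1.0, TACLP = 1.0, APLP = 0.95,
                                GHP = 0.4, TACHP = 0.4, APHP = 0.35),
                    ancestral = TRUE, extra_snps = 200L),
    Guanapo   = mk("Guanapo", c(GLP = 0.95, GHP = 0.2)),
    Tacarigua = mk("Tacarigua", c(TACLP = 0.95, TACHP = 0.2)),
    Aripo     = mk("Aripo", c(APLP = 0.95, APHP = 0.2)),
    Oropouche = mk("Oropouche", c(OLP = 0.95, OHP = 0.2)),
    Madamas   = mk("Madamas", c(MADLP = 0.95, MADHP = 0.2))
  )
  annotation <- list(n_genes = 300L,
                     pathways = c(cadherin_analog = 18L, pwA = 25L, pwB = 40L,
                                  pwC = 12L, pwD = 30L),
                     chrom_len = chrom_len, gene_len = round(chrom_size / 300),
                     sweeps = per_river,
                     focal = "cadherin_analog", focal_per_river = 3L)
  list(config = config, sweeps = sweeps, annotation = annotation)
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_demography()], plants every sweep of the scenario, and
#' emits annotations; collects the planted truth.
#'
#' @param scenario A list as returned by [default_scenario()].
#' @param seed Integer seed.
#' @return List with `hap`, `popmap`, `annotation` and `truth` (sweep specs,
#'   carrier haplotypes per sweep, focal pathway and planted focal genes).
#' @export
generate_dataset <- function(scenario = default_scenario(), seed = 1) {
  sim <- simulate_demography(scenario$config, seed = seed)
  hap <- sim$hap
  carriers <- list()
  for (nm in names(scenario$sweeps)) {
    hap <- plant_sweep(hap, sim$popmap, scenario$sweeps[[nm]],
                       seed = derive_seed(seed, paste0("sweep_", nm)))
    carriers[[nm]] <- attr(hap, "sweep_carriers")
  }
  ann <- do.call(emit_annotations,
                 c(scenario$annotation, list(seed = derive_seed(seed, "annot"))))
  list(hap = hap, popmap = sim$popmap, annotation = ann,
       truth = list(sweeps = scenario$sweeps, carriers = carriers,
                    focal = ann$focal, focal_genes = ann$truth$focal_genes))
}

#' Write a generated dataset to standard file formats
#'
#' Writes a phased VCF, a popmap TSV, gene intervals as BED (0-based
#' half-open), the gene-to-pathway map as TSV, and the planted truth as JSON.
#'
#' @param dataset As returned by [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_vcf <- file.path(dir, "genotypes.vcf")
  write_vcf(dataset$hap, f_vcf)
  f_pm <- file.path(dir, "popmap.tsv")
  write.table(dataset$popmap, f_pm, sep = "\t", quote = FALSE, row.names = FALSE)
  f_bed <- file.path(dir, "genes.bed")
  g <- dataset$annotation$genes
  write.table(data.frame(g$chrom, format(g$start, scientific = FALSE, trim = TRUE),
                         format(g$end, scientific = FALSE, trim = TRUE), g$gene),
              f_bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  f_pw <- file.path(dir, "pathways.tsv")
  write.table(dataset$annotation$pathways, f_pw, sep = "\t", quote = FALSE,
              row.names = FALSE)
  f_tr <- file.path(dir, "truth.json")
  truth <- dataset$truth
  truth$sweeps <- lapply(truth$sweeps, unclass)
  jsonlite::write_json(truth, f_tr, auto_unbox = TRUE, digits = NA)
  invisible(c(f_vcf, f_pm, f_bed, f_pw, f_tr))
}
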