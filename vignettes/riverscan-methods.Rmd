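---
title: "Methods: detecting convergent selection across replicated river pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting convergent selection across replicated river pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Riverine fish such as Trinidadian guppies repeatedly colonise upstream
low-predation (LP) habitat from downstream high-predation (HP) sources,
and repeatedly evolve a characteristic LP phenotype. Whether that phenotypic
convergence is mirrored at the genomic level — the same windows, the same
genes, or merely the same functional pathways — depends on how adaptive
variation is distributed across a drainage-structured metapopulation with
founding bottlenecks and downstream-biased migration. `riverscan` implements
the full analysis chain for asking that question on phased SNP data from
replicated HP–LP pairs, together with a forward simulator that generates the
whole study design synthetically so every stage is testable end to end.

The pipeline mirrors the logic of a replicated natural experiment:

1. **structure** — genome-wide PCA with per-population centroid drift,
   folded two-dimensional site frequency spectra (2dSFS), and Patterson's
   D / f4-ratio introgression screening;
2. **scans** — three within-river HP-vs-LP selection statistics in 10 kb
   windows, each with its own outlier rule;
3. **convergence** — intersection of scan outliers into candidate windows,
   cross-river overlap tabulation, clustering into larger regions, and a
   SNP-count sanity permutation;
4. **enrichment** — pathway-level convergence via a multi-river permutation
   test;
5. **haplotype follow-up** — local-PCA/MDS ancestry deviation, haplogroup
   calling, and windowed BIONJ branch-length contrasts for large candidate
   haplotypes.

## Selection scans

All scans operate on the same non-overlapping 10 kb window index and on
sites that survive the matrix-level filters (biallelic, global minor allele
frequency ≥ 0.05 computed over all called chromosomes, missing in at most
50% of the individuals of every population).

**AFD.** The absolute allele frequency difference of a biallelic SNP is
`|p_HP − p_LP|`, which scales linearly from 0 (identical) to 1 (fixed
difference). Sites invariant within the river are removed, each window is
summarised by its median AFD, and windows with fewer than 6 river-variant
SNPs are excluded from outlier calling (their medians are still reported).
The outlier cutoff is the 0.95 genome quantile of eligible window medians,
capped at 0.5: an AFD of 0.5 is the smallest change that can flip the major
allele, and we read the capped rule as `min(q95, 0.5)`. The alternative
reading (`max`) would make the test *less* sensitive exactly when the genome
is most differentiated, which we consider counterintuitive; the quantile and
the cap are both parameters.

**Differentiation with a neutral threshold.** Window differentiation is
Hudson's FST as a ratio of sums: per SNP, numerator
`(p1−p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1)` and denominator
`p1(1−p2) + p2(1−p1)`. The outlier threshold is the 0.95 quantile of a
pseudo-observed-data (POD) null distribution. POD windows are built by
resampling *contiguous blocks* of observed per-SNP components, with block
sizes drawn from the observed distribution of window SNP counts and start
points uniform over the genome-wide SNP ordering. Contiguity matters:
neutral window statistics are overdispersed relative to independent SNPs
because linked SNPs drift together, and a POD built from independently
resampled SNPs understates that variance (in our calibration runs it flagged
~14% of fully neutral windows instead of ~5%; contiguous blocks flag ~6%).
Random placement still destroys the alignment between windows and any
locus-specific signal, which is what makes the quantile a neutral cutoff.

**XP-EHH.** For each core SNP, EHH(x) is the probability that two
haplotypes drawn without replacement are identical over the span from the
core to x; iHH is the trapezoid integral of EHH over physical distance,
truncated when EHH < 0.05 (configurable); the score is
`ln(iHH_HP / iHH_LP)`. Scores are z-normalised genome-wide *per SNP* and
then averaged within 10 kb windows; a window is an outlier when
`|mean z| > 2`. The alternative order (normalising window means) is
a genuinely open choice; we normalise per SNP first because it makes the
genome-wide score distribution exactly standard normal by construction and
keeps window means comparable across windows with different SNP counts.
Haplotypes with a missing allele inside the current span are dropped from
that core's computation, as haplotype-scan tools conventionally do.

**Candidates.** A window is a candidate when flagged by at least two of the
three scans. Requiring all three would miss biologically expected cases —
for instance divergent selection fixing alternate haplotypes leaves no
XP-EHH contrast — while any single scan alone is too noisy.

An association-style aggregator (`aggregate_association`) turns any
externally supplied per-SNP score into window means and flags windows above
the 0.999 quantile, reproducing the window logic used for genome-wide
association scores without re-implementing the underlying Bayesian model.

## Convergence across rivers

`overlap_sets` partitions the union of all rivers' candidate windows into
exact-subset cells (the cells of an upset plot), `cluster_sliding` merges
runs of 100 kb sliding windows (50 kb increments) containing candidates into
larger regions, and `snp_count_permutation` checks whether outlier windows
carry unusual SNP counts: the observed median SNP count is compared against
medians of equally many windows drawn without replacement (10,000 draws by
default). All Monte-Carlo p-values carry the +1 correction
`p = (1 + #extreme)/(n_perm + 1)`, so they are never exactly 0 and never
exceed 1. Draws are without replacement because the observed outlier set is
itself a without-replacement subset of the genome's windows.

## Pathway-level convergence

Fold enrichment of a pathway among a river's outlier genes is the standard
over-representation ratio `FE = (k/n)/(K/N)`. The convergence question is
whether FE > 1 in *all* rivers (or any four of five) more often than chance
allows. The null draws, independently per river, a random outlier set of
the observed size uniformly without replacement from the background;
weighting by pathway size arises implicitly, because a pathway with more
genes captures proportionally more of any random draw. Under uniform
sampling the pathway hit count is exactly Hypergeometric(K, N−K, n), so the
null is evaluated with `rhyper()` draws rather than materialised gene sets —
the distributions are identical and the permutation loop becomes trivial
(this equivalence is property-tested against explicit set sampling). An
explicitly weighted sampler (`sampler = "stratified"`, genes weighted by
their pathway-membership counts) is available for sensitivity analysis, as
the weighting language of this class of test is ambiguous.

The reported p is the +1-corrected probability that a null permutation shows
at least as many FE > 1 rivers as observed. This data-dependent form is the
one under which degenerate inputs behave correctly (a pathway equal to the
whole background has FE identically 1 and p = 1) and under which p is
approximately uniform for random outlier sets; the probability of the rule
itself (`p_rule`) is also reported.

## Population structure and introgression

**PCA and centroid drift.** PCA is computed on the centered (optionally
`sqrt(p(1−p))`-scaled) dosage matrix of an LD-pruned SNP set
(`--indep-pairwise`-style greedy pruning: 50-SNP windows, step 5,
r² ≤ 0.2, iterated to a fixpoint so the bound holds over the retained set).
Because the matrix is centered, the global centroid is the origin, and the
distance of each population's centroid from the origin in the leading axes
measures its drift from the common ancestral state: founding bottlenecks
push derived LP populations further out than their HP sources.

**2dSFS.** Each site's called allele counts are projected to a common
sample size with hypergeometric weights
`P(j) = C(k,j) C(n−k, m−j) / C(n,m)`; the projection pair `(m1, m2)` is
chosen to maximise the expected number of segregating sites after
projection. Folding is joint: any cell whose summed allele count exceeds
`(m1+m2)/2` is added to its complementary cell, and complementary pairs
exactly on the fold are combined into the cell with the smaller first
index, so the folded spectrum carries no mass above the fold. A
per-population fold is a documented alternative we did not adopt; the joint
minor allele is the convention of the SFS tooling this format feeds.

**D and f4-ratio.** For a trio (P1, P2; P3) with outgroup O,
`ABBA = (1−p1) p2 p3 (1−p4)` and `BABA = p1 (1−p2) p3 (1−p4)` are summed
over sites and `D = Σ(ABBA−BABA)/Σ(ABBA+BABA)`; the standard error comes
from a delete-one block jackknife over contiguous bp blocks (default 100 kb
on the synthetic genome, at least 20 blocks required). The f4-ratio
estimator of the admixture fraction splits P3's haplotypes into random
halves a/b once under the run seed and computes
`f4(P1,P2;P3a,O) / f4(P1,P3b;P3a,O)`. Screening keeps trios with
Bonferroni-corrected p < 0.001 and f4-ratio > 0.05.

## Haplotype-region follow-up

**Local PCA / MDS.** Each window of 100 SNPs is summarised by the rank-2
eigen-approximation of its sample-covariance matrix with eigenvalues
normalised by the window's total variance; windows are compared by the
Frobenius distance between these reconstructions and embedded with
classical MDS. The distance is invariant to eigenvector sign and to
rotation within tied eigenvalues, which makes it safe against the
arbitrariness of per-window PCA. The exact between-window distance of
local-ancestry methods is tool-specific; this reconstruction distance is
the fixed convention of this package.

**Haplogroups.** Over a candidate region, individuals separate on PC1 into
homozygote–heterozygote–homozygote clusters. Manual cutoffs are replaced by
deterministic 1-D k-means with centers initialised at the PC1 minimum,
median and maximum (midpoint instead of median when the median coincides
with an extreme, which happens when one cluster dominates); clusters are
labelled hom-REF/het/hom-ALT by mean regional dosage, so the heterozygote
cluster always lies between the homozygote clusters.

**Branch-length contrast.** In each 100 kb window the pairwise Nei standard
distance `D = −ln(J_xy / sqrt(J_x J_y))` between individual allele-frequency
profiles (dosage/2) feeds a BIONJ tree; the mean tree-path distance over all
between-population pairs is the window's value. Negative BIONJ branch
lengths are clamped to zero with the deficit recorded. The focal region's
value is located as a percentile of the chromosome's window distribution,
*excluding* windows overlapping the focal region — at desk scale a
chromosome has tens of windows, and including the focal region's own
constituents caps the attainable percentile below the conventional 95th.
Infinite Nei distances (no shared alleles at any locus) exclude the window.
Individual-level profiles (rather than population pools) are used because
the contrast is defined as the mean distance between individuals.

## The synthetic study

`simulate_demography()` is a discrete-generation forward Wright–Fisher
simulator: haploid gametes are resampled with diploid pairing, each gamete
draws a possibly-migrant parent, recombines with Poisson crossovers
(chromosomes assort independently), and mutations land on unoccupied
integer bp (occupied positions are skipped, guaranteeing biallelic sites).
Founding events copy a configurable number of diploids from the source
deme and hold the new deme at its founder size for the bottleneck duration.
The root deme is seeded with standing variation drawn from the neutral
frequency spectrum (P(count = c) ∝ 1/c) in linkage equilibrium; local LD
then builds up during the simulated generations. A forward simulator was
chosen over a coalescent one because sweeps and bottlenecks must be
plantable mid-history and because every object the pipeline consumes
(phased haplotypes with recombination structure) falls out directly.

The default scenario (`default_scenario()`) mirrors the field design:
3 drainages, 5 rivers, 10 populations, sample sizes 12–20 diploids per
population. Effective sizes are ~100× desk-scale reductions of per-river
demographic estimates, clamped to [25, 120] diploids so that every deme can
supply its sample and the rank order of river sizes is preserved;
within-river migration probabilities are scaled up by each river's time
compression factor (true LP size over scaled LP size, capped at 0.1), which
preserves the ratio of migration lag to LP drift time so that poorly
connected rivers stay strongly drifted and well-connected rivers stay
weakly differentiated; migration remains downstream-biased (LP→HP stronger
than HP→LP) in every river. LP demes are founded from their HP demes through founding
bottlenecks. Sweeps are *imposed*, not evolved: `plant_sweep()` copies a
donor haplotype over an interval into randomly chosen recipients until the
target frequency is reached, with `extra_snps` new derived sites added on
the donor lineage to give the haplotype the divergence an old haplotype
would carry. The scenario plants one large ancestral haplotype near-fixed
in the LP populations of the Caroni-analog drainage (polymorphic in their
HP sources) plus one smaller sweep per river, and `emit_annotations()`
co-locates a focal pathway's genes with the per-river sweeps.

The genome is 3 × 600 kb with mutation rate 8e-7 per bp per generation and
0.6 crossovers per gamete per chromosome. These are not biological
estimates; they were chosen once so that (i) 10 kb windows typically carry
enough river-variant SNPs to pass the 6-SNP filter, (ii) the planted
ancestral haplotype persists intact in carriers over its full extent, and
(iii) a complete simulated study finishes in about a minute. There is no
within-river recombination map to inherit, so the crossover rate is a free,
documented parameter.

What the generator does *not* emulate: sequencing reads, genotype
likelihoods or realistic missingness (only a uniform per-call dropout),
selection dynamics (sweeps appear instantaneously), chromosome-scale
recombination-rate variation, and reference biases. Passing tests therefore
demonstrate that the statistics behave correctly on drift-structured,
LD-bearing data with planted signals — not that they are robust to
sequencing artefacts.

## Calibration results the test suite enforces

The test suite (and nothing else) establishes these properties, at the
stated problem sizes:

- per-SNP AFD, Hudson components, Nei's distance, fold enrichment, overlap
  tabulation and hypergeometric projection match independent brute-force
  reimplementations to 1e-12 on ≥100 random fixtures each;
- heterozygosity decays as `(1 − 1/(2N))^t` within 5% (N = 50, t = 50,
  500 loci over 10 freely recombining chromosomes, 4 replicates);
- two demes of N = 100 exchanging m = 0.0025 reach a Hudson FST within
  ±0.05 of the structured-coalescent expectation `1/(1 + 8Nm) = 1/3`
  (for two demes the within-deme coalescence time is the panmictic total
  2N_T and the between-deme excess is 1/(2m));
- an LP founding bottleneck (founder 4 of an HP deme of 80) loses ≥30%
  heterozygosity and drifts further from the PCA centroid than its source
  in ≥90% of 50 replicates;
- planted sweeps (LP 0.95 / HP 0.25) are recovered as ≥2-of-3 candidates in
  ≥80% of 50 replicates, while fully neutral data yield 5% ± 2% POD-flagged
  windows;
- both permutation tests give approximately uniform p under their nulls
  (fraction ≤ 0.05 within [0.03, 0.07] over 1,000 replicates at
  n_perm = 999) and ≥90% power at p < 0.05 on the planted focal-pathway
  scenario (25 replicates of a reduced five-river design);
- D statistics show |Z| < 3 in ≥95% of 100 no-gene-flow replicates and the
  f4-ratio recovers a planted admixture fraction of 0.2 within ±0.07
  (mean over 50 replicates);
- the planted ancestral haplotype region is recovered by local-PCA MDS
  extremes, by haplogroups that match planted carrier status exactly, and
  by a focal branch-length contrast above the chromosome's 95th percentile,
  each in ≥80% of 50 replicates.

Null-calibration fixtures are chosen so the discrete Monte-Carlo tests have
enough resolution to exhibit uniformity: window SNP counts are
negative-binomial (mean 20, size 2; genomic window counts are overdispersed
relative to Poisson because of LD and rate variation), and the enrichment
null uses a background of 500 genes with a 60-gene pathway and 40-gene
outlier sets, for which the all-five-rivers pattern has null probability
near 0.045.

## Numerical and degenerate-input choices

- Quantiles use R's default (type 7) definition throughout.
- `pod_threshold` refuses fewer than 100 POD SNPs; thresholds are
  deterministic under a seed.
- EHH integration includes the first point below the cutoff, then stops;
  cores with zero iHH in either population are skipped and logged.
- Windows with zero river-variant SNPs are excluded from AFD/FST; windows
  whose Hudson denominator sums to zero are undefined.
- `filter_sites` is idempotent; LD pruning is deterministic (the later site
  of an offending pair is removed) and iterates to a fixpoint.
- Monomorphic sites are retained by the pruner (their r² is undefined).
- Terminal partial windows are kept and flagged; SNP-count-based rules
  handle them downstream.
- Coordinates are 0-based half-open for windows/BED, 1-based for site
  positions (as in VCF); a site at position p lies in window [a, b) iff
  a < p ≤ b.
- One global seed deterministically derives per-stage seeds by hashing the
  stage name, so any stage can be rerun alone with identical output.

## Known limitations

- XtX-style Bayesian differentiation is deliberately not reimplemented; the
  Hudson-FST + POD-quantile surrogate preserves the windowing and decision
  rule but not the covariance-aware model, and is labelled as such in
  outputs.
- The POD null is built from the observed genome; strong, widespread sweeps
  contaminate it and make thresholds conservative (we measured this
  directly when a quarter of a small synthetic genome was swept). With
  realistic sweep fractions the effect is negligible.
- Desk-scale chromosomes carry few 100 kb windows, so branch-contrast
  percentiles are coarse.
- The f4-ratio's random half-split of P3 adds seed-dependent variance that
  matters at small haplotype counts.
- The simulator's scaled-down sizes preserve N·m and summary-statistic
  structure, not absolute time scales; divergence-date style inference is
  out of scope.
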