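---
title: "Methods: window-based selection scans and the DCMS composite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window-based selection scans and the DCMS composite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dcmscan)
```

This vignette is the package's own account of its science: the model
behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator emulates (and what it does not), the numerical
conventions, and the design choices made where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## The problem

A recent hard selective sweep drags one haplotype to high frequency,
leaving three footprints around the selected site: depressed nucleotide
diversity, an excess of rare variants (negative Tajima's D), and
unusually long stretches of haplotype homozygosity (extreme iHS/nSL). No
single statistic is reliable on its own — each has its own sensitivity
profile and false-positive modes — so this package combines four of them
per genomic window into one de-correlated composite (DCMS) and calls
candidate regions from its tail.

## Quality control

Two tracks share the same site filters, applied in a fixed order with
exclusive attribution so the exclusion table is additive (input = sum of
per-criterion exclusions + remaining):

1. *Hard filters* on the GATK annotations: a site fails when `FS > 60`,
   `QD < 2`, `MQ < 40`, `QUAL < 30`, `MQRankSum < −12.5` or
   `ReadPosRankSum < −8` (all strict inequalities; a site can count
   toward several rules in the per-rule tally). The two rank-sum
   annotations are routinely absent in real callsets for sites without
   heterozygous carriers, so an absent value *passes* those two rules;
   the other four are unconditional and an absent value fails.
2. *Depth*: retain sites whose mean per-sample depth lies in
   `[2, μ + 3σ]`, with `μ, σ` taken over per-site mean depths.
3. *Site QC*: any missing genotype (call rate < 100%), then MAF ≤ 0.05
   (strictly greater survives), then Hardy–Weinberg exact p < 10⁻⁶.
4. *LD pruning* (diversity track only): greedy PLINK-style
   `--indep-pairwise 50 10 0.5`. Inside each 50-SNP window, while any
   retained pair has r² > 0.5 the member of the worst pair with the
   lower MAF is removed (tie: the later site); the window slides by 10
   SNPs. The victim rule is not specified by the tools this mirrors, so
   the contract tested is the *invariant* — no surviving within-window
   pair above the threshold — rather than an exact kept set. LD is left
   intact in the selection track because extended LD is itself the
   signal there.
5. *Samples*: pairwise IBS `mean((2 − |dᵢ − dⱼ|)/2)`; while any pair is
   ≥ 0.95 the lower-call-rate member is dropped.

The Hardy–Weinberg test is the two-sided conditional exact test: with
the minor-allele count fixed, all heterozygote counts of matching parity
are weighted by the exact conditional distribution and the probabilities
of configurations no more likely than the observed one are summed. The
suite checks it against an independent enumeration using Levene's
absolute probabilities for every table with n ≤ 20.

## Diversity summaries

Observed homozygosity is the per-individual fraction of non-heterozygous
sites. The inbreeding coefficient is `F = (O − E)/(L − E)` with
`E = Σ(1 − 2p̂q̂)` from sample allele frequencies — deliberately without a
small-sample correction, which keeps the closed forms of the contract
(a fully heterozygous individual at p = 0.5 sites has F exactly −1) at
the cost of a negative bias of order 1/2N; at panel scale that bias is
well inside the between-individual spread, which is how the calibration
test brackets it. The one-sample location test is the Wilcoxon
signed-rank test (the standard one-sample analogue of the Mann–Whitney U
test); both rank tests use exact distributions up to n = 25 without
ties and the tie/continuity-corrected normal approximation otherwise.
PCA runs on centered, *unscaled* dosages (whether unit-variance scaling
was used upstream is unstated; unscaled is `prcomp`'s default and the
choice is documented here), with signs fixed by making each component's
largest-magnitude loading positive.

## The four statistics

**Windows.** All statistics are compared on one grid: 0-based half-open
`[start, start + 100 kb)` windows anchored at coordinate 0, step 25 kb;
a site belongs to every window covering it; windows with fewer than 10
SNPs are excluded before any standardization.

**Tajima's D** per window uses the standard constants
(`a1, a2, b1, b2, c1, c2, e1, e2` for n haplotypes) with
`π̂ = Σ 2d(n−d)/(n(n−1))` summed over window sites and S the segregating
count; windows with S = 0 are undefined and excluded.

**π** is per-site `2d(n−d)/(n(n−1))`, averaged per window.

**iHS and nSL.** EHH among the carriers of a core allele at extension x
is the probability that two random carriers are identical from the core
to x (`Σ C(m_g,2)/C(n_c,2)` over identity groups). iHH integrates the
EHH curve by the trapezoidal rule against physical distance, both
directions from the core, and `iHS = ln(iHH_A/iHH_D)`. nSL is the same
machinery with every inter-site step counting length 1 and no gap rule.
Numerical conventions, matching the defaults of the standard scan tool:

* integration stops after including the trapezoid into the first site
  where EHH < 0.05;
* a site is skipped (NA, with a reason code) if the chromosome edge, or
  a gap > 200 kb (iHS only), is reached before the cutoff;
* truncation at the maximum extension (1 Mb physical for iHS, 200 sites
  for nSL) keeps the site;
* no genetic map is assumed (physical distance = constant-rate map), and
  with no outgroup available the REF allele is treated as ancestral.
  Mispolarization flips the sign of a score; because iHS/nSL enter the
  composite two-tailed, that error is largely absorbed.

Raw iHS/nSL trend with derived-allele frequency, so they are z-scored
within 50 equal-width frequency bins (sparse bins merge leftward; a
zero-variance bin yields z = 0). Window means of π and the standardized
scores are then z-standardized genome-wide across included windows;
Tajima's D enters as computed. The order "standardize then window-mean
then genome z" was one of two readings of the upstream description; both
differ only by an affine rescaling when window SNP densities are
similar, and the next stage is rank-based, so the choice is immaterial
downstream (asserted by test).

## DCMS

Each statistic's window column becomes fractional-rank p-values
`p = rank/(n+1)` (mean ranks on ties, so p never reaches 0 or 1):
left-tailed for D and π (selection depresses them), two-tailed — ranked
by descending magnitude of the standardized value — for iHS and nSL.

The 4×4 correlation matrix across windows is estimated by FAST-MCD with
support fraction α = 0.75 and 50 000 random (d+1)-element starting
subsets (the estimator is written in compiled code: each start is
expanded until nonsingular, concentrated twice, and the ten best
candidates are iterated to convergence; when `choose(n, h)` is small the
h-subset search is exhaustive, which is also how the tiny-instance
oracle test can demand 1e-9 agreement). The covariance is rescaled by
the usual consistency factor and converted to a correlation (the factor
cancels there). Exactly collinear columns make every subset singular;
that degeneracy is detected up front and reported as an exact fit using
the classical estimate.

The composite is `DCMS_j = Σᵢ logit(1 − p_ij)/wᵢ` with
`wᵢ = Σₖ |r_ik|`: a statistic perfectly correlated with another shares
its weight, so d duplicated statistics contribute exactly one
statistic's worth (an algebraic identity in the test suite, together
with invariance to monotone transforms of raw columns and to the
logarithm base after the p-value refit). Natural log is the convention;
the base only rescales scores and the p-values are refit to the realized
distribution.

Window p-values come from a normal fit to the genome-wide DCMS
distribution: mean/SD, or median and 1.4826·MAD with `robust = TRUE`.
The pipeline default is the robust fit because selection inflates the
right tail of the very distribution being used as the null; on a small
simulated genome the sweep's own windows are a noticeable fraction of
the fit sample and the mean/SD fit visibly loses power. Windows with
−log₁₀ p ≥ 4 are candidates; strictly overlapping candidate windows
merge into regions (abutting windows do **not** merge — the merge uses
`min.gapwidth = 0` — since whether adjacency was joined upstream is
unstated and strict overlap is the conservative reading). Merged-region
sizes are therefore always 100 kb + 25 kb·k. Genes overlap a region iff
their half-open intervals share at least one base; a gene partially
overlapping a boundary counts (≥ 1 bp rule).

## The simulator: a stated world

The generator's job is to produce phased diploid VCFs whose statistical
structure exercises every downstream rule, with a truth table for the
planted defects. Defaults describe the scale used across the test bed
and are not tuned per test: 20 diploids (2N = 40), 2 Mb chromosomes,
~4 000 SNPs (2 SNPs/kb), LD scale 20 kb, mean depth 11.4× (the coverage
scale of a small resequencing panel), sweeps with carrier fraction 0.6
and ±150 kb cores.

*Neutral model.* Each haplotype copies a founder label (pool of 16)
along the chromosome, switching to a random founder between adjacent
sites with probability `1 − exp(−gap/λ)`; identical-label runs of
characteristic length λ produce the haplotype sharing that EHH sees. A
pure copy-from-founders model cannot also deliver the neutral site
frequency spectrum — with F founders the singleton fraction collapses
(checked numerically at design time: 0.01–0.18 versus the required
0.235 at 2N = 40) — so the derived-allele *count* of each site is drawn
directly from the neutral `P(k) ∝ 1/k` spectrum and the carriers are
chosen as the haplotypes with the smallest per-founder scores, where the
scores follow an AR(1) process along the chromosome with the same
correlation length λ. Allele sharing thus tracks founder sharing (LD
decays on the λ scale; λ → 0 recovers unlinked sites) while the sample
SFS is exact by construction.

*Sweep model.* A hard sweep is caricatured by haplotype copying: one
donor haplotype overwrites `⌈carrier_fraction·2N⌉` random haplotypes
over the core interval. This produces exactly the footprint the scan
detects (a long shared core at high frequency, depressed π, shifted
SFS) and nothing else — no partial recombination into the sweep, no
soft sweeps, no demography, no recombination-rate variation. A green
sweep-recovery test therefore establishes that the pipeline detects a
clean hard-sweep footprint at the stated scale, not that it has the
power profile of a coalescent-calibrated scan on real data.

*Planted defects.* A configured fraction of sites receives at least one
annotation violating a hard filter (each rule drawn with probability
0.4, at least one forced); clean sites draw from safe ranges
(QD ∈ [5,30], MQ ∈ [50,60], FS ∈ [0,30], QUAL ∈ [100,1000], rank sums
∈ [−2,2]). Missing genotypes are written `./.` — missingness carries no
phase, so the phased reader accepts them and the call-rate rule removes
those sites before any haplotype statistic runs. The truth table
(position, violated filters, missing count) is emitted beside the VCF
and is what the QC contract tests compare against.

## Scale choices in the tests

Fractional-rank p-values bound the evidence a window can carry: with n
windows the smallest achievable p is 1/(n+1), so a single 2 Mb
chromosome (77 windows) cannot push any window past −log₁₀ p ≥ 4 — the
sweep-recovery acceptance criterion on that geometry is therefore about
the *top-ranked* window and the sweep/neutral maximum-DCMS comparison,
exactly as stated. The end-to-end fixture that must *call* a region
uses a 4 × 2 Mb genome (~308 windows), where the p floor leaves
headroom and the sweep occupies a small enough fraction of windows for
the robust null fit to be clean. The neutral-calibration invariant runs
at 770 windows (10 chromosomes) instead of the full-scale ≥ 3000, with
the Poisson bound scaled accordingly.

## Known limitations

* REF-as-ancestral polarization biases individual iHS signs where REF is
  derived; rely on the two-tailed composite, not signed iHS, for calls.
* The MCD consistency factor assumes elliptical data; window statistics
  are skewed under selection. This perturbs the covariance scale (which
  cancels in the correlation) more than the correlation itself.
* The normal fit for DCMS p-values is a convenience null, not a
  coalescent null; thresholds transfer from the upstream design, they
  are not FDR-calibrated.
* Genotype-based r² is used for pruning (haplotype-based r² was the
  other reading; the upstream description does not say).
* The inbreeding estimator's 1/2N bias is documented above and not
  corrected, to preserve the stated closed forms.
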