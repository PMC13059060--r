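---
title: "Detecting sex-linked regions with slrscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sex-linked regions with slrscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slrscan)
```

## The problem

In many amphibians and fishes, sex chromosomes are young and barely
degenerated: X and Y are morphologically identical and differ only
across a limited sex-linked region (SLR). Such regions leave two
complementary footprints in whole-genome resequencing data from a
male/female cohort:

* **Genotypic**: at X/Y-differentiated sites, XY males are
  heterozygous while XX females are homozygous for the X allele. This
  elevates male-vs-female F_ST, male SNP density, and male
  heterozygosity locally.
* **Coverage**: sequence present only on the Y (hemizygous) recruits
  male reads but essentially no female reads, producing an extreme
  male:female depth ratio.

`slrscan` implements the full discovery chain over these signals —
windowed scans, locus-level screens, per-individual scores with a
cross-chromosome concordance test, coverage-marker extraction, and
supporting diagnostics (LD, change-points, PCA/NJ structure) — plus a
forward simulator that plants SLRs with known truth so each stage has
a recovery test.

## Statistical model of each stage

### Windowed F_ST between the sexes

Per biallelic site, the Weir–Cockerham (1984) variance components
$a$ (among groups), $b$ (among individuals within groups) and $c$
(within individuals) are computed from the two sexes' called sample
sizes, allele frequencies and heterozygote frequencies; the per-site
estimate is $\hat\theta = a/(a+b+c)$. Windowed values default to the
ratio-of-sums $\sum a / \sum (a+b+c)$ over the sites of a window
(`mode = "weighted"`), the conventional meaning of windowed F_ST in
genome scans; a mean-of-ratios mode is also exposed because reports
differ in which they print. Negative per-site estimates are a normal
finite-sample outcome and are never clipped; sites with
$a+b+c = 0$ (monomorphic) are undefined and excluded from windows.

Candidate SLRs are the windows at or above the top-1% quantile of the
windowed F_ST distribution (linear interpolation between order
statistics; per-genome by default, per-chromosome via
`quantile_scope`). Flagged windows bridged by at most
`max_gap_windows` are merged, and runs with at least
`min_flagged_windows` flagged members are reported. The merge/min-run
parameters are artifact additions — practitioners usually read such
scans off a Manhattan plot — and are fully configurable.

### Coverage and SNP-density tracks

The per-window coverage statistic is
$\log_2(\bar d_M + 0.01) - \log_2(\bar d_F + 0.01)$, with $\bar d_M$,
$\bar d_F$ the mean depths over males and females. The pseudocount
makes the statistic finite when females have no reads and sets the
scale of the hemizygous signature: male depth 16x against female zero
gives $\log_2(16.01/0.01) \approx 10.6$, whereas equal coverage gives
0. The statistic is antisymmetric under swapping the sex labels, which
is how the W-direction (female-specific) screen is run.

SNP density per sex counts loci variable within that sex's called
genotypes per Mb (alternative: alt-carrier counts, via
`density_mode`), and the ratio track applies the same pseudocount.

### Locus classification and the consistency filter

Three locus labels are supported. `xy_strict`: all called males
heterozygous, all called females fixed for one homozygote. `xy_like`
(relaxed): females fixed homozygous and at least a fraction
`male_het_enrichment` (default 0.5) of called males heterozygous —
the relaxation matters because males carrying an undifferentiated
(X-like) Y dilute the strict pattern. `zw_strict` swaps the sexes.
All three are invariant to which allele is REF, and loci with fewer
than `min_called_per_sex` (default 3) called genotypes per sex are
left unclassified to avoid single-call artifacts.

The consistency filter used ahead of heat-map visualization retains
loci with no missing call and one shared genotype within each sex; the
XY-pattern subset additionally requires the shared male genotype to be
heterozygous and the shared female genotype homozygous. We read the
within-sex consistency requirement as applying to both sexes
simultaneously: retained counts then properly exceed XY-pattern
counts, since loci fixed identically in both sexes also pass.

### Per-individual sex-linkage scores and co-occurrence

A locus panel is defined a priori from a defining contrast — all
females versus the strongly male-associated (M2) males — inside a
candidate region, in relaxed or strict mode. The panel is then frozen;
each individual's score is the proportion of heterozygous genotypes
among its called genotypes over panel loci. Two structural facts
follow from the construction and are asserted by the tests:

* every defining female is fixed homozygous at every panel locus, so
  defining females score exactly 0 (not approximately 0);
* scores of non-defining samples cannot alter panel membership.

Concordance of sex-linkage between two regions (e.g. the main SLR and
a small degenerate SLR on another chromosome) is tested by
dichotomizing each individual's two scores at panel-specific
thresholds (defaults 0.6 and 0.3, score >= threshold meaning "high"),
tabulating the 2x2 table, and applying the two-sided Fisher exact test
alongside Spearman correlation on the raw scores. For the archetypal
fully concordant cohort of 22 individuals (5 high/high, 17 low/low)
the Fisher p is exactly $1/\binom{22}{5} \approx 3.80\times10^{-5}$.
The Spearman p uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df; at $n = 22$,
$\rho = 0.725$ this gives $p \approx 1.3\times10^{-4}$, matching the
scale of published values for the same statistic, which supports the
choice; exact permutation p-values would differ slightly in the tails.

### Coverage markers and male classes

Male-specific (Y-specific) candidate markers are windows where every
female is at or below `max_female_depth` (default 0: literally no
female coverage) and at least `min_male_fraction` of the consulted
males reach `min_male_depth`; a subset sample sheet restricts the
screen to the informative males (e.g. females + M2 only) when part of
the males carry an X-like Y. Hemizygous regions are runs of at least
`hemi_min_windows` windows with log2 coverage ratio >=
`hemi_log2_threshold` (default 3, i.e. >= 8-fold male excess — safely
below the ~10.6 full-hemizygosity signature at 16x but above diploid
fluctuation).

Males are assigned to genotypic classes by the score rule (score >=
0.6 on the SLR panel = M2, else M1) or by 2-means clustering on PC1 of
SLR SNPs with the cluster nearer the female centroid labelled M1. M1
males are interpreted as carrying weakly differentiated, possibly
recombining Y haplotypes; M2 males carry the divergent Y.

### Diagnostics

*LD*: composite (dosage-correlation) r2 over samples called at both
loci — appropriate for unphased genotypes and deterministic, though
not identical to haplotype-frequency r2 from EM phasing. Within an XY
SLR scored in males, X-like and divergent-Y haplotypes segregate
together, so r2 is near 1 across the region; females show background
LD only. Note the finite-sample floor: independent loci give
$E[r^2] \approx 1/(n-1)$.

*Change-points*: greedy binary segmentation on any windowed series
(repeat content, GC, coverage) with within-segment SSE cost, leftmost
tie-breaking, and either a fixed number of splits or an SIC penalty
($\beta = \log n$ per change-point; the reference implementation's
MBIC default is approximated by SIC since neither a Q nor a penalty
was fixed upstream). Greedy binary segmentation is not globally
optimal at low signal-to-noise — the first split can land mid-step —
so oracle-equality tests run in the well-separated regime.

*Structure*: dosage PCA (per-locus centering on $2\hat p$, scaling by
$\sqrt{2\hat p(1-\hat p)}$, mean imputation of missing dosages,
deterministic sign convention), allele-sharing IBS distances with
pairwise deletion, and an in-house Saitou–Nei neighbor-joining
implementation (lowest-index tie-breaking; negative branch lengths
clamped to zero with the deficit moved to the sibling) cross-checked
against an independent implementation on additive matrices.

## The simulator: what it emulates, and what it does not

`sim_config()` defaults describe a realistic discovery cohort:

| parameter | default | rationale |
|---|---|---|
| cohort | 5 F + 12 M1 + 5 M2 | the two-male-class population structure the score stage must resolve |
| mean depth | 16.1x | typical mid-depth resequencing |
| depth noise | gamma-mixed Poisson, dispersion 0.1 | overdispersed window depth without read-level simulation |
| windows | 50 kb | the scan resolution used throughout |
| genome | 60 Mb over 3 chromosomes | desk-scale stand-in for a multi-Gb genome (see below) |
| background SNPs | 13 per kb | genome-wide density of a deep amphibian resequencing panel (tens of millions of SNPs over a few Gb) |
| XY SLR | 2 Mb at 3 XY SNPs/kb on chr6 | scales a ~70k-locus panel down to a 2 Mb region |
| degenerate SLR | 100 kb at 0.3/kb on chr2 | a second, weak region (tens of loci) on another chromosome |
| hemizygous segment | 200 kb on chr2, female noise floor 0–0.25x | Y-specific sequence; the ~10-fold coverage signature arises from the pseudocount formula, not from a hard-coded ratio |
| m1_y_similarity | 0.95 | M1 males carry the X-like genotype at 95% of XY loci (no quantitative value is available; this is a free parameter) |
| genotype error / missingness | 0.001 / 0.02 | typical post-filter call quality |

Autosomal genotypes are Hardy–Weinberg draws at Beta(0.8, 0.8)
frequencies, identical for both sexes, so autosomal windowed F_ST is
centred at zero. At XY loci, females are fixed homozygous for the X
allele, M2 males heterozygous, and M1 males X-like at rate
`m1_y_similarity`.

Two scale choices deserve emphasis because they shape what passing
tests mean. First, the genome is ~50x smaller than a real amphibian
genome while the planted SLR is full-size (2 Mb), so the SLR occupies
~3% of windows instead of <1%; the top-1% rule therefore flags only
the strongest SLR windows, and recovery is judged by whether a called
region's midpoint falls inside the planted interval, not by boundary
reconstruction. Second, the SLR-defining scan in the recovery tests
contrasts the females with the divergent-Y (M2) males — the original
discovery design — because a scan against all males dilutes XY F_ST
through the X-like M1 majority; the package supports both contrasts
and the dilution is itself visible in the all-male scan.

The simulator does not model recombination maps, coalescent ancestry,
linked selection, reference bias, or read-level artifacts; LD in the
background is purely the finite-sample floor. Passing recovery tests
therefore demonstrate correctness of the inference chain under the
assumed generative model, not robustness to alignment or calling
artifacts in real data.

## Numerical choices and degenerate inputs

* Genotypes are alt-allele dosages 0/1/2 with NA for missing; any
  half-missing VCF call is missing; phase is ignored.
* Internal coordinates are 0-based half-open everywhere; VCF positions
  are converted on read/write, and loci keep their 1-based `pos`.
* MAF filtering drops strictly below the threshold (a locus at exactly
  0.05 survives `min_maf = 0.05`), matching the common tooling
  convention; missingness drops strictly above.
* LD pruning sweeps windows of 50 surviving SNPs (step 10) and repeats
  until a fixed point, which makes the filter idempotent; within a
  window the member with more missing calls is dropped, ties to the
  later position.
* Quantile thresholds use linear interpolation between order
  statistics (type 7).
* Empty panels yield NA scores and are excluded pairwise from the
  co-occurrence table with a logged count; an all-zero 2x2 table has
  Fisher p = 1.
* `wc_site_components` returns undefined components when a group has
  no called genotype or both groups are single diploids.
* `binseg_mean` ignores split gains below a floating-point tolerance
  (1e-10 of the total SSE), so constant series produce no
  change-points.

## Problem sizes used by the shipped tests

The default simulated cohort (60 Mb, ~780k loci, 22 samples) runs the
full scan in a few seconds. The recovery suite uses 20 independent
cohorts; unit tests use 4 Mb cohorts with ~5k loci. These sizes were
chosen so the whole suite exercises every stage at meaningful scale
while remaining comfortable on a laptop.

## Known limitations

* Windows are non-overlapping tiles; captions describing "sliding"
  windows with step < size are approximated by tiling (step size
  configurable).
* The relaxed-mode enrichment cutoff (0.5) is a package default; the
  exact cutoff behind published XY-like panel sizes is not
  recoverable.
* Composite r2 differs from haplotype-frequency r2 when phase matters.
* The Spearman p is a t approximation; at n ~ 20 it is accurate to the
  first decade but is not an exact permutation p.
* Score-based male-class assignment presumes the panel region truly is
  the SLR; on a non-SLR region all males score near 0 and collapse
  into M1.
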