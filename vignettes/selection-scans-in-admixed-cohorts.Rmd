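---
title: "Selection scans in admixed cohorts: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans in admixed cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixscan)
```

## The problem

An admixed population — one formed recently from several differentiated
ancestral components — can carry signals of positive selection of three
distinct kinds:

* **private** sweeps that happened in its autochthonous component before
  admixture;
* **shared** sweeps inherited from a source population (either a sweep that
  predates the split, or adaptive admixture that imported an already-selected
  haplotype);
* **post-admixture** selection acting after the admixture pulse on haplotypes
  of a particular ancestry, which skews local ancestry at the selected locus.

No single statistic sees all three. `admixscan` therefore implements the
standard battery — allele-frequency differentiation, haplotype homozygosity,
and local-ancestry deviation — and classifies the resulting candidate
regions by where the evidence appears.

## Statistics

**Weir–Cockerham FST.** Per-SNP variance components for two populations of
diploids: `a` (among populations), `b` (among individuals within
populations), `c` (within individuals), computed from per-population sample
sizes, allele frequencies and observed heterozygosity; the estimator is
`a / (a + b + c)`. Sites monomorphic across the union, or with fewer than
two genotyped individuals in a group, are flagged undefined and excluded
from ranking. Individuals missing either haplotype at a site are excluded at
that site.

**EHH, iHH, iHS.** EHH at distance *d* from a core site is the probability
that two random haplotypes carrying the core allele are identical over the
intervening interval, `sum(choose(n_i, 2)) / choose(n_c, 2)` over the
partition of carriers into identical extended haplotypes; EHH(0) = 1 by
definition. iHH is the trapezoidal integral of EHH over physical distance,
truncated at the last point at or above the cutoff (default 0.05); a curve
that reaches the chromosome end or a gap larger than `maxgap_bp` (default
200 kb) while still above the cutoff is *censored* and the site is excluded
rather than integrated to the edge, which would bias iHH downward near
chromosome ends. Raw iHS is `ln(iHH_ancestral / iHH_derived)` with both
directions summed per allele; sweeps on the derived allele push it strongly
negative. Scores are standardized to mean 0 / SD 1 within 20 equal-width
derived-allele-frequency bins spanning `[maf_min, 1 - maf_min]`; bins with
fewer than two scored sites are merged with their nearest occupied
neighbour. Haplotypes are dropped from a curve at their first missing call,
and the pair denominator follows the retained carriers.

**XP-EHH.** Pooled-allele EHH (all haplotypes; the core allele is part of
the extended-haplotype identity) is computed in both panels over the *same*
extent per direction — out to the further of the two panels' cutoff
crossings — so the faster-decaying panel contributes its sub-cutoff tail
over the shared interval. The raw score `ln(iHH_A / iHH_B)` is positive when
homozygosity extends further in panel A, and is standardized genome-wide.
Whether per-chromosome or genome-wide standardization is used matters little
for rank-based outlier calling; genome-wide is used and single-chromosome
inputs make the two identical.

**Rank-based combination.** Within each scan, site *i* receives
`p_i = rank_i / (N + 1)` (rank 1 most extreme; average ranks on ties; the
`N + 1` denominator keeps p strictly positive so the combined score stays
finite). The top 1% of FST (signed) and of |XP-EHH| (absolute value — both
tails are informative) are intersected, and the intersection is ordered by
Fisher's combined score `-2(ln p_FST + ln p_XPEHH)`, chi-square with 4
degrees of freedom under independence. Only the induced ranking is used
downstream, so the score's scale is immaterial; the chi-square tail is
reported for reference, not as a calibrated p-value (the two ranks are not
independent).

**LAD.** From per-haplotype ancestry tracts, the dosage `alpha_k(s)` at site
*s* is the fraction of haplotypes whose covering tract carries label *k*;
LAD is the standardized deviation from the genome-wide level, thresholded at
|LAD| > 4.42. Two standardizations are offered:

* `method = "binomial"` (default): center = median dosage, scale =
  `sqrt(c(1 - c) / n_hap)`. Under the pulse model haplotypes are
  independent, so the binomial SE is the *exact* null SD of a per-site
  dosage. Crucially, it cannot be inflated by a true selected region.
* `method = "moments"`: genome-wide mean and empirical SD — the natural
  choice when the input spans a whole genome and any selected region is a
  negligible fraction of the scanned sites.

The default departs from the plain empirical SD deliberately. On a single
simulated chromosome of 25 Mb, a post-admixture sweep drags a multi-megabase
ancestry bump covering 10–20% of all sites; the empirical SD then triples
and the scan can no longer reach its own threshold — the moment estimator
masks the very signal it is meant to standardize. The binomial construction
is immune to this and agrees with the moment construction under neutrality.
The 4.42 threshold itself is inherited as an external calibration and is
configurable.

**Classification.** Candidate regions are single-linkage merges of outlier
sites within 200 kb, padded by 100 kb per side (matching the few-hundred-kb
windows in which such signals are conventionally displayed; configurable). A
target region overlapping (≥ 1 bp) any source-scan region is
`shared_with_<source>` — the overlap alone cannot distinguish adaptive
admixture from a residual shared sweep, and the label does not try to;
overlapping a significant LAD region gives `post_admixture`; neither gives
`private_target`. Multiple labels are reported in the fixed order
post-admixture, shared, private. Gene annotation uses half-open interval
intersection, so an abutting gene is not attached. Region overlap rather
than gene-name identity keeps the classification independent of annotation
dialects.

## The simulator

`simulate_scenario()` produces ground-truth datasets for four scenarios
(neutral, private_sweep, shared_sweep, post_admixture_sweep). It emulates:

* **Four differentiated components.** Per-site frequencies per pool are
  Balding–Nichols draws around a shared ancestral frequency (uniform
  0.05–0.95) with divergence parameter `target_fst = 0.10`; each pool's 300
  haplotypes are recombinant mosaics of 150 Bernoulli founder haplotypes
  scrambled by 100 effective generations of recombination, giving a
  background EHH decay scale of roughly 170 kb. Realized mean pairwise FST
  between pools lands near the 0.10 target.
* **Pulse admixture.** Each of the 200 cohort haplotypes draws ancestry
  breakpoints as a Poisson process of rate `g * r` per bp (tract lengths
  exponential, mean `1/(g r)`), labels tracts independently with the
  admixture proportions, and copies alleles from a random haplotype of the
  labelled pool. Defaults: `g = 10` generations,
  `q = (0.55, 0.153, 0.20, 0.097)` for the Maghrebi-, European-, West/East-
  African- and Middle-Eastern-like components — the European-like fraction
  matching the 15.3% genome-wide average estimated in western North African
  cohorts. The admixture date is a free parameter of the simulator, not an
  estimate.
* **Sweeps.** Haploid multiplicative fitness with the deterministic
  recursion `p' = p(1+s)/(1+ps)` for the favoured-allele frequency, plus
  stochastic resampling with per-meiosis recombination — the simplest model
  that produces both the frequency shift and the hitchhiking signature.
  Pre-admixture sweeps default to `s = 0.05`, 400 generations, and
  `p0 = 0.002` (a hard sweep from a single founder copy, the classic model
  for the skin-pigmentation-type signals such scans recover); the sweep
  locus is chosen where the favoured allele is nearly private to the swept
  component, as expected for a young mutation. The selected phase is
  simulated with standard population rescaling (factor
  `sweep_popsize / pool_size ≈ 8`): fewer steps at proportionally stronger
  selection and recombination. The frequency trajectory is *exactly*
  preserved (the recursion is linear in logit space), as are the drift ratio
  t/N, the carrier-coalescence intensity, and the hitchhiking scale r·t; a
  panel-sized population run un-rescaled for 400 generations would instead
  lose most of its background diversity to artificial drift. Resampling
  stops once the favoured allele fixes. Post-admixture selection
  (`s = 0.1`, 15 generations by default) runs in an expanded admixed
  population of 5000 haplotypes — the cohort is a sample from a large
  population, and simulating the selected phase at cohort size would add
  drift to the ancestry-dosage field — favouring haplotypes whose local
  ancestry at the locus matches the selected component, splicing tracts and
  alleles through fitness-weighted parents.

**Geometry.** One chromosome of 25 Mb with 2000 SNPs (12.5 kb spacing) and a
uniform map of `r = 3e-8` Morgans/bp — the upper range of human sex-averaged
rates. The map rate was chosen so that the hitchhiking block of the default
400-generation sweep (`~1/(r t)` ≈ 80 kb) sits within the 100 kb
localization window used in the power checks, while ancestry tracts
(mean 3.3 Mb) still tile the chromosome several times per haplotype.
Multi-chromosome scans are concatenations of single-chromosome runs.

**What the simulator does not emulate** — and hence what passing checks do
not demonstrate about real data: no mutation during the sweep, no background
selection, no variable recombination map or hotspots, no genotyping error,
no phasing or local-ancestry-inference error (tracts are ground truth; real
tract calls carry switch errors that blur LAD), no continuous or multi-pulse
admixture, and no X chromosome. Coordinates are 0-based half-open
internally, 1-based in VCF.

## Numerical and interface choices

* EHH cutoff 0.05 and maximum gap 200 kb are the conventional scanning
  defaults; iHH is in bp·EHH units, harmless because both iHS and XP-EHH are
  ratios.
* Distances are physical bp under a uniform genetic map; no map file is
  consumed.
* QC filters apply in the order missingness (≤ 10%), per-population exact
  HWE (p ≥ 1e-8; a site fails if any population fails), MAF (≥ 0.05),
  biallelic-SNP check; a site failing several is counted under the first.
  MAF is computed on the assigned analysis samples after merging, mirroring
  the post-merge filtering order of the motivating workflow. A single
  post-merge QC pass is exposed; per-dataset pre-merge passes are the
  caller's concern.
* LD pruning (50 kb windows, 5-SNP step, r² ≤ 0.5) uses diploid genotype
  dosage correlation — the cited pruning tool's convention — whereas
  `ld_pair_stats` reports haplotype-frequency D, D′ and r²; the two
  conventions are intentionally distinct.
* Unphased or half-missing VCF genotypes become missing on both haplotypes:
  haplotype statistics cannot use them, and silently treating them as phased
  would corrupt EHH.
* The exact HWE test enumerates the conditional distribution of the
  heterozygote count in log space; the two-sided p sums all outcomes no more
  probable than the observed one (with a 1e-12 relative tolerance against
  ties lost to floating point).
* `run_full_scan` writes every intermediate table as TSV plus a JSON
  manifest holding the config, package version, seed and per-stage row
  counts — and no timestamps, so a rerun with identical inputs and seed is
  bit-identical.

## Problem sizes used in the bundled checks

The packaged tests and the acceptance script run at desk scale: oracle
equivalences on 200 random instances (FST; 20-haplotype × 50-site EHH
matrices), the full HWE enumeration to n = 25, normalization contracts on
one 2000-SNP neutral cohort, and 20 seeds per scenario for calibration
(neutral LAD exceedance, zero post-admixture labels) and power
(private-sweep iHS localization within 100 kb at the top 0.1%;
post-admixture peak |LAD| > 4.42; shared-sweep presence in the combined
FST ∩ XP-EHH set and a `shared_with_EUR` classification). These sizes were
chosen as the smallest at which the binomial uncertainty of a 20-seed rate
is compatible with the stated thresholds.

## Known limitations

* For a *completed* sweep, the maximum |iHS| frequently sits not on the
  fixed core site but on partially-hitchhiked flanking sites 100–400 kb
  away, whose intermediate-frequency tag alleles mark a purer, longer-shared
  subset of swept haplotypes — a well-documented property of the statistic,
  reproduced by the simulator. Localization of long-completed sweeps to
  better than a few hundred kb should therefore not be expected from iHS
  rank alone; in the bundled power checks the top-0.1% set falls within
  100 kb of a 400-generation private sweep in roughly 70–75% of seeds, with
  the remainder peaking on the flanks of the same signal.
* The chi-square tail of the combined score is a ranking convenience, not a
  calibrated significance level, because the two rank p-values are computed
  on overlapping data.
* LAD inherits its 4.42 threshold from an external genome-wide calibration;
  on correlated sites the per-site exceedance fraction is bursty, which is
  why calibration statements are averages over seeds.
* With missing data, the EHH pair denominator follows the retained carriers,
  so a curve need not be monotone at sites where haplotypes drop out.
* Candidate regions from a single-chromosome scan use genome-wide
  standardizations computed on that chromosome; concatenate chromosomes
  before scanning when possible.
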