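---
title: "Methods: SDR discovery, strata dating and sweep scans in zwscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SDR discovery, strata dating and sweep scans in zwscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwscan)
```

`zwscan` implements three linked analyses for a female-heterogametic (ZW)
plant genome assembled from the female: locating the sex-determination
region (SDR) on the W chromosome, dating the evolutionary strata created by
W-chromosome inversions, and scanning wild/cultivar resequencing panels for
domestication selective sweeps. This vignette describes the models, the
tunable parameters and the design choices, including every place where the
published protocol under-determines the algorithm and the package had to
decide.

## Coordinates and reporting conventions

All in-memory coordinates are 1-based and inclusive; BED and bedGraph are
converted at the I/O boundary. Span lengths are reported in Mb as
`(end - start) / 1e6` rounded half-up to two decimals, because published
span tables follow that convention (e.g. Chr14:39979216-52678755 prints as
12.70 Mb; `end - start + 1` would give the same two-decimal value here, but
the subtraction convention reproduces every published span in the package's
tests, so it is fixed once and used everywhere).

## SDR discovery from pooled coverage

**Model.** Pooled female and male read depths are compared in fixed windows
(default 10 kb). With pool depth ratios `F/(F+M)`, a region present only on
the W appears with `F/(F+M)` near 1 (males carry no W), a Z-like region
duplicated in males appears below 0.5, and ordinary sequence sits at 0.5.
The SDR of an old ZW system is a mosaic: W-specific segments interleave with
W homologs of Z sequence that are coverage-balanced, so one continuous
stretch of divergence is not expected and the caller must merge divergent
runs across internally balanced gaps.

**Classification.** A window with total depth below `min_total` (default 10
reads) is `low_coverage`. Otherwise it is `W_specific` when
`ratio_f > 0.5 + delta`, `male_elevated` when `ratio_f < 0.5 - delta`, else
`balanced`. `delta = 0` reproduces the literal 0.5 cutoff. The function
default is `delta = 0.05`; the pipeline default is `delta = 0.12`, chosen
from a power calculation: with Poisson pool depths of ~30x per window the
standard deviation of `ratio_f` on balanced sequence is about 0.065, so
`delta = 0.05` misclassifies ~44% of balanced windows (which makes every
chromosome one connected divergent chain), while `delta = 0.12` holds the
per-window false rate near 6% yet still detects W-specific windows
(deviation 0.5) essentially always and male-elevated windows (deviation
~0.17) at >80%.

**Calling.** Maximal runs of non-balanced windows are computed; runs of at
least `min_run` windows (default 20, i.e. 200 kb) are *major* runs, and
only chromosomes with major runs can carry a call (chromosomes are ranked
by total major-run bp). Runs down to `min_seed_run` windows (default 3)
take part in gap bridging, so that a long divergent segment fragmented by
classification noise does not widen its apparent gaps. Runs separated by
gaps up to `max_gap` (default 1 Mb) chain into one span — the mosaic
structure above is why merging is required; the published protocol does not
state its gap rule, so the 1-Mb default is the package's choice, sized
below the SDR-internal balanced gaps it must not break and above any gap it
must bridge. Finally the span's edges are refined to the outermost window
with `|ratio_f - 0.5| >= edge_delta` (default 0.25): a real SDR boundary is
anchored by strong divergence, whereas the one or two marginal windows that
random noise attaches to a run edge are not.

**Evidence integration.** Three SNP layers from the sexed resequencing
panel annotate the call: (i) per-site allelic association with sex, a 2x2
allele-count chi-square with `-log10(P)`; (ii) Weir-Cockerham Fst between
the sexes in 20-kb windows, thresholded at the empirical top-1% quantile
computed genome-wide (whether the original analysis took the quantile
genome-wide or per chromosome is not stated; genome-wide is the stricter,
simpler choice); (iii) female-specific SNP blocks — sites whose allele is
carried by >= 90% of females and <= 0 males, grouped into runs of >= 10
sites with gaps <= 100 kb (the original rule is unstated; these thresholds
are the package's documented defaults). `support` counts layers
overlapping the span (0-3).

The association cutoff deserves a note. The exact-form allelic chi-square
replaces a mixed-model association test, whose kinship matrix cannot be
reproduced without the original panel. For a fully penetrant W-linked site
in a 22-female/22-male panel — every female heterozygous, every male
reference — the allele table is 22/44 vs 0/44, the chi-square is 29.33 and
`-log10(P)` is about 7.2. That is the *maximum attainable* score for
realistic sex-linked sites at this sample size, so a mixed-model-scaled
cutoff of 10 would discard perfect signal. The `integrate_evidence()`
default keeps `assoc_cut = 10` for compatibility with that convention, but
the pipeline default is `assoc_cut = 6`, approximately a Bonferroni
genome-wide level (0.05 / 1e5 tests ~ 5e-7) for the allelic test, which
preserves the detection behaviour the substitution is meant to preserve.

A genetic-map diagnostic supports chromosome identification: per
chromosome, the Spearman correlation between physical and genetic marker
positions and the longest physical span with no cM increase; a ZW
chromosome with a large non-recombining region ranks first (lowest
correlation, longest plateau).

## Strata dating

**Collinearity.** W-Z anchor pairs (one-to-one homologs) are ordered along
W and given Z ranks; maximal runs with monotone ranks are blocks —
ascending runs collinear, descending runs inverted. A run tolerates rank
jumps up to `max_rank_gap` (default 2) and must contain `min_block_anchors`
anchors (default 3). Full dynamic-programming collinearity scoring (as in
MCScanX) is unnecessary here because the input is an already-paired gene
set; on such input the DP reduces to maximal monotone runs. The
breakpoint-splitting oracle in the test suite checks the chaining on all
small permutations.

**Divergence.** Each anchored CDS pair is scored with the Nei-Gojobori
(1986) counting method: fractional synonymous site counts per codon
(averaged over the two sequences; at each codon position the fraction of
single-base changes that are synonymous, with changes to stop codons
excluded and the denominator renormalised), observed synonymous and
nonsynonymous differences with multi-hit codons averaged over all orderings
of single changes, and the Jukes-Cantor correction
`d = -(3/4) ln(1 - (4/3) p)`. Pathways through stop codons are excluded
and the weights renormalised (the DnaSP-like behaviour); a
`stop_paths = "count"` toggle retains them. When every pathway of a codon
passes through a stop, all pathways are used. A proportion >= 0.75 leaves
the correction undefined; the estimate is returned as `NA` with a
`saturated` flag. Silent-site divergence `Ksil` is taken equal to `Ks`
because only CDS is supplied (no noncoding silent sites); the output flags
this.

**Dating.** `T = Ksil / (2 mu)` with `mu = 7.5e-10` substitutions per site
per year, the clock rate estimated for *Pistacia*. One stratum per
inverted block, summarised by the median pair age and numbered oldest
first; blocks with fewer than 3 dated pairs are flagged low-confidence.

## Sweep scan

Diversity is computed per subgroup in 50-kb windows sliding by 10 kb
(`pi` = sum over sites of `2*p*q*n/(n-1)` divided by window bp, the
VCFtools windowing convention), after the standard hard filters
(DP in [2, 40], quality >= 20, missing <= 20%, MAF >= 5%; the MAF rule
removes sites *below* 5%, so exactly 5% is retained). The wild/cultivar
ratio `pi_W / pi_C` flags diversity loss; windows with `pi_C = 0` and
`pi_W > 0` become infinite and rank above all finite values.

The LD signature is scored with an omega statistic on a 20-kb grid: at each
grid point, for the nearest `max_snps_side` (default 25) polymorphic sites
per side and all split sizes `l, r >= 2`, omega is the mean within-side
r-squared over the mean between-side r-squared, maximised over splits, with
`eps = 1e-6` stabilising the denominator at perfect block structure.
r-squared is the squared Pearson correlation of unphased dosage vectors
(haplotype-based LD would need phased data; only the outlier ranking
matters for the scan).

Candidate regions are the top 5% of each statistic (ties at the quantile
included), expanded by 4-kb flanks, with overlapping expansions merged;
flanks are added to each statistic's regions *before* intersecting (the
published order of flanking and intersecting is ambiguous; flank-first is
the more permissive reading and keeps the two statistics symmetric). The
intersection of the two region sets, merged where intersections overlap, is
the sweep call; every region must retain support from both statistics.
Genes overlap regions by the any-overlap (>= 1 bp) rule.

Two absolute effect floors (pipeline defaults `ratio_floor = 2`,
`omega_floor = 5`; 0 disables both and restores the literal quantile rule)
are applied to the outlier candidates. A pure top-5% x top-5% intersection
necessarily reports regions even on data with no sweeps, because empirical
quantiles always select carriers; the floors sit far above null sampling
noise (ratio ~ 1 +- a few percent in windows with thousands of sites;
omega ~ 1-4) and far below the planted effect (ratio 5, omega in the
tens), so they suppress null false positives without costing power. They
were fixed from this separation argument before the recovery studies were
run.

## The synthetic-data generator

Every detector is exercised on seeded synthetic data with a
machine-readable truth set; all generators are pure functions of
(config, seed), with independent sub-streams per generator.

* **Layout** — one 55-Mb ZW chromosome ("Chr14") and two 20-Mb autosomes;
  the SDR truth at Chr14:39979216-52678755 (12.70 Mb) contains six
  W-specific and two male-elevated segments (the first and last divergent
  segments touch the SDR boundaries, as coverage divergence is what defines
  those boundaries) and three inversions aged 8.18, 3.80 and 3.47 Mya with
  170/173/44 anchor pairs, plus two small collinear blocks.
* **Pooled coverage** — per-window depths are Poisson with female mean 30
  everywhere, male mean 0 on W-specific segments, 60 on male-elevated
  segments and 30 elsewhere; a window belongs to a segment by its midpoint.
* **Sex panel** — 22 females and 22 males. Background sites carry allele
  counts drawn from the neutral folded spectrum (weights 1/i) and planted
  *exactly* across the pooled alleles, so the realised SFS matches the
  model and sex is independent of genotype; SDR sites are heterozygous in
  every female and absent from every male. The pooled samples of a real
  study would come from an F1 cross; family structure is not emulated.
* **Population panel** — generated on a dedicated 2-Mb chromosome
  (theta = 0.008 on the full 95-Mb layout would mean several million
  segregating sites; the 2-Mb scale keeps a full recovery study at desk
  scale while leaving ~200 diversity windows and 100 omega grid points).
  100 samples (20 wild, 20/20/40 cultivars). Sites are planted exactly as
  in the sex panel, with subgroup frequencies hypergeometric, so subgroups
  are undifferentiated outside sweeps. Inside a planted sweep
  (default: 60-kb span, reduction factor 5), the affected subgroups have a
  monomorphic 20-kb core around the centre; flanking sites either go
  monomorphic or carry a latent haplotype dosage shared within 5-kb tiles
  (flip rate 0.05), which creates high within-flank and background
  cross-centre LD — the omega signature — without letting a single latent
  frequency draw dominate a window's diversity. The retained-site fraction
  is calibrated in closed form (`keep = (w/(w - core)) * h_neutral /
  (factor * h_latent)` with `h_neutral = 1/a_n`) so a 50-kb window centred
  on the sweep has `pi_C = pi_W / factor` in expectation.
* **W-Z gene pairs** — for a block of age `T`, the pair's true
  Jukes-Cantor synonymous distance is `2*mu*T`: the generator plants the
  clock-expected number of synonymous single-base changes (rounded) at
  random synonymous positions, split at random between the lineages, with
  nonsynonymous changes at 5% of the synonymous expectation (purifying
  selection; rejection of stop codons throughout). Planting the expected
  count rather than a Poisson draw is deliberate: at the youngest stratum
  age a 1000-codon gene expects only ~4 synonymous substitutions, so a
  Poisson count is lattice-valued in steps of ~25% of its mean and the
  *median* recovered age would be biased by up to one lattice step;
  deterministic planting plus gene-length variation (uniform +-50% around
  1000 codons, mirroring real CDS length spread) makes the median recovery
  unbiased at the percent level. Anchor order is reversed on W within
  inversions.
* **Genetic map** — markers every 200 kb; autosomal cM increments are
  proportional to physical distance with 10% multiplicative noise; across
  the SDR the genetic position is exactly constant.

What passing the recovery studies shows — and does not show. The generator
reproduces the *statistical signatures* the detectors key on (coverage
dropout, penetrant sex-linkage, diversity loss with LD block structure,
clock-like divergence, recombination plateaus) with clean Poisson/binomial
noise. It does not emulate mapping artefacts, repeat-driven coverage
variance, admixture, linked selection outside sweeps, or coalescent
genealogical noise; recovery on these fixtures validates the algorithms,
not their behaviour on any particular real dataset.

## Problem sizes

The shipped studies use one 55-Mb + two 20-Mb chromosomes at 10-kb coverage
windows (~9500 windows), sex panels of ~25 000 sites, population panels of
~95 000 sites x 100 samples on 2 Mb, and 200 gene pairs x ~1000 codons per
stratum; the boundary-recovery, sweep-recovery and null-control studies
each use 20 seeds. These sizes were chosen so that a full run of the test
suite is a desk-scale job while each study still has the resolution its
tolerance requires (e.g. one 10-kb window on a 12.7-Mb SDR).

## Known limitations

* Omega uses genotype (dosage) correlation, not haplotype LD, and a
  bounded number of SNPs per side; it is a ranking statistic here, not a
  likelihood.
* `Ksil` without noncoding sites equals `Ks`; true silent-site clocks that
  include introns/UTRs would differ.
* Tajima's D uses the median observed allele count per window for its
  constants; under heavy, uneven missingness a per-site-exact treatment
  would differ slightly.
* The SDR caller assumes the span boundaries are anchored by strong
  coverage divergence; an SDR whose outermost segment is only mildly
  male-elevated would have its edge trimmed to the outermost strong window.
* The anchor-count and annotated-gene-count views of SDR gene content are
  not reconciled; the package reports anchor counts.
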