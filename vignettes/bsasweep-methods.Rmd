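---
title: "Mapping dominant traits with bulked segregants and sweep scans: methods and design"
author: "bsasweep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping dominant traits with bulked segregants and sweep scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsasweep)
```

## The problem this package addresses

A dominant trait — for instance a larval behaviour retained in a wild
silkworm and lost in a domestic strain — segregates 1:1 in a first backcross
(BC1) between the F1 carrier and the homozygous recessive recurrent parent.
Pooling extreme-phenotype individuals into two bulks and sequencing the pools
turns linkage into an allele-frequency signal: near the causal locus the
trait-positive bulk is enriched for the donor (wild) allele, the
trait-negative bulk is depleted of it.  `bsasweep` implements the complete
desk-side analysis of such an experiment — marker selection from a VCF,
per-site and windowed SNP/InDel indexes, a permutation confidence band,
candidate-region calling — together with the population-genomic follow-up
used to shortlist domestication candidates inside a mapped interval: windowed
F~ST~ and nucleotide diversity over a domestic and a wild panel,
allele-frequency tracks, and codon-level effect annotation.  A third arm
provides the expression-table utilities used to compare candidate-gene
expression between strains.

Everything is exercised end to end on seeded simulators that reproduce the
statistical structure of the design, with ground truth retained for
parameter-recovery tests.

## The index statistics

For a biallelic marker with `ref` reads supporting the recurrent parent's
genotype and `nonref` reads supporting the donor genotype, the SNP/InDel
index is

$$\mathrm{index} = \frac{\mathrm{nonref}}{\mathrm{ref} + \mathrm{nonref}},$$

so 0 means every read matches the recurrent parent and 1 means every read is
the alternative.  Zero-depth sites are *missing*, never 0 — an index of 0 is
a biological statement, not a coverage artefact.  Markers are sites where the
two parents are homozygous for different alleles, each parent is covered by
at least 7 reads, and the site is neither low-covered in **every** bulk
(depth < 7 in all of them; a single low bulk is tolerated) nor missing (zero
depth) in any bulk.  The both-bulks-low rule is deliberate: requiring only
one adequately covered bulk keeps markers that still carry one-sided
information, and is the literal reading of the filtering rule this design
follows.  After filtering, counts are re-oriented so "reference" always means
the recurrent parent's allele, even where the genome assembly happens to
carry the donor allele.

Profiles are computed in sliding windows of 1 Mb every 10 kb (defaults;
half-open intervals anchored at position 1, trailing partial windows kept and
truncated at the chromosome end).  A window's value is the unweighted mean of
the per-marker indexes inside it; empty windows are missing and are never
imputed or called.  The Δ index is the windowed index of the trait-positive
bulk minus that of the trait-negative bulk, so linkage to a dominant causal
locus pushes Δ towards its ideal BC1 value of 0.5: the positive bulk is
entirely heterozygous there (index 0.5) and the negative bulk entirely
homozygous (index 0).

## The permutation confidence band

What exactly is "permuted" in a pooled design is underdetermined — reads
carry no individual labels, so label permutation between two pools is not
defined.  We therefore implement the band the way QTL-seq-style analyses
construct their confidence intervals: a parametric no-linkage null.  At each
of `nPerm = 1000` replicates, each bulk's non-reference count at each marker
is redrawn as Binomial(observed depth, 0.25) — 0.25 because a random BC1 bulk
is half heterozygous (pool frequency 0.5) and half homozygous-reference — the
windowed Δ is recomputed, and the band is the per-window 2.5% and 97.5%
empirical quantile at the default 95% level.  The band is per-window, so it
widens where marker count or depth drops; `nullFreq` is configurable for
other designs.

Two properties of this construction matter in practice:

* **Calibration is with respect to its own null family.**  Independent
  redraws from the same count-resampling null (see `nullCounts()`) exceed
  the 95% band at the nominal ≈5% rate.
* **A real null cross is more variable than the count null.**  In a true
  no-linkage cross the bulks are particular sets of 20 individuals; the
  sampling noise of bulk composition is shared by every marker a haplotype
  block spans, so window averaging removes read noise but not composition
  noise, and windowed Δ exceeds the count-resampling band far more often
  than 5%.  This is a known property of depth-based bands in pooled designs,
  it is why mapping peaks are judged against the band rather than every
  local wiggle, and it is why the default region-calling mode is `"peak"`
  (top-quantile windows, default top 0.5%, ties broken leftmost) rather than
  `"strict"` band exceedance.  `"strict"` mode remains available, two-sided
  by default to match a 95% confidence *interval*, with one-sided options.

Candidate regions from two independent bulk pairs (e.g. two body-colour
sets) can be intersected with `intersectRegions()` to narrow a shared
interval.

## Sweep screening

Inside a mapped interval, domestication candidates are screened with three
statistics over two haploid panels ("domestic", large; "wild", small):

* **Windowed F~ST~** — Hudson-type ratio of averages:
  per site $N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
  \frac{p_2(1-p_2)}{n_2-1}$ and $D = p_1(1-p_2) + p_2(1-p_1)$, with a window
  estimate $\sum N / \sum D$.  Hudson's estimator is the default because the
  panel sizes are extremely unbalanced (hundreds of domestic strains versus
  a handful of wild ones) and its within-population variance correction is
  robust to that; a Weir–Cockerham variance-components estimator is
  available as an option.  Negative window values are clamped to 0 for
  reporting; the raw values are retained.
* **Windowed π** — per window, unbiased per-site heterozygosity
  $2\hat p(1-\hat p)\,n/(n-1)$ summed over sites and divided by the window
  length in bp.  The denominator is the window span, not the number of
  callable sites; this is stated in the output metadata because the
  alternative convention changes the scale.
* **Allele frequency** — the fraction of calls (or reads, in count mode)
  supporting the reference genotype, per site and population.

Sweep windows are flagged when their F~ST~ lies in the top 5% quantile
(computed over the windows analysed, i.e. the chromosomes carrying candidate
regions, not a genome-wide panel) *and* domestic π is below wild π.  Both
conditions together are the sweep signature; high F~ST~ with preserved
domestic diversity is not flagged.  Genes whose span intersects a flagged
window are reported as candidates.  The sweep scan uses 10 kb windows every
5 kb by default — finer than the mapping scan because sweep signals are
sub-gene-scale — and both geometries are configurable.  Sites with fewer
than two non-missing calls in a population are skipped.

## Effect annotation

Gene models are parsed from GFF3 (gene/mRNA/exon/CDS) with the genome FASTA;
models whose total CDS length is not a multiple of 3 are flagged and
excluded from coding calls.  A CDS SNP is classified by mutating its codon
and translating: synonymous, non-synonymous, stop-gain or stop-loss, with
protein notation like `G115D` (1-based residue from the initiator
methionine).  Indels are frameshift or in-frame by length modulo 3.
Minus-strand genes are handled by complementing the alternate allele and
working in transcript coordinates; the test suite checks the single-codon
fast path against a full-protein-diff oracle on randomly generated
multi-exon genes of both strands.  Variants in multiple models get one call
per model (the intended gene sets are single-isoform).  `divergentNonsynonymous()`
shortlists non-synonymous calls whose domestic/wild frequency gap is at
least 0.8 — the filter that surfaces near-fixed coding substitutions.

## Expression utilities

Heatmap normalisation is the row Z-score with the sample standard deviation;
constant rows become zeros and are flagged.  The strain comparison scales
FPKM by (mean library depth / sample library depth) and applies a classical
equal-variance two-sided Student's t-test per gene and stage, with no
multiple-testing correction — matching the analysis convention this workflow
reproduces ("Student's t-test" is read as the pooled-variance test, and the
sidedness, unstated there, is taken two-sided as the conservative default).
Degenerate inputs are explicit: under-replicated groups give missing
p-values, and constant equal groups give p = 1 with a flag.

## What the simulators emulate — and what they do not

`simulateCross()` draws one F1 meiosis per BC1 individual: a
Poisson(`recombRate`) crossover count with breakpoints uniform on the
chromosome (no interference), alternating between the two F1 haplotypes; the
recurrent parent contributes a constant gamete, so genotypes are hom-ref or
het only, and segregation is 1:1.  Only the donor-side gamete recombines,
consistent with a cross design in which the F1 is the male parent (female
Lepidoptera are achiasmatic).  Phenotypes follow the causal genotype with
configurable penetrance (default 1: fully dominant and fully penetrant);
with no causal position the phenotype is a fair coin flip, giving a clean
no-linkage null cross.  Bulks are the first-k trait-positive and first-k
trait-negative individuals so tests are reproducible.  `sampleBulkCounts()`
emulates pooled sequencing: the pool's donor-allele frequency is
(het members × 0.5)/bulk size, total depth is Poisson (minimum 1) and the
non-reference count binomial; parents are sequenced at frequency exactly 0
and 1.  There is no base-error model: the statistics operate on
post-filtering counts, and adding a small symmetric error rate would only
widen the band.

Defaults encode the emulated study conditions: ~200 BC1 individuals, bulks
of 20, pooled depth ~30×, parents ~21×, ~2,000 informative markers on a
20 Mb chromosome with the causal locus at 4 Mb.  The genetic map length
behind the design is not knowable from the published description; the
default `recombRate` of 2 Morgans per chromosome is a declared free
parameter, not a species estimate.

`simulatePanel()` draws, outside the sweep, one shared per-site frequency
per site from a symmetric Beta with shape $a = h/(1-2h)$, which makes the
expected heterozygosity equal the configured baseline (0.3 by default, a
typical per-SNP value for a variant panel).  Inside the sweep the wild
population keeps its baseline draw while the domestic population sits at a
near-fixation frequency $\varepsilon$ with
$2\varepsilon(1-\varepsilon) = {}$`sweepDiversityPop1`, fixed for the allele
that is minor in the wild population — jointly producing elevated F~ST~,
depressed domestic π and near-fixed domestic alleles, with a frequency shift
of at least `divergenceBoost`.  Defaults: 137 + 7 haploid samples, 25,000
sites on 5 Mb, sweep at 3.7–4.0 Mb, domestic sweep heterozygosity 0.02,
shift 0.5.  Deliberately *not* modelled: linkage disequilibrium and
coalescent genealogy within the panel, demography, multi-chromosome maps,
and any indel realism beyond treating indels as biallelic markers.  Passing
recovery tests on these panels therefore shows the estimators and the
flagging logic are correct, not that the pipeline is robust to LD structure
or complex demography in real panels.

Each simulator consumes a single master seed; `simulateCross()` seeds the
generator with it directly, `sampleBulkCounts()` with seed + 1 (so counts
are reproducible regardless of call order), and draws occur in a fixed,
documented order.  Identical configurations yield byte-identical fixture
files.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive in all I/O; windows are half-open
  `[start, start + W)` internally and reported with their half-open end.
* Empty windows are `NA` everywhere, excluded from quantiles, exceedance
  and region calls.
* F~ST~ windows with a zero denominator are missing; negative values clamp
  to 0 in the reported profile only.
* Region merging uses a gap threshold of one window width in the mapping
  scan (adjacent overlapping windows merge naturally).
* Quantiles (band bounds, top-5% F~ST~ cutoff, peak threshold) use R's
  default continuous quantile; ties in peak mode break leftmost.
* Multiallelic VCF records are skipped by default (the index is a
  two-allele statistic); parent genotypes come from GT calls, not from
  count heuristics.

## Problem sizes used by the test suite

The shipped tests run the full recovery experiments at the default study
scale: 50 seeded crosses (200 × 2,000 genotype matrices) for causal-locus
recovery, 50 seeded panels (144 × 25,000) for sweep localisation, a
1,000-replicate band with 30 independent null datasets for calibration, 200
replicate crosses for the Δ expectation, and 500 random variants for the
annotation oracle.  These sizes were chosen so the whole suite completes in
a couple of minutes while keeping Monte-Carlo error well inside each
tolerance.

## Known limitations

* The permutation band underestimates the variance of a *real* null cross
  (bulk-composition noise), as discussed above; strict-mode calls should be
  read accordingly.
* The panel simulator draws sites independently; window statistics on real
  panels are smoother than on simulated ones at equal density.
* Effect annotation does not predict splice-site disruption, does not rank
  multi-transcript consequences, and reproduces effect *classes*, not any
  specific annotation tool's vocabulary.
* FPKM quantification, read alignment and variant calling are upstream of
  this package: it consumes VCF, GFF3/FASTA and FPKM tables.

## A minimal session

```{r example, eval = FALSE}
cfg <- CrossConfig(seed = 7L)
truth <- simulateCross(cfg)
markers <- selectMarkers(sampleBulkCounts(truth),
                         parents = c("P_P50", "P_Wild"))
delta <- deltaProfile(windowProfile(markers, "B_pos"),
                      windowProfile(markers, "B_neg"))
band <- permutationBand(markers, "B_pos", "B_neg", seed = 1L)
candidateRegions(delta, band, mode = "peak")

panel <- simulatePanel(PanelConfig(seed = 3L))
scan <- sweepCandidates(fstWindow(panel),
                        piWindow(panel, "pop1"), piWindow(panel, "pop2"))
sweepRegions(scan)
```
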