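---
title: "Detecting introgression with windowed ABBA-BABA scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting introgression with windowed ABBA-BABA scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abbascan)
```

## The problem

When three ingroup taxa and an outgroup are compared at polarized biallelic
sites, the species tree (((P1,P2),P3),O) predicts that the two discordant
site patterns — ABBA (derived allele shared by P2 and P3) and BABA (shared
by P1 and P3) — occur at equal frequency if discordance is caused only by
incomplete lineage sorting (ILS). Gene flow between P2 and P3 breaks that
symmetry. `abbascan` turns this into a genome scan: it computes Patterson's
D in windows, confirms candidate windows with the f_d admixture-fraction
statistic, and finally requires candidate windows to be *less diverged*
between the exchanging pair than the scaffold background (d_xy), which is
the signature separating recent introgression from retained ancestral
variation.

## The statistics

At site $i$ with derived-allele frequencies $\hat p_{i1},\dots,\hat p_{i4}$
for (P1, P2, P3, O):

$$C_{ABBA}(i) = (1-\hat p_{i1})\,\hat p_{i2}\,\hat p_{i3}\,(1-\hat p_{i4}),
\qquad
C_{BABA}(i) = \hat p_{i1}\,(1-\hat p_{i2})\,\hat p_{i3}\,(1-\hat p_{i4}),$$

$$D = \frac{\sum_i C_{ABBA}(i) - \sum_i C_{BABA}(i)}
           {\sum_i C_{ABBA}(i) + \sum_i C_{BABA}(i)}.$$

For haploid single-genome assemblies every frequency is 0 or 1 and the
weights reduce to counts of the two patterns. D = 0 is expected under the
null of no introgression; significance per window is assessed with a
delete-one block jackknife over contiguous site blocks (default 20 per
window, configurable) and a two-sided z-test. The jackknife estimator is a
design choice of this package: the procedure it implements only states
that a z-test was used, and the block jackknife is the field-standard
estimator for D's standard error under linkage.

The confirmation statistic substitutes, at each site, the higher of
$\hat p_{i2}, \hat p_{i3}$ (the per-site donor frequency $P_D$) for *both*
P2 and P3 in the numerator sum $S$:

$$f_d = \frac{S(P_1, P_2, P_3, O)}{S(P_1, P_D, P_D, O)},$$

i.e. the observed ABBA–BABA excess relative to the excess under complete
introgression. It is reported as undefined for windows whose excess is
non-positive — the statistic is meaningful only in the D > 0 direction —
and such windows can never pass the f_d filter.

Absolute divergence between taxa x and y over a region with $n$ comparable
positions:

$$d_{xy} = \frac{1}{n}\sum_{i=1}^{n}
  \left[\hat p_{ix}(1-\hat p_{iy}) + \hat p_{iy}(1-\hat p_{ix})\right].$$

ILS does not reduce d_xy between P2 and P3 (discordant genealogies coalesce
*deeper*, not shallower), whereas a recently transferred tract is nearly
identical between donor and recipient. Requiring candidate windows to be
significantly below the scaffold's d_xy background therefore removes
ILS-driven false positives.

## The filter cascade

`introgression_scan()` tiles each scaffold into windows (0-based half-open;
default adjacent 5-kb windows, with 50 kb, 100 kb and 500 kb as the other
preset scales and a configurable step for sliding scans) and applies:

1. **D significance** — retain windows with jackknife z-test p < 1e-3,
   |D| > 0.59 and |ABBA − BABA| > 10. The |D| and gap components guard
   against windows whose nominal significance rests on few informative
   sites; the gap is evaluated on the frequency-weighted sums, which equal
   pattern counts for haploid inputs. The |D| > 0.59 component is exposed
   as an explicit criterion (and can be disabled) because it functions as
   an independent threshold in the compound rule.
2. **f_d top decile** — compute the 90th percentile of f_d over *all*
   windows with defined f_d genome-wide (linear-interpolation quantile,
   R type 7) and retain candidates at or above it. The reference set is
   genome-wide rather than candidates-only so that the cutoff measures
   heterogeneity in genetic variation, not the candidates' own
   distribution.
3. **d_xy reduction** — per scaffold, the background is the mean window
   d_xy and its standard error over windows (SEM); candidates pass with a
   one-sided lower-tail z-test at p < 0.01. Candidates are included in the
   background by default (the background is meant to be the whole
   scaffold); exclusion is available behind a flag. Partial terminal
   windows are retained and flagged in all outputs but excluded from the
   background estimate, where their shorter length would inflate the
   variance.

The three stages are nested by construction. No multiple-testing
correction is applied across windows by default, matching the raw
per-window thresholds of the procedure; a Benjamini–Hochberg option exists
on the stage-1 p-values.

```{r example}
sim <- simulate_quartet(sim_config(seed = 1))
scan <- introgression_scan(sim$sites, window_size = 5000)
scan
head(scan$regions[, c("start", "end", "abba", "baba", "d", "fd", "dxy")])
```

```{r plot, fig.width = 7, fig.height = 3.5}
plot(scan)
```

## Inputs, polarization and coordinates

Three readers produce the same `quartet_sites` container: VCF
(`read_quartet_vcf()`, haploid allele identity or diploid dosage/2),
four-record aligned FASTA (`read_aligned_fasta()`), and a simple tabular
SNP dialect (`read_snp_table()`). All follow one polarization contract:
the outgroup allele is ancestral, so the outgroup's derived frequency is 0
at every retained site; sites where the outgroup is polymorphic or carries
a third allele are dropped and counted (a permissive mode with fractional
outgroup frequency exists behind a flag). Multiallelic and missing-data
sites are dropped, never imputed, with per-reason counters carried on the
object. Internally positions are 1-based (VCF convention); window
arithmetic and all BED output are 0-based half-open. Alignment columns are
anchored to the ungapped outgroup coordinate so that windows from any
input share one reference frame.

The d_xy divisor $n$ is the number of callable aligned positions per
window when the input is an alignment (the FASTA reader records them);
with VCF or tabular input invariant-site counts are unavailable, so $n$
falls back to window length in bp, monomorphic positions contributing 0.
The mode is recorded on the scan object and is always the same for windows
and background, so stage 3 compares like with like.

## What the simulator emulates — and what it does not

`simulate_quartet()` generates four haploid genomes on the species tree
(((P1,P2),P3),O) under JC69, with split depths 0.01 / 0.05 / 0.10
substitutions/site by default — pairwise divergences of roughly 2%, 10%
and 20%, the scale of congeneric fungal genomes with a family-level
outgroup. ILS is emulated by topology resampling: each block (default 1 bp,
i.e. an independent draw per site) is discordant with probability 0.2,
the two discordant topologies being equiprobable, so ABBA and BABA are
exactly equally frequent in expectation outside tracts. Introgression is
modelled as tract replacement: the recipient's sequence inside a planted
tract is re-derived from the donor's with a residual divergence of 0.01,
about a tenth of the ~0.1 background d_xy(P2,P3) — simultaneously creating
the ABBA excess and the d_xy reduction that the cascade requires. The
default layout plants ten 5-kb tracts at 100-kb intervals, aligned to the
5-kb window grid so that benchmark recall and precision are unambiguous at
the scan's native resolution. These defaults give ~50 informative
(ABBA + BABA) sites per null 5-kb window, enough that the compound
stage-1 rule behaves as a null filter rather than a small-count artifact.

Two deliberate simplifications matter for interpreting test results.
First, the per-site topology draw makes discordant sites independent; real
ILS tracts are linked over kilobase scales, which inflates window-level D
variance and *breaks the per-window z-test's calibration* once the
discordance correlation length approaches the jackknife block span
(window size / block count). `ils_block_length` is configurable precisely
so this regime can be studied; with long blocks, window-scale topology
clustering mimics introgression and stage-1 retention rises far above the
nominal level, as it will in real genomes with coarse recombination.
Second, discordant genealogies reuse the species-tree depths rather than
coalescing deeper, so simulated ILS slightly *reduces* P2–P3 divergence at
discordant sites instead of leaving it untouched; with per-site draws this
effect is spread uniformly and does not create window-scale d_xy dips, but
it means the simulation under-represents the d_xy contrast a coalescent
would give. Passing tests therefore demonstrate the statistics and the
cascade logic, not performance on genomes with realistic linkage,
recombination-rate variation, indels or repeat content.

`expected_pattern_rates()` provides the simulator's independent oracle: it
computes the *exact* JC69 probabilities of the ABBA and BABA site patterns
for each regime's genealogy by enumerating internal-node states, rather
than a first-order approximation — in the concordant regime the patterns
arise only from parallel double hits, a second-order effect a first-order
form would report as zero, leaving nothing to compare observed counts
against.

## Numerical and degenerate-case choices

* D is undefined (NA) when a window has no informative weight; undefined
  windows never pass any filter.
* Jackknife with fewer than two informative blocks: SE, z and p are NA
  with a degeneracy flag. SE = 0 with D = 0 gives p = 1; SE = 0 with
  D ≠ 0 (e.g. an all-ABBA tract window, where every replicate equals 1)
  is reported as p = 0 with the degeneracy flag set, so such windows pass
  stage 1 but remain identifiable.
* f_d: undefined for non-positive numerator or denominator; stage-2 ties
  at the percentile cutoff are kept (≥).
* d_xy z-test: scaffolds whose background rests on fewer than two full
  windows, or has zero spread, are flagged unusable and their candidates
  are dropped with an explicit counter — never silently passed.
* All outputs are byte-deterministic given identical inputs and
  configuration; the simulator requires an explicit seed and restores the
  caller's RNG state.

## Problem sizes used in the test suite

The packaged checks run the generator at 1 Mb (reference and null
calibration, 20 replicate seeds), 2×10^5 bp (pattern-rate validation, 20
seeds) and smaller fixtures for I/O round-trips — sizes chosen so the
whole suite exercises every stage, including 4,000 null windows for the
stage-1 false-positive rate, while remaining a desk-scale computation.
The scan itself is linear in sites and windows; genome-scale inputs are
limited by reading, not by the statistics.

## Known limitations

* The tabular writer encodes haploid (0/1) tables only; fractional
  frequencies round-trip through VCF instead.
* Scaffold lengths are taken from VCF `##contig` headers when present and
  otherwise fall back to the last observed variant position, which
  truncates trailing windows.
* The clade-level summary deliberately reports only stage-1 D
  significance at the 500-kb scale; f_d and d_xy are per-locus
  refinements and are not aggregated across quartets.
* Functional annotation of introgressed genes (domain/GO databases) is
  out of scope; the gene report carries the GFF attribute text so
  external annotations can be joined.
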