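# abbascan

Windowed ABBA-BABA introgression scans for four-taxon genome comparisons.

`abbascan` is for population and comparative genomicists who have four
aligned genomes — a sister pair P1 and P2, a candidate gene-flow partner
P3, and an outgroup O — and want to locate genomic regions exchanged
between non-sister taxa while excluding incomplete lineage sorting (ILS).
It was designed with haploid single-genome assemblies in mind (e.g. fungal
genome comparisons), but accepts allele frequencies from diploid VCFs too.

## The method

At each polarized biallelic site $i$ the two discordant patterns are
weighted by derived-allele frequencies $\hat p_{i1},\dots,\hat p_{i4}$
(outgroup last):

$$C_{ABBA}(i)=(1-\hat p_{i1})\hat p_{i2}\hat p_{i3}(1-\hat p_{i4}),\quad
C_{BABA}(i)=\hat p_{i1}(1-\hat p_{i2})\hat p_{i3}(1-\hat p_{i4})$$

and windows are screened by a three-stage cascade:

1. **Patterson's D** $= (\sum C_{ABBA}-\sum C_{BABA})/(\sum C_{ABBA}+\sum
   C_{BABA})$ with a delete-one block-jackknife z-test; retain windows
   with p < 10⁻³, |D| > 0.59 and |ABBA − BABA| > 10.
2. **f_d** $= S(P_1,P_2,P_3,O)/S(P_1,P_D,P_D,O)$, the observed
   ABBA−BABA excess relative to complete introgression ($P_D$ = the
   per-site larger of $\hat p_2,\hat p_3$); retain only the genome-wide
   top decile.
3. **d_xy** $= \frac1n\sum_i[\hat p_{ix}(1-\hat p_{iy})+\hat
   p_{iy}(1-\hat p_{ix})]$ between the exchanging pair; retain windows
   significantly *below* the scaffold background (one-sided z-test,
   p < 0.01). Recent introgression reduces donor–recipient divergence;
   ILS does not.

Surviving windows are reported as introgressed regions (TSV/BED) and can
be annotated against GFF3 gene models. A deterministic four-taxon genome
simulator with planted donor→recipient tracts provides ground truth for
every stage. See the methods vignette
(`vignettes/introgression-scan.Rmd`) for assumptions, parameter defaults
and numerical edge cases.

## Worked example

Simulate a 1-Mb four-taxon genome with ten planted 5-kb introgression
tracts, scan it, and annotate the hits:

```r
library(abbascan)

sim  <- simulate_quartet(sim_config(seed = 1))
scan <- introgression_scan(sim$sites, window_size = 5000)
scan
#> Introgression scan: 200 windows of 5,000 bp (step 5,000) on 1 scaffold(s)
#>   filter cascade: 200 windows -> 10 (D z-test) -> 10 (f_d top 10%) -> 10 (d_xy reduced)
#>   genome-wide D (pooled windows): 0.2055
#>   d_xy pair (p2, p3), divisor mode: bp

head(scan$regions[, c("start", "end", "abba", "baba", "d", "fd", "dxy")], 3)
#>    start    end abba baba         d        fd    dxy
#> 1  50000  55000  198    2 0.9800000 0.7935223 0.0102
#> 2 150000 155000  188    1 0.9894180 0.7890295 0.0100
#> 3 250000 255000  205    1 0.9902913 0.8095238 0.0096
```

The cascade narrows 200 windows to exactly the 10 planted tracts: each
carries a near-saturated ABBA excess (D ≈ 0.98, ~200 ABBA vs ~2 BABA
sites), a top-decile admixture fraction (f_d ≈ 0.8), and d_xy an order of
magnitude below the ~0.09 scaffold background — the joint signature of a
recent transfer. Annotating against gene models overlapping the regions:

```r
genes  <- simulate_gene_models(sim$config)
report <- genes_in_regions(genes, scan)
length(unique(report$gene_id))
#> [1] 20
```

Real inputs enter through `read_quartet_vcf()`, `read_aligned_fasta()` or
`read_snp_table()` with a `quartet_config()` mapping taxa to samples;
`run_scan()`/`run_annotate()`/`run_summarize()` write TSV/BED outputs and
JSON run manifests, and `inst/cli/abbascan` exposes the same steps as
shell subcommands (`simulate`, `scan`, `annotate`, `summarize`).

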