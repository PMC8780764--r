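# tuarchitect

Genome-wide transcript-boundary inference for bacteria from end-sequencing
profiles: call transcription start sites (TSS) from differential RNA-Seq
(dRNA-Seq) TAP(+)/TAP(−) 5'-end tracks, call transcript 3'-end positions
(TEP) from two Term-Seq replicates with a leave-one-out modified z-score,
classify both against the gene annotation, assemble transcription units
(TUs) and TU clusters, and annotate the cis-regulatory elements around the
boundaries (promoter −10/−35 elements and spacers, U-rich terminator
windows, SARP-type heptameric repeats). A seeded synthetic-data generator
emulates a GC-rich actinobacterial genome with planted boundaries so every
stage is validated by parameter recovery.

The package is aimed at microbial transcriptomics groups working with
dRNA-Seq/Term-Seq data — particularly from GC-rich organisms such as
*Streptomyces*, where terminator U-tracts are weak and promoter scanning
must cope with a 70% GC background.

## The method in brief

**TSS calling.** Nonzero TAP(+) 5'-end positions are clustered (gap
< 100 nt), sub-clustered under a positional standard-deviation bound
(σ < 10 nt), filtered (sub-cluster read sum > 3), and each surviving
sub-cluster emits its maximum-count position; positions with more TAP(−)
than TAP(+) reads are discarded as processed 5' ends. TSSs are primary (P)
or secondary (S) within [−500, +100] nt of a start codon, else internal
(I), antisense (A) or intergenic (N); primary TSSs with 5'-UTR < 9 nt are
leaderless.

**TEP calling.** Intergenic Term-Seq 3'-end positions (10 nt invasion into
the downstream gene allowed) are clustered (gap < 10 nt) and scored with a
modified z-score computed leave-one-out over the cluster:

    μ = mean(others)          σ = sqrt(mean(others²) − μ²)
    Z(x) = (r(x) − μ) / σ

Positions with r(x) < 3 or Z < 3 are dropped per replicate; for each pair
of overlapping replicate cluster spans, the surviving position with the
highest replicate-summed count inside the span intersection becomes the
TEP. TEPs are cis-regulatory (C, inside a gene's leader, ≥ 80 nt from its
primary TSS), primary/secondary (< 500 nt downstream of a stop codon),
antisense or intergenic.

**TU assembly.** Each P/S/I TSS pairs with P/S TEPs along its downstream
gene chain, where consecutive intergenic gaps may not exceed 500 bp; A/N
TSSs scan 1 kbp downstream; C TEPs pair only with their own gene's TSSs.
TUs are mono-cistronic, poly-cistronic, cis-regulatory or sRNA, and TU
clusters are the connected components of the TU–gene sharing graph.

See `vignettes/transcript-boundaries.Rmd` for the full model description,
parameter table and design rationale.

## Worked example

```r
library(tuarchitect)

params <- simParams(seed = 42)       # 100 kb, 70% GC, 60 genes
sim <- simulateDataset(params)
sim$genome
#> Genome 'sim_genome': 100000 nt, GC 69.7%

res <- runBoundaryPipeline(sim$profiles, sim$genes, sim$genome)
table(res$tss$category)
#>  P
#> 33
table(res$tus$category)
#> mono_cistronic poly_cistronic
#>             19             14
head(res$tus, 3)
#>    tu_id tss_position tep_position strand       gene_ids n_genes       category
#> 1 TU0001         1803          501      -           g001       1 mono_cistronic
#> 2 TU0002         5537         2410      - g002,g003,g004       3 poly_cistronic
#> 3 TU0003         7790         6365      -           g005       1 mono_cistronic
```

All 33 planted TSSs are recovered as primary TSSs of their genes, and the
14 planted operons come back as poly-cistronic TUs with their exact gene
lists (TU0002 spans the three-gene operon g002–g004 on the minus strand;
its TEP at 2410 lies 3' of the last gene, which on this strand is the
lower coordinate). Downstream summaries of the same run:

```r
utrStatistics(res$tss, res$tep)$leaderless
#> $count
#> [1] 8
#> $fraction
#> [1] 0.2424242   # generator plants leaderless 5'-UTRs at rate 0.2

prom <- annotatePromoters(res$tss[res$tss$category == "P", ], sim$genome)
summary(prom$spacer_length)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   11.00   18.00   22.00   21.03   24.00   28.00
```

On this random 70%-GC background the −10/−35 scanner reports spacers over
its full admissible range; on real promoters the distribution concentrates
at the biological 12/19-nt modes.

File-based workflows use `readGenome()` (FASTA), `readAnnotation()` (GFF3),
`readEndProfile()` (strand-pair of bedGraphs) and
`writeFeatureTable()`/`readFeatureTable()` (TSV + BED6 companions); a thin
command-line front end over the same functions ships in
`inst/cli/tuarchitect.R`.

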