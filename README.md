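# repeatloop

Repetitive-element enrichment analysis for R-loop peak sets.

R-loops — DNA:RNA hybrids with a displaced single strand, mapped genome-wide
by DRIP-seq as peak intervals — form preferentially near genes and promoters,
and several classes of repetitive elements (satellites, LINEs, simple and
low-complexity repeats, …) have been implicated in their formation.
`repeatloop` is for analysts who have peak calls in hand and want to ask, at
base-pair resolution, *which RepeatMasker repeat classes and families are
over- or under-represented in my R-loop regions, and against what null?*

For each repeat unit *k* (a class or family) the package computes the base
percentage

```
x_k = 100 · bases(peaks ∩ repeats_k) / bases(peaks)
```

and scores it against three control backgrounds:

| control  | null hypothesis                         | statistic                      |
|----------|------------------------------------------|--------------------------------|
| genome   | peaks fall uniformly in the assembly     | `log10(x_k / y_k)`             |
| GRO      | peaks fall where transcription happens   | `log10(x_k / y_k)`             |
| sampling | peaks keep their lengths and location categories, otherwise random | Z-score of `p_k` in 1000 matched draws `{q_k,j}` |

The sampling control redraws the peak set 1000 times, preserving exactly the
peak count, the multiset of peak lengths, and each peak's genomic-location
category under the priority partition
`promoter2k > terminator2k > exon > intron > intergenic` (2000-nt strand-aware
flanks). Degenerate cases are reported as explicit NA flags
(`absent_in_peaks`, `absent_in_control`, `zero_variance`) rather than dropped.

The package also provides the surrounding pipeline: BED / chrom.sizes / UCSC
rmsk / RepeatMasker `.out` / GTF / GFF3 readers, interval algebra (merge,
base-level intersect/subtract, whole-peak filtering of RNaseH-sensitive
peaks), genome partitioning with per-peak category assignment, base-level
Venn summaries of R-loops × transcribed regions × genes, and a synthetic-data
generator with planted, recorded ground truth so that every stage is testable
without external downloads.

## Worked example

Simulate a 1-Mb study with a 3× satellite enrichment planted in the peaks,
then run the full analysis:

```r
library(repeatloop)

# 1. simulate a study with a 3x satellite enrichment planted in the peaks
sim <- pipeline_simulate(list(seed = 7, multipliers = list(Satellite = 3)),
                         out_dir = "rl_demo")

# 2. run the full analysis against all three controls
res <- pipeline_run(list(rloop_bed   = "rl_demo/rloops.bed",
                         gro_beds    = "rl_demo/gro.bed",
                         genes       = "rl_demo/genes.gtf",
                         repeats     = "rl_demo/repeats.tsv",
                         chrom_sizes = "rl_demo/chrom.sizes",
                         n_samples   = 500, seed = 7, level = "class"),
                    out_dir = "rl_out")

# 3. inspect the sampling-control Z-scores
mat <- res$matrices$class
subset(mat, control == "sampling" & unit %in% c("Satellite", "LINE", "RC"))
```

which logs each stage and prints:

```
[repeatloop] genome: 2 chromosomes, 1000000 bases
[repeatloop] R-loop peaks in: 500 (270158 bases)
[repeatloop] GRO transcribed regions: 1 sample(s) merged to 67 intervals (361099 bases)
[repeatloop] annotations: 100 genes, 1560 repeat elements
[repeatloop] partition built (flank 2000)
[repeatloop] sampling control: 500 groups, seed 7
[repeatloop] enrichment_class.tsv: 33 rows
[repeatloop] R-loop bases in transcribed regions: 36.2%

   level      unit  control observed_pct          control_summary statistic na_flag
13 class      LINE sampling    13.670889  mean=14.9883;sd=1.26088 -1.044875    none
16 class        RC sampling     1.692343 mean=1.37553;sd=0.299856  1.056559    none
19 class Satellite sampling     9.953065 mean=5.47012;sd=0.698851  6.414737    none
```

The planted class stands out (satellites cover 9.95% of peak bases against a
matched-null mean of 5.47%, Z = +6.4) while unplanted classes stay within the
null band. `rl_out/` contains the TSV reports: `enrichment_class.tsv` (one row
per unit per control), `genomic_distribution.tsv` (fraction of peaks per
region category), `venn.tsv` (the seven exclusive base counts and the
percentage of R-loop bases inside transcribed regions) and
`size_summary.tsv` (peak length summary).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/repeatloop.R`
(`Rscript repeatloop.R run --config run.yaml --out outdir [--seed N]`).

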