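---
title: "Repetitive-element enrichment in R-loop peak sets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repetitive-element enrichment in R-loop peak sets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the data

R-loops — three-stranded structures in which a nascent RNA hybridises back to
its DNA template and displaces the non-template strand — are mapped genome-wide
by DRIP-seq as sets of peak intervals. A natural question is whether particular
classes of repetitive elements (LINEs, SINEs, LTR retrotransposons, satellites,
simple repeats, and so on, in RepeatMasker's two-level class/family taxonomy)
are over- or under-represented inside those peaks, and against what background
that question should be asked.

`repeatloop` takes this analysis from the point where peak calling ends. Its
inputs are interval data only: R-loop peaks and transcribed-region peaks as
BED, repeat annotations as a UCSC rmsk-style table or RepeatMasker `.out`
file, gene annotations as GTF/GFF3, and chromosome sizes. No sequence is read;
the analysis is purely positional.

## The statistic

For a repeat unit $k$ (a class or a family) and a peak set $P$, the basic
observable is the base percentage

$$x_k = 100 \cdot \frac{\mathrm{bases}(P \cap R_k)}{\mathrm{bases}(P)},$$

where $R_k$ is the merged set of elements of unit $k$ and $\mathrm{bases}$
counts each genomic base once (both operands are merged first). Units are
scored independently: a base covered by elements of two different classes
counts toward both, because RepeatMasker annotations of different classes can
genuinely overlap, and merging happens only *within* a unit.

Because "enriched" depends entirely on the null hypothesis, three control
backgrounds are built, each matching a different idea of where R-loops "could
have been":

1. **Genome control** — R-loops fall uniformly anywhere. The control peak set
   is the whole assembly (minus gap intervals if a gap track is supplied).
   The statistic is the ratio on the log scale,
   $\mathrm{enrichment}_k = \log_{10}(x_k / y_k)$, with $y_k$ the unit's
   percentage in the control.
2. **GRO control** — R-loops form where transcription happens. The control is
   the merged set of GRO-seq transcribed regions itself, scored with the same
   log-ratio.
3. **Sampling control** — R-loops have their observed lengths and
   genomic-location preferences, but are otherwise random. 1000 control groups
   are drawn, each preserving the template peaks exactly in number, in the
   multiset of lengths, and in each peak's location *category* (see below).
   With $p_k$ the observed percentage and $\{q_{k,j}\}$ the 1000 control
   percentages, the statistic is the Z-score
   $(p_k - \bar q_k) / \mathrm{sd}(q_k)$.

Positive statistics mean over-representation. No multiple-testing machinery is
applied: the output is a matrix of raw enrichment scores, one row per unit per
control, with explicit NA flags instead of silently missing values
(`absent_in_peaks` when $x_k = 0$, `absent_in_control` when $y_k = 0$ — the
control flag wins when both are zero — and `zero_variance` when all sampling
draws are identical).

Two numerical choices are pinned down because they would otherwise be
ambiguous: the Z-score uses the sample standard deviation (divisor $n-1$;
at $n = 1000$ the difference from $n$ is negligible, but exact tests need one
definition), and "overlap" means sharing at least `min_overlap_bases = 1`
base, everywhere, configurable.

## The genome partition

"Location category" is defined by a priority partition of the genome into
promoter2k, terminator2k, exon, intron and intergenic. Promoter2k is the 2000
bases immediately upstream of a gene start, terminator2k the 2000 bases
downstream of the gene end — both strand-aware (a minus-strand gene's promoter
sits to its right) and clipped at chromosome ends rather than discarded.
Introns are gene bodies minus exons; intergenic is everything else. A base
claimed by several categories goes to the highest-priority one, in the order
`promoter2k > terminator2k > exon > intron > intergenic`; within a category,
overlapping claims are merged. The result provably tiles the genome: every
base is in exactly one category, and the package's tests verify this against a
brute-force per-base scan.

A peak is assigned the highest-priority category it overlaps by at least
`min_overlap_bases`. A three-category variant
(`promoter2k > gene > intergenic`) is available for coarser accounting of
transcribed-region peaks. Genes without strand are treated as `+` with a
warning, since "upstream" presupposes an orientation. Gene spans (not exons)
represent "genes" in the base-level Venn summary of R-loops, transcribed
regions and genes; overlapping gene annotations are merged there.

## The sampling control in detail

The published description of the matched control — same number of peaks, same
lengths, same genomic location — leaves "same location" operational. We define
it as assignment equality: a control interval of length $L$ matches its
template iff `assign_peak_category()` puts it in the template's category under
the same priority rule. Placement is rejection sampling:

* a chromosome is drawn with probability proportional to its length,
* a start is drawn uniformly among positions where the interval fits,
* the draw is accepted when its assigned category equals the template's and,
  optionally, it avoids assembly gaps.

Sampling is with replacement across and within groups — two control intervals
may overlap. This avoids infeasibility on small genomes and respects the fact
that nothing in the matched-null definition forbids it. A template that is
still unplaced after `max_rejection_attempts` rounds (default 1000) falls back
to a uniformly chosen segment of its category with a uniform start inside the
segment (the interval may extend past the segment); the run warns once with
the fallback count. This guarantees termination for very long peaks in rare
categories at the cost of a slight loosening of the null for those intervals;
at the package's default scales the fallback fires rarely or never.

Internally, category assignment during sampling uses the fact that the
partition tiles each chromosome contiguously: the categories overlapped by
$[s, e]$ are a consecutive run of segments found by binary search, so the hot
loop runs on plain integer vectors. The tests assert the fast path agrees
exactly with the reference GRanges implementation.

## The synthetic-data generator

Because the published numbers derive from external aligners and peak callers
on large public datasets, correctness here is established on synthetic genomes
with planted, recorded ground truth. The generator emulates the *structure* of
those datasets, not their scale:

* **Genome and genes** — by default two 500-kb chromosomes and 100
  non-overlapping genes with log-normal lengths (median 4 kb), random strand,
  and exon chains whose first and last segments are exonic.
* **Repeats** — a class→family hierarchy echoing RepeatMasker (16 families in
  11 classes, ~1500 elements), log-normal element lengths, placed uniformly by
  default or into configured partition categories.
* **R-loop peaks** — 500 peaks with log-normal lengths, median 600 nt (inside
  the 414–998 nt range that DRIP-seq studies report across species), and a
  promoter-heavy category distribution (45% promoter2k, 10% intergenic,
  consistent with the reported 5.5–15.8% intergenic fractions). Each peak's
  category is drawn from those probabilities, then the peak is placed by the
  *same operational rule the sampling control uses* — uniform in the genome,
  accepted when its assigned category matches. This makes null data and the
  sampling null exchangeable by construction, which is exactly what a
  calibration test needs.
* **Planted enrichment** — a per-unit multiplier $m_k$ thins acceptance within
  the chosen category: a candidate overlapping unit $k$ is accepted with
  relative weight $m_k$. Multipliers of 1 reproduce the null exactly; the
  annotation files are never rewritten, so the emitted dataset stays
  internally consistent.
* **Transcribed regions** — a configured fraction of genes (default 0.7) is
  marked transcribed; spans are extended downstream by a run-on flank
  (default 500 nt) and merged.

What the generator does *not* emulate: nucleotide sequence (no GC skew, no
G-quadruplexes), read-level noise, peak-caller artefacts, chromatin context,
or correlated placement of repeats and genes. Passing tests therefore
demonstrate that the statistics and controls do what they claim on interval
data with known structure — not that any particular biological conclusion
transfers to a real genome.

## Test scales and what the suite shows

The suite runs at deliberately small scales chosen so each property is checked
exactly or with comfortable statistical margins: interval algebra and the
partition are compared with per-base boolean-array oracles on ≤100-kb genomes;
sampling exactness is checked on a 50-peak template across all 1000 groups;
null calibration pools Z-scores from 50 independent 500-peak simulations with
200-draw nulls (mean Z within ±0.3, fewer than 10% beyond ±1.96); planted 3×
and 0.33× effects must reach |Z| ≥ 3 in at least 90% of 20 replicates with
ratio statistics agreeing in sign. The 200-draw nulls are a scaled-down stand-in
for the 1000-draw production setting; the Z-score is insensitive to this beyond
wider Monte-Carlo error in $\bar q$ and $\mathrm{sd}(q)$.

## Known limitations

* The matched null conditions on one categorical covariate (the five-way
  location label). Finer confounders — GC content, distance to the TSS within
  the promoter window, repeat density gradients — are not matched, by design,
  mirroring the published construction.
* Peaks whose category cannot be matched (extremely long peaks, vanishing
  categories) are placed by the fallback rule, slightly diluting the null for
  those intervals.
* Ratio statistics against the genome/GRO controls have no dispersion model;
  they are descriptive log-ratios, and the sampling-control Z is the
  inferential statistic.
* Strand is carried through I/O but ignored by all set operations; it matters
  only for promoter/terminator orientation and the GRO run-on extension.
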