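# flowintern

Quantifying whether a fluorescently labelled compound merely sticks to the
plasma membrane of a cell or is actually taken up into the cytoplasm is a
recurring problem in delivery studies of antisense oligonucleotides,
peptides and nanoparticles. Imaging flow cytometry produces a per-cell
multichannel image gallery at population scale; `flowintern` turns such
galleries into internalization statistics. It is aimed at scientists who
have per-cell image stacks (e.g. exported from an imaging flow cytometer)
plus standard tab-delimited per-sample statistics reports, and who want an
open, scriptable equivalent of the usual proprietary masking/gating/report
workflow — including a seeded synthetic-data generator so every step can be
validated without instrument data.

## What it computes

**Masks.** From the brightfield channel each cell is segmented into an
object mask; the *cytoplasm* mask shrinks it by repeated erosion until at
most a target percentage of the area remains (70% by default), and the
*membrane* ring is the tight object mask minus the cytoplasm, so the two
partition the cell exactly. An optional nucleus mask is an n-px erosion of
a mask built on a nuclear-dye channel.

**Internalization coefficient.** For compound channel intensity I and
masks C (cytoplasm) ⊆ O (object),

    IC = log10( mean_{C}(I - bg) / mean_{O}(I - bg) ),   clamped to [-6, 6]

Positive IC means the per-pixel signal concentrates inside the cell; cells
with IC > 0 are gated as internalized.

**Signal-distribution entropy.** The compound signal inside the cytoplasm
mask is quantized to 8 bits and summarised by the Shannon entropy of its
grey-level co-occurrence matrix (GLCM, four directions, 1 µm offset):

    H = -Σ_i Σ_j p(i,j) log2 p(i,j)     [bits]

High H = spatially uniform (diffuse) signal; low H = concentrated foci
(endosomal-type accumulation).

**Gating cascade.** Events pass, in order: focus (gradient-RMS), time
(discard the first 20 s of acquisition), singlets (area and aspect-ratio),
viability (viability-dye total < 1×10⁴, strict), uptake (compound total
above a negative-control-derived threshold) and internalization (IC > 0,
strict). Spillover compensation, estimated from single-stain controls as a
median-ratio matrix and applied as its inverse, can be switched in before
the viability/uptake gates.

**Statistics.** Per-timepoint reports (`File` column with
`<object>_<replicate>.daf` names) are parsed into a tidy table, then:
one-way ANOVA between objects at each timepoint (F, ω² with a
noncentral-F confidence interval), Tukey HSD with Cohen's d,
repeated-measures ANOVA within each object over time (F, generalized
eta-squared with a bootstrap CI), paired t-tests with Cohen's dz, all
pairwise families Benjamini–Hochberg corrected at p < 0.05, with an
exclusion log for units that fail the replicate-minima rules.

## Worked example

```r
library(flowintern)

cfg <- synth_config(seed = 7, internalized_fraction = 0.7)
gallery <- generate_gallery(cfg, 300)
blank <- generate_gallery(synth_config(seed = 8, total_signal = 0), 50)

result <- run_pipeline(gallery, negative_control = feature_table(blank))
print(result$tree)
#> <population_tree>
#>   all              300
#>   in_focus         285
#>   time_ok          181
#>   singlets         174
#>   viable           167
#>   uptake           167
#>   internalized     116
result$summary$Internalized_Pct
#> [1] 69.46108
result$summary$Median_Entropy
#> [1] 9.198585
```

The generator placed 70% of cells' compound signal in the cytoplasm; after
focus/time/singlet/viability/uptake gating the pipeline reports 69.5% of
uptake-positive cells as internalized (IC > 0) — the cascade recovers the
ground truth to within a point. The median cytoplasmic entropy of ~9.2
bits reflects the diffuse default signal mode; punctate galleries score
lower. `write_report()` turns `result$summary` into the tab-delimited
per-sample report consumed by the statistics side:

```r
write_report(result$summary, "t4.txt")
tab <- read_reports(c("t1.txt", "t4.txt"), times = c("1h", "4h"))
res <- run_stats(tab)
export_results(res, "results/")        # four CSV sections + raw mirror
plot_summary(tab, "by_object", "results/summary.png")
```

Command-line wrappers for the three stages live in `inst/cli/`
(`simulate.R`, `analyze.R`, `stats.R`).

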