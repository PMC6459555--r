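# punctaflux

Quantitative analysis for reporter-based CRISPR screens of autophagy.

Pooled screens with tandem-fluorescent (tf) autophagy reporters read
out a single biology — autophagic flux — through three very different
data types, and each needs its own quantitative machinery:

1. **3D confocal imaging** of autophagosomal punctae (e.g. LC3⁺ or
   WIPI2⁺ structures): cells must be found against an empty-field
   background model, segmented from nucleus seeds, and their punctae
   counted and colocalized across channels, per cell, without manual
   thresholds biasing the comparison between genotypes.
2. **Flow cytometry** of tf reporters (RFP–GFP fusions to LC3 or
   autophagy receptors): lysosomal delivery quenches GFP, so the
   per-event Red:Green ratio *R = I_RFP / I_GFP* rises with flux.
   Populations are summarized by quantiles, normalized to a reference
   state, split when bimodal, and turned into a per-knockout
   fold-repression score
   *(R_gene − R_ATG9A) / (R_control − R_ATG9A)*.
3. **FACS-sorted sgRNA sequencing**: cells sorted into the top and
   bottom thirds of the ratio distribution, guides counted from reads
   anchored at the vector sequence `CACCG`, and genes scored by their
   high/low-bin enrichment, averaged over replicates and normalized so
   the ATG9A (autophagy-null) row equals 1.

punctaflux implements all three stages as a tested R package, plus
**ground-truthed synthetic generators** — image stacks with known cell,
nucleus, and punctum placements; flow populations with known mode
structure; sorted screens with planted hits — so every stage is
verifiable end to end without any raw microscopy or sequencing data.

## Worked example

Simulate a field of 30 cells in which 79% of green punctae have a
coincident red punctum (a knockout-like colocalization regime), run the
full imaging pipeline, and compare against the generator's truth:

```r
library(punctaflux)

sc  <- generate_scene(scene_spec(seed = 1, coloc_fraction = 0.79))
cfg <- run_config(speck_min_voxels = 1000)   # speck bound at synthetic scale
res <- run_image_pipeline(sc$stacks, sc$empty_field, cfg)

res$table
#> <puncta_table> field field1: 30 cells, 188 green / 177 red punctae

head(res$table$cells[, c("cell", "n_green", "n_red",
                         "n_green_overlapping_red",
                         "frac_green_overlapping")], 5)
#>   cell n_green n_red n_green_overlapping_red frac_green_overlapping
#> 1    1       9     9                       9              1.0000000
#> 2    2       0     3                       0                     NA
#> 3    3       6     8                       6              1.0000000
#> 4    4       9     5                       6              0.6666667
#> 5    5       3     4                       0              0.0000000

res$table$field$frac_green_overlapping   # recovered field-level fraction
#> [1] 0.7659574
g <- subset(sc$truth$puncta, channel == "green")
mean(!is.na(g$partner_id))               # realized truth for this seed
#> [1] 0.7589744
```

The pipeline recovers the realized colocalized fraction to better than
one percentage point; cells with no green punctae report a missing
fraction, not zero. The flux side works the same way:

```r
ev <- generate_flow_population(flow_pop_spec(
  n_events = 5000,
  modes = list(list(fraction = 1, median_ratio = 4, log_sd = 0.1)),
  seed = 2))
summarize_flux(compute_ratios(ev))
#> <flux_summary> n=5000 median=4.024 IQR=[3.389, 4.819]
#>                P10/P90=[2.896, 5.627] (normalized to none)

fold_repression(4, 2, 10)   # gene median 4, ATG9A 2, control 10
#> [1] 0.25
```

Screen scoring runs from FASTQ (`count_sgrnas_from_reads()`), from
standard count tables (`read_screen_counts_tsv()`), or from the
`simulate_sorted_screen()` generator, through `run_screen()`, which
normalizes counts, scores replicates, averages them, and anchors the
reference gene at 1.

The methods vignette (`vignettes/punctaflux-methods.Rmd`) documents the
models, parameter defaults, and the generators' scope in detail.

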