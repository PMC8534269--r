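# lc3topo

Where does autophagy happen inside a moving cell? `lc3topo` quantifies the
back-front spatial organization of autophagy organelles - autophagosomes,
autolysosomes, and lysosomes - in single cells migrating on micro-patterned
substrates, together with the cell's own motility. It is aimed at cell
biologists doing live-cell imaging with the tandem RFP-GFP-LC3 reporter
(or an acidotropic lysosomal dye) who want reproducible, scriptable
per-portion statistics instead of an interactive macro.

## The method in brief

With the tandem reporter every LC3 compartment is RFP-positive, while GFP
survives only until lysosomal fusion quenches it: **yellow** (GFP+RFP)
spots are autophagosomes, **red-only** spots are autolysosomes. Per frame
of a multi-channel time lapse, the pipeline

* rotates all coordinates so the migration direction maps onto +x;
* segments cell, nucleus and puncta (Gaussian blur + Otsu threshold, with
  difference-of-Gaussian background subtraction for the puncta);
* classifies each RFP object by its overlap fraction with GFP objects
  (&ge; 0.3 &rarr; autophagosome);
* splits the cell into 10 nucleus-anchored portions - 5 of equal width from
  back edge to nucleus centroid (#0-#5) and 5 from centroid to front edge
  (#5-#10) - and histograms counts and areas per portion;
* computes per-cell indicators (totals, autophagy flux = red/yellow ratio,
  nucleus relative position, cell area) averaged over time points;
* tracks the nucleus centroid: average speed (&micro;m/h), directionality
  ratio d/D, direction autocorrelation, plot-at-origin, and a turning-cell
  exclusion;
* compares conditions per indicator (Mann-Whitney or Welch t) and per
  portion (Welch t per portion).

A deterministic synthetic time-lapse generator (`generate_timelapse()`,
presets for six experimental conditions) provides ground truth for every
stage, so the whole pipeline is testable without real microscopy data.

## Worked example

```r
library(lc3topo)

scene <- generate_timelapse(scene_preset("normal_motile", seed = 7))
res <- run_cell(scene$stack, run_config(), cell_id = "cell_1")
res
#> cell_profile 'cell_1': 5/5 valid frames; classes: autophagosome, autolysosome
#>   mean counts: autophagosome 24.8, autolysosome 34.8; flux ratio 1.4; speed 12.01 um/h
round(res$summary$mean_density$all, 3)
#>    p0    p1    p2    p3    p4    p5    p6    p7    p8    p9
#> 0.000 0.000 0.000 0.020 0.084 0.222 0.295 0.245 0.107 0.027
```

The per-portion density profile of this simulated motile cell peaks at
portion #6, immediately in front of the nucleus (position #5), and the
nucleus track recovers the configured 12 &micro;m/h. Cohorts and condition
comparisons:

```r
motile <- run_cohort("normal_motile", 13, base_seed = 101)
static <- run_cohort("normal_static", 12, base_seed = 201)
compare_profiles(motile$profiles$all, static$profiles$all)
plot_profile(motile)
```

A thin command-line wrapper lives at `inst/cli/lc3topo.R`
(`simulate` / `analyze` / `cohort` subcommands).

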