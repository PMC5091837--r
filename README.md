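# satrep

Quantitative analysis of pericentromeric satellite biology: repeat-family
ChIP-seq enrichment against concatenated "repeat genomes", chromocentre
counting in single-nucleus images, and qPCR quantification (ΔΔCt, percent
input, transcript decay) — with seeded synthetic-data generators so the whole
pipeline is testable against exact ground truth.

## The problem

Mouse pericentromeres are tandem arrays of **major satellite** repeats
(centromeres proper carry **minor satellite**); their heterochromatinisation
clusters them into DRAQ5/DAPI-dense nuclear foci, the **chromocentres**.
Asking whether a protein binds these repeats, whether their transcription is
de-repressed by a treatment, and whether chromocentre organisation changes,
requires three quantifications that standard single-locus tooling does not
cover:

1. **Repeat-family enrichment.** Reads cannot be assigned to individual
   repeat copies, so all annotated instances of a family (from a
   RepeatMasker `rmsk` table or `.out` file) are concatenated into one
   artificial reference — a *repeat genome* — with copies separated by an
   `NNNNN` spacer so reads cannot align across copy boundaries. Hits are
   distinct reads with ≥ 1 alignment (multi-mapping allowed), and binding is

   ```
   fold = (hits_chip / total_chip) / (hits_input / total_input)
   CI95 = exp( log fold ± 1.96 · sqrt(1/h_c − 1/T_c + 1/h_i − 1/T_i) )
   ```

2. **Chromocentre counts.** Per nucleus: Gaussian smooth → threshold at
   1.3 × in-mask background → 8-connected components → equivalent radius
   `sqrt(area/π)` → count spots with radius **> 2.75 px**. Two treatment
   arms are compared by a Pearson chi-squared test on the per-cell count
   histograms, pooled to expected counts ≥ 5.

3. **qPCR.** ΔΔCt fold changes (`efficiency^−ΔΔCt`, spike-in or
   housekeeping reference), percent-of-input with no-antibody background
   subtraction, marks relative to total H3, and exponential decay fits
   `y = A·e^(−kt)` with half-life `ln 2 / k`.

## Worked example

Everything below is synthetic, seeded, and reproducible:

```r
library(satrep)

toy  <- make_toy_genome(seed = 1, families = c("major_sat", "minor_sat"))
fams <- group_by_family(toy$catalog)
rg   <- build_repeat_genome(toy$genome, fams$minor_sat)
rg   <- add_consensus(rg, "minor_sat_consensus", minor_satellite_consensus)
rg
#> repeat_genome 'minor_sat': 840 nt, 4 segment(s) (3 instance, 1 consensus),
#>   spacer 'NNNNN', strand policy reverse_complement_minus

sim   <- simulate_reads(toy$genome, toy$catalog, seed = 2,
                        enrichment = c(major_sat = 1.2, minor_sat = 1.9))
chip  <- count_hits_reads(sim$chip,  rg)
input <- count_hits_reads(sim$input, rg)
chip; input
#> hit_counts 'minor_sat': 489 / 100000 reads (0.489%)
#> hit_counts 'minor_sat': 226 / 100000 reads (0.226%)

enrichment(chip, input)[, c("family", "fold", "ci_low", "ci_high")]
#>      family     fold   ci_low  ci_high
#> 1 minor_sat 2.163717 1.848588 2.532566
```

The ChIP library was simulated with a true 1.9-fold weighting of
minor-satellite positions; the estimate is the hit-rate ratio and its 95%
interval covers the generative factor (counts this small make the interval
wide — that is the point of reporting it).

```r
nuc <- simulate_nucleus_image(seed = 3, n_spots = 14, radii = c(3, 4, 6))
count_chromocentres(detect_spots(nuc$image, nuc$mask))
#> [1] 14          # all generated radii exceed 2.75 px

ct  <- simulate_ct_table(seed = 4, folds = c(MG132 = 10))
est <- relative_expression(ct$table, "major_sat", "spike", "MG132", "DMSO")
sprintf("fold = %.2f +/- %.2f SEM (n=%d)", est$fold, est$sem, est$n)
#> [1] "fold = 10.35 +/- 0.25 SEM (n=6)"
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/satrep.R` (`annot`, `build`, `count`, `enrich`, `spots`,
`spots-compare`, `qpcr-rel`, `qpcr-decay`, `sim-*`); run it with
`Rscript $(Rscript -e 'cat(system.file("scripts/satrep.R", package="satrep"))') <command> --help`.

## Documentation

See the methods vignette (`vignettes/satellite-repeat-pipeline.Rmd`) for the
models, the parameter defaults and their rationale, what the synthetic
generators do and do not emulate, and known limitations.
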