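# hepavol

Slice-summation (Cavalieri) CT hepatic volumetry and its behaviour under
slice decimation, for veterinary and medical imaging researchers who want to
know how few manually traced slices still give a reliable liver volume.

Manual CT hepatic volumetry computes the liver volume from per-slice traced
areas,

    V = t * sum_i A_i         (A_i: slice area, cm^2; t: slice thickness, cm)

Tracing every slice is slow, so a natural shortcut is to trace only every
k-th slice (slice interval = k * thickness) and extrapolate:

    V_hat = t * sum_{i in S} A_i * N / |S|

where N is the total number of liver-bearing slices and S is one of the k
possible phase-offset subsets (each starting slice yields its own estimate).
`hepavol` implements both estimators, enumerates every phase, quantifies
interobserver variability of the full volumes (coefficient of variation
CV = SD/mean x 100, greatest percent difference = range/mean x 100, and
symmetric pairwise percent differences), and summarises the decimation error
|V_hat - V| / V x 100 per thickness-interval group, per slice interval and
per slice-count bin.

Because no clinical CT series ship with the package, a synthetic phantom
generator produces cohorts with the canonical design: 8 subjects at 2.5 mm
and 8 at 3.75 mm slice thickness, livers spanning 36-63 slices, smooth
unimodal cross-sectional area profiles, and three simulated observers whose
multiplicative tracing noise is calibrated to a cohort mean CV of 2.5%.
Binary masks can be exchanged as NIfTI volumes (`voxelize()`,
`mask_to_series()`, `read_mask_nifti()`).

## Worked example

```r
library(hepavol)

cohort <- generate_cohort(phantom_spec(seed = 7))   # 16 subjects x 3 observers
study  <- run_study(cohort)
study
#> <decimation_study>
#>   576 decimated measurements (7 groups), 48 full volumes
#>   cohort full volume: 824.2 (SD 321.2) cm^3
#>   interobserver CV: 2.0 (SD 1.1) %
#>   max |pct diff| using >= 20 slices: 3.8 %
summary(study)
#> Per-group percent difference from the corresponding full volume:
#>       group mean_pct_diff sd_pct_diff greatest_pct_diff n_measurements
#>       2.5-5           1.1         1.0               3.5             48
#>     2.5-7.5           2.3         1.6               5.8             72
#>      2.5-10           2.1         1.7               7.5             96
#>      2.5-15           3.9         3.0              12.9            144
#>    3.75-7.5           1.2         1.1               4.0             48
#>  3.75-11.25           2.7         1.6               6.1             72
#>     3.75-15           2.7         2.0               8.1             96
#> ...
#> Greatest percent difference per slice-count bin:
#>    bin n_measurements greatest_pct_diff
#>    <10            138              12.9
#>  10-14            207               8.1
#>  15-19            123               5.8
#>  20-24             69               3.8
#>   >=25             39               2.2
```

Reading the output: 576 decimated measurements arise from the 7 non-full
groups (k = 2, 3, 4, 6 at 2.5 mm; k = 2, 3, 4 at 3.75 mm: 192 per observer).
Mean decimation error grows with the slice interval within each thickness,
while the worst case tracks the *number of slices used*: bins with 20 or
more slices stay below the 5% acceptability threshold. The interobserver CV
of the 48 full volumes sits near its 2.5% calibration target.
`plot(study, "slices")` reproduces the error-vs-slice-count scatter with the
dotted 5% reference line.

Command-line wrappers with the same behaviour live in `inst/cli/hepavol.R`
(`generate` / `volumetry` / `study` subcommands; each run writes a
`manifest.json` with the seed and full specification, and re-running a
manifest's seed reproduces the outputs bit-identically).

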