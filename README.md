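# implacc — accuracy analysis for guided dental implant placement

`implacc` quantifies how accurately dental implants were placed relative
to a virtual surgical plan. It is written for the in-vitro workflow used
to evaluate surgical guide systems (for example a screw-retained guide
versus a conventional mucosa-supported guide in an edentulous mandible):
planned and post-placement implant meshes are exported as STL, aligned
into one coordinate frame, and each implant pair is reduced to the three
standard accuracy metrics

* **coronal deviation** `A = √(Δx² + Δy² + Δz²)` at the platform centre (mm),
* **apical deviation** `B`, the same distance at the implant apex (mm),
* **angular deviation**, the unsigned 3D angle between the planned and
  achieved long axes (degrees),

followed by the SPSS-style two-group comparison: per-metric group
summaries (n, mean, SD, SEM), Levene's variance screen (mean-centred),
and independent-samples t tests with both the pooled-variance (Student)
and unpooled (Welch) rows.

The toolkit covers the full chain:

| stage | functions |
|---|---|
| mesh I/O (binary + ASCII STL) | `read_stl()`, `write_stl()` |
| implant pose from a mesh | `implant_template()`, `fit_long_axis()`, `pose_from_mesh()` |
| rigid registration | `kabsch_align()`, `icp_refine()`, `align_scan()` |
| scan-body inference | `scan_body_library()`, `infer_implant_pose()` |
| deviation metrics | `compare_implants()`, `deviation_magnitude()`, `angular_deviation()` |
| statistics | `build_reports()`, `levene_test()`, `t_test_independent()` |
| synthetic studies | `study_design()`, `error_model()`, `generate_study()`, `expected_deviations()` |
| batch pipeline | `run_pipeline()`, `stats_from_table()`, `parse_nomenclature()` |

A hierarchical synthetic-study generator (a shared per-guide seating
error plus independent per-implant errors — four implants share one
seated guide, so they are not independent) makes every stage testable
without physical models. See the methods vignette
(`vignettes/implant-accuracy-methods.Rmd`) for the model, its calibrated
defaults, and the numerical conventions.

## Worked example

The package ships a complete 40-implant bench-study table (ten mandible
models, four implants each; blocks 1–5 placed with a screw-retained
guide, blocks 6–10 with a mucosa-supported one):

```r
library(implacc)
reports <- build_reports(example_deviation_table())
print(reports)
#> Coronal deviation A (mm)
#> method 1: n = 20, mean = 0.4515, sd = 0.1599, sem = 0.0358
#> method 2: n = 20, mean = 1.2230, sd = 0.6101, sem = 0.1364
#>   Levene (mean-centred) F = 8.1914, p = 0.006809
#> mean difference -0.7715 (n = 20, 20)
#>   equal t = -5.4707, df = 38.00, p = 3.029e-06, se = 0.1410, 95% CI [-1.0570, -0.4860]
#>   welch t = -5.4707, df = 21.60, p = 1.809e-05, se = 0.1410, 95% CI [-1.0643, -0.4787]
#> Apical deviation B (mm)
#> method 1: n = 20, mean = 0.2800, sd = 0.1314, sem = 0.0294
#> method 2: n = 20, mean = 0.8940, sd = 0.3986, sem = 0.0891
#>   Levene (mean-centred) F = 16.1526, p = 0.0002669
#> mean difference -0.6140 (n = 20, 20)
#>   equal t = -6.5424, df = 38.00, p = 1.03e-07, se = 0.0938, 95% CI [-0.8040, -0.4240]
#>   welch t = -6.5424, df = 23.08, p = 1.105e-06, se = 0.0938, 95% CI [-0.8081, -0.4199]
#> Angular deviation (degrees)
#> method 1: n = 20, mean = 1.9910, sd = 0.9842, sem = 0.2201
#> method 2: n = 20, mean = 2.8685, sd = 1.9540, sem = 0.4369
#>   Levene (mean-centred) F = 5.4108, p = 0.02545
#> mean difference -0.8775 (n = 20, 20)
#>   equal t = -1.7937, df = 38.00, p = 0.08083, se = 0.4892, 95% CI [-1.8679, 0.1129]
#>   welch t = -1.7937, df = 28.06, p = 0.08365, se = 0.4892, 95% CI [-1.8795, 0.1245]
```

Reading: the screw-retained guide halves the linear deviations (coronal
0.45 vs 1.22 mm, apical 0.28 vs 0.89 mm; both `p < 0.001`, with Levene
confirming unequal variances, so the Welch row is the one to quote),
while the angular difference (1.99° vs 2.87°) is not significant
(`p = 0.081`).

The same analysis runs mesh-first. A synthetic study stands in for the
scanner exports here:

```r
design <- study_design()                         # 5 models/method, 4 implants each
generate_study(design, out_dir = "meshes")       # {block}{position}_{pre|post}.stl + manifest
res <- run_pipeline("meshes", "out")             # deviation_table.csv + report CSVs
```

or from a shell, via the bundled CLI:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "implacc.R", package = "implacc"))')" \
  all --out study_out --seed 3
```

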