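# plvnet

Source-level weighted functional-network analysis of event-related EEG,
built around phase-locking-value (PLV) connectivity in the late
response-inhibition (NoGo-P3) window. The package is aimed at EEG
researchers who want a fully scripted, testable version of the classic
Go/NoGo network analysis: epoching and artifact rejection, zero-phase
band-pass filtering, regularized minimum-norm source estimation, PLV
adjacency matrices per frequency band, weighted graph indices, and
covariate-adjusted group statistics with Bonferroni familywise control.

Because raw study EEG of this kind is rarely shareable, the package ships
a phase-coupled oscillator cohort simulator whose ground truth is known in
closed form, so the entire chain can be validated end to end without any
download.

## The model in brief

For nodes *i, j* with instantaneous phases φᵢ(t, k) on trial *k*, the
across-trials phase-locking value at time *t* is

    PLV_ij(t) = | (1/N) Σ_k exp( i (φ_i(t,k) − φ_j(t,k)) ) |

averaged over the 200–700 ms post-stimulus window, separately for alpha
(8–12 Hz), low beta (12–18), high beta (18–30) and gamma (30–55). The
resulting weighted adjacency W feeds four global indices — mean nodal
strength Σⱼwᵢⱼ, mean Onnela weighted clustering
Cᵢ = Σ_{j≠h}(wᵢⱼwᵢₕw_{jh})^{1/3} / (kᵢ(kᵢ−1)), characteristic path length
(mean shortest-path distance with edge length 1/w), and global efficiency
(mean inverse distance) — plus nodal clustering. Group comparisons are
ANCOVAs (anxiety, depression and ADHD-trait scores as covariates) with
partial η² effect sizes, Bonferroni thresholds (e.g. 0.05/16 = 0.003125
for 4 indices × 4 bands), Bonferroni post-hoc pairwise contrasts, and
partial Pearson correlations between nodal clustering and trauma
measures.

The simulator plants coupling by giving every node a wrapped-normal
per-trial phase jitter of SD σ around a common trial phase; the expected
PLV of a pair is then exactly `exp(−(σᵢ² + σⱼ²)/2)`, which is what the
tests check the pipeline against.

## A worked example

```r
library(plvnet)

cfg <- pipeline_config(
  sim = sim_config(n_subjects_per_group = c(15, 25, 15),
                   n_nodes = 20, n_trials = 48,
                   sample_rate = 125, nogo_only = TRUE, seed = 7))
res <- run_pipeline(cfg)
print(res)
#> <pipeline_result>
#>   subjects: 55 (groups: low=15, middle=26, high=14)
#>   bands: alpha, low_beta, high_beta, gamma | PLV window 200-700 ms
#>   global tests: 4/16 significant at 0.003125

subset(res$stats$table, band == "low_beta" & index == "clustering",
       select = c(F, p, partial_eta_sq, p_low_high))
```

The printed summary says that with the default planted effect (expected
mean PLV 0.445 / 0.430 / 0.415 for the low / middle / high trauma-analog
groups) this 55-subject cohort shows 4 of the 16 index-by-band cells
significant at the Bonferroni threshold 0.05/16 = 0.003125: the high
group's weaker phase coupling depresses strength, clustering and
efficiency and lengthens paths, and the covariate-adjusted group test
picks that up. `render_report(res)` prints the full group-mean ± SD
table per index and band with pairwise p values and partial η², and
`run_pipeline` with `output_dir` set persists every stage artifact plus a
JSON manifest.

Individual stages are exported — `generate_cohort()`,
`bandpass_filter()`, `epoch_recording()`, `reject_artifacts()`,
`select_condition()`, `minimum_norm_inverse()`, `apply_inverse()`,
`downsample_nodes()`, `instantaneous_phase()`, `plv_matrix()`,
`global_metrics()`, `ancova_group_test()`, `partial_correlation()` — so
any slice of the chain can be run on its own data. A thin command-line
wrapper lives in `inst/scripts/run_pipeline.R`.

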