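# cytogate

Template-driven, hierarchical, automated gating for flow and mass cytometry.

## The problem

Clinical cytometry studies — intracellular cytokine staining (ICS) trials,
CyTOF phenotyping panels — produce hundreds of FCS files that are still
routinely gated by hand. Manual gating is slow and subjective, while fully
unsupervised clustering produces populations that are hard to interpret and
hard to match across samples. `cytogate` takes the middle road: the analyst
declares the *gating strategy* — the familiar tree of nested populations, the
markers that define each one, and the data-driven algorithm that should place
each gate — in a plain CSV template, and the package fits every gate to every
sample automatically. The template is staining-panel specific but **data
agnostic**: the same CSV gates any standardized data set using that panel.

Key design points:

- **Hierarchical model.** Populations form a tree; a child's events are
  always a subset of its parent's. Gates are fitted on parent-population
  events only, exactly as a manual analyst would subset before drawing the
  next gate.
- **Disk-backed events.** All samples live in a single on-disk container
  (magic header + JSON index + one row-major float32 blob per sample); one
  sample's events are materialised at a time, so studies of hundreds of
  files gate within a bounded memory footprint.
- **Cached event indices.** Per-(sample, population) membership vectors are
  cached, which makes the `2^k` Boolean polyfunctionality subsets of `k`
  cytokine gates cheap: for 5 cytokines under the CD4 and CD8 parents that
  is 64 disjoint subsets per sample; for 9 CyTOF functional markers under 4
  maturational subsets, 2048.
- **Grouped fitting.** A template row can pool samples that must be compared
  directly (e.g. all stimulations of one subject-visit) so they share one
  bitwise-identical threshold, or copy a reference gate fitted on a negative
  control (e.g. the 99th percentile of the unstimulated sample).

## The statistics at the core

For a 1-D marker with intensity density `f` (arcsinh scale), the *minimum
density* gate places the threshold at

    t = argmin_{x in (m1, m2)} f_h(x)

where `f_h` is a Gaussian KDE (Silverman bandwidth x `adjust`, 512-point
grid) and `m1 < m2` are its two dominant modes. The *tail gate* for rare
populations walks right from the dominant mode of the normalised density and
stops where the descent slope first flattens above `-tol`. Quantile and
reference gates transfer `Q_p` of a control sample. 2-D gates include a
least-absolute-deviations singlet band in area-height space, its DNA-DNA
CyTOF analogue, boundary-event rectangles, and the `chi^2_2(level)` ellipse
of a seeded EM Gaussian mixture component.

Each event in a parent population then gets a k-bit code (bit i = inside the
i-th marker gate); tabulating codes yields counts for all `2^k` disjoint
Boolean combinations, their proportions of parent, and the *degree of
functionality* (popcount). Downstream, per-combination proportions are
background-corrected (stimulated minus matched negative control, no
truncation), screened with a linear mixed model
`proportion ~ visit * treatment + (1 | subject)` (one-sided Wald test of the
interaction, Bonferroni), and compared across gating methods with Lin's
concordance correlation coefficient

    rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean x - mean y)^2)

and the exact paired Wilcoxon signed-rank test.

## Worked example

Simulate a miniature ICS trial (2 subjects x 2 visits x 4 stimulations,
already on the transformed scale), gate it with the shipped template, and
enumerate the Boolean cytokine subsets:

```r
library(cytogate)

sim   <- simulate_ics(ics_scenario(n_subjects = 2, n_events = 3000), seed = 7)
store <- create_store(sim$samples, tempfile(fileext = ".bin"))
gs    <- gating_set(store)
tpl   <- parse_template(system.file("extdata", "ics_template.csv",
                                    package = "cytogate"))
apply_template(gs, tpl, seed = 11)

head(population_stats(gs)[, 1:4], 4)
#>          sample_id                    path count proportion_of_parent
#> 1 s001_pre_negctrl                       /  3000            1.0000000
#> 2 s001_pre_negctrl               /boundary  3000            1.0000000
#> 3 s001_pre_negctrl      /boundary/singlets  2864            0.9546667
#> 4 s001_pre_negctrl /boundary/singlets/live  2729            0.9528631

cd4 <- "/boundary/singlets/live/cd3/CD4+CD8-"
tbl <- enumerate_subsets(gs, cd4,
                         file.path(cd4, c("IFNg", "IL2", "TNFa", "GzB", "CD57")))
nrow(tbl) / length(sample_ids(store))
#> [1] 32
subset(tbl, sample_id == "s001_pre_negctrl" & degree >= 1 & count > 0)[1:3, 4:7]
#>               combo_label count proportion_of_parent degree
#> 2 IFNg+IL2-TNFa-GzB-CD57-     1         0.0009017133      1
#> 5 IFNg-IL2-TNFa+GzB-CD57-     5         0.0045085663      1
#> 9 IFNg-IL2-TNFa-GzB+CD57-    14         0.0126239856      1
```

`proportion_of_parent` is the fraction of the parent population inside each
gate (the third row above says ~1.3% of this sample's CD4 T cells are GzB
single-positive); counts across the 32 combos sum exactly to the CD4 parent
count because thresholds are half-open.

The same pipeline from the command line:

```sh
Rscript inst/cli/cytogate simulate --scenario ics --out simdata --seed 1
Rscript inst/cli/cytogate validate --template inst/extdata/ics_template.csv
Rscript inst/cli/cytogate run --template inst/extdata/ics_template.csv \
    --data simdata --metadata simdata/metadata.csv --out results_run --seed 42
Rscript inst/cli/cytogate stats --results results_run --metadata simdata/metadata.csv
```

`run` writes `population_stats.csv`, `subset_table.csv`, a gating-set sidecar
JSON and a manifest; `stats` writes background-corrected proportions, paired
post-minus-pre differences, and the mixed-model screening report.

## Store layout

`store.bin` = `"CYTOGATE-STORE-1\n"` + 4-byte little-endian index length +
UTF-8 JSON index (shared channel list; per-sample byte offset, row count,
markers, metadata) + concatenated row-major little-endian float32 event
blocks, one per sample.
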