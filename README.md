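# dnbtei

Dynamic network biomarker (DNB) analysis of treatment time courses:
find the gene module whose collective dynamics signal the disease state,
track its **therapeutic effect index** across treatment, and call the
**pre-stable state** — the timepoint at which a patient's molecular state
has settled toward the healthy level.

The package is written for transcriptomic time courses with three sample
groups: a `control` group at diagnosis, `treatment` samples at ordered
timepoints, and a `health` reference cohort. The motivating application
is chronic myeloid leukemia under imatinib, but nothing in the code is
disease-specific.

## The method

For a module $M$ with out-group $O$ at timepoint $t$, with $r_t$ the
Pearson correlation across the samples at $t$:

- $\mathrm{CV}_t$ — mean over $g \in M$ of $\mathrm{SD}_t(g)/|\bar{x}_t(g)|$
  (average coefficient of variation),
- $\mathrm{PCC}_t$ — mean $|r_t|$ over gene pairs within $M$,
- $\mathrm{OPCC}_t$ — mean $|r_t|$ over pairs between $M$ and $O$,

$$\mathrm{TEI}_t = \frac{\mathrm{CV}_t \times \mathrm{PCC}_t}{\mathrm{OPCC}_t},
\qquad \text{pre-stable state} = \arg\min_{t\,\in\,\text{treatment}} \mathrm{TEI}_t .$$

The pipeline: (optional log2 and location-scale batch adjustment) →
differential expression (Student's t-test p < 0.05 and fold change ≥ 1.5)
→ control-referenced standardization → hierarchical clustering of DEG
profiles (distance 1 − r, average linkage) → DNB selection by each
cluster's index ratio between the first treatment timepoint and health →
TEI trajectory and pre-stable call → per-timepoint correlation networks
(|PCC| > 0.4 edges, node SD attributes, GraphML export). A seeded
synthetic-data generator plants a module with a known pre-stable
timepoint so the whole analysis is testable offline. See the methods
vignette (`vignettes/dnb-methods.Rmd`) for every modelling choice.

## Worked example

```r
library(dnbtei)

sim <- simulate_dnb_data(dnb_sim_config("strong", seed = 2026))
res <- run_pipeline(sim$expr, sim$meta,
                    pipeline_params(contrast_timepoint = 1, k_clusters = 10),
                    out_dir = "results/run_strong")
print(res)
```

```
DNB pipeline run: 500 genes x 50 samples
  DEGs: 40  clusters: 10  DNB size: 34
  pre-stable state: timepoint 3 (|TEI - TEI_health| = 0.0009427)
  timepoint_order timepoint_label is_health      cv    pcc   opcc     tei
1               1         treat_1     FALSE 0.48192 0.9802 0.9757 0.48411
2               2         treat_2     FALSE 0.27830 0.9383 0.9320 0.28017
3               3         treat_3     FALSE 0.04200 0.2757 0.2609 0.04438
4               4          health      TRUE 0.04431 0.3111 0.3041 0.04533
  is_pre_stable
1         FALSE
2         FALSE
3          TRUE
4         FALSE
```

Reading the output: 40 genes pass the DEG filter; the selected DNB (34
genes) shows high variability (CV) and tight internal correlation (PCC)
early in treatment, both collapsing by timepoint 3, where the TEI reaches
its minimum and essentially matches the healthy reference — timepoint 3
is called the pre-stable state, which here equals the planted ground
truth (`sim$truth$t_star`). The run directory receives the DEG and
volcano tables, the DNB member list, cluster scores, the TEI trajectory,
per-timepoint networks (GraphML and edge list), a `summary.json` and a
`run.log` recording every skipped-gene decision.

The `analysis/` directory holds the numbered driver scripts of the full
study — `01_simulate.R` (datasets), `02_pipeline.R` (one run, shown
above), `03_replication.R` (50-replicate recovery and null-calibration
study), `04_networks.R` (network decay along treatment) — each writing
its tables under `results/`.

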