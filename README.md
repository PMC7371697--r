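# phosmarker

Integrative analysis of baseline (phospho)proteomes of cancer cell line
panels against phenotypic drug-sensitivity data.

Large cell line panels (NCI60-like pan-cancer panels, CRC65-like colorectal
panels) can be profiled to a depth of thousands of protein groups and tens of
thousands of phosphorylation sites (p-sites), and the same panels carry
published dose-response data for hundreds of drugs. `phosmarker` implements
the analysis layer that connects the two: it functionalizes proteins and
p-sites through activity scores and co-abundance networks, and it mines the
panel for (phospho)protein markers that explain why some cell lines respond
to a drug and others do not. It is aimed at computational biologists working
with features x cell-lines intensity matrices (log10 LFQ-like arbitrary
units) and drugs x cell-lines sensitivity matrices (GI50- or sAUC-oriented).

## What it computes

* **Phosphoprotein aggregation** — per protein group and cell line, the
  log10 of the summed linear-scale intensities of its observed p-sites;
  missing only when every member site is missing.
* **Pathway and kinase activity landscapes** — per-feature z-scores across
  the panel, averaged over pathway members (proteins + their p-sites) or
  over three kinase evidence channels (kinase abundance, kinase
  phosphorylation, substrate phosphorylation, with inhibitory sites
  negated). Raw scores are min-max rescaled per entity to a *relative
  activity* in [0, 1]; a PCA embedding with Gaussian-kernel smoothing turns
  them into landscapes whose mountains mark groups of high-activity cell
  lines, and per-cell-line waterfalls rank entities.
* **Correlation-network modules and guilt-by-association** — WGCNA-style
  unsigned adjacency `|cor|^beta`, topological overlap
  `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`,
  average-linkage clustering with a fixed-height cut, module eigenfeatures,
  three-axis association (functional sets / modules / binary phenotype such
  as MSI status) via hypergeometric enrichment and moderated t-tests, and
  transfer of set annotations to unannotated module members.
* **Outlier markers** — calls `(feature, cell line)` pairs whose abundance
  exceeds the leave-one-out median of the other cell lines by a fold
  threshold (default 5-fold, i.e. 0.7 log10 units), plus detection-only
  calls, and clusters the binary incidence matrix by Jaccard distance to
  reveal co-outlying site groups (e.g. a hyperactive fusion kinase elevating
  its whole substrate set in one line).
* **Drug-association models** — Pearson screening of every feature-drug
  pair with at least seven pairwise-complete observations (BH-corrected per
  drug), elastic-net models per drug with cross-validated penalty (1-SE
  rule) and sign-specific marker frequency ranking, exhaustive
  random-forest subset models over a small metabolic panel (all C(14, 3..7)
  = 9,802 subsets), and a screen restricted to regulatory
  (activating/inhibitory) kinase p-sites.
* **Sparse multiblock PLS (SMBPLSR)** — latent components linking the
  protein and p-site blocks to the drug matrix with sparse feature weights,
  nonnegative block-combination weights and sparse drug weights, so each
  component reads as a cluster of drugs with a shared mode of action plus
  the sparse marker set explaining their shared sensitivity profile.
* **Synthetic panels** — a seeded generator (`simulate_dataset`) producing
  all of the above inputs with planted ground truth: tissue covariance,
  MNAR missingness, planted modules, active pathways/kinases, single-line
  outliers, linear drug markers, drug clusters sharing markers, and an
  MSI-like phenotype.

All statistics use explicit missing values (never zero on the log scale),
and every drug-direction label is derived from one canonical orientation
(higher = more sensitive; GI50-like input is negated on ingest).

## Worked example

```r
library(phosmarker)

sim <- simulate_dataset(sim_config(seed = 1))   # NCI60-like synthetic panel
sim$psite
#> <intensity_matrix[psite]> 400 features x 60 cell lines, 4.4% missing

# single-cell-line outlier p-sites (>= 5-fold above the other lines)
calls <- call_outliers(sim$psite, threshold_fold = 5)
head(calls[order(-calls$excess), ], 3)
#>           feature cell_line   excess detection_only n_observed
#> 30 PROT0105_pS419      CL33 1.365418          FALSE         60
#> 29 PROT0182_pS888      CL33 1.237431          FALSE         60
#> 8      KIN5_pY912      CL16 1.207758          FALSE         60

# kinase activity waterfall of the cell line carrying the planted KIN1 driver
kact <- kinase_activity(median_center(sim$protein), median_center(sim$psite),
                        sim$kinase_substrates, sim$annotation)
head(waterfall(kact, sim$truth$active_kinase_lines[["KIN1"]]), 3)
#>   entity  relative
#> 1   KIN1 1.0000000
#> 2   KIN6 0.3216229
#> 3   KIN3 0.1417893

# correlation screen against the drug panel (pairwise-complete n >= 7)
mk <- correlation_screen(sim$protein, sim$drugs_sauc)
head(mk[!is.na(mk$q) & mk$q < 0.05, ][order(mk$q[!is.na(mk$q) & mk$q < 0.05]), ], 3)
#>       feature   drug         r            p            q  n   direction
#> 4862 PROT0062 DRUG17 0.6537538 1.977890e-08 5.933669e-06 59 sensitivity
#> 1564 PROT0064 DRUG06 0.6545692 2.498913e-08 7.496740e-06 58 sensitivity
#> 6082 PROT0082 DRUG21 0.6033837 1.082932e-06 3.248795e-04 55 sensitivity
```

The excess column is in log10 units (1.37 is a 23-fold elevation); relative
activity 1.0 marks the cell line where the kinase is maximally active; the
screen's `r` is the Pearson correlation between feature abundance and
canonical sensitivity, so a positive `r` marks a sensitivity marker
(`PROT0062` is the planted SLFN11-like common marker). The printed
fold-change convention is available directly:
`fold_change(6.64, 8.82, round_to_int = TRUE)` is `151`.

A config-driven end-to-end run (`aggregate -> normalize -> activity /
modules / outliers -> associate / smbpls`, with a checksummed manifest) is
available as `run_pipeline("config.yaml")` or the `run` subcommand of the
CLI wrapper in `inst/cli/phosmarker.R`; `simulate`, `aggregate` and
`normalize` subcommands cover the individual stages.

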