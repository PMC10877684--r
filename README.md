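# tcrtrack

Clonal tracking of TCRβ repertoires between peripheral blood (PB) and
visceral adipose tissue (VAT).

In obesity, T cells infiltrate insulin-sensitive tissues and can contribute
to insulin resistance. Because the TCRβ CDR3 junction is a clonal barcode,
paired repertoire sequencing of PB and VAT from the same individual makes
T-cell exchange between fat and blood directly observable: a clonotype seen
in both compartments of one person is a **recirculating clone**, and the
compartment where its relative sequence count (within-repertoire frequency)
is higher indicates where it expanded. `tcrtrack` implements this analysis
for cohorts of lean controls (LC), obese normoglycemic (OB-ND) and obese
dysglycemic (OB-Dys) individuals, for PD-1⁺ and PD-1⁻ CD4 conventional
T-cell subsets.

## What it computes

For repertoires $R_{PB}, R_{VAT}$ of one individual with clone frequencies
$p_i$ (normalized over productive clonotypes):

- **Recirculation fraction** — $f = |K_{PB} \cap K_{VAT}| / |K_{VAT}|$ over
  clone keys $K$ (CDR3 amino-acid identity by default; `aa+V`, `aa+V+J`
  optional), with the PB-denominated converse also reported; group medians
  compared by Kruskal–Wallis, paired PB/VAT counts by Wilcoxon signed-rank.
- **Directionality** — each shared clone is VAT-expanded
  ($p^{VAT} > p^{PB}$), PB-expanded, or tied; group-level stacked fractions
  separate a physiological regime (VAT-expanded majority) from a
  dysglycemic one (PB-expanded majority).
- **Diversity and usage** — plug-in Shannon entropy
  $H = -\sum_i p_i \ln p_i$ (nats), richness, V-gene/family usage.
- **Publicity** — clones carried by ≥ 2 individuals, Venn partition of
  clone keys by group combination, and Fisher's exact group-divergence test
  on shared clones (2×2 construction documented and pluggable; odds ratio
  is the cross-product ratio $ad/bc$).
- **Motif patterns** — clusters of CDR3s sharing a central-region k-mer
  (positions 4…L−3, k ∈ {3,4}), scored for motif over-representation
  (one-sided Fisher), V-gene enrichment, and length bias; retained iff
  unique CDR3s ≥ 3 and all three scores ≤ 0.05 (inclusive). GLIPH2 output
  tables can be imported and filtered identically.
- **Annotation** — exact CDR3 matches against a VDJdb-style database after
  confidence filters (score ≥ 1, MHC class II, CD4); multi-species matches
  flagged.
- **Metabolic** — HOMA-IR = glucose(mg/dL) × insulin(mU/L) / 405, ADA
  glycemia classes with precedence D > PreD > ND, and a Pearson screen for
  genes with r > 0.8 and p < 0.05 against HOMA-IR.

A seeded generator (`generate_cohort()`) produces paired-compartment
cohorts with planted recirculation fractions, expansion biases, public
pools, motif spikes and correlated genes — with exact ground truth — so the
whole pipeline is testable without patient data.

## Worked example

```r
library(tcrtrack)

sim <- generate_cohort(default_scenarios(clones_per_repertoire = 300),
                       seed = 1, subsets = "PD1pos")
tr <- track_cohort(sim$cohort, subset = "PD1pos", key = "aa")
tr$summaries[["LC"]]
#> <tcr_recirc_summary> LC (PD1pos): median recirc 5.00% of VAT; 60 clones: 98% VAT- / 2% PB-expanded
tr$summaries[["OB-Dys"]]
#> <tcr_recirc_summary> OB-Dys (PD1pos): median recirc 12.00% of VAT; 252 clones: 43% VAT- / 57% PB-expanded
compare_recirculation(tr)$kruskal$p_value
#> [1] 0.0003354626

st <- build_sharing_table(sim$cohort)
length(public_clones(st))
#> [1] 30

expr <- generate_expression(sim$cohort$clinical, n_genes = 200,
                            n_correlated = 20, seed = 2)
res <- correlate_with_homa(expr$expr, sim$cohort$clinical)
sum(res$retained)
#> [1] 20
```

Read as: lean controls share ~5% of their VAT clones with blood and almost
all of those are VAT-expanded, while the dysglycemic group shares ~12% with
a PB-expanded majority — the directionality inversion the tracking module
is designed to detect; the group difference in recirculation fractions is
significant by Kruskal–Wallis. The sharing table recovers exactly the 30
planted public clones, and the metabolic screen retains exactly the 20
planted HOMA-IR-correlated genes.

`run_pipeline(run_config(...))` chains all stages over a cohort manifest
and writes TSV tables plus a JSON run log; `inst/cli/tcrtrack.R` is a thin
shell wrapper (`simulate`, `run`). The methods vignette
(`vignettes/repertoire-tracking.Rmd`) documents the model, the parameter
defaults, and what the synthetic cohorts do and do not emulate.

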