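# phoscoreg

Phosphosite-resolved co-regulation network analysis from curated
phosphoproteomics compendia.

Individual phosphosites on the same protein can respond to different
signals and drive different outputs. Given a long-format compendium of
phosphosite observations — one row per site per experimental comparison,
across many publications — `phoscoreg` identifies, for each major
phosphosite of a target protein (the worked examples use the kinase MELK),
the phosphosites on *other* proteins (PsOPs) whose regulation consistently
tracks it, stratifies those partners into functional roles, and exports the
result as a signed network for Cytoscape-style tools. It is written for
computational biologists doing phosphoproteomics meta-analysis.

## Method

1. **Class-I filtering** — keep confidently localized sites: localization
   probability ≥ 0.75 and A-score ≥ 13 (missing A-scores pass by default).
2. **Direction calling** — per comparison, a site is Up if fold change
   ≥ 1.3 with p < 0.05, Down if ≤ 0.76 with p < 0.05, else Unchanged;
   conflicting duplicate peptides become Ambiguous and are excluded.
3. **Site statistics** — detection frequency per site across profiling and
   differential datasets (deduplicated at dataset level) selects the target's
   major sites; a lollipop/domain table is exported.
4. **Co-occurrence** — for target-site pairs, counts of joint events
   n<sub>UU</sub>, n<sub>UD</sub>, n<sub>DU</sub>, n<sub>DD</sub> over shared
   informative conditions; positive co-regulation ratio
   Σ(n<sub>UU</sub>+n<sub>DD</sub>)/Σ(n<sub>UD</sub>+n<sub>DU</sub>), its
   reciprocal for negative, and a bounded concordance score for heatmaps.
5. **High-confidence PsOPs** — for each (target site m, PsOP o) pair, the
   2×2 table [[n<sub>UmUo</sub>, n<sub>UmDo</sub>], [n<sub>DmUo</sub>,
   n<sub>DmDo</sub>]] is tested with a two-sided Fisher's exact test; a pair
   is called positive/negative when p < 0.05, the sign-appropriate ratio is
   ≥ 0.15, concordant (resp. discordant) events dominate, and evidence spans
   ≥ 2 conditions and ≥ 2 publications.
6. **Role annotation** — flat-file resource snapshots classify partners as
   upstream kinases (site-specific), co-regulated kinases, phosphatases,
   binary interactors, and substrates, with core/pairwise/exclusive sharing
   across the three major sites.
7. **Network export** — one signed graph (GraphML, SIF, node/edge TSVs);
   every role-stratified view is a filter of it.

A synthetic-compendium generator with planted partners provides ground truth
for null calibration and recovery benchmarking. See the methods vignette
(`vignettes/phosphosite-coregulation.Rmd`) for assumptions and design
rationale.

## Worked example

The package bundles a 12-condition toy compendium (4 differential studies,
3 target sites, 8 PsOPs) with matching annotation resources:

```r
library(phoscoreg)
ext <- function(f) system.file("extdata", f, package = "phoscoreg")
cfg <- pipeline_config(
  ext("toy_compendium.tsv"), outdir = "toy_out", target = "MELK",
  resources = list(kinase_substrate = ext("toy_kinase_substrate.tsv"),
                   predicted_kinase_site = ext("toy_predicted_kinase_site.tsv"),
                   interaction = ext("toy_interaction.tsv"),
                   kinase_list = ext("toy_kinase_list.tsv"),
                   phosphatase_list = ext("toy_phosphatase_list.tsv")),
  alias_map = ext("toy_alias_map.tsv"), domains = ext("toy_domains.tsv"))
res <- run_pipeline(cfg)

res$major_sites
#> [1] "MELK_S356" "MELK_S505" "MELK_S529"

dplyr::filter(res$scan, o_site == "MKI67_T2085")
#> # A tibble: 3 × 12
#>   m_site    o_site      n_UmUo n_UmDo n_DmUo n_DmDo   fet_p ratio_pos ratio_neg
#>   <chr>     <chr>        <int>  <int>  <int>  <int>   <dbl>     <dbl>     <dbl>
#> 1 MELK_S356 MKI67_T2085      6      0      0      6 0.00216       Inf         0
#> 2 MELK_S505 MKI67_T2085      6      0      0      6 0.00216       Inf         0
#> 3 MELK_S529 MKI67_T2085      4      0      0      4 0.0286        Inf         0
```

The Ki-67 site `MKI67_T2085` moves with all three MELK sites in every
shared comparison: 6 concordant-up plus 6 concordant-down conditions at
S356 give FET p = 2/924 ≈ 0.0022 with an infinite positive ratio (no
discordant event), so it is called a positive partner at all three sites —
a pan-site co-regulator. Sharing of binary interactors across the sites:

```r
sharing_partition(res$roles, "binary_interactor", "positive",
                  res$major_sites)[c("core", "pairwise")]
#> $core
#> [1] "MKI67_T2085" "TTK_S436"
#>
#> $pairwise
#> $pairwise$`MELK_S356&MELK_S505`
#> [1] "SF3B1_T303"
#> ...
```

`toy_out/` then contains the stage tables (`coregulation.tsv`,
`venn_positive.tsv`, `roles.tsv`, ...), `network.graphml` / `network.sif`,
and a JSON manifest of row counts and parameters. A thin CLI wrapper with
`run-all` and `simulate` subcommands is installed at
`system.file("cli", "phoscoreg", package = "phoscoreg")`.

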