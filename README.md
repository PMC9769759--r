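# gutmodules

Species-resolved functional profiling of gut metagenomes across diet
groups: score Gut Metabolic Modules (GMMs) from KEGG-orthologue
profiles, attribute them to the contributing species, and test which
species' contributions differ between diets.

## The problem

Gut microbiomes are functionally redundant: cohorts with near-identical
pooled functional capacity can have that capacity carried by different
organisms. Diet studies comparing omnivores, pescatarians, vegans and
vegetarians typically find little difference in overall composition or
module abundance — the signal sits in *which species contribute which
functions*. `gutmodules` is an R package for that analysis:

* **Module scoring** — a module is an ordered list of reaction steps,
  each a set of alternative KOs or KO complexes. For KO abundances
  *x* (RPK): complex value `min(x_k)`, step value = **sum** over
  alternatives, coverage = fraction of steps > 0, module abundance =
  **median** over steps when coverage ≥ the cutoff (default 0.66),
  else 0.
* **Species contributions** — with HUMAnN-style stratified input each
  species' own rows are scored independently; contribution fractions are
  species module score over the sum across strata (species +
  unclassified).
* **Test cascade** — per (module, species) feature: Kruskal–Wallis across
  diet groups, Benjamini–Hochberg over features, then Dunn's pairwise
  post hoc tests (tie-corrected pooled-rank variance) BH-adjusted within
  significant features; significance at adjusted *P* < 0.05.
* **Community context** — Bray–Curtis (`Σ|x−y| / Σ(x+y)`) + PCoA,
  cross-cohort similarity (1 − BC), bootstrap core-microbiota detection
  (detection > 0.0001% relative abundance, ≥ 75% prevalence, 100
  bootstraps), Firmicutes/Bacteroidetes and *Prevotella*/*Bacteroides*
  ratios, VANISH family aggregation.
* **Synthetic studies** — a generator for taxon profiles, stratified KO
  tables, metadata and module catalogues with planted contribution
  effects, so the whole pipeline is testable against known ground truth.

Input formats: MetaPhlAn-style taxonomic TSV, HUMAnN-style stratified
gene-family TSV, metadata TSV, and a documented GMM flat-file dialect
(`?read_gmm_definitions`).

## Worked example

Simulate a 140-sample diet study (4 × 35) in which one species'
contribution to one module is four-fold higher in vegans, then recover it:

```r
library(gutmodules)
library(dplyr)

effect <- tibble::tibble(module_id = "MF0007",
                         species = "s__Bacteroides_uniformis",
                         diet_group = "vegan", fold_change = 4)
sim <- simulate_dataset(simulation_config(planted_effects = effect, seed = 2))

scores  <- score_table(sim$ko_table, sim$catalogue, strata_mode = "per_species")
contrib <- contributions(scores)
fit     <- differential_contributions(contrib, sim$metadata)
fit
#> Differential contribution test cascade
#>   features tested:      600
#>   significant (adj p < 0.05): 1
#>   BH scope:             global

tidy(fit) |> filter(significant, test == "kruskal_wallis")
#> # A tibble: 1 × 9
#>   module_id species  test  group1 group2 statistic  p_value    p_adj significant
#>   <chr>     <chr>    <chr> <chr>  <chr>      <dbl>    <dbl>    <dbl> <lgl>
#> 1 MF0007    s__Bact… krus… <NA>   <NA>        60.3 5.15e-13 3.09e-10 TRUE
```

Of 600 candidate (module, species) features, exactly the planted one is
flagged: its Kruskal–Wallis H is 60.3 (BH-adjusted *P* ≈ 3×10⁻¹⁰), and
Dunn's post hoc tests mark all three vegan-vs-other pairs significant
(e.g. pescatarian–vegan z = −6.87, adjusted *P* ≈ 4×10⁻¹¹) while no
vegan-free pair is:

```r
tidy(fit) |> filter(test == "dunn", significant) |> head(3)
#> # A tibble: 3 × 9
#>   module_id species  test  group1 group2 statistic  p_value    p_adj significant
#>   <chr>     <chr>    <chr> <chr>  <chr>      <dbl>    <dbl>    <dbl> <lgl>
#> 1 MF0007    s__Bact… dunn  omniv… vegan      -6.16 7.32e-10 2.20e- 9 TRUE
#> 2 MF0007    s__Bact… dunn  pesca… vegan      -6.87 6.59e-12 3.95e-11 TRUE
#> 3 MF0007    s__Bact… dunn  vegan  veget…      5.81 6.42e- 9 1.28e- 8 TRUE
```

`run_all(pipeline_config(...))` orchestrates every stage (ratios, family
aggregates, distance + ordination, core sets, scores, contributions,
cascade) from input files to TSV outputs with a run manifest; a thin CLI
with per-stage subcommands ships in `inst/scripts/gutmodules`. The methods
vignette (`vignettes/gut-metabolic-modules.Rmd`) documents the model,
parameter defaults, generator assumptions and design decisions.

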