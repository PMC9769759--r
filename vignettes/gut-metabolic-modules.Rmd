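---
title: "Scoring gut metabolic modules and testing species contributions across diet groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring gut metabolic modules and testing species contributions across diet groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gutmodules)
library(dplyr)
```

## The scientific problem

Gut microbiomes are famously redundant: many species can perform the same
metabolic function, so two communities with similar functional capacity can
have that capacity carried by different organisms. Comparing cohorts only at
the level of pooled functional profiles therefore misses a biologically
important axis of variation — *which species contribute which functions*.
`gutmodules` implements the analysis pattern for diet-stratified stool
metagenome studies in which taxonomic composition barely differs between
groups (omnivore, pescatarian, vegan, vegetarian) while the species behind
key functions do:

1. **Rule-based module scoring.** KEGG orthologue (KO) abundance profiles
   are condensed into Gut Metabolic Modules (GMMs) — curated, ordered sets
   of reaction steps, each satisfiable by alternative KOs or KO complexes.
2. **Species-stratified scoring and contributions.** With HUMAnN-style
   stratified input, each species' own KO rows are scored separately,
   giving per-species module abundances and relative contribution
   fractions.
3. **A nonparametric test cascade.** Kruskal–Wallis across diet groups per
   (module, species) feature, Benjamini–Hochberg adjustment, then Dunn's
   pairwise post hoc tests within significant features.
4. **Community context.** Bray–Curtis dissimilarity and principal
   coordinates, cross-cohort similarity profiles, bootstrap core-microbiota
   detection, Firmicutes/Bacteroidetes and *Prevotella*/*Bacteroides*
   ratios, and VANISH-family aggregation.
5. **A synthetic-data generator** that emulates the study design end to
   end, so every stage has a testable ground truth without any external
   download.

## Module scoring semantics

A module definition is an ordered list of steps; each step is a set of
alternatives; each alternative is a non-empty set of KOs (a *complex* when
it has more than one member). For a KO abundance vector $x$ (reads per
kilobase, RPK; absent KOs count as 0):

* **alternative (complex) value** — $\min_{k \in \text{complex}} x_k$:
  a complex is limited by its scarcest member;
* **step value** — the **sum** over the step's alternatives: parallel
  routes add capacity;
* **coverage** — the fraction of steps with positive value;
* **module abundance** — the **median** over step values if coverage
  $\ge$ the cutoff, else 0.

```{r}
steps <- list(list("K00001"),                 # step 1
              list("K00002", "K00003"),       # step 2: two alternatives
              list(c("K00004", "K00005")))    # step 3: a complex
score_module(steps, c(K00001 = 10, K00002 = 2, K00003 = 4,
                      K00004 = 6, K00005 = 2))
```

Two tunables matter (`module_scoring_config()`):

* `coverage_cutoff` (fraction, default **0.66**): a module is treated as
  absent unless roughly two thirds of its steps are detected. The cutoff is
  applied after coverage is computed, and the true coverage is always
  reported, so sensitivity analyses over the cutoff need no rescoring.
* `step_aggregation` (`"median"` default, or `"mean"`): the median is
  robust to a single inflated step (e.g. a promiscuous KO shared with an
  unrelated pathway).

The within-step rules (sum over alternatives, min over complex members) are
fixed: they encode the biology of alternatives and complexes rather than a
statistical preference.

Two design points were genuinely open and are worth stating:

* **Per-species scores are computed from each species' own KO rows**, not
  by apportioning the pooled score. Coverage is species-specific: a species
  lacking most of a pathway's steps should not be credited with the module
  just because the community as a whole has it.
* **Contribution denominators are sums of stratum scores** (species plus
  UNCLASSIFIED), not the TOTAL-row score, so fractions are exactly
  normalised; the TOTAL stratum is scored from the unstratified rows and
  kept for reference. When no stratum has positive abundance the fractions
  are undefined and propagate as `NA`, never as 0.

## The test cascade

`differential_contributions()` applies, per (module, species) feature:

1. tie-corrected Kruskal–Wallis across the four diet groups (samples with
   undefined contributions are excluded per feature, not imputed; any
   feature with a group below 3 usable samples is skipped with a warning);
2. Benjamini–Hochberg over the omnibus p-values — across all features by
   default, or within each module (`bh_scope = "per_module"`); the
   multiple-testing family is a genuine degree of freedom in this design,
   so both modes are exposed rather than asserting one;
3. for features passing `alpha` (default 0.05) after adjustment, Dunn's
   z-tests for all six group pairs, using the tie-corrected pooled-rank
   variance, BH-adjusted within the feature.

The UNCLASSIFIED stratum participates in contribution denominators but is
not itself tested: it is not a species. Ties receive average ranks
throughout; the Wilcoxon helper uses exact enumeration for small untied
groups and the normal approximation with continuity correction otherwise.

## Core microbiota

`core_taxa()` implements bootstrap core detection: resample samples with
replacement (same n) `n_bootstraps` times (default 100); in each resample a
taxon qualifies if its prevalence at the detection threshold (relative
abundance strictly greater than `min_relative_abundance`, default 1e-6 as a
fraction, i.e. 0.0001%) reaches `min_prevalence` (default 0.75). "Chosen
using bootstraps" is under-specified on its own, so the retention rule is
explicit: a taxon is core when it qualifies in at least
`bootstrap_retention` of resamples, default **all of them** — conservative
and reproducible; the qualifying fraction is reported per taxon so other
retention rules can be applied post hoc. Profiles are stored in percent;
each sample is renormalised to proportions before thresholding, so percent
and proportion tables behave identically. `shared_core()` reports the
overlap under three denominators (union and either cohort's core), because
"x (y%) shared" statements are ambiguous about the denominator.

## Community comparisons

Bray–Curtis dissimilarity, $\mathrm{BC}(x,y) = \sum_i |x_i - y_i| / \sum_i
(x_i + y_i)$, is computed at species rank on per-sample renormalised
profiles (cross-cohort tables carry unequal unclassified mass, so
renormalisation is enforced rather than optional). Ordination is classical
PCoA; Bray–Curtis is not Euclidean, so negative eigenvalues occur — they
are clamped to zero for variance-explained reporting and no Cailliez
correction is applied (the simplest defensible default; coordinates are
unaffected). Cohort similarity profiles average $1 - \mathrm{BC}$ from each
reference sample to all samples of each target cohort, after aligning
taxon spaces by union with zero fill. Ratios:
Firmicutes/Bacteroidetes at phylum rank, *Prevotella*/*Bacteroides* at
genus rank; zero denominators are flagged undefined by default rather than
pseudocounted, and a pseudocount policy is available. The VANISH family
list (Succinivibrionaceae, Paraprevotellaceae, Prevotellaceae,
Spirochaetaceae) ships as `vanish_families()`; BloSSUM-style lists are
user-supplied since no canonical list exists.

## What the generator emulates — and what it does not

`simulate_dataset()` produces a complete study bundle: MetaPhlAn-style
multi-rank taxon profiles, HUMAnN-style stratified KO tables, metadata and
a module catalogue.

* **Taxa.** A 30-species panel spanning six phyla (`default_taxa()`). Per
  sample, presence is Bernoulli per taxon; composition over present taxa is
  Dirichlet with per-cohort centroids; westernized centroids put high mass
  on Bacteroidaceae and little on VANISH families, non-westernized
  centroids the reverse. Centroids are parameterised as `concentration`
  (default 90) times centroid proportions.
* **Function.** Each species carries each module with probability
  `carry_prob` (0.7); every KO of a carried module gets an independent
  log-normal RPK draw (`meanlog = log(50)`, `sdlog = 0.75`) scaled by the
  species' relative abundance. The UNCLASSIFIED stratum is an independent
  log-normal mass with expected share `unclassified_fraction` (0.3, typical
  of stratified functional profiles); TOTAL rows are exact sums.
* **Effects.** A planted effect multiplies one species' KO rows for one
  module by `fold_change` in one diet group — the level at which the
  biological contrasts of interest live. Because module scoring is
  homogeneous of degree one, the species' module score scales by exactly
  the fold-change; its contribution *odds* scale by the same factor.

Default scale: 4 diet groups × 35 samples = 140 samples, matching a
mid-sized single-cohort diet study; 20 modules × 30 species ≈ 600
candidate (module, species) features.

**Deliberate simplifications.** The generator is a structural emulation,
not a statistical portrait of real cohorts: real stool metagenomes have
hundreds of species, heavier-tailed and more overdispersed abundances than
a concentration-90 Dirichlet, correlated KO noise within genomes, profiler
biases, and unclassified fractions that vary by sample. Passing tests on
synthetic data therefore demonstrate that the pipeline's inference is
correct *when its assumptions hold* — calibrated type-I error, power
against planted multiplicative effects, exact bootstrap behaviour — not
that any particular real cohort would yield the same significance lists.

**The power-study design.** The generator's central contract is that
planted 4-fold contribution effects at the default configuration are
recovered by the scoring + cascade pipeline with high power and precision.
Three design choices make that a fair experiment rather than a lucky one:
effects are planted on species the profiler consistently detects
(`plant_effects()` restricts targets to panel prevalence ≥ 0.9 — power
against an effect in a species absent from 40% of samples is a different,
detection-limited question); each module has many carriers, so a planted
species' share of its module is small and the compensatory (compositional)
shift induced in the *other* carriers stays below detectability — this is
also the realistic regime, since real modules have many contributors; and
"recovered" means the full cascade flags the feature (BH-significant
omnibus *and* at least one significant Dunn pair), which is the flagging
rule used for reporting.

## Numerical choices and degenerate inputs

* Detection is *strictly greater than* the abundance threshold.
* All-identical groups give H = 0 and p = 1 (Kruskal–Wallis) and p = 1
  (Wilcoxon) by convention instead of NaN.
* Zero-abundance modules yield `NA` contributions, excluded per feature.
* Bootstrap resampling, the only stochastic stage of the analysis
  pipeline, derives its seed from the single pipeline seed; the generator
  derives independent stage seeds from its master seed. Fixed seeds give
  byte-identical output TSVs.
* Scores are invariant to KO row order and alternative order; the
  vectorised scorer is tested for *exact* (bitwise) agreement with a
  brute-force evaluator of the definition semantics, including the
  long-double averaging of the two middle order statistics in even-step
  medians.
* An all-absent synthetic sample is redrawn up to 100 times, then errors.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script experiments run at: 1000 randomized
scoring instances (≤5 modules, ≤6 steps, ≤4 species, 6 samples) for oracle
equivalence; 1000 null features at 4 × 35 samples for cascade calibration
(raw omnibus type-I error, expected ≈ the nominal 5%; the BH-adjusted
cascade flags essentially nothing under a complete null); 200 replicates of
the 10-planted-effect recovery experiment; a 300-sample cohort with fixed
per-taxon prevalences and 10 bootstrap seeds for core exactness; and two
20-sample cohorts for the westernized/non-westernized similarity contrast.

## Known limitations

* The shipped module catalogue machinery is generic; it does not include
  any curated GMM catalogue — users supply their own flat file (the
  dialect is documented at `?read_gmm_definitions`).
* No compositional transformation (CLR etc.) is applied before ranking;
  the cascade inherits the compositional coupling of contribution
  fractions, which is mild when modules have many contributors but can
  matter for two-species modules.
* PERMANOVA, covariate adjustment and mixed models are out of scope.
* Reading binary BIOM files or marker-level profiler output is out of
  scope; all IO is TSV and the flat-file catalogue dialect.
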