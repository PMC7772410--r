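# operomer

Evidence-integrated functional annotation of hypothetical proteins — the
uncharacterized "operome" of a prokaryotic genome — built around the
annotation of the rumen methanogen *Methanobrevibacter ruminantium* M1
(756 hypothetical proteins among 2,278 coding genes).

Individual prediction tools are unreliable on such proteins, so the
package integrates six evidence channels (motif, domain, structure,
evolutionary trace, physicochemical, localization) with graded
literature support into a 12-level confidence score:

* **prediction component** (0–6): the number of distinct channels
  agreeing on the winning normalized function label, after filtering
  evidence at e-value ≤ 10⁻⁵ and removing DUF (domain of unknown
  function) hits;
* **literature component** (0–6): the maximum taxonomic provenance of
  matching literature (6 = same organism, 5 = phylogenetic neighbors,
  4 = methanogens, 3 = archaea, 2 = bacteria, 1 = eukaryotes);
* **retention**: an assignment is kept only when *both* components are
  ≥ 3 (combined score 0–12).

Around the score the package provides the full desk pipeline:
sequence-derived physicochemical profiling (molecular weight,
theoretical pI by Henderson–Hasselbalch bisection, instability index
`II = (10/L)·Σ DIWV(x_i x_{i+1})` with the <40 stability rule, aliphatic
index `X(Ala) + 2.9·X(Val) + 3.9·(X(Ile)+X(Leu))`, Kyte–Doolittle
GRAVY), sliding-window transmembrane calling, noisy-OR evidence
combination `S = 1 − Π(1 − sᵢ)` and quality-weighted structural model
averaging, functional categorization into metabolic subsystems,
operon-like gene-neighborhood detection, and a seeded synthetic-data
generator with planted truth so the whole pipeline is testable offline.
Curated annotation tables for the M1 operome ship as package data.

## Worked example

Simulate a study-sized input bundle, run the pipeline, and compare
retention with the planted truth:

```r
library(operomer)

cfg <- generator_config(seed = 20260921)   # 756 proteins, 6 channels
dat <- gen_dataset(cfg)
res <- run_pipeline(dat, out_dir = "results/annotation")
#> [operomer] select: 756 of 756 proteins match candidate keywords
#> [operomer] physchem: 756 profiles computed
#> [operomer] topology: 53 membrane candidates of 756
#> [operomer] score: 256 of 756 retained (prediction and literature >= 3)
#> [operomer] categorize: 256 retained proteins categorized
#> [operomer] neighborhood: 6 clusters over 32 genes
```

256 of 756 simulated proteins (33.9%) survive the dual ≥3 retention
rule, and the decisions equal the planted truth (channel support ≥ 3
and literature level ≥ 3) exactly. The curated tables reproduce the
study's annotation structure:

```r
ann <- load_annotation_tables()
flat <- categorize_annotation(ann)
summarize_assignments(flat, n_candidates = 756)
#> Operome annotation summary
#>   assigned: 153 of 756 candidates (20.2%)
#>   by category:
#>     metabolic_enzyme              119  (77.8%)
#>     transcriptional_regulator      20  (13.1%)
#>     ...
```

and the bundled operon layout resolves into the six named clusters:

```r
cluster_report(detect_clusters(load_operon_layout_fixture()))$label
#> [1] "hsp"  "TRAM" "dsr"  "cbs"  "anti-toxin" "cas"
```

The numbered scripts under `analysis/` run these steps end to end and
write their tables under `results/`:
`01_simulate.R` → `02_annotate.R` → `03_curated_tables.R` →
`04_neighborhood.R`.

## Documentation

The methods vignette (`vignettes/operome-annotation.Rmd`) describes the
confidence model and its design decisions, all formulas and constant
tables, the synthetic generator's assumptions, and known limitations.
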