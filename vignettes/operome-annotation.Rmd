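---
title: "Evidence-integrated annotation of a hypothetical-protein operome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-integrated annotation of a hypothetical-protein operome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operomer)
```

## The problem

A third to three quarters of the predicted coding genes in a newly
sequenced prokaryotic genome are annotated only as *hypothetical
proteins* — gene products with no experimentally assigned function. This
uncharacterized fraction is often called the **operome**. For
*Methanobrevibacter ruminantium* M1, a hydrogenotrophic rumen methanogen
and a prime target for enteric-methane mitigation, 756 of 2,278 coding
genes fall in this class. No single prediction tool annotates such
proteins reliably; the practical approach is to combine several weak
evidence sources and keep only assignments that several of them agree
on and that published experimental work supports.

`operomer` implements that combination procedure as a reusable, fully
offline pipeline: the external prediction tools themselves (InterProScan,
CDD, SMART, PROSITE, Swiss-Model, SIFTER, PSORTb, TMHMM, SignalP, ...)
are out of scope — their outputs are *ingested* as normalized evidence
tables — while every aggregation, scoring, filtering and categorization
step is implemented and tested here.

## The confidence model

Evidence is organized into six **prediction channels** — `motif`,
`domain`, `structure`, `evolutionary`, `physchem`, `localization` —
mirroring the six prediction tasks of the combined approach. The scoring
scheme is:

* **Prediction component (0–6).** After filtering (e-value ≤ 10⁻⁵,
  inclusive; DUF hits removed), function labels are normalized
  (casefolded, punctuation stripped, tokens sorted, synonym map applied)
  and, per protein, each canonical label is credited with the number of
  *distinct* channels supporting it. The label with the highest channel
  count wins and its count is the component: unanimous agreement across
  all six channels scores 6. Ties break by lowest best e-value, then
  lexicographically — deterministic by construction.
* **Literature component (0–6).** Matching literature records are graded
  by taxonomic provenance: 6 = same organism, 5 = phylogenetic
  neighbors, 4 = methanogens, 3 = archaea, 2 = bacteria, 1 = eukaryotes.
  The component is the *maximum* level over records matching the winning
  label (the only monotone choice), 0 if none match.
* **Combined score (0–12) and retention.** The combined confidence is
  the sum. An assignment is retained only when *both* components are at
  least 3; a component below 3 rejects it.

The scheme's published description fixes the endpoints (maximum 12,
unanimity scores 6, the < 3 rejection rule) but not how partial
agreement across 2–5 channels maps to scores; the distinct-channel-count
rule used here is this package's design decision, chosen because it is
the unique monotone interpolation that reproduces both endpoints.
Likewise "50% of the score comes from predictions" is realized as the
6-point prediction component. Supporting channels (`physchem`,
`localization`) contribute labels only through configurable rules and
count like any other channel once present; they cannot outvote three
agreeing sequence/structure channels because a channel contributes at
most one vote.

Two printed combination formulas from the structural and evolutionary
channels are provided as primitives. The noisy-OR evidence combination
`sifter_combine()` computes `1 - prod(1 - s_i)`. The composite model
score `qmean5()` uses coefficients (0.3, 0.17, 0.7, 80, 45) exactly as
published in the procedure this package implements; they are knowingly
inconsistent with the original QMEAN publication's weights, so the
coefficient vector is a function argument and can be substituted.

## Physicochemical properties

All formulas operate on the 20 standard residues only; ambiguity codes
(B, Z, X, U) are rejected by default and excluded from property sums in
permissive mode, because the printed formulas are undefined for them.

* **Instability index**: `II = (10/L) * sum(DIWV(x_i x_{i+1}))` over the
  L−1 overlapping dipeptides, with the published 400-entry Guruprasad
  dipeptide weight table shipped as data. II < 40 classifies *stable*;
  exactly 40 classifies *unstable* because the published rule defines
  stability strictly as "< 40".
* **Aliphatic index**: `X(Ala) + a·X(Val) + b·(X(Ile)+X(Leu))` in mole
  percent, with Ikai's coefficients a = 2.9, b = 3.9 as defaults (the
  procedure names a and b but prints no values).
* **GRAVY**: mean Kyte–Doolittle hydropathy per residue (the scale
  GRAVY is conventionally defined on).
* **Molecular weight**: average residue masses plus one water.
* **Theoretical pI**: the root of the Henderson–Hasselbalch net-charge
  curve (EMBOSS pKa set, swappable via the config), found by bisection
  on pH 0–14 to 10⁻⁴ pH units. Net charge is strictly decreasing in pH,
  so the root is unique; tests verify bisection against a dense grid
  scan to 0.01.

Property values are kept at full precision internally; pipeline TSVs
print 4 decimals (fixed formatting, so re-runs are byte-identical) and
reports round to 2.

## Transmembrane calling and localization

`predict_tm_segments()` is a transparent hydropathy-window caller:
window means (default window 19) above a threshold (default 1.6) at
each full-window center form runs, runs extend to window bounds, merge,
and survive if at least 15 residues long — the classic Kyte–Doolittle
transmembrane heuristics, used because the upstream HMM tools are out
of scope and published parameters are not stated. Localization is a
three-rule classifier: any TM segment → membrane; ingested
signal-peptide evidence without TM → secreted; otherwise cytoplasmic.
Signal peptides are never predicted, only ingested.

## Functional categorization

Retained assignments are categorized by an ordered rule list — EC
number present → metabolic enzyme (the strongest categorical signal in
curated tables); then regulator/repressor/transcription-factor,
transporter/permease/antiporter/translocase, binding, and cell-cycle
keywords; fallback `other`. Metabolic enzymes additionally resolve a
subsystem code (AAB, AAT, ACD, C1UA, CHB, CSB, CPEB, FALB, GPME, INM,
NNB, PMR, RR, SMD, tRR, OTR) from the section heading of the curated
metabolic table through a user-extensible map; headings without a
dedicated code (e.g. "Small molecule reactions") map to OTR. Fold-class
tallies are supported verbatim through an optional `fold` evidence
column; no fold recognition is performed.

The package ships machine-readable reproductions of the curated
annotation tables (cell division: 5 rows naming 9 distinct proteins;
transcriptional regulation: 10 rows, 25 distinct loci; metabolic
subsystems: 119 locus-level enzyme assignments). The recorded headline
counts of the source dataset are available via `dataset_notes()`; it
deliberately preserves two internally inconsistent printed pairs (the
"73%" operome fraction vs 756/2278 ≈ 33%, and 96 vs 119 metabolic
enzymes) without reconciling them, and none of those numbers is used as
a test oracle.

## Operon-like neighborhood detection

`detect_clusters()` is a single linear scan over start-sorted loci: a
cluster of hypothetical-protein genes breaks when the intergenic gap
exceeds `max_gap`, the strand changes, or a known-function gene
intervenes; clusters need at least `min_size` genes. "Operon-like" has
no published quantitative definition here, so the defaults — 200 bp
gap, 2 genes, same strand, non-HP genes break — are standard prokaryotic
operon heuristics and are documented as this package's choice. A
bundled **synthetic** layout (`load_operon_layout_fixture()`) realizes
the six reported gene arrangements (hsp, TRAM, dsr, cbs, anti-toxin,
cas; 32 HP genes in total) with plausible gene sizes and spacings,
because the source states the structure but prints no coordinates.
Correctness is tested against a brute-force transitive-closure oracle
on random layouts.

## The synthetic-data generator

`generator_config()` defines the simulated study conditions:

* 756 candidate proteins (the study's candidate count), lengths uniform
  60–400 residues, residue-i.i.d. uniform composition;
* each channel reports the planted label with probability 0.5 — a
  neutral coin per channel, chosen once because the study reports no
  per-tool agreement rates;
* literature levels uniform over 0–6 (0 = no record), again a neutral
  default in the absence of published level frequencies;
* e-values log-uniform in 10⁻²⁰–10⁻⁸ (below the filter cutoff, so the
  truth table's support counts are realized exactly), 5% DUF
  contamination;
* decoy labels drawn from a per-protein, per-channel disjoint namespace
  so the planted truth is unambiguous (a colliding-decoy mode exists for
  stress tests), and e-values independent of correctness by default
  (a signal mode ties low e-values to true labels for tie-break tests).

Under these conditions the planted-truth recovery property — *retained
⇔ realized channel support ≥ 3 and literature level ≥ 3* — holds
exactly, and the expected retention rate is
`P(Binom(6, 0.5) ≥ 3) × 4/7 ≈ 0.375` before DUF losses. What the
generator does **not** emulate: realistic protein composition,
homology structure between proteins, correlated tool errors, or real
tool output formats. Passing tests therefore demonstrate the logic of
the integration procedure, not the accuracy of any upstream predictor
on real proteomes; the study's dataset-level headline numbers (257 of
756 annotated, 91 membrane proteins, ...) depend on running external
web tools on the real proteome and are not reproduced here.

## Numerical and degenerate-input choices

* E-value cutoff comparison is inclusive (`≤ 10⁻⁵`).
* The DUF pattern is a word-bounded `DUF<digits>` token in the label or
  identifier, case-insensitive.
* Label normalization sorts tokens, making it order-insensitive but
  also conflating reorderings; the synonym map handles true synonyms.
* pI of an all-positive (or all-negative) charge curve clamps to the
  scan bounds 0/14; sequences shorter than the TM window warn and
  return no segments rather than erroring.
* `weighted_model_average()` refuses a zero weight sum;
  `combined_confidence()` validates component ranges.
* Problem sizes in the test suite (2,000-protein recovery runs over 20
  seeds, 100-layout oracle comparisons, 100-sequence property checks)
  were chosen to exercise the asymptotics the invariants rely on while
  keeping the suite around a minute of CPU.

## Limitations

* Scores quantify *agreement*, not correctness: six tools sharing a
  biased database can agree confidently and wrongly.
* The channel-count rule treats channels as exchangeable and
  independent; no channel weighting is attempted.
* The hydropathy TM caller is a heuristic stand-in for topology HMMs
  and makes no inside/outside orientation calls.
* Categorization keywords are English-surface rules; curated EC numbers
  are the only robust categorical signal.
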