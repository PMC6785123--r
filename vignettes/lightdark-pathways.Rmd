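---
title: "Light and dark pathway analysis: model, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light and dark pathway analysis: model, conventions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathlight)
```

## The question the package answers

Targeted therapy options for many solid tumors are thin, while most
approved cancer drugs have well-characterized protein targets outside
their registered indications. `pathlight` asks, for a cohort of tumors
with somatic mutation and/or copy-number data: *which biological pathways
are recurrently hit across the cohort, and which of those are already
reachable by an approved cancer drug?* Enriched pathways containing at
least one drug-target gene are **light** (repurposing candidates);
enriched pathways containing none are **dark** (future drug-development
space). Because pathway databases are hierarchical, a dark pathway may
additionally sit beneath a light ancestor, which the nesting annotation
flags as an indirect targeting opportunity.

## Cohort construction

Mutations are consumed as MAF-like rows (sample barcode, gene symbol,
variant classification) and filtered to high/moderate-impact classes:
missense, nonsense, nonstop, frameshift insertion/deletion, in-frame
insertion/deletion, splice site and translation start site. Low/modifier
classes (UTRs, flanks, intron, intergenic, RNA, silent, splice region)
are excluded, and classes in *neither* list are dropped with a warning
rather than an error, because the MAF class vocabulary drifts across data
releases. Copy-number input is a GISTIC-thresholded gene × sample matrix;
only ±2 calls (high-confidence deletions/amplifications) are retained,
and the sign is then discarded — the analysis treats "deleted" and
"amplified" as one *altered* state, because the pathway-level question is
where aberrations concentrate, not their direction.

Gene symbols are normalized through a user-supplied synonym map (approved
symbols map to themselves, aliases map through the table, everything else
is reported as unmapped). The map is a file, not a live service, so runs
are reproducible offline. Symbols are compared case-sensitively after
whitespace trimming, since approved human gene symbols are
case-significant.

The retained records are aggregated into an *aberration profile*:
per-patient sets of aberrant genes with the transposed gene→patients map
kept consistent. The **cohort size** — the denominator of every
cohort-coverage proportion — counts patients with at least one *retained*
aberration of the matching data type, so mutation and copy-number tables
(and each HPV stratum) each use their own denominator.

## The over-representation test

Let `N` be the number of genes belonging to at least one pathway (the
*universe*), `m` a pathway's size, `K` the number of aberrant genes inside
the universe, and `k` the number of aberrant pathway members. The test
treats the pathway as a draw of `m` genes from the universe and computes
an upper-tail hypergeometric probability. Two conventions are
implemented:

* `tail = "ge"` (default): the inclusive tail `P(X >= k)`. This is the
  standard over-representation convention: it is a valid p-value (its
  null distribution is stochastically no smaller than uniform), so the
  downstream false-discovery-rate control is trustworthy in every regime.
* `tail = "gt"`: the exclusive tail `P(X > k)`, i.e. one minus the
  inclusive CDF at `k`. Its defining property is that a *fully covered*
  pathway (`k = m`) has `p` exactly 0 and survives any multiple-testing
  correction.

The two conventions matter because cohort-level binarization saturates:
with several hundred patients, most universe genes are aberrant in at
least one patient, so `K/N` approaches 1 and even a fully covered pathway
has an unremarkable inclusive-tail p-value (approximately `(K/N)^m`). In
that regime only the exclusive tail has power, and it concentrates all of
it on fully covered pathways — which is why ranked tables produced under
it are dominated by pathways with pathogenicity 1. The price is that
`P(X > k)` is anti-conservative as a p-value (it equals the inclusive
p-value of `k + 1`), so in saturated cohorts it will also light up fully
covered pathways under the null; it should be read as a
screening/replication convention, not a calibrated test. We keep the
valid inclusive tail as the default and expose the exclusive tail as an
explicit option; the validation suite exercises false-discovery control
with `"ge"` and planted-signal recovery in a saturated cohort with
`"gt"`, because each property belongs to the convention that claims it.

Aberrant genes outside the universe are excluded from `K`: the population
of the test is the pathway gene space, and in real cohorts a large
fraction of mutated genes map to no pathway. Pathways with `k = 0` are
still tested (at `p = 1`) so that the multiple-testing multiplicity is
always the full pathway count. The test is symmetric in `m` and `K`, so
the "genes-as-draws" versus "pathway-as-draws" orientation does not
affect results. If `K = 0` the run degenerates: all p-values are set to 1
with a warning (this also guards the exclusive tail, for which
`P(X > 0) = 0` would otherwise mark everything significant).

Adjustment uses Benjamini–Yekutieli (BY), which controls FDR under
arbitrary dependence — appropriate because pathway membership overlaps
heavily and hierarchically nested pathways are near-duplicates of their
parents. BY inflates Benjamini–Hochberg by the harmonic factor
`c(n) = 1 + 1/2 + … + 1/n`; q-values are reported unrounded and pathways
with `q < alpha` (default `alpha = 0.05`) are enriched.

## Drug-target evidence and the light/dark call

Drug–target interaction rows carry an evidence level: I (interaction
reported only), II (literature support), III (at least one experimental
binding value, in nM). A level-III row without a binding value violates
its own definition and is rejected at parse time. Per target, summaries
keep the *maximum* evidence level and the *minimum* (strongest) binding
value across that target's interactions.

The light/dark call itself uses target **presence only**: an enriched
pathway with ≥ 1 targeted member gene is light, with none is dark. No
evidence-level floor or binding cutoff is applied by default — those are
reporting filters (an optional `min_evidence_level`, and a strict
`< 1000` nM binding filter for per-pathway drug listings), because
whether a pathway is in reach of the pharmacopoeia is a different
question from which specific interactions are strong enough to list.
Target coverage (percentage of a pathway's genes that are targets) is
rounded half-away-from-zero to an integer percent, so 4 targets among 22
genes reports as 18%. Targets whose symbols fail normalization are
excluded with a log message.

## Prioritization, overlap, nesting

Enriched pathways are ranked descending by pathway pathogenicity
(proportion of member genes aberrant anywhere in the cohort), then
descending by cohort coverage, then ascending by display name. The name
tie-break is our own addition — the first two keys tie frequently (many
pathways reach pathogenicity exactly 1) and a total, deterministic order
is a prerequisite for reproducible reports. Ranks are assigned separately
within each (data type, label) table. Proportions are reported to 8
decimals; partition summaries round percentages to integers.

Mutation and copy-number runs are compared on pathway identity within
matching label (light-in-both, dark-in-both, exclusives). The nesting
annotation walks **all** transitive ancestors in the pathway hierarchy,
not just immediate parents: a dark pathway whose direct parent is not
itself enriched can still sit beneath an enriched light grandparent, and
that is precisely the pattern worth surfacing. The hierarchy must be
acyclic; a cycle is a structural error reported with one offending cycle.

## HPV stratification

Tumor HPV status is assembled from three annotation sources into
confidence tiers: primary-source positive with whole-genome sequencing
available, or positive with corroboration from either secondary source →
highest-confidence positive; positive with neither → high-confidence
positive; primary-source negative with WGS → high-confidence negative;
everything else unclassified. The primary source takes precedence on
conflict. Stratified reruns use only highest-confidence positives as the
HPV-positive cohort and high-confidence negatives as the HPV-negative
cohort, each with its own cohort-size denominator.

## The synthetic-data generator

The generator exists so that every pipeline stage can be validated
against known truth without any data download. It emulates: a pathway
database with configurable size, overlap and an acyclic level-structured
hierarchy; per-patient aberrations as independent Bernoulli draws per
gene (background rate, overridden by a planted per-pathway member rate);
MAF-like mutation rows whose true events always carry an included impact
class, plus excluded-class decoy rows that exercise the impact filter
without touching the truth bookkeeping; copy-number matrices with ±2
calls for true events and ±1 decoys that the threshold removes; a tiered
drug–target table seeding a configurable fraction of pathways (level mix
defaulting to 1% I / 15% II / 84% III, level-III values log-uniform in
0.1–10^4 nM); and clinical tables realizing requested HPV stratum sizes.
Identical seeds reproduce identical output bytes, and the generators
restore the caller's RNG stream.

Deliberate simplifications: aberrations are independent across genes and
patients (no mutational signatures, no gene-length effect, no
segment-level copy-number correlation), all patients share one rate, and
drug names are abstract labels. Passing tests therefore demonstrate that
the statistical machinery and bookkeeping are correct under the stated
model — not that the model captures the correlation structure of real
tumor cohorts.

Default study conditions (used throughout the validation suite): 50
pathways of 20 genes over a 1000-gene universe, 100 patients, background
rate 0.02 per gene per patient, planted member rate 0.5. At these
settings a gene is aberrant in ≥ 1 of 100 patients with probability
`1 − 0.98^100 ≈ 0.87` — an intentionally saturated regime mirroring real
cohorts, and the reason the tail-convention discussion above is not
academic.

## Validation suite and problem sizes

The test suite validates: the hypergeometric tail against exhaustive
enumeration via binomial coefficients for every parameter combination
with `N ≤ 60` (tolerance 1e-12); BY against the hand-computed step-up
formula and elementwise dominance over BH on 1000 random vectors;
false-discovery control on 200 seeded null cohorts (inclusive tail;
fraction of runs with any enrichment bounded by `0.05 + 3` binomial
standard errors); planted-pathway recovery on 100 seeded cohorts at the
default study conditions (exclusive tail; ≥ 95% recovery, and light/dark
labels matching generator truth in 100% of runs — the classification is
deterministic given enrichment); nesting against brute-force transitive
closure on 50 random 100-node hierarchies; and byte-identical end-to-end
reruns under fixed seeds. Worked-example arithmetic (8-decimal cohort
proportions, integer coverage and partition percentages, the < 1000 nM
drug count) is asserted against hand-verifiable values. These sizes keep
the whole suite under a minute on one CPU while leaving each statistical
check adequately powered.

## Numerical and edge-case choices

* Proportions are rounded half-away-from-zero to 8 decimals; integer
  percentages likewise. R's default half-to-even rounding would differ on
  exact half-way cases.
* `alpha = 0` is allowed in `enrich_pathways()` and enriches nothing
  (useful as a null switch); `run_config()` requires `alpha` in (0, 1).
* Readers default to lenient mode (drop-and-log malformed rows) because
  public cohort files contain malformed rows; strict mode turns the same
  conditions into errors. Structural problems (unknown evidence levels,
  non-integer copy-number calls, hierarchy cycles, contradictory
  duplicate HPV rows) are always errors.
* Patient IDs default to the full sample barcode, with optional
  truncation to a configurable number of dash-separated fields.
* Binding values are compared in nM with no unit conversion; input must
  already be nM-denominated.

## Known limitations

Cohort-level binarization discards per-patient aberration counts and
cannot distinguish one highly mutated patient from many moderately
mutated ones; the cohort-coverage metric partially compensates. The
light/dark call ignores drug directionality (an activating aberration and
an inhibitor may not match). Expression data, rank-based enrichment and
survival association are out of scope. The exclusive-tail convention
should not be combined with FDR interpretation in saturated cohorts, as
discussed above.
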