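---
title: "Auditing a DNA barcode reference library: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a DNA barcode reference library: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refaudit)
```

`refaudit` audits aligned barcode reference libraries: alignment and
reading-frame QC, haplotype collapsing, pairwise divergence, local
barcoding-gap detection, distance-gap MOTU delimitation, and
morphology-versus-cluster congruence. This vignette explains the models
and conventions behind each stage, the parameters that matter, and the
design choices made where more than one reasonable convention exists.

## Input model and the missing-symbol convention

The unit of analysis is a *reference set*: an aligned nucleotide matrix
joined to per-specimen metadata (species name from morphology, an
a-priori cluster label, family, and free columns). It is represented as a
plain tibble — one row per specimen, `sequence` as an uppercase string —
so the whole dplyr vocabulary applies between pipeline stages.

A single convention defines "missing" everywhere: any symbol outside
A/C/G/T — gaps, `?`, `N`, and *all* partial IUPAC ambiguities (R, Y, …).
Partial ambiguities could in principle be matched probabilistically, but
raw-distance practice treats them as missing, and using one set for site
statistics, haplotype collapsing and distances keeps the stages mutually
consistent: a column that contributes no state to site statistics also
contributes no comparison to any distance.

Coordinates are 0-based and half-open: the barcode trimming window is
`[offset, offset + 658)` by default, matching the standard animal-barcode
(Folmer) fragment length. The reading frame of a trimmed fragment is not
knowable from the alignment alone, so `check_stop_codons()` defaults to
`frame = "auto"`: all three frames are screened and the one with the
fewest stop codons is kept (ties resolved to the lowest frame index, for
determinism). The default genetic code is invertebrate mitochondrial, in
which only TAA and TAG terminate; codons containing a missing symbol are
skipped rather than guessed.

## Haplotype collapsing

Two policies are exposed. `strict` equates sequences only when equal at
every column. The default `ambiguity_tolerant` policy — the behaviour
advertised by the Collapsetypes family of tools — lets missing symbols
match anything: two sequences conflict only where both carry unambiguous,
different bases. That compatibility relation is not transitive (`ANG` is
compatible with both `AAG` and `ACG`, which conflict with each other), so
some grouping rule must be chosen. We group greedily in record order, and
a record joins the first haplotype *all* of whose members it is
compatible with; otherwise it founds a new haplotype. This keeps every
haplotype internally pairwise-compatible (an invariant the tests
re-check), makes the result a deterministic function of record order, and
guarantees `strict` never yields fewer haplotypes than
`ambiguity_tolerant`.

## Distances

Divergence is the uncorrected p-distance under pairwise deletion: for
each pair, only columns where both sequences carry an unambiguous base
are compared, and the distance is the mismatch fraction over those
columns. No substitution-model correction is applied — for barcode-gap
audits the observed divergence is the quantity of interest, and
model-corrected distances would only stretch the scale. The per-pair
compared-site count is kept alongside the distance: with ~3–4% missing
data the effective overlap varies by pair, and a distance over 20 sites
should not be trusted like one over 600. A pair with *zero* comparable
columns gets a flagged `NA` distance rather than an error; downstream
summaries drop such pairs and warn with their count. Internally the full
matrix is computed from per-base indicator matrices with four matrix
products, so the cost is a few dense multiplications rather than an
O(n²·L) interpreted loop; the test suite verifies exact agreement with a
naive per-column oracle and with `ape::dist.dna(model = "raw",
pairwise.deletion = TRUE)`.

Distances are stored as proportions throughout and converted to
percentages (one decimal place) only at report boundaries, so no rounding
ever happens inside a computation.

## Cluster audit and the local barcoding gap

For each cluster the audit reports min/mean/max intra-cluster distance,
the nearest-neighbour (NN) cluster — the other cluster containing the
sequence at minimum distance from any member — and the gap flag
`intra_max < nn_distance`. Three conventions needed fixing:

* **Strict inequality.** Equality of `intra_max` and NN distance counts
  as overlap, since the defining condition is that the maximum
  within-species distance be *smaller* than the distance to the nearest
  species.
* **Singletons.** A single-sequence cluster has no intra-cluster pairs;
  its summary statistics are reported as `NA`, but for the gap test
  `intra_max` is taken as 0 so that singletons — common in real reference
  libraries — remain evaluable: they show a gap whenever their NN
  distance is positive.
* **Pooled means.** The overall within- and between-cluster means pool
  all pairwise distances, rather than averaging per-cluster means: that
  is the natural reading of an "overall mean" and weights each sequence
  pair equally. The "mean range" quoted for between-cluster divergence
  is, by contrast, computed over per-cluster-pair means, which is the
  scale on which closest and farthest cluster pairs are usually reported.
  Both views are available (`summarize_audit()` returns the per-pair
  means table).

NN ties are broken by lexicographic cluster name, again for determinism.

## MOTU delimitation by threshold scan

`delimit_motus()` sweeps all informative thresholds in a prior range —
midpoints between consecutive distinct pairwise distances, clipped to
`[lo, hi]`, plus the bounds themselves; the default range 0.005–0.05
covers the usual prior on conspecific barcode divergence. At each
threshold single-linkage components (chains of pairs at distance ≤ t)
form the candidate MOTUs. Single linkage was chosen over average or
complete linkage because it is the linkage that threshold-based barcode
clustering actually implies, and because it makes the scan provably
monotone: the number of groups is non-increasing in t and each finer
partition refines every coarser one — both asserted as properties in the
test suite.

Each candidate partition is scored by its narrowest local gap,
`min_c (NN(c) − intra_max(c))` (singletons contributing 0 intra), and the
selected partition maximises this score, with ties resolved toward fewer
groups and then toward the smaller threshold. This gap-width score is a
deliberate simplification of composite probability/rank scores used by
recursive partitioners (ASAP and relatives): the phenomenon those scores
chase is the existence of a distance gap, and the gap width is the
directly testable analogue. The package therefore does not promise to
reproduce any particular ASAP partition, and tree-based delimitation
(PTP/mPTP) is out of scope — externally produced MOTU tables can instead
be imported as an ordinary partition and compared with
`compare_partitions()`.

Pairs with undefined distance are treated as farther than `hi` — they can
never link. This is the conservative choice: linking through a
zero-overlap pair would let two sequences cluster on no evidence at all.
A partition with a single group has no between-cluster distance and is
given a score of −∞, so it is selected only when every candidate
threshold yields one group (e.g. an all-identical library).

## Congruence classification

With clusters as the unit, categories are derived from the species ×
cluster contingency: a species is *split* when its members occupy ≥ 2
clusters, and a cluster is a *match* (one name, not split), *lump* (≥ 2
names, none split), *split* (one split name), or *both*. The categories
are mutually exclusive and exhaustive, and the test suite checks the
implementation against an independent recomputation from the raw
contingency table on a thousand random partition pairs.

Specimens excluded from the assessment (typically morphologically
ambiguous larvae or females) are removed *before* split status is
evaluated, so a species is judged only on the analysed ids; specimens
with empty species names are auto-excluded with a warning rather than an
error, because real metadata contains unidentified material. A cluster
whose members are all excluded is reported as `excluded` rather than
silently dropped, keeping the category counts summing to the cluster
count.

## The synthetic library generator

`simulate_reference_set()` generates libraries with the divergence
structure the audit assumes, plus full ground truth. The model is a star
genealogy per species: one random root sequence; each species ancestor
mutated from the root independently per site with probability
`between_divergence / 2`; each specimen mutated from its ancestor with
probability `within_divergence / 2`; mutations go to a uniformly chosen
alternative base. A coalescent within species would be more realistic but
is unnecessary: the audit consumes only pairwise distances, and the star
model hits the intended mean-divergence structure with far less
machinery.

The per-site "mutate with probability r to a uniform alternative" kernel
is exactly a Jukes–Cantor step, and such steps compose in closed form:
`M(a)M(b) = M(c)` with `(1 − 4c/3) = (1 − 4a/3)(1 − 4b/3)`. Two tips at
composite per-site rate c from their common ancestor mismatch with
probability `2c − (4/3)c²`. `expected_pairwise_divergence()` computes
this expectation from the explicit 4×4 matrices (the closed form is
checked against it in the tests, and the generator against both by
simulation at long sequence length). With the defaults —
`within_divergence = 0.008`, `between_divergence = 0.186` — the exact
expectations are ≈ 0.00798 within and ≈ 0.1806 between; the between
expectation sits ~3% below the nominal target because the two
root-to-ancestor steps can hit the same site, which is the accepted
behaviour of this parameterisation rather than something to re-tune.

Defaults emulate a curated regional CO1 library: 20 species × 5
sequences (typical per-species sampling in such libraries), 658 bp, 3.6%
missing data injected as `N` (exercising the single missing-symbol
convention), stop codons avoided in frame 0 by resampling third codon
positions (so the frame=auto screen has a true frame to find). Label
perturbations are applied last: a *lump event* rewrites one species'
labels to another species' name; a *split event* renames half (floor) of
one species. Affected species are drawn without replacement, so injected
events map 1:1 onto congruence categories when the written labels are
compared against the truth — which is how the tests recover event counts
exactly.

What the simulator does *not* emulate: rate heterogeneity across sites,
codon structure beyond stop avoidance, geographic/population structure,
introgression, NUMTs, or uneven cluster sizes beyond the per-species
count vector. Passing the recovery tests therefore shows the pipeline's
statistics are computed correctly under the assumed divergence structure;
it does not show the audit would be similarly clean on real libraries,
where overlapping divergence distributions are precisely the interesting
cases.

## Problem sizes and determinism

The bundled validation runs use 20 replicate libraries of 100 sequences ×
658 bp — large enough that pooled divergence means are stable to well
under the ±10–20% recovery bands, small enough to keep the whole suite
interactive. Every stochastic step flows from a single integer seed
(replicate seeds are drawn once from the master seed), and every
tie-break in the pipeline (greedy haplotype order, NN ties, threshold
selection, frame ties) is specified, so identical inputs give
byte-identical reports apart from the timestamp in the provenance block.

## Known limitations

* The gap-width score is not an ASAP score; on libraries with graded
  divergence structure the selected threshold may differ from ASAP's
  partition even when both are defensible.
* Pairwise deletion means different pairs are measured on different site
  sets; with heavy, non-random missingness (e.g. mixed mini-barcodes)
  distances are not strictly comparable across pairs. The `n_compared`
  matrix is exposed so users can filter.
* Congruence classification treats cluster labels as given; it does not
  re-derive clusters from a tree, and it has no notion of "how wrong" an
  incongruent cluster is beyond its category.
* The ambiguity-tolerant haplotype count depends on record order (a
  consequence of non-transitive compatibility); the order-dependence is
  documented and deterministic, not removed.
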