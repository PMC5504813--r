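---
title: "Utility-preserving k-anonymization with a generalization ceiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Utility-preserving k-anonymization with a generalization ceiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anonceil)
```

## The problem

Health-data custodians who publish record-level tables must prevent
re-identification through quasi-identifiers (QIs) such as age, sex and
zipcode. The standard remedy, *k*-anonymity via full-domain generalization,
replaces QI values with ranges or taxonomy ancestors until every record is
indistinguishable from at least *k* − 1 others. Its chronic failure mode is
over-generalization: a handful of outlier records force the whole table into
enormous ranges, destroying analytic value. Prior fixes — suppressing or
relocating the outliers — sacrifice *data truthfulness*: published records no
longer correspond to real people, so analyses can return false positives and
negatives.

`anonceil` implements an alternative: cap the damage generalization may do,
and repair the resulting k-anonymity deficits with clearly-accounted-for
synthetic rows.

## The model

**Generalization degree.** For a numeric attribute with domain $[L, U]$
generalized to $[L_q, U_q]$, the degree is
$D_A = (U_q - L_q)/(U - L)$; for a categorical attribute generalized to a
taxonomy node covering $|M_p|$ of the $|M|$ leaves, it is
$D_A = (|M_p| - 1)/(|M| - 1)$. A record's degree $D(r)$ is the mean of its
per-QI degrees. Both lie in $[0, 1]$: 0 means exact, 1 means the value
carries no information.

**h-ceiling.** A published table satisfies the *h*-ceiling iff
$D(r) \le h$ for every record. This is the utility guarantee: no record is
generalized beyond the chosen ceiling. An immediate corollary is that the
loss metric LM — the mean per-cell degree — is also at most $h$.

**Counterfeit records.** Under a tight ceiling, some equivalence classes
(maximal sets of records with identical generalized QI signatures) will hold
fewer than *k* members. Rather than widening their signatures, the method
inserts *counterfeit records*: rows that copy the class's QI signature and
draw a sensitive value at random. Every class then has $\ge k$ rows at every
lattice node, so k-anonymity always holds.

**The catalog.** To restore truthfulness, the publisher discloses how many
counterfeits of each sensitive value exist — but naming the class would let
an adversary delete the counterfeit and break k-anonymity. The catalog
therefore reports counts per *group* of classes, `(class-id list, sensitive
value, count)`. A group is safe when, for every member class and value *s*,
the counterfeits of *s* there are matched by at least as many *real* records
of *s* in the group's other classes: by pigeonhole, every candidate location
of the counterfeits then has an alternative, so no record (and no class) can
be pinned down. `is_safe_group()` tests the condition; `group_catalog()`
builds a safe grouping greedily, seeding with the classes hardest to conceal
(largest counterfeit totals) and merging each with the partner offering the
largest matched concealment count, real records being pledged
one-per-counterfeit. Pledging is deliberately stricter than the bare safety
condition — it guarantees every emitted group is safe by construction, at the
price of occasionally returning `NULL` for instances a cleverer grouping
could save; a `NULL` catalog simply makes the search discard that node.
Recipients who need truthful data apply `truthful_view()`: per entry, up to
*count* rows of the named value are QI-suppressed in each class of the group,
the *count* counterfeits are removed, and the rest survive with masked QIs —
the output has exactly the original number of real records.

**Reconstruction error (RCE).** Utility is scored by comparing, for every
real record, the probability density a recipient would infer for it before
and after anonymization:
$RCE = \sum_t \int (\tilde{\mathcal G}_t(x) - \mathcal G_t(x))^2\,dx$.
The original density is a unit mass on the record's exact cell per attribute;
the anonymized density is uniform over the generalized region. When the
record's class sits in a catalog group holding counterfeits of the record's
own sensitive value, all its densities shrink by the factor
$o/(o + c)$ (real over real-plus-counterfeit in the group) — in the
seven-record demo below the factor is $3/4$, i.e. a 25% chance the record is
counterfeit. On the integer cell grid, each attribute's integral has the
closed form $(1 - s/w)^2 + (w - 1)(s/w)^2$ for region width $w$ and scale
$s$, which the implementation uses directly; `record_density()` materializes
the density vectors for inspection. Counterfeit rows contribute no terms of
their own — their entire effect is the down-weighting of real records.

The RCE integral is implemented as a sum of per-attribute one-dimensional
integrals (QIs plus the sensitive attribute), matching the per-attribute
density model; a joint-product formulation over the full dimensional space
would be an alternative reading, but the per-attribute decomposition
reproduces all the desk-scale quantities (including the 3/4 scaling) and
keeps RCE additive over records and attributes, which the tests exploit.

## The search

Full-domain generalization choices form a lattice: one level per QI, bottom =
exact data, top = everything at maximum level. `anonymize()` walks it
bottom-up. The record degree is monotone along lattice edges (a parent
node's class is a union of child-node classes, so its region contains
theirs), so once a node violates the ceiling all its ancestors are pruned
unevaluated. Each surviving node is anonymized end to end — generalize,
insert counterfeits, group the catalog — and scored; nodes whose catalog is
`NULL` are discarded. The winner minimizes RCE, with ties broken by LM, then
total level, then the lexicographic node vector. With `h = NULL` the whole
lattice is searched and the winner's maximum record degree is reported as
`h_used`.

Counterfeit sampling uses one master seed with an independent substream per
node keyed by the node vector, so evaluation order cannot change results and
fixed inputs are bit-reproducible.

### Numerical and design choices

* **Tight intervals.** The published numeric signatures are collapsed to the
  members' `[min, max]` after grouping (`tighten = TRUE`, the default), and
  feasibility, LM and RCE are computed on these tightened signatures — that
  is what the worked examples require (a width-10 age bin holding ages 35–37
  is published, and scored, as `[35-37]`). Monotonicity survives tightening,
  so pruning stays sound. `tighten = FALSE` preserves the literal fixed-bin
  reading.
* **Feasibility comparisons** use `D(r) <= h` with a `1e-9` float guard;
  printed two-decimal degrees elsewhere are rounded displays of full-precision
  values.
* **Bins** are anchored at the domain minimum, half-open, clipped at the
  maximum, on an integer grid; level-0 width is 1. Degenerate domains
  (`U = L`) and single-leaf taxonomies are configuration errors since the
  degrees are undefined.
* **Counterfeit sensitive values** default to the `empirical` strategy
  (frequency-weighted over the whole table). The model only requires a
  random draw from the sensitive domain (`uniform` implements that literal
  reading), but empirical sampling makes the drawn values far likelier to be
  concealable — a value with no real occurrences elsewhere can never satisfy
  the safety condition — and it distorts the sensitive marginal less.
* **Classes are numbered** in order of first member appearance; greedy
  tie-breaks prefer candidates with fewer own counterfeits, then lower class
  ids. Both choices exist purely for determinism.
* **No re-sampling:** when a node's counterfeit draw turns out unconcealable
  the node is discarded rather than redrawn, keeping each node's evaluation a
  pure function of (table, k, node, seed).

## Queries on generalized data

`run_query()` evaluates count/mean aggregations with per-attribute filters
and grouping on the original table, the published rows, or the truthful
view. A generalized row contributes to a predicate by its uniform-overlap
fraction (size of region ∩ predicate over region size), multiplied over filtered
attributes — the same uniformity assumption as the RCE density model. Means
use region midpoints as the per-row expected value; fully suppressed rows
span the whole domain. `query_error_rate()` reports the mean over groups of
$|est - truth| / \max(truth, 1)$; the floor-1 denominator avoids division by
zero on empty groups. The per-group-mean error definition is this package's
own choice and is stated here precisely because alternative aggregate
definitions exist.

## Synthetic tables

`default_ehr_spec()` generates the EHR-like tables used in the randomized
tests: an age-like QI drawn from two clusters (means 32 and 63, sd 4–5) with
10% uniform outliers, a zipcode-like QI with two tight clusters (22,500 and
55,200) and 5% outliers, a balanced binary sex-like QI, and a five-valued
disease attribute with skewed frequencies (0.55/0.25/0.12/0.05/0.03). The
outlier fractions are the point: scattered records make every moderate
zipcode binning leave some class under *k*, forcing the plain k-anonymity
baseline up to full-domain ranges (LM ≈ 0.6 at *k* = 10) while the ceiling
method holds LM under *h* by construction. These tables emulate cluster
structure, outliers and skew — not the dependence structure, longitudinal
patterns or realistic code distributions of real EHRs, so passing tests show
the algorithmic guarantees hold, not that utility on any particular real
dataset will match.

Randomized suites use 1,000-row tables, 50 seeds for the LM-bound sweep and
200 seeds for the catalog-safety oracle, with an exhaustive-enumeration
adversary check on instances of up to 6 classes; search optimality is
verified against brute-force re-scoring of all 50 nodes of the demo
lattice. These sizes keep every property check exact or well-powered at
desk scale.

## A worked run

```{r demo}
fx <- demo_ehr_fixture()
res <- anonymize(fx$table, fx$schemas, k = 4, h = 0.02, seed = 3)
res
res$catalog$entries
head(truthful_view(res$classes, res$catalog, fx$schemas), 8)
```

Three 30s women and four 60s men split into two tight classes; the women's
class gains one counterfeit to reach *k* = 4, and the catalog discloses it
against both classes so neither can be singled out. The truthful view
returns exactly the seven real records, one of them QI-masked.

## Known limitations

* Generalization is full-domain only; subtree/local recoding, multidimensional
  (Mondrian) cuts, clustering, suppression and relocation are out of scope.
* One sensitive attribute; no l-diversity/t-closeness style constraints on
  its distribution within classes.
* The greedy catalog grouping is not minimal: it may use larger groups than
  necessary, and may fail (`NULL`) where an exhaustive grouping would
  succeed.
* The whole-table empirical counterfeit distribution slightly tilts the
  published sensitive marginal toward frequent values; the catalog makes the
  tilt exactly removable.
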