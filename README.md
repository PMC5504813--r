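# anonceil

Utility-preserving k-anonymization of tabular health data: full-domain
generalization under a **ceiling on the generalization degree**, counterfeit
records to repair k-anonymity, and a provably privacy-safe **catalog** of the
counterfeits that lets recipients reconstruct a truthful dataset.

## Who this is for

Data custodians (hospitals, registries, national health services) who must
publish record-level tables under k-anonymity but cannot afford the
over-generalization that outlier records force on classical full-domain
algorithms — and analysts on the receiving end who need to know exactly how
much synthetic content a published table carries, and how to remove it.

## The method in brief

Quasi-identifier generalization is scored by its *degree*: for a numeric
attribute generalized to `[L_q, U_q]` within domain `[L, U]`,

    D_A = (U_q − L_q) / (U − L),

for a categorical attribute generalized to a taxonomy node covering `|M_p|`
of `|M|` leaves, `D_A = (|M_p| − 1)/(|M| − 1)`, and a record's degree `D(r)`
is the mean over its quasi-identifiers. A published table satisfies the
**h-ceiling** iff `D(r) ≤ h` for every record — a hard cap on information
loss (the loss metric LM, the mean cell degree, is then ≤ h too).

Under a tight ceiling some equivalence classes fall short of `k` members.
Instead of widening them, **counterfeit records** carrying the class
signature and a randomly drawn sensitive value fill the deficit, and a
**catalog** `(class-id list, sensitive value, count)` discloses the
insertions per *group* of classes. Groups are formed so that every
counterfeit is matched by at least as many real records of the same value in
the group's other classes — by pigeonhole, no adversary can locate the
counterfeits, and honest recipients can strip them out again
(`truthful_view()`), recovering exactly the real records (some with masked
quasi-identifiers).

The search (`anonymize()`) walks the generalization lattice bottom-up,
prunes by degree monotonicity, anonymizes every feasible node end to end and
returns the node minimizing the **reconstruction error** RCE — the summed
squared difference between each real record's original and published
probability densities, including the catalog's down-weighting
`real/(real + counterfeit)` of records whose value the catalog names.

## Worked example

The package ships a seven-record demo EHR table (three women in their 30s,
four men in their 60s; diseases Pneumonia/Diabetes/Anemia):

```r
library(anonceil)
fx <- demo_ehr_fixture()
res <- anonymize(fx$table, fx$schemas, k = 4, h = 0.02, seed = 3)
res
#> <anon_result>
#>   node: (2, 0, 3)   k = 4, h = 0.02
#>   2 classes, 8 published rows (1 counterfeit)
#>   LM = 0.0138  DM = 32  RCE = 12.7299
#>   catalog:
#>  class_ids sensitive count
#>        1;2  Diabetes     1
```

The women's class `<[35-37], F, [22071-23061]>` (degree 0.01) had only three
members, so one counterfeit Diabetes row was inserted; the men's class
`<[61-66], M, [55099-55324]>` (degree 0.02) was already full. The catalog
names *both* classes: since real Diabetes records exist in each, the
counterfeit cannot be located, and each Diabetes record now carries a 25%
chance of being the counterfeit (density scale 3/4). Recipients wanting
truthful data reconstruct it:

```r
truthful_view(res$classes, res$catalog, fx$schemas)
#>  class_id     age sex       zipcode   disease
#>         1 [35-37]   F [22071-23061] Pneumonia
#>         1 [35-37]   F [22071-23061]  Diabetes
#>         1 [35-37]   F [22071-23061]    Anemia
#>         2 [61-66]   M [55099-55324] Pneumonia
#>        NA       *   *             *  Diabetes
#>         2 [61-66]   M [55099-55324]  Diabetes
#>         2 [61-66]   M [55099-55324] Pneumonia
```

Seven rows — the original real-record count — with one Diabetes row masked:
one of the suppressed Diabetes rows was the counterfeit, and the survivors
are all real.

Compare the plain k-anonymity baseline, which must pool all seven records
into one class with degree 0.55:

```r
baseline_k_anonymize(fx$table, fx$schemas, k = 4)$metrics$lm
#> [1] 0.5480552
```

## Documentation

The methods vignette (`vignettes/ceiling-anonymization.Rmd`) covers the
model, the safety argument for the catalog, the RCE density model, all
tunable parameters and the package's numerical choices and limitations.
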