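# semnetverify

Simulation and inference toolkit for a **sparse labeled semantic
network** account of speeded category verification ("A carrot is a
vegetable" — true or false?), together with its **feature-comparison
criterion-shift** rival. It is aimed at cognitive modellers who want to
reproduce, probe, or extend the signature behavioural contrast between
the two accounts: how the *typicality effect* (atypical-minus-typical
mean correct RT for true items) responds to the kind of false items
mixed into a block.

## The models

**Network model (two stages).** Memory is a sparse directed graph whose
edges carry a relation label — `SUBSET` (exemplar → category),
`SUPERSET`, `COORD` (contrasting exemplars) — and a strength
*s* ∈ (0, 1]. Stage 1 races two strength-ordered searches (one from each
stimulus term) through all paths of length ≤ 2 (the *stopping length*);
each edge traversal costs a gamma latency with mean
`base + scale / s`, so typicality (strength) lives here. Stage 2
classifies the retrieved label 2-tuple by production rule —
(`SUBSET`, NULL) or (`COORD`, `SUBSET`) ⇒ set–superset ⇒ *true*;
(`COORD`, NULL) or (`COORD`, `COORD`) ⇒ coordinate ⇒ *false*;
(`SUBSET`, `SUPERSET`) ⇒ ambiguous ⇒ keep retrieving — at a constant
`eval_time` per application, independent of typicality. Consequence:
coordinate and reversed false contexts add a constant to true-item RT
and leave the typicality effect **unchanged**.

**Feature model (counter race).** Features are sampled at the pair's
overlap probability *p*; `c_true` accumulated matches give *true*,
`c_false` mismatches give *false*, each sample costing `sample_time`.
A similar false context shifts the criterion upward
(`c_true → c_true_shifted`), and since expected samples ≈ *c/p*, the
typicality effect grows linearly in the criterion — the context
**amplifies** it. The network model falls back on this machinery in
cross-category false contexts, where every retrievable chain is
ambiguous.

The package also ships a synthetic taxonomy / stimulus-list generator
reproducing the blocked designs (including counterbalancing and the
each-predicate-twice rule), an experiment harness with per-participant
outlier trimming, and the matching statistics: paired *t*, Cohen's
*d = t/√n*, unit-information Bayes factors BF01 at prior scales
*r* ∈ {1.0, 0.5}, exact noncentral-*t* power, contrast tables, and
binned standardized-effect comparison. See the vignette
(`vignettes/category-verification-model.Rmd`) for the model details and
every default's rationale.

## Worked example

```r
library(semnetverify)

# one Bayes factor from a printed t statistic
bf01_unit_information(-0.49, n = 24, r = 1.0)
#> [1] 4.436271

# simulate 24 participants through the four-condition blocked design
res <- run_pipeline(run_config("EXP1", n_participants = 24, master_seed = 1))
contrast_table(res$trials)
#> Typicality-effect contrasts vs ANOMALOUS (baseline effect 422 ms)
#>           label       effect_ms       delta_ms  n     t     d bf01_r1 bf01_r05
#>      COORDINATE 424 (374 - 475)   3 (-52 - 57) 24  0.10  0.02  4.9700   2.6300
#>  CROSS_CATEGORY 523 (467 - 579) 102 (33 - 170) 24  3.07  0.63  0.0995   0.0856
#>        REVERSED 402 (357 - 448) -19 (-82 - 43) 24 -0.64 -0.13  4.0700   2.2000
```

Read the rows as: the simulated typicality effect in the Coordinate
(424 ms) and Reversed (402 ms) conditions is statistically equal to the
Anomalous baseline (422 ms) — t near 0 and BF01 > 4 favour the null of
an invariant effect — while the Cross-Category condition, served by the
shifted-criterion feature fallback, amplifies the effect by ~100 ms
(t = 3.07, BF01 ≈ 0.1 favouring a difference). True-item mean RTs are
also ~150 ms longer under Coordinate/Reversed than Anomalous (the
constant path-evaluation stage). That is the two accounts' signature
dissociation, reproduced in simulation.

```r
power_paired_t(0.2, n = 24, alpha = 0.2)   # 0.3895…: power to detect d = 0.2
classify_tuple("COORD", "SUBSET")          # "SET_SUPERSET"
```

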