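---
title: "A sparse labeled-network model of category verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A sparse labeled-network model of category verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semnetverify)
```

## The task and the two competing accounts

In speeded category verification a participant decides whether "A
*subject* is a *predicate*" ("Peas are vegetables") is true. Typical
exemplars are verified faster than atypical ones — the *typicality
effect* — and the size of that effect depends on what kind of *false*
items surround the true ones. The theoretically loaded contrast is:

* **Feature-comparison models** treat verification as a similarity
  computation: features are sampled one at a time, and independent
  counters accumulate matches (toward "true") and mismatches (toward
  "false"). Semantically similar false items force a *criterion shift* —
  more matches required before answering true — which slows everyone
  down but slows atypical exemplars more, because their matches accrue
  more slowly. Prediction: similar false contexts **amplify** the
  typicality effect.
* **Sparse labeled-network models** store relations explicitly as
  directed associations labeled `SUBSET` (exemplar to category),
  `SUPERSET`, or `COORD` (between contrasting exemplars). Verification
  is a two-stage process: stage 1 *retrieves* a connecting path, stage 2
  *evaluates* the retrieved labels with production rules. Retrieval time
  depends on associative strength (hence typicality); evaluation time
  does not. Prediction: contexts that merely add an evaluation stage
  (coordinate or reversed false items) lengthen all true responses by a
  **constant**, leaving the typicality effect unchanged, while a context
  the network cannot discriminate (cross-category false items) forces a
  fallback to similarity judgment — and there the effect grows.

This package implements both accounts as simulators, plus the stimulus
machinery and the inferential toolkit (unit-information Bayes factors,
noncentral-*t* power, contrast tables) needed to express the predictions
as statistics.

## Stage 1: the retrieval race

The memory structure is a sparse directed labeled graph. Sparseness is
doing real work: an atypical exemplar need not hold a direct `SUBSET`
edge to its category, and may reach it only through a coordinate, e.g.
`COORD(chicken, hawk)` then `SUBSET(hawk, bird)`. Two searches run in
parallel, one from each stimulus term. Each search performs iterative
deepening over path length up to a *stopping length* (2 by default:
co-occurrence networks have short mean path lengths, so deeper retrieval
buys little and costs much), exploring edges within a frontier in
descending strength order. Each edge traversal costs a gamma-distributed
latency with mean

$$\mu(s) = \texttt{edge\_time\_base} + \texttt{edge\_time\_scale}/s,$$

so stronger associations are retrieved earlier both in order and in
time. The stage-1 outcome is the first connecting path either search
completes; if neither connects, retrieval is *exhausted* after the
slower search's total exploration time plus a constant overhead, and the
terms are deemed unrelated.

Design choices the literature leaves open, fixed here and injectable as
parameters:

* **Latency law.** Only monotonicity in strength is theoretically
  constrained. We use a gamma with shape `edge_time_shape` (default 4)
  because it is positive and right-skewed like empirical RT
  distributions; the whole law sits behind `retrieval_params()` so a
  shifted-Wald or similar could be swapped in.
* **Race semantics.** The two searches are fully independent simulated
  clocks (no shared frontier); the winner's clock is the stage-1
  latency.
* **Search discipline.** Iterative deepening with within-frontier
  descending-strength order makes exhaustion well defined and matches
  the strength-ordered-selection assumption. Ties break
  lexicographically, so a seed fixes the full outcome sequence
  bit-for-bit.

## Stage 2: production rules over label 2-tuples

With stopping length 2, a retrieved chain is summarised by a 2-tuple of
labels, the second element being `NULL` for a direct association. Each
tuple indexes a production rule (see `production_table()`): `SUBSET`
chains and `COORD`-then-`SUBSET` establish a set–superset relation
(true); the mirrored rows establish superset–set; `COORD` chains
establish a coordinate relation; mixed tuples such as
(`SUBSET`, `SUPERSET`) — robin–animal–bird — are *ambiguous* and carry
no decision value. Four rows of the table are fixed by the worked
examples in the source literature; the rest follow from transitivity and
from mirror symmetry (a path read from the predicate is reversed and has
`SUBSET`/`SUPERSET` swapped before classification — the package mirrors
tuples rather than maintaining a second table). The whole table is a
single replaceable constant.

Each rule application costs a constant `eval_time`, *independent of
typicality by construction*. That is the model's additive-factors
commitment: typicality lives in stage 1, false-context type in stage 2,
so their effects on RT are additive. Policy by condition:

* **Anomalous context:** any retrieved path means "true"; exhaustion
  means "false". No evaluation stage.
* **Coordinate / Reversed contexts:** evaluate tuples in retrieval
  order; set–superset answers true, coordinate or superset–set answers
  false, ambiguous resumes retrieval. If retrieval exhausts with only
  ambiguous evidence the response is "false" (a guessing variant is
  available via `guess_true_rate`, default off; ambiguous paths are rare
  enough in generated taxonomies that the choice is inert at the level
  of means).
* **Cross-category context:** every retrievable chain is ambiguous —
  the network cannot tell *watermelon–vegetable* from a true item — so
  the trial routes to the feature model with the shifted criterion.
  The fallback strategy is explicit and swappable.

Strict seriality (evaluation starts only after a path is retrieved) is
assumed; cascaded processing is not modelled.

## The feature counter model

`feature_verify()` samples features one at a time; a sample matches with
the stimulus type's overlap probability. TRUE is declared at `c_true`
matches (`c_true_shifted` under a criterion shift), FALSE at `c_false`
mismatches; RT is `base_time` plus samples times `sample_time`. When the
false counter is effectively unreachable the expected sample count is
`c/p`, so the typicality effect under criterion `c` is approximately
`c (1/p_atyp - 1/p_typ) * sample_time` — linear in `c`, which is the
amplification prediction in closed form.

## The synthetic taxonomy and what it calibrates

`generate_taxonomy()` builds a master taxonomy (164 categories of 6
exemplars by default, grouped into domains of 4 coordinate categories)
with the structural properties the models trade on; stimulus-list
builders then reproduce the blocked designs (four 80-trial blocks with a
20/20/40 composition in design 1; two 160-trial conditions with derived
anomalous controls in design 2), including counterbalancing, the
two-uses-per-predicate rule, and practice items drawn from reserved
categories so no practice term recurs at test.

Parameter defaults were chosen once, analytically, to make the
*simulated reference conditions* land near the published condition
means — they are the study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `base_time` | 700 ms | encoding + motor residual; absorbs what the model does not decompose |
| `edge_time_base`, `edge_time_scale` | 60, 260 ms | one strong-edge retrieval (~385 ms at s = 0.8) puts typical true RT near ~1.1 s |
| `typical_strength` / `atypical_strength` | 0.8 / 0.55 | graded direct-link strength; the race-adjusted gap yields a ~300–400 ms typicality effect |
| `p_atypical_direct_link` | 0.9 | the sparse minority of atypicals reach their category only via a coordinate, contributing the long tail of the effect |
| `eval_time` | 150 ms | the constant true-item slowing in coordinate/reversed contexts |
| `c_true`, `c_true_shifted` | 4, 8 | doubling the criterion roughly doubles the feature-model effect (~250 to ~500 ms at overlaps 0.9/0.7 and `sample_time` 200 ms) |
| `scale_sdlog` | 0.15 | log-normal between-participant RT scale giving realistic between-subject SDs |

Feature vectors are binary, derived domain base → category prototype →
exemplar with flip rates (0.3, then 0.08/0.25 for typical/atypical)
chosen so mean pairwise overlap orders as typical-true > atypical-true >
reversed ≈ coordinate > cross-category > anomalous, the qualitative
ordering of published similarity ratings. "Judged semantically
unrelated" is operationalised as *no path of ≤ 2 edges and overlap below
0.55* — a proxy for experimenter judgment.

### What the generator does not emulate

Tokens are content-free identifiers: word frequency and length matching,
collected typicality norms, and real English taxonomy are out of scope.
Accuracy is generator-driven (mis-wired `SUBSET` edges and cross-domain
`COORD` links are the only error sources for the network model), so
simulated accuracies do not track the published ones except
qualitatively. Most importantly, **absolute false-item RT levels in
exhaustion-driven conditions are too slow**: the exhaustion semantics
(serial traversal of every bounded path from both terms) sums many edge
latencies, so simulated anomalous-false RTs run several seconds where
humans answer in ~1.5 s — humans presumably terminate on diminishing
returns rather than exhaustively. The package's qualitative claims all
concern *true*-item RTs and their contrasts, which the exhaustion tail
does not touch. Passing tests therefore show the model architecture
produces the published *pattern* (invariance vs amplification), not that
it fits absolute human latencies.

## The inference toolkit

The contrast machinery mirrors a published contrast table: the paired
*t* on per-participant typicality-effect differences against the
anomalous baseline, Cohen's *d = t/√n* (the only convention consistent
with the published (*t*, *N*, *d*) triples), and the unit-information
BF01

$$\mathrm{BF}_{01} = \frac{(1 + t^2/\nu)^{-(\nu+1)/2}}
{(1 + n r^2)^{-1/2}\left(1 + \frac{t^2}{\nu(1 + n r^2)}\right)^{-(\nu+1)/2}},
\qquad \nu = n - 1,$$

evaluated at prior scales r = 1.0 and 0.5. Power uses the exact
noncentral-*t* CDF (noncentrality *d√n*), two-sided — a one-sided
computation does not reproduce the published values. Per-participant
effects can be standardized, binned at 0.25 SD with pooling at +2.25 SD,
and compared across conditions with a standard two-sample chi-square
(zero-count bins dropped, df = bins − 1).

Outlier trimming (`trim_outliers()`) removes, in a single pass,
latencies more than 2.5 SD above a participant's mean in a condition; it
is off by default since it changes nothing qualitatively, and on default
simulations it touches under 1.5% of responses.

## Numerical and bookkeeping choices

* All randomness flows from a master seed through per-stream child
  seeds (`taxonomy`, `stimuli`, `design`, one per participant), so
  adding participants never perturbs earlier streams and any artifact is
  reproducible from the config document plus seed.
* Deterministic orderings everywhere a tie could arise: path
  enumeration is lexicographic over the visited word sequence; edge
  exploration sorts by strength, then target, then label.
* Degenerate inputs fail loudly: self-loops, out-of-range strengths and
  unknown labels are rejected at construction; zero-variance difference
  vectors are an error in `paired_t()`; empty trimming cells pass
  through untouched.
* Problem sizes used by the shipped tests: the full 24-participant
  four-block design for the headline signature, a 16-participant run of
  design 2 for the task-difficulty control, 100 random networks × 100
  runs for retrieval soundness, 10^5 counter races per cell for the
  criterion-shift curve, and 200 replications per arm for parameter
  recovery of null and +150 ms interactions.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(run_config("EXP1", n_participants = 24, master_seed = 1))
contrast_table(res$trials)
```

On this seed the simulated typicality effect is statistically
indistinguishable between the anomalous, coordinate and reversed
contexts (BF01 > 4 at r = 1 for both contrasts) while the cross-category
context amplifies it by ~100 ms (BF01 ≈ 0.1), and true-item latencies
are ~150 ms longer wherever path evaluation runs — the package-level
restatement of the two models' signature difference.

## Known limitations

Beyond the generator caveats above: no spreading-activation decay,
priming, or learning across trials; no speed–accuracy trade-off
modelling; no `NOT_A` or property links; the hierarchical-level
alternative account and distributional-vector variants are out of
scope. The production table's four unanchored rows are principled
reconstructions (transitivity + mirror symmetry) and are exposed as a
replaceable constant precisely because they are the least-constrained
part of the model.
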