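---
title: "Shared neighborhood scoring on tripartite pharmacological networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared neighborhood scoring on tripartite pharmacological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snslink)
library(dplyr)
```

## The model

snslink predicts missing links in a heterogeneous pharmacological network
with three node kinds — drugs, proteins, diseases — and four link
categories (drug–protein, protein–disease, drug–disease, protein–protein).
Classical common-neighbor indices assume a monopartite graph; projecting a
multipartite network onto one kind discards exactly the low-degree
information that matters for sparsely annotated drugs and diseases. The
shared neighborhood score works on the heterogeneous graph directly.

For a node pair $(i, j)$ the score is

$$S_{ij} = \sum_k W_{ik} W_{kj}, \qquad
  W_{ik} = a_{ik} + P\!\left(s^{(0)}_{ik}\right)\,\delta_{a_{ik},0},$$

where $a_{ik}$ is the adjacency indicator, $s^{(0)}_{ik}$ is the pair's
shared-neighbor count, and $P(n)$ is the *connection probability*: the
fraction of directly connected pairs among all pairs sharing exactly $n$
neighbors, with $P(0) = 0$. A real link weighs 1; an unconnected
("virtual") link weighs the probability that a pair with its shared count
is connected. Expanding the product splits the score into three terms:

* $s^{(0)}$ — bridges real on both sides ("Shared Nodes Count"; the
  **simple** score);
* $s^{(1)}$ — bridges real on one side, virtual on the other;
* $s^{(2)}$ — bridges virtual on both sides.

The **extended** score is $s^{(0)} + s^{(1)} + s^{(2)}$. With the
calibration forced to $P \equiv 0$ the extended score collapses to the
simple count — a reduction the test suite asserts exactly.

The published form of the second-order term omits the summation symbol
that the defining product $\sum_k W_{ik}W_{kj}$ implies; we sum over
bridges in all three terms, which is the only reading consistent with the
definition.

### Bridge support

A bridge $k$ contributes only if $W_{ik} > 0$ and $W_{kj} > 0$. Because
$P(0) = 0$, that requires $k$ to lie within two hops of *both* endpoints,
so the implementation enumerates exactly that candidate set; it is an
exact bound, not a pruning heuristic, and the test suite checks it against
a brute-force evaluation that materializes the full weight matrix.

Weights are looked up in the calibration of the bridge link's own
category: a drug–disease score uses drug–protein-calibrated $P$ for its
drug-side virtual links, and so on. Two same-kind cases need a rule the
score definition does not supply: drug–drug and disease–disease pairs have
no link category (no such pair is ever connected, so their empirical
connection probability is zero) and weigh 0; virtual protein–protein links
reuse the protein–disease calibration as a proxy, switchable via
`pp_weight_category` in `calibrate_graph()`.

### Leave-one-out

An existing link would trivially inflate its own score. Scoring a
connected pair with `leave_one_out = TRUE` therefore removes the edge
before *every* term — including the shared counts inside the weights — so
the result is identical to scoring the pair on a copy of the graph with
the edge physically deleted (asserted exactly in the tests). A narrower
convention that removes the edge only from the second-order term exists in
the literature; we adopt the full removal because the stated purpose, a
score independent of the link's own presence, is only achieved that way.
Calibration, in contrast, is computed once on the full graph and frozen:
re-estimating $P(n)$ for every held-out edge would change the measure, not
just the measurement.

## Calibration

`calibrate_graph()` tallies, per category, the shared-count distribution
of every cross-kind pair (`count_shared_distribution()`; $n = 0$ pairs are
obtained by complement arithmetic rather than enumeration) and fits

$$f(x) = \frac{1}{1 + e^{a + bx}}$$

to the points $(n, P(n))$, $n \ge 1$, by weighted least squares with
weight equal to the number of pairs at each $n$. The fit is deterministic:
it starts from $a = -\mathrm{logit}(\text{overall connection rate})$,
$b = -1$. A fit with $b \ge 0$ — connection probability not increasing
with shared count, violating the method's premise — is rejected as a
monotonicity error, and flat tables are rejected before fitting. On
simulated tables with 20,000 pairs drawn from a known logistic the fit
recovers $(a, b)$ within $\pm 0.1$.

Three evaluation policies govern how $P(n)$ is served during scoring:

| policy | observed $n$ | unobserved $n \ge 1$ |
|---|---|---|
| `hybrid` (default) | empirical ratio | fitted curve |
| `fitted` | fitted curve | fitted curve |
| `empirical` | empirical ratio | 0 |

$P(0) = 0$ under every policy. The source material is ambiguous about
whether weights use the raw ratios or the fitted curve; `hybrid` follows
the data where it exists and the curve where it must extrapolate, and the
other two readings remain available. Calibration is per category because
link counts are wildly uneven across categories, so the same shared count
carries different evidence in each. When a category's fit fails (too few
distinct counts, or no trend) that category falls back to `empirical` with
a warning rather than failing the whole bank.

Because the raw score is unbounded and category-dependent, equal raw
scores do not mean equal connection odds. `calibrate_score_normalizer()`
bins scored pairs of known status (20 equal-width bins by default), fits
the same logistic family to fraction-connected versus bin midpoint, and
maps raw scores monotonically into $(0, 1)$.

## The synthetic study system

`generate_network()` emulates the single statistical property the method
rests on: connected pairs share more neighbors than unconnected pairs. It
is a planted-community (stochastic-block-style) generator — nodes are
assigned uniformly to latent modules and each eligible pair links
independently with `p_within` inside a module and `p_between` across
modules. Defaults: 60 drugs, 120 proteins, 60 diseases, 6 modules,
`p_within = 0.25`, `p_between = 0.01`, protein–protein probabilities
equal to the cross-kind ones, and drug–disease probabilities halved
(`dd_scale = 0.5`) to mirror the pronounced scarcity of curated
drug–disease links relative to drug–protein links in real pharmacological
databases — a shape emulation, not a numeric target. Setting
`p_within = p_between` yields the Erdős–Rényi null model used to check
false-positive behavior (AUC ≈ 0.5, KS non-significant). One seeded
stream drives all draws in a fixed documented order, so output is
byte-reproducible.

What the generator does *not* emulate: heavy-tailed degree distributions,
curation and ascertainment bias, correlated multi-database provenance, and
hub proteins. Green tests on these networks show the machinery is correct
and that the method behaves as designed *when its premise holds*; they do
not certify performance on any real database.

`split_links()` provides the holdout protocol: a seeded fraction of one
category's edges is removed from a training copy, negatives are sampled
among pairs unconnected in the original graph, and the extended score on
the training graph is asked to rank held-out positives above negatives.

## Evaluation protocol

`ks_compare()` contrasts the shared-count distribution of all connected
pairs with that of the unconnected pairs (by default the full unconnected
set, capped at 50,000 — the distribution-level comparison the method's
validation uses; an explicit sample size can be passed). Both the
two-sided p-value and the one-sided value in the direction "connected
stochastically larger" are reported. With ~100 connected pairs an
equal-size negative sample lacks the power to push p below stringent
thresholds even under strong separation, which is why the full set is the
default.

`compare_simple_extended()` scores the category's links (leave-one-out)
against an equal-size seeded negative sample, evaluates the simple and
extended scores on the identical pair set, and reports both ROC curves.
AUC uses the Mann–Whitney rank statistic with midranks; ties are abundant
in the integer-valued simple score, so tie handling is observable — all
scores tied gives exactly 0.5 — and the trapezoidal area under the
reported curve equals the rank AUC to 1e-9. On the default planted
networks (seeds 1–10) the extended score improves the mean AUC by about
0.08 over the simple count, with both well above chance; the magnitude of
the published improvements on the full curated database is not
reproducible at this scale and is not a target of the test suite.

## The repositioning filter

`find_candidates()` implements the four-criterion candidate screen for a
disease query against a broader disease class:

1. score above a threshold (default 0.004) **and** Shared Nodes Count
   satisfying `max_shared` (default 0 — candidates supported purely by
   indirect evidence, i.e. genuinely novel pairs; the constraint is an
   exact bound with a configurable relaxation);
2. membership in an approved-drug list;
3. no existing drug–disease link to *any* node of the class ("not
   previously used for a class drug", operationalized as graph absence);
4. a direct drug–protein link to at least one class-associated protein.

The disease class is an explicit node list: resolving class terms to
ontology identifiers is curation and out of scope. The 0.004 threshold is
applied to the normalized score by default — the normalizer's $(0,1)$
range is the natural home for so small a cutoff — with
`score_space = "raw"` available since the original statement of the
threshold does not name the space. Every emitted record carries its
supporting bridge paths; their weight products re-sum to the pair's score
(`explain_candidate()`), and `audit_candidates()` re-derives all four
criteria from the graph as an independent post-hoc check.

## Numerical choices and scale

* Bridge sums run in sorted node order; equality assertions use 1e-9.
* Shared counts come from one sparse matrix product per graph, frozen
  alongside the calibration; leave-one-out corrections adjust the affected
  counts exactly.
* The test suite and the acceptance script use graphs of 24–240 nodes and
  10 replicate seeds — sizes at which every brute-force oracle (full
  weight matrix, $O(N^2)$ pair scans) is exact and fast; the package
  targets desk-scale networks, not million-node graphs.

## A worked example

The canonical five-node configuration — bridge $m$ linked to both ends,
$k$ linked only to $j$ with $s^{(0)}_{ik} = 2$, and $l$ linked to neither
with $s^{(0)}_{il} = 3$, $s^{(0)}_{lj} = 1$ — evaluates to

$$S_{ij} = 1 + P(2) + P(3)\,P(1),$$

which with the probability table $P(1)=0.2$, $P(2)=0.5$, $P(3)=0.7$ gives
$1.64$:

```{r worked-example}
toy <- pharm_graph(
  tibble::tibble(
    source_id   = c("i", "m", "k"),
    source_kind = c("drug", "protein", "protein"),
    target_id   = c("m", "j", "j"),
    target_kind = c("protein", "disease", "disease")
  ),
  nodes = tibble::tibble(id = "l", kind = "protein")
)
bank <- manual_calibration_bank(c("1" = 0.2, "2" = 0.5, "3" = 0.7))
sn_score(toy, bank, "i", "j",
  shared_counts = c("i|k" = 2, "i|l" = 3, "j|l" = 1))
```

The injected `shared_counts` stand for counts frozen on the larger network
surrounding the excerpt; the five drawn nodes alone cannot realize them.

## End-to-end on a synthetic network

```{r pipeline}
net  <- generate_network(synth_params(seed = 1))
g    <- net$graph
bank <- calibrate_graph(g)
glance(bank)

ks_compare(g, "drug_disease", seed = 1)
compare_simple_extended(g, bank, "drug_disease", seed = 1)
```

```{r roc-plot, fig.width = 5, fig.height = 4}
autoplot(compare_simple_extended(g, bank, "drug_disease", seed = 1))
```

## Known limitations

* Desk-scale only: all-pairs calibration is quadratic in the kind sizes.
* The protein–protein proxy calibration is a modelling convenience; no
  ground truth for virtual PP weights exists in the score's definition.
* Multi-subunit protein complexes are not resolved; each protein
  identifier is one node.
* The synthetic generator validates mechanism, not real-world accuracy
  (see above).
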