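---
title: "Methods: dominance, association networks and reliability from camera-trap event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominance, association networks and reliability from camera-trap event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(packsocial)
```

packsocial analyses coded camera-trap observations of a small social group
of animals — it was developed for a territorial golden jackal pack watched
by a fixed camera grid — and answers three questions about the group's
social system: who outranks whom (dominance), who associates with whom
(social structure), and whether the coded data themselves are trustworthy
(reliability). This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design was open.

## The observation model

The unit of observation is the 30-second camera-trap **recording**. Human
coders watch each recording and emit one row per behavioural event, using a
fixed 13-behaviour ethogram (`ethogram()`). Exactly two behaviours —
aggression and submission — are directed at a recipient; all others,
including scent marking, are recorded without one. Animals that could not
be identified are logged with the reserved actor label `UNIDENTIFIED`:
such rows are kept (they still count as detections) but are excluded from
any computation that needs an identity.

Two files define a study: a **roster** (`id, sex, life_stage, entry_date,
exit_date`) and an **event log** (`recording_id, timestamp, camera_id,
behaviour, actor, recipient, present`). Roster tenure encodes the group's
composition timeline — a member's exit date marks dispersal, a pup's entry
date its first appearance — so "who was in the group on day *d*" is always
the roster filtered by tenure. The `present` column lists every individual
co-detected in the recording; *appearing in the same recording* is this
package's operationalisation of "observed in close proximity". Whether
proximity should instead require simultaneous frames is not decidable from
a coded log; the recording is the natural unit because it is what coders
actually label, and the choice is exposed rather than buried: every
association quantity downstream consumes the same `present` sets.

## Reliability diagnostics

**Cohen's kappa.** Intra-observer reliability is estimated by
re-identifying a random sample of detections and cross-tabulating first-
versus second-round labels. With observed agreement $p_o$ (diagonal mass of
the confusion table) and chance agreement $p_e = \sum_k r_k c_k / n^2$ from
the margins,

$$\kappa = \frac{p_o - p_e}{1 - p_e}.$$

The unweighted, two-round, single-observer form is the right one here;
weighted and multi-rater variants are deliberately out of scope. $\kappa$
is undefined when all mass sits in one row–column pair ($p_e = 1$), which
`cohens_kappa()` reports as an error rather than a number.

**Temporal independence.** Repeated triggers of the same camera on the
same animals would pseudo-replicate every downstream count. The check is
the sample autocorrelation of per-bin recording counts,

$$r_k = \frac{\sum_{t=1}^{n-k} (x_t-\bar x)(x_{t+k}-\bar x)}
            {\sum_{t=1}^{n} (x_t-\bar x)^2},$$

computed by `autocorrelation()` on the output of `detection_series()`. The
series definition is an interpretation — the field convention names the
diagnostic but not the series — so it is configurable: the default is
daily bins of recording counts, with lags up to $\min(30, \lfloor n/4
\rfloor)$, the usual guidance for short series. Note that a genuine
composition change (dispersal, a pup cohort) shifts the mean of the series
and will legitimately inflate $|r_k|$; the diagnostic flags
nonstationarity of any origin, not camera artefacts specifically.

## Dominance: win rules and David's scores

Three behaviours carry rank information, and each event adds exactly one
"win" to a directed win-count matrix $s$ over the adults:

* **aggression** actor → recipient: one win for the aggressor over the
  recipient;
* **submission** actor → recipient: one win for the *recipient* over the
  displayer — a submissive display concedes the dyad;
* **scent marking** by an actor: one win for the marker over **each** other
  adult in the group on that day (tenure-based roster).

The scent-mark rule is the literal reading of a mark being directed
"towards the rest of the group"; the defensible alternative — a single
aggregate point split across the others — is available as
`scent_mark = "single"` on `build_dominance_matrix()`. The two differ in
totals but rarely in ordering. Only adults enter the matrix; juveniles do
not compete for rank.

From $s$, dyadic win proportions are $P_{ij} = s_{ij}/(s_{ij}+s_{ji})$,
with $P_{ij} = 0$ for dyads never observed interacting (the plain
proportion convention). David's score combines direct and
opponent-weighted wins and losses,

$$w_i = \sum_j P_{ij}, \quad w2_i = \sum_j w_j P_{ij}, \quad
  l_i = \sum_j P_{ji}, \quad l2_i = \sum_j l_j P_{ji},$$
$$DS_i = w_i + w2_i - l_i - l2_i, \qquad
  NormDS_i = \frac{DS_i + N(N-1)/2}{N}.$$

$\sum_i DS_i = 0$ and $\sum_i NormDS_i = N(N-1)/2$ always, and
$NormDS \in [0, N-1]$; the test suite asserts these identities over a
thousand random matrices. The shrinkage-corrected proportion
$D_{ij} = P_{ij} - (P_{ij}-1/2)/(n_{ij}+1)$ is offered
(`method = "dij"`) but off by default: it changes the score sums, and
published NormDS tables computed with it will *not* total $N(N-1)/2$ —
a useful diagnostic when reproducing someone else's table whose variant is
undocumented.

Ranking is by NormDS descending. Printed score tables can tie to the shown
precision, so `rank_hierarchy()` breaks ties deterministically — more raw
wins, then fewer raw losses, then lexicographic id — and records which
criterion decided each position. The tie-break is this package's
convention, not a community standard.

## Association networks

`cooccurrence_counts()` tallies $n_i$ (recordings containing $i$) and
$x_{ij}$ (recordings containing both) over distinct recordings. A
`collapse_map` merges raw ids into one node — the canonical use is folding
an indistinguishable pup cohort into a single `"Pups"` node — and a
recording holding several merged ids counts once for the merged node.

Edge weights are either raw counts ($x_{ij}$, the default, matching
sociograms drawn from "number of recorded associations") or the
simple-ratio index

$$SRI_{ij} = \frac{x_{ij}}{n_i + n_j - x_{ij}} \in [0, 1],$$

the fraction of sightings of the dyad in which both were together. Which
index a published network used is often unstated; both are first-class
here, and reproductions should try both. Centrality and the fast-greedy
partition are invariant to a global rescaling of weights, so the choice
matters only where $n_i$ vary strongly between individuals.

**Eigenvector centrality** solves $A v = \lambda_1 v$ for the leading
eigenvector of the weight matrix: a node is central when its neighbours
are central. `eigenvector_centrality()` uses power iteration from the
uniform vector on the shifted matrix $A + sI$ with $s$ the largest
weighted degree — the shift leaves eigenvectors untouched but makes the
leading eigenvalue strictly dominant, so bipartite-like graphs (stars,
single edges) cannot oscillate between two accumulation points. Iterates
are renormalised to maximum 1; convergence is declared when successive
iterates differ by less than `tol` ($10^{-12}$ by default, capped at
$10^5$ iterations), and scores are reported with the top node at exactly
1, the convention of published centrality tables. Disconnected networks
are an error by default — mixing components silently would zero one of
them — with `largest_component = TRUE` as the explicit opt-in.

**Modularity** of a partition $c$ is

$$Q = \frac{1}{2m}\sum_{ij}\left(A_{ij} - \frac{k_i k_j}{2m}\right)
      \delta(c_i, c_j),$$

the within-community weight fraction minus its expectation under a
degree-preserving null. $Q > 0.3$ is the conventional threshold for
"strong" community structure and is exposed as a parameter, not a
constant. **Fast-greedy agglomeration** starts from singletons and
repeatedly merges the connected pair of communities with the largest
$\Delta Q = 2(e_{ij} - a_i a_j)$; the returned partition is the state of
maximum $Q$ along the merge trace (which includes the all-singleton
state, so a single-edge network correctly ends as one community with
$Q = 0$). Ties in $\Delta Q$ are broken by the lexicographically smallest
pair of community labels, each community labelled by its smallest member
id — an arbitrary but bit-reproducible rule. Greedy agglomeration is not
an exact maximiser in general; the tests verify exactness on planted
two-clique graphs by exhaustive enumeration of all partitions up to 8
nodes, which is the regime these group sizes occupy.

## The synthetic generator

`simulate_event_log()` exists so every stage can be validated by parameter
recovery without field data. It emulates, with known ground truth, the
features of the study system that the pipeline must detect:

* **Latent hierarchy.** Each adult carries a strength $s_i$; in an
  agonistic event within a dyad, $i$ beats $j$ with probability
  $\sigma(\beta(s_i - s_j))$. The logistic win model guarantees a linear
  latent order, the structure a stable canid group displays. Dyad-day
  event counts are Poisson($\lambda$): camera-trap detections of brief
  agonistic moments are sparse and memoryless, and a rate per dyad-day is
  directly interpretable. A configurable fraction of events is emitted as
  the loser's submissive display rather than the winner's aggression; the
  two encodings land the identical dominance-matrix win, which the tests
  assert.
* **Association clusters.** Each recording has a uniformly chosen anchor;
  every other present individual joins with probability `p_in` (same
  planted cluster) or `p_out` (other cluster). An optional
  `dominant_pair_coupling` boosts co-detection of the two strongest
  adults, emulating a bonded pair that is recorded together unusually
  often.
* **Composition timeline.** A dispersal set leaves after a given day, a
  pup cohort enters as juveniles from another, and the roster's
  entry/exit dates record both — so period splitting, tenure-based
  scent-mark fan-out and the collapsed pup node all get exercised.
* **Identification noise.** `simulate_reidentification()` relabels a
  sample of detections correctly with probability $q$, else uniformly to
  another id, yielding a confusion table whose expected kappa is a known
  monotone function of $q$.

Defaults are fixed at study-like conditions and not tuned per analysis:
7 adults whose strengths place a dominant pair (2.5, 2.3) well above five
homogeneous subordinates (0.6), $\beta = 1.5$, $\lambda = 0.1$ agonistic
events per dyad-day, 5 recordings per day over 120 days (a four-month
deployment at the observed detection rate of a few recordings per day),
three dispersers at day 60 and six pups from day 75, $q = 0.9$. All
randomness flows from the single config seed through a locally scoped
Mersenne-Twister stream, so identical seeds give byte-identical logs and
the caller's RNG state is never disturbed.

What the generator does **not** emulate: space (camera identities carry no
geometry), diel activity rhythms, behaviour-dependent detectability,
misidentification inside the analysis log (noise enters only the
reliability table), and litter effects beyond a shared entry date. Passing
recovery tests therefore show that the estimators invert the generative
model they target — not that field data meet that model's assumptions.

## Numerical and degenerate-input conventions

* Unobserved dyads get $P_{ij} = 0$, not `NA`; the Dij flag exists for
  sensitivity analysis.
* `cohens_kappa()` errors on $p_e = 1$; `autocorrelation()` errors on
  constant series and on series shorter than `max_lag + 2`.
* Power iteration: tolerance $10^{-12}$ in max-norm, uniform start, spectral
  shift by the maximum weighted degree, deterministic throughout.
* Fast-greedy ties: smallest lexicographic community-label pair. Equal-Q
  states along the merge trace resolve to the earliest (least merged) one.
* Disconnected networks error in both centrality and community detection
  rather than being analysed silently.
* `restrict_log()` treats dates as whole days, inclusive on both ends;
  events by unidentified actors pass the life-stage filter (their stage is
  unknown) but are skipped, and counted, by the dominance stage.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at the scale of the target system: groups of 2–10 individuals for
the score invariants (1000 random matrices), networks of up to 20 nodes
against a full eigendecomposition and up to 12 against a double-sum
modularity oracle, exhaustive partition enumeration up to 8 nodes, and
100-seed recovery experiments with roughly 30 interactions per dyad and
200 planted-cluster recordings. These sizes were chosen to match the
study system — a single social group of well under twenty animals — where
exhaustive oracles are feasible and recovery rates are sharp.

## Known limitations

* The recording is the association unit; finer proximity within a
  recording is not represented.
* Greedy modularity maximisation can be suboptimal on structures unlike
  the planted two-cluster regime it is verified on; for groups this small
  the exhaustive check in the test suite is the guard.
* NormDS tie-breaking and the `"single"` scent-mark variant are package
  conventions; published tables using other conventions can differ in
  low-rank order even when scores agree.
* The ACF diagnostic conflates camera-induced autocorrelation with real
  nonstationarity (e.g. a composition change mid-study); interpret it
  alongside the group timeline.
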