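---
title: "Methods: barcode lineage delimitation, host-shift mapping, and diversification-rate analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode lineage delimitation, host-shift mapping, and diversification-rate analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`divshift` implements a complete analysis workflow for densely sampled
DNA-barcode radiations: it delimits haplotype lineages from an mtCOI
alignment, summarizes specimen records into per-lineage character states
(host species, host tissue, biogeographic region), reconstructs ancestral
states by parsimony and by stochastic character mapping, asks whether the
proportion of lineage splits accompanied by host shifts has changed through
time, and tests whether the tempo of lineage accumulation departs from a
constant-rate birth process. This vignette documents the models, the
parameter choices, and the design decisions behind each stage, in the order
the `analysis/` scripts run them.

## Data model

Everything downstream consumes a rooted, ultrametric, time-calibrated tree
(`ape::phylo`) whose node ages are measured in Ma before the present. Node
ages are the primary temporal coordinate; branch lengths are derived as
parent age minus child age. `validate_timetree()` snaps tip ages within
1e-6 Ma onto the present line (consensus trees summarized with median
branch lengths are rarely exactly ultrametric) and larger deviations are an
error unless `force_ultrametric = TRUE` extends every terminal branch to
the maximum root-to-tip depth. Multifurcating trees are read and written,
but every operation that consumes a strictly binary branching sequence
(branching profiles, the gamma statistic, the model fits, parsimony) rejects
them: resolving polytomies is out of scope, and silently breaking ties
would manufacture branching times that were never inferred. Simultaneous
node ages are ordered by preorder index, a deterministic tie-break that no
derived quantity depends on.

`truncate_tree(tree, age)` implements the truncated-phylogeny device used
to probe sensitivity to very recent, possibly non-independent lineages:
every branch crossing the age line becomes a tip on that line and the tree
is re-zeroed, so a cutoff of 1 Ma removes all divergences younger than 1 Ma
and shortens every surviving path by 1 Ma. The interval is half open — a
node sitting exactly on the line survives (as a tip). With that convention
the tip count of the truncated tree equals the lineage-through-time count
at the cutoff, and the gamma statistic of the truncated tree is identical
to the gamma of the original tree profiled with `cut_age` at the cutoff;
the test suite checks both identities on random trees.

## Lineage delimitation

Distances are raw counts: `raw_distances()` counts columns where both
sequences carry an unambiguous A/C/G/T and the bases differ (`N`), along
with the number of comparable columns; the proportional distance is
`N / comparable`. No substitution-model correction is applied — the
delimitation thresholds are defined on observed differences.

The guide tree is a standard Saitou–Nei neighbor-joining tree. Because the
partition rule needs reproducible output, two details are pinned down: ties
in the Q matrix break toward the smallest (row, column) index pair, and a
negative branch length is clamped to zero with the deficit transferred to
its sibling branch, preserving path lengths through the joined node. The
tree is rooted on a designated outgroup; when none exists (synthetic
scenarios), the workflow midpoint-roots the tree instead.

`delimit_lineages()` produces the finest partition into groups that are
monophyletic on the guide tree such that every between-group pair of
sequences differs by at least `min_diff = 3` substitutions (three mutations
over 504 columns is the 0.5% figure usually quoted; the integer rule is
authoritative, and with it the partition is parameterized by a count, not a
percentage). The algorithm chains all pairs closer than `min_diff` into
components, then closes each group to monophyly, merging groups whose
clades overlap, until stable.

Two paraphyly rules handle the classic star-radiation situation in which a
surviving ancestral haplotype sits in the middle of several divergent
descendant groups. Within each component, any haplotype (set of identical
sequences) whose removal splits the component into two or more parts that
are pairwise at least `min_diff` apart, while itself lying within
`min_diff` of several of them, is an ancestral-haplotype candidate; the
most central candidate (smallest mean distance to the rest of the
component) is taken to be the ancestor. If it is represented by at most
three specimens it is excluded from the partition altogether; otherwise the
ancestor and its descendant groups are combined into a single lineage and
the component is not revisited. The "at most three specimens" cutoff and
the merge-when-common alternative mirror how such cases are resolved in
practice; treating centrality as the mark of ancestry is our
interpretation, chosen because it is deterministic and testable (the suite
cross-checks the resulting partitions against a brute-force search for the
finest valid monophyletic partition on small cases).

Species-level clusters use single linkage at proportional distance
strictly below 0.04: single linkage matches the chaining behavior of
divergence-threshold species assignment, and the test suite verifies it
against a transitive-closure oracle. Exemplars are medoids — the member
minimizing mean within-lineage distance, ties lexicographic; the criterion
used historically is unstated, and the medoid is the least arbitrary
representative of a haplotype cluster.

## Character coding

Specimen records ("unknown" entries dropped) become per-lineage relative
state frequencies. Three codings express within-lineage variation:

* **polymorphic** — every state observed in at least 5% of a lineage's
  specimens (`min_freq = 0.05`);
* **predominant** — the modal state plus any state within 0.2 of the modal
  frequency (`window = 0.2`);
* **simplified** — the modal state only, ties lexicographic.

The polymorphic and predominant codings bracket the range of reasonable
interpretations of low-frequency alternative host records (real
polymorphism versus occasional error); the simplified coding is what the
permutation test and the trait-model fits require. Flies reared from both
flower sexes simply appear as polymorphism in the tissue character — there
is no dedicated "both" state.

## Parsimony reconstruction

Unordered (Fitch) parsimony on the binary tree, with polymorphic tips
treated as satisfiable by any member state at no cost. The implementation
is a unit-cost Sankoff dynamic program: a postorder pass computes the
minimal number of changes within each subtree conditional on the node's
state, a preorder pass the complement, and their sum yields the MPR set of
every node (states attained in at least one most-parsimonious
reconstruction). Tree length is invariant across resolutions.

Ambiguity is resolved two ways, both realizing exactly the MPR length. At
each node the candidate states minimize (cost below the node) + (1 if the
state differs from the parent's resolved state). DELTRAN keeps the parent's
state whenever it is a candidate, postponing changes toward the tips;
ACCTRAN takes a non-parental candidate whenever one exists, pulling changes
toward the root. Remaining ties break lexicographically, so both
resolutions are deterministic. The suite verifies, against exhaustive
enumeration on all small cases, that lengths and MPR sets are exact and
that both resolutions stay inside the MPR sets.

## Mk models, tip priors, and stochastic mapping

The Mk machinery evaluates the phylogenetic likelihood of a discrete
character by Felsenstein pruning with per-node rescaling. Two departures
from the textbook setup matter here:

* **Tip priors.** Tip partial likelihoods are initialized to the observed
  per-lineage state frequencies rather than one-hot vectors, so
  within-lineage variation enters the model as data-driven uncertainty
  about the tip state.
* **Root prior.** Uniform over the observed alphabet. The source analysis
  does not state its choice; uniform keeps the likelihood invariant to
  state relabeling, which the suite asserts.

The default rate structure is equal rates (one parameter); symmetric and
all-rates-different structures are available by flag. Equal-rates
transition probabilities use the closed form
`P_ii(t) = (1 + (k-1) e^{-kqt})/k`; other structures use the matrix
exponential. Rates are estimated by bounded optimization on the log scale.
Fits are cross-checked against an independent Mk implementation
(`phytools::fitMk`) and against brute-force enumeration of internal states
on small trees.

`stochastic_map()` samples complete character histories conditional on the
tip priors and a fitted (per-tree, not pooled, mirroring the per-tree
handling of a posterior tree sample) equal-rates model: backward filtering
gives the conditional node-state distributions, nodes are sampled forward
from the root, and each branch's path is simulated conditional on its
endpoint states — by rejection sampling (cap 10,000 attempts), falling back
to exact uniformization sampling for improbable endpoint pairs. Ten maps
per tree is the default, matching the 2500-maps-over-250-trees design.
Sampled node-state frequencies are checked against exact enumerated
marginals on a fixed four-tip tree.

## Split tallies and the permutation test

A split is "old" when its node age is at least the 3 Ma breakpoint (the
boundary is closed on the old side; the source's "before or after" leaves
the boundary open and node ages exactly on it have measure zero), "young"
otherwise; an optional exclusion age (1 Ma when reproducing the
truncated-tally variant) drops the youngest splits. A shift at a split
means its two immediate descendants carry non-overlapping states: resolved
single states for internal nodes (ACCTRAN and DELTRAN tallied separately),
coded state sets for tips. A shift in host species *or* host tissue counts
as a host shift, since either constitutes a change in the larval niche. For
stochastic maps the state of each descendant branch is read at the branch's
*end* — immediately before that lineage's own next split — so any number of
intermediate transitions along a long branch contributes at most one shift,
keeping the likelihood-based tallies commensurable with parsimony.

The permutation test asks whether D = P_old − P_young (composite
host-or-tissue shift by default) exceeds what tip-label shuffling produces.
The reference reconstruction uses MPR-set disjointness, with no
ACCTRAN/DELTRAN split: a split counts as a shift only when the descendant
MPR sets are disjoint, which makes the observed statistic a single
well-defined number; how ambiguous nodes entered the original analysis is
unstated, and resolving them both ways would make the null and observed
statistics incommensurable. Whole rows of the simplified matrix are
shuffled jointly across characters, preserving their cross-correlation
under the null. Both the raw `b/m` p-value (which can be exactly 0, the
form in which the original result is reported) and the `(b+1)/(m+1)`
correction are emitted. The suite verifies type-I calibration (rejection
rate 0.05 within two Monte-Carlo standard errors over 1000 null
replicates) and that a planted old-era-only signal yields raw p = 0 at
m = 1000.

The Fitch down/up bitmask engine used inside the permutation loop is
validated against the Sankoff engine on random cases; the two routes are
distinct implementations of the same MPR semantics.

## Trait-tempo models

`fit_trait_models()` compares, for the simplified host character: an
equal-rates Mk fit on the untransformed tree (1 parameter); an early-burst
model in which the rate decays as `e^{a t}` from the root (`a <= 0`,
implemented exactly as a branch-length transform by integrating the
multiplier along each branch); and Pagel's delta (node depths from the root
raised to `delta` in [1e-3, 3], rescaled to preserve total depth). Both
transforms nest the equal-rates model (`a = 0`, `delta = 1` are
identities), so their log-likelihoods can never be lower; if the inner
optimizer fails to match the nested fit the null parameter is returned
instead. AIC differences are reported relative to equal rates (positive =
transform worse). On constant-rate data the expected penalty is about +1.5
for early burst (the decay exponent sits at a boundary, so the expected
likelihood gain is half a chi-square unit) and about +1 for delta — not the
full +2, because a free parameter fits some noise; the tests assert those
calibrated expectations together with the hard nesting bound dAIC <= 2.

## Diversification analysis

The branching profile of a tree collects the ordered branching times
`b_1 > ... > b_{n-1}`, the internode intervals `g_k` (duration with exactly
`k` lineages; `g_n` runs from the last split to the present or cut line),
and the cumulative sums `T_i = sum_{k<=i} k g_k`. The gamma statistic is

```
gamma = ( mean(T_2 ... T_{n-1}) - T/2 ) / ( T sqrt(1 / (12 (n-2))) )
```

with `T = T_n`; under a constant-rate pure-birth process with complete
sampling it is asymptotically standard normal. P-values are reported both
two-tailed (`2(1 - Phi(|gamma|))`) and one-tailed lower (`Phi(gamma)`),
always: published tables of this analysis family mix the two conventions
(full-tree rows match two-tailed probabilities, truncated-tree rows match
one-tailed lower ones despite a two-tailed header), so the package exposes
both rather than guessing intent.

Four models are fitted to each profile by maximum likelihood, all sharing
the likelihood skeleton
`lnL = sum_{k=2}^{n-1} ln(k lambda_k) - sum_{k=2}^{n} k lambda_k g_k`,
where `lambda_k` is the per-lineage speciation rate while `k` lineages
exist. The final interval `g_n` is included in the survival term: the
probability model requires the waiting time beyond the last split to be
accounted for, so the generator and the likelihood agree
(`E[g_k] = 1/(k lambda)` is asserted for the simulator).

* **pure birth** — `lambda_k = lambda`; closed-form MLE
  `lambda_hat = (n-2)/T`.
* **birth–death** — Nee-style likelihood of the branching times conditioned
  on the crown age and survival of both crown lineages, parameterized by
  net rate `r > 0` and extinction fraction `a in [0, 1)`; multi-start
  bounded quasi-Newton on `(log r, a)`. At `a = 0` it equals the pure-birth
  likelihood exactly (including the `(n-1)!` ordering constant), and the
  fit is cross-checked against `ape::birthdeath`.
* **DDL** — logistic density dependence `lambda_k = r (1 - k/K)`, `K > n`.
  For fixed `K` the rate has a closed-form profile MLE, so the fit is a 1-D
  search over `log(K - n)`; the upper bound `K = n + 1e8` serves as the
  pure-birth limit candidate, keeping the fitted DDL likelihood within
  1e-6 of pure birth on rate-constant data (a bound the suite asserts).
* **DDX** — power-law density dependence `lambda_k = r k^{-x}` with
  `x in [0, 5]`; `x = 0` is pure birth.

`compare_models()` reports the AIC table and `dAIC` = best constant-rate
AIC minus best density-dependent AIC, positive favoring density dependence.

Sensitivity to incomplete sampling follows the simulate-prune-compare
procedure: for each assumed missing fraction `f` on a 10% grid, simulate
pure-birth trees with `round(n/(1-f))` tips, prune random tips down to
`n`, compute the statistic, and compare the observed value against the
empirical null (two-tailed quantiles for gamma, upper one-tailed for dAIC,
at alpha = 0.05); the reported "max % missing" is the last significant grid
point before the first non-significant one. At `f = 0` and n = 115 the
simulated two-tailed critical values are ±1.96 to within Monte-Carlo error,
which is the calibration the acceptance script recomputes.

## The synthetic-data generator

`generate_scenario()` produces the three inputs with the statistical
structure the analysis assumes, plus full ground truth (tree, per-branch
character histories with logged shift ages, true modal states,
diversification parameters). Defaults mirror the target study's shape: 115
lineages, 13 Ma crown age, a 3 Ma era changepoint, twelve host species,
the four tissue classes, seven regions, ~33 specimens per lineage (~3800
records), and 504-column barcodes.

Where the study conditions do not pin a number, values were fixed once at
field-plausible levels and are documented here: characters evolve as
equal-rates chains with per-era total shift rates of 0.40/0.04 per Ma
(host, strong old-to-young collapse), 0.12/0.015 (tissue), and 0.25/0.25
(region, deliberately era-constant) — chosen so the simulated tallies show
the qualitative pattern the method is meant to detect (a large host
contrast, none for region) without being calibrated to any printed
percentage. Specimen records are Dirichlet-multinomial around the true
terminal state with concentration 25 over a baseline mass of 0.2, which
puts the modal state near 90–95% of specimens, the stated level of host
fidelity; sequences evolve under Jukes–Cantor at 0.01 substitutions per
site per Ma (about 2% pairwise divergence per Ma of separation), with each
lineage contributing a second haplotype carrying on average half an extra
mutation. Characters evolve independently of one another by default; an
optional coupling knob multiplies host rates on branches with a region
change, for exploring correlated host shift and dispersal.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: posterior uncertainty in the tree (a single true
tree stands in for a posterior tree sample), alignment gaps and ambiguity codes,
substitution-rate heterogeneity across sites or lineages, geographically
structured dispersal, extinction in the default tree model, and any
correlation between sampling effort and lineage age. Analyses of real
radiations inherit all of those complications.

## Numerical choices and degenerate inputs

Optimizers work on log-transformed rates with multiple starts where the
surface can be multimodal (birth–death); 1-D fits use golden-section
search. Likelihood pruning rescales per node, so 200-tip trees at extreme
rates do not underflow. A character with a single observed state yields a
degenerate zero-rate Mk fit and zero-length parsimony reconstructions. A
constant character gives D = 0 and raw permutation p = 1; a breakpoint
outside the range of node ages gives an empty bin and D = NA. Zero-length
internal branches are legal (simultaneous ages); a state change across one
is an error in mapping. The permutation engine handles up to 30 states per
character (bitmask width).

Test-suite problem sizes are chosen to make each property decisive yet
quick: exhaustive oracles run on trees of at most 7 tips and 3 states,
distributional checks use 1000–10,000 replicates of small trees, recovery
checks use 50–200 tips, and the null-calibration suites state their
Monte-Carlo tolerances (2–3.5 standard errors) explicitly.

## Known limitations

* The ancestral-haplotype rules are an operationalization of a procedure
  described by example; genuinely reticulate situations (several equally
  central candidates) fall back to deterministic tie-breaks rather than
  network analysis.
* ACCTRAN/DELTRAN are local, greedy resolutions; they realize the MPR
  length but are not unique conventions across software.
* The equal-rates Mk default ignores asymmetric gain/loss dynamics;
  symmetric and all-rates-different structures are available but slower
  and data-hungry.
* Diversification fits condition on crown age and survival; richer
  conditioning schemes (e.g., on tip counts under incomplete sampling) are
  deliberately replaced by the simulation-based sensitivity procedure.
* The permutation null shuffles whole rows, preserving cross-character
  correlation but not any phylogenetic signal in the states themselves;
  it tests label exchangeability, not model adequacy.
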