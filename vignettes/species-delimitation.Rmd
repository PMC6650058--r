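---
title: "Multi-marker species delimitation for green-tide macroalgae"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-marker species delimitation for green-tide macroalgae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulvabarcode)
```

## The problem

Green-tide forming macroalgae of the genus *Ulva* are notoriously hard to
identify morphologically: thallus shape is plastic, field identifications
are frequently wrong, and several named species are separated by little or
no sequence divergence. The standard remedy is two-locus DNA barcoding — a
fast-evolving chloroplast marker (*tuf*A) and the nuclear ribosomal ITS —
combined with tree-based assignment against a curated reference library,
and cross-validated with algorithmic species-delimitation methods (ABGD and
single-threshold GMYC). `ulvabarcode` packages that whole workflow, plus a
two-locus simulator so every stage can be validated end-to-end without any
sequence downloads.

## Distances

Pairwise divergence uses the Kimura 2-parameter model. With transition
proportion $P$ and transversion proportion $Q$ over the compared sites,

$$d = -\tfrac12 \ln\!\big( (1 - 2P - Q)\sqrt{1 - 2Q} \big).$$

Sites carrying gaps, `N` or IUPAC ambiguity codes are treated as missing.
Under **complete deletion** (the default, matching the common
barcoding-tool convention) any column with a missing value in any sequence
is removed before every pairwise computation; **pairwise deletion** masks
per pair. When the log argument is non-positive (saturation) the pair is
flagged *undefined* rather than producing NaN; undefined pairs are excluded
from all means and rejected by downstream consumers that need complete
matrices (NJ, ABGD), with an explicit report.

The "±" on reported average divergences is a bootstrap standard error over
alignment columns (1000 replicates by default, seeded). This is a
documented convention of the package, chosen because it is the default
behaviour of the common desktop tools that print such values.

## Trees

Neighbor-joining (Saitou–Nei, via `ape::nj`) and UPGMA (average linkage,
via `phangorn::upgma`) are the native tree builders; maximum-likelihood,
Bayesian or clock trees produced elsewhere can be supplied as Newick and
enter the pipeline on equal footing. Negative NJ branch-length estimates
are clamped to zero and the clamped deficit recorded. Bootstrap supports
resample alignment columns with replacement; replicate $r$ uses seed
$s + r$ so runs are bit-reproducible for a fixed input. One caveat worth
knowing: identical haplotypes create exactly tied distances, so the join
order inside weakly resolved regions depends on the input ordering of the
sequences — strongly supported splits are stable under permutation, weak
ones can shift by a few points.

Trees are rooted on the outgroup; a multi-tip outgroup must form a split of
the unrooted tree, otherwise rooting fails loudly (midpoint rooting is
available only by explicit request).

## ABGD

Automatic Barcode Gap Discovery partitions sequences at the "barcode gap"
— the empty interval between intra- and interspecific pairwise distances.
The detector used here is a deterministic dialect of the original
slope-based procedure, because the original's local-window details are not
fully recoverable from its description:

* sort all pairwise distances; consider consecutive gaps
  $g_i = D_{i+1} - D_i$;
* a gap is *eligible* when its right edge lies beyond the prior maximum
  intraspecific divergence $P$ (i.e. $D_{i+1} > P$) — so a gap straddling
  $P$ counts;
* a gap is *significant* when $g_i > X \cdot w_i$, where the reference
  width $w_i$ is the mean of gaps $g_1,\dots,g_i$; the first gap, which has
  no left window, is instead compared against the mean of the remaining
  gaps (this lets reference-only datasets, where the barcode gap is the
  very first gap, still split);
* the threshold $\theta$ is the midpoint of the first significant eligible
  gap, and groups are single-linkage components joining pairs with
  $d < \theta$.

The initial partition (IP) uses one global gap; the recursive partition
(RP) re-applies detection inside each group (same $P$ and $X$, per the
cited method's fixed-prior recursion) until no group splits (depth cap 10).
RP always refines IP. Across a prior sweep (20 log-spaced values in
$[0.001, 0.1]$, gap widths $X \in \{1.0, 1.5, 2.0\}$ by default) the
retained partition minimises $|n_{IP} - n_{RP}|$, ties broken towards the
larger prior — the selection rule used in the study this workflow
reproduces. Exact parity with the ABGD web server is not promised; the
dialect is validated by its limiting behaviours (one group once $P$
exceeds every distance; singletons below the smallest gap; group counts
non-increasing in $P$) and by recovery of the true species count on
simulated clean-gap data.

## GMYC

The single-threshold Generalized Mixed Yule–Coalescent model assumes an
ultrametric tree whose branching events switch, at an unknown threshold
time $T$, from between-species diversification (rate
$\lambda_1 n_d^{p_1}$, $n_d$ = species-level lineages) to within-species
coalescence (rate $\lambda_2 n_k^{p_2}$ inside each cluster $k$). Ordering
the $n-1$ node heights from the present, each inter-event interval of
duration $x_i$ contributes its waiting-time density under the total rate

$$b_i = \lambda_1 n_{d,i}^{p_1} + \lambda_2 \sum_k n_{k,i}^{p_2},
\qquad \log L = \sum_i \big(\log b_i - b_i x_i\big).$$

Candidate thresholds are midpoints between consecutive *distinct* node
heights (heights tied within $10^{-7}$ of the root height are merged — a
cut between numerically tied events would admit an arbitrarily high fitted
rate over a zero-length interval), plus one candidate below the youngest
node. At that lowest candidate every event belongs to the single
diversification class, which is exactly the null single-process model
($b = \lambda n^{p}$): the null is therefore always nested in the scan and
$\log L_{GMYC} \ge \log L_{null}$ holds structurally.

At each threshold the four rate parameters are maximised by bounded
L-BFGS-B ($\lambda \in [10^{-8}, 10^6]$, $p \in [-2, 10]$) from five
deterministic data-derived starts; single-class fits use the closed-form
profile $\lambda^\* = K / \sum_i x_i n_i^{p}$ with a 1-D search over $p$.

**Significance.** The classic convention tests $2(\log L_{GMYC} -
\log L_{null})$ against $\chi^2_3$. The threshold, however, is a nuisance
parameter that does not exist under the null, and the likelihood ratio is
maximised over the whole candidate scan, so the $\chi^2_3$ test
over-rejects (we measure roughly 12% at a nominal 5% on pure coalescent
trees). The default p-value is therefore a scan-adjusted bound: Bonferroni
over the interior candidate thresholds of the per-threshold $\chi^2_2$
test. This is conservative by construction; `p_value_method = "chisq3"`
restores the classic convention for comparability with other software, and
a boundary-mixture heuristic is also available.

Entities are clusters plus singletons; singletons are *not* counted as
clusters (reconciling "clusters" with "ML entities" terminology). The
threshold confidence set collects candidates within 1.92 log-likelihood
units of the optimum, and the entity-count range over that set is the
reported CI. Haplotypes are collapsed by exact string equality (including
ambiguity characters — deterministic, no ambiguity-aware matching is
invented) before GMYC. When no externally built chronogram is supplied,
a UPGMA tree on K2P distances serves as the desk-scale stand-in for a
relaxed/strict-clock Bayesian chronogram; real-data GMYC counts should be
read with that substitution in mind.

## Specimen assignment

Per tree, a specimen takes the species of the smallest clade containing it
and at least one reference; among several reference species in that clade,
the lowest mean K2P to the specimen wins; a specimen whose smallest
reference-bearing clade is the root stays unassigned. Per gene, a species
must win a strict majority of the tree inferences (with the study's three
inferences — NJ, ML, BI — this is "majority of inferences"). Across genes:
agreement after synonym mapping gives the species; two different species
give *discordant* (both names are recorded); one gene silent gives the
other gene's call flagged single-gene (needed because real datasets drop a
few sequences per locus); both silent gives *unidentified*.

Reference species whose between-species mean K2P falls below 0.002
(configurable) are merged as synonyms, transitively; the canonical name is
alphabetically first unless an alias table overrides. The threshold was
chosen to merge pairs at 0.0–0.1% divergence while leaving ~0.7%
species complexes separate, and those complexes are handled by the alias
table rather than synonymy. Per-locus synonym maps are merged by union
(near-zero divergence at either locus merges the pair) — the conservative
reading of "same species at both genes" is available by supplying a custom
map. Outgroup references carry a pseudo-species name, so a specimen pulled
into the outgroup at one locus surfaces as an ordinary discordance.

Reference curation builds a bootstrap NJ tree of candidate references,
keeps up to two representatives (the most mutually divergent pair) per
species whose conspecifics form a supported monophyletic clade (support
$\ge 70$ by default — "strong" support is not quantified in the source
workflow, 70 is the common bootstrap convention), and discards candidates
whose removal restores conspecific monophyly and whose nearest K2P
neighbour is heterospecific — the operational form of "clusters with
distantly related species".

## The simulator

`simulate_dataset()` draws a Yule species tree, rescales it so the mean
between-species path equals $\delta_{inter} - \delta_{intra}$, grafts a
Kingman coalescent per species rescaled to mean pairwise
$\delta_{intra}$, attaches a three-tip outgroup clade well outside the
ingroup, and evolves both loci under K80($\kappa$) with per-locus rate
multipliers using exact per-branch transition probabilities
(`phangorn::simSeq`) — no Gillespie simulation, no indels (gap handling is
tested on hand-built fixtures instead). Defaults mirror the kind of
island-wide coastal survey this workflow targets: nine species with specimen counts
74, 47, 30, 13, 9, 8, 4, 4, 4; two references per species; locus lengths
813/732 with rate multipliers 1.0/1.3; $\delta_{intra} = 0.004$ (observed
intraspecific range 0.03–0.9%), $\delta_{inter} = 0.06$ (observed means
5.9–8.8%); $\kappa = 2$; 23 sites; five gene-discordant specimens.

Two deliberate departures from a naive draw:

* **Minimum interspecific divergence.** A Yule tree rescaled only in its
  mean occasionally contains a split so recent that two "species" are
  effectively identical. All pendant edges are therefore lengthened by a
  common constant (which preserves ultrametricity and shifts every pairwise
  path equally) until the closest species pair reaches
  `min_inter_frac` × mean (default 0.15 — about the ratio between the
  closest good-species pair and the mean divergence in published *Ulva*
  surveys). The clean-gap CI fixtures raise this to 0.6.
* **Forced species monophyly.** A coalescent tuft deeper than its species'
  pendant edge would make the species paraphyletic; tufts are shrunk to
  90% of the pendant when needed.

Gene discordance is injected at the membership level — a specimen is
simulated inside a different species at the second locus — which directly
produces the observed phenotype without modelling introgression. Synonym
pairs duplicate a reference sequence under a second species name at zero
divergence. `expected_divergence()` returns the closed-form per-locus
targets ($\delta \times$ rate multiplier), which the realized K2P means
track within Monte-Carlo error; this is the simulator's self-consistency
oracle.

What the simulator does **not** emulate: alignment error and ambiguously
aligned regions (real ITS needs masking — the pipeline exposes a column
mask rather than guessing coordinates), rate variation across sites,
indels, contamination, or population structure within species. Passing
tests on simulated data therefore validate the machinery and its
statistical behaviour, not the field realism of any particular dataset.

## Numerical choices and degenerate inputs

* Distance ties: single-linkage grouping and NJ joins break ties by the
  current id ordering — deterministic across platforms.
* `detect_gap` applies a $10^{-9}$ relative tolerance so exactly uniform
  spacings never register as gaps through floating-point noise.
* Complete deletion that removes every column is an error instructing
  pairwise mode; an all-gap column is simply non-variable in site
  statistics.
* A group of size one has an undefined (NA) within-group mean, never 0.
* Trees with all internal nodes at one height are rejected by GMYC; T must
  lie strictly inside (0, root height).
* External chronograms are accepted only within $10^{-6} \times$ root
  height of ultrametric.

## Problem sizes used in the shipped validation

The test-suite and the acceptance script validate at desk scale: 1000
random pairs for the K2P oracle; 200 random additive matrices (≤12 taxa)
for NJ; 100 seeds × S ∈ {3, 5, 9} clean-gap simulations for ABGD recovery;
100 20-tip coalescent trees for GMYC type-I and 50 5-species × 4-sample
trees (stem/tuft ratio 10) for entity recovery; three frozen 5-species
two-locus fixtures (clean / discordant / synonym-rich) for the assignment
rules and the full pipeline. These sizes are the package's validation
design; the pipeline itself runs comfortably at survey scale (hundreds of
specimens).

## Known limitations

* The ABGD dialect reproduces the documented limiting behaviour but is not
  a re-implementation of the reference web server's slope estimator;
  partition counts on real data can differ near the selection boundary.
* UPGMA chronograms are a crude clock; GMYC entity counts from them are
  stand-ins for chronogram-based counts, not substitutes.
* The scan-adjusted GMYC test trades power for calibration; with strong
  signal the likelihood-ratio is large enough that the trade rarely
  matters, but marginal cluster structure may test non-significant (as the
  motivating survey itself found for both markers).
* The majority rule needs at least two inferences per gene to differ from a
  pass-through; with a single confident gene and one all-unassigned gene
  the confident gene decides, whatever its support — flagged in the output.
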