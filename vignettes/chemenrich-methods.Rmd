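---
title: "Methods: ontology enrichment for small-molecule sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology enrichment for small-molecule sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemenrich)
```

# The model

## Ontology substrate

A ChEBI-style ontology is a directed multigraph of terms with edges running
child → parent (specific → general). Three relation types matter here:
`is_a` (the transitive subclass backbone), `has_part` (compositional,
treated as hierarchical), and `has_role` (links a molecule to a
biological/chemical role class). Everything else (e.g.
`has_functional_parent`) is non-hierarchical, is stored as relation
`"other"`, and is excluded from both annotation and display. A term is a
**molecule** exactly when it carries an InChI line notation; the InChI
string itself is an opaque marker — no chemistry is performed. All other
terms are **classes**.

Membership propagates from molecules upward: a molecule belongs to every
class in its ancestor closure over `{is_a, has_part, has_role}`, with two
deliberate restrictions:

* `has_role` is taken only as the first hop from a molecule and never
  chained class-to-class (a role class that itself "has role" something
  does not pass its molecules along); inside the role branch, `is_a`
  chains normally. This matches the usual reading of "molecule has_role
  antibiotic, antibiotic is_a drug".
* `has_part` participation in membership is controlled by
  `propagate_has_part` (default `TRUE`). The source material names
  `has_part` only for the display graph; because the display "relies on
  the transitivity of the used relationships", we treat it as hierarchical
  for membership too, with the flag available to recover the
  display-only behaviour.

The background population is always the analysed ontology itself: `N_e`
molecules and `N_c` classes are counted on the branch-restricted graph
actually being analysed (structural, role, or all), so that a role-branch
analysis has a coherent role-annotated population rather than the whole
file's.

## Plain analysis

For a recognised, deduplicated sample of $n$ molecules, each class hit at
least once is tested with the one-sided binomial tail
$p = P[X \ge k]$, $X \sim \mathrm{Bin}(n, K/N_e)$. Classes never hit are
not tested: a class with zero observations cannot be over-represented, and
keeping the BH family to the tested classes keeps the correction finite
and mirrors what the result graph displays. The literal sentence in the
source describes dividing by the number of *classes*; that variant is
preserved as `population_mode = "classes"`, but the default is the
molecule-count denominator, which is the statistically coherent binomial
population for trials defined over queried molecules. Under-representation
is out of scope.

## Weighted analysis

Weights in $[0,1]$ accompany each identifier. For a class with $m$ sample
members of accumulated weight $S$, the p-value approximates
$P[\sum_{j=1}^m W_j \ge S]$ with $W_j$ iid from the *empirical*
distribution of the complete submitted weight list (including entries
later found unrecognised — the submitted list is the declared null).
The approximation is the Lugannani–Rice saddlepoint tail on the empirical
CGF $K(t) = \log \tfrac1B \sum_i e^{t w_i}$ (computed with max-shift
stabilisation):

$$\hat w = \operatorname{sign}(\hat t)\sqrt{2(\hat t S - m K(\hat t))},
\qquad \hat u = \hat t \sqrt{m K''(\hat t)},$$
$$p \approx 1 - \Phi(\hat w) + \phi(\hat w)(1/\hat u - 1/\hat w),$$

with $\hat t$ the root of $m K'(\hat t) = S$.

Numerical choices (all this package's decisions, validated against a
Monte-Carlo resampling oracle in the acceptance suite):

* $\hat t$ is found by Newton iteration safeguarded by bisection on a
  bracketing interval, to residual $|mK'(\hat t) - S| \le 10^{-10}
  \max(1, S)$.
* For $|\hat t| < 10^{-8}$ the formula degenerates ($1/\hat u - 1/\hat w$
  cancels badly); a normal approximation on the mean/variance of the
  background is used instead.
* $m = 1$ classes use the exact empirical tail proportion: a saddlepoint
  on a single lattice-like draw is unreliable, and the exact count is
  free.
* Boundary cases: $S \le m\,\min w$ gives 1, $S > m\,\max w$ gives 0, and
  at the upper support point the exact point-mass power
  $(\Pr[W = \max w])^m$ is returned. Results are clamped to $[0,1]$.
* No lattice/continuity correction is applied; the acceptance tolerance
  (15% relative against $10^6$ Monte-Carlo replicates) absorbs the
  discreteness of empirical backgrounds.

With fewer than two distinct weights the background is degenerate; the
analysis warns and falls back to plain semantics on the id set, which also
guarantees that all-equal-weight input reproduces the plain ranking
exactly.

**Fragment analysis** is the weighted analysis forced onto the structural
branch, with molecule leaves and root vertices protected from pruning (see
below): the use case is ranking candidate structures for fragmentation
spectra, where the molecular leaves are the objects of interest.

## Multiple testing and per-class descriptives

Raw p-values are corrected with Benjamini–Hochberg's step-up FDR across
the tested classes, uniformly in all three modes. Each row reports the
fold of enrichment $(k/n)/(K/N)$ — undefined (exported as an empty cell)
when $K = 0$ — and the sample percentage $100k/n$. Rows are ordered by
`p_adj`, then `p_raw`, then `class_id`, a fixed total order that makes
output byte-reproducible.

# Pruning

The result graph is the analysed ontology restricted to `is_a`/`has_part`
with statistics attached to tested nodes. Five operators compact it:

* **zero-degree vertex** — drops isolated nodes;
* **root children** (`levels`) — drops every node within `levels` levels
  of a root (depths $0..\text{levels}-1$, minimum distance over all
  roots); these are very general classes like "chemical entity";
* **molecule leaves** — drops InChI-bearing nodes with no incoming edge;
* **high-p-value branch** (`alpha`) — a node is removed iff *every* node
  in its down-set (itself and all descendants toward the leaves) has
  p > `alpha`; equivalently, a node survives iff it or some descendant is
  significant, so ancestors of significant nodes are always kept. It
  operates on the BH-corrected p by default (configurable to raw);
  nodes without statistics count as high-p.
* **linear branch collapse** — maximal stretches of nodes with exactly
  one incoming and one outgoing edge are removed and replaced by a single
  edge between the surrounding nodes, with the removed ids recorded on
  the replacement edge (`collapsed_count` in exports). The surrounding
  nodes must themselves be non-branching at the junction: the sides of a
  diamond are not collapsed, which also guarantees that reachability
  between retained nodes is exactly preserved.

A **strategy** is three ordered pruner lists — pre-loop (once), loop
(repeated until a full pass changes neither nodes nor edges), final (once)
— plus a set of protected node categories. The loop terminates because
each pass either removes something or exits; a guard trips at
$10|V|$ passes. Presets:

| preset | pre-loop | loop | final | protected |
|---|---|---|---|---|
| `plain_default` | high-p(α), collapse, root-children(3) | mol-leaves, high-p, collapse, zero-degree | — | — |
| `weighted_default` | same | same | zero-degree | — |
| `fragment_default` | high-p(α), collapse | high-p, collapse, zero-degree | — | molecule leaves, roots |

The plain preset is the published strategy verbatim. The final-phase
composition for the weighted and fragment analyses is not specified in the
source; the weighted final zero-degree pass and the fragment preset's
protections are this package's declared decisions. For fragments the
protection set (rather than merely omitting the molecule-leaves and
root-children pruners) is what actually honours "terminal molecular leaves
or root vertices are not removed": without it the high-p pruner would
silently delete untested molecule leaves.

# The synthetic world

`make_ontology()` emulates the features of a curated chemical ontology
that the engine exercises: a structural `is_a` DAG grown by preferential
attachment to earlier classes (each class draws 1..`max_parents` parents),
sparse `has_part` edges, a role branch under a root named "role" reachable
from molecules via `has_role`, InChI-marked molecule leaves, and one motif
of each pruner target (a 3-node linear chain, a diamond, an isolated
class). A **planted class** is attached directly under the structural root
and holds `planted_class_size` molecules exclusively. This top-level
placement is deliberate: with the planted class nested under a small
intermediate class, that ancestor (planted set plus two or three
molecules) is *genuinely* and sometimes more sharply enriched — correct
behaviour of the method, but it makes "the planted class ranks first"
ill-posed. At top level the only proper ancestors are near-background, and
the planted signal is identified with exactly one class.

`make_sample()` draws the plain sample without replacement with
`planted_effect`-fold odds for planted molecules (effect 1 = exchangeable
null), and in weighted mode submits every molecule with truncated-normal
weights: background centred at 0.1 (sd 0.1), planted centred at
$0.1 + 0.8(1 - 1/\text{effect})$ — 0.9 for a strong effect, collapsing to
the background at the null.

The default stated world for recovery checks is 2000 classes, 500
molecules, a planted class of 20, effect 10, samples of 40 — sizes on the
order of a single ontology branch and a realistic metabolomics hit list.
What a green recovery test establishes: under a strong, exclusive,
top-level planted signal, both analyses put that class first (competition
ranking on `p_adj`; BH flattens the top ranks into exact ties, so rank-1
is defined as attaining the minimal `p_adj`). What it does not establish:
behaviour under correlated annotations, partially overlapping signals,
real ChEBI depth (~10⁵ terms), or identifier noise beyond
unrecognised-id dropping.

# Degenerate inputs and edge behaviour

* Unknown sample ids are dropped with a report; the recognised molecules
  then act as a subsample of the submitted set, and the run report says
  so. A fully unrecognised sample is a hard error listing the ids.
* Duplicate ids collapse to one entry (weighted: keeping the maximum
  weight) with a count in the report.
* Obsolete ontology terms are parsed and flagged but excluded from edges,
  molecule sets and indices; edges to undeclared or obsolete targets are
  dropped and counted in the parse report.
* An ontology with no InChI-bearing term cannot be analysed (no
  population) and errors immediately.
* `mode = "fragment"` silently forces `branch = "structural"`; plain mode
  rejects weighted rows and vice versa.

# Known limitations

* The empirical-background assumption means weighted p-values are
  conditional on the submitted weight list; they are not calibrated
  against any external population.
* SIF export is lossy by design (no attributes); GraphML and node-link
  JSON are the lossless hand-offs.
* No OWL parsing, no identifier mapping from other naming systems, no
  structure-based class assignment: inputs must already be ontology
  CURIEs (bare integers are normalised to the `CHEBI:` prefix).
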