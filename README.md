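# chemenrich

Ontology-based enrichment analysis for sets of small molecules.

Metabolomics and systems-biology experiments produce lists of metabolites —
often with intensities, fold-changes or identification scores attached. To
interpret such a list one asks which chemical families or biological roles
are over-represented in it, relative to a background ontology of small
molecules such as ChEBI, where fully specified molecules (terms carrying an
InChI) sit at the leaves of a structural `is_a` hierarchy and connect to a
parallel role hierarchy through `has_role`. `chemenrich` answers that
question: it parses a ChEBI-style OBO file into a typed directed graph,
propagates molecule membership up the hierarchy, tests every ontology class
hit by the sample, corrects for multiple testing, and compacts the result
into a small annotated graph that can be exported to standard network
formats.

## The statistics

**Plain (unweighted) analysis.** For a recognised sample of *n* molecule
identifiers and a class containing *K* of the *N* background molecules,
each queried identifier is a Bernoulli trial with success probability
*p = K/N*, and the class's raw p-value is the upper binomial tail

p_raw = P[X ≥ k],  X ~ Binomial(n, K/N),

where *k* is the number of sample molecules in the class. Because *p*
depends on the class's population share, equal success counts in two
classes do not imply equal enrichment. (A `population_mode = "classes"`
option divides by the number of ontology classes instead of molecules.)

**Weighted analysis.** Each identifier carries a weight in [0, 1]
(intensity, fold-change, p-value, ...). For a class whose *m* sample
members accumulate weight *S*, significance is the tail probability
P[Σ W_j ≥ S] under iid draws from the empirical distribution of the
complete submitted weight list, approximated by the Lugannani–Rice
saddlepoint formula on the empirical cumulant generating function
K(t) = log mean exp(t·w_i):

ŵ = sign(t̂)·√(2(t̂S − mK(t̂))),  û = t̂·√(mK″(t̂)),
p ≈ 1 − Φ(ŵ) + φ(ŵ)(1/û − 1/ŵ),

with t̂ solving mK′(t̂) = S. Classes with a single member use the exact
empirical tail count. **Fragment analysis** is weighted analysis restricted
to the structural branch (inputs read as molecular fragments from
fragmentation mass spectrometry), with molecule leaves and root vertices
protected from pruning.

All raw p-values are corrected with the Benjamini–Hochberg step-up FDR over
the family of tested classes; each row also reports the fold of enrichment
(k/n)/(K/N) and the sample percentage 100·k/n.

**Pruning.** The result graph (restricted to the hierarchical `is_a` and
`has_part` relations) is compacted by five operators — zero-degree vertex,
root-children (top levels), molecule leaves, high-p-value branches, and
linear-branch collapse — composed into a strategy with a pre-loop phase, a
loop phase applied to fixpoint, and a final phase. Presets `plain_default`,
`weighted_default` and `fragment_default` are provided and fully
overridable.

## Worked example

No ontology download is needed: the package generates ChEBI-like synthetic
ontologies with a planted enriched class.

```r
library(chemenrich)
spec <- fixture_spec(n_classes = 200, n_molecules = 120,
                     planted_class_size = 12, planted_effect = 10,
                     sample_size = 40, role_fraction = 0.2, seed = 1)
fix <- make_ontology(spec)                      # 370 terms, planted CHEBI:1250
smp <- make_sample(fix$graph, spec, "plain")    # 40 ids, 10x odds for planted
res <- run_analysis(fix$graph, smp, analysis_config("plain"))
head(res$rows[, c("class_id", "name", "k", "n", "K", "N", "p_raw", "p_adj", "fold")], 5)
```

```
   class_id                 name  k  n  K   N        p_raw      p_adj     fold
 CHEBI:1250        planted class 12 40 12 120 0.0003808343 0.04265344 3.000000
 CHEBI:1132 structural class 131  2 40  2 120 0.1433298524 0.86604760 3.000000
 CHEBI:1234        role class 25  3 40  5 120 0.2320761276 0.86604760 1.800000
 CHEBI:1038  structural class 37  8 40 18 120 0.2440667370 0.86604760 1.333333
 CHEBI:1025  structural class 24  2 40  3 120 0.2642214679 0.86604760 2.000000
```

The planted class tops the table: 12 of its 12 background molecules
(K = 12 of N = 120) appear among the 40 sampled ids (k = 12), a 3-fold
enrichment with BH-corrected p = 0.043; everything else is background.
`res$graph` holds the pruned result graph and `export_bundle(res, "out/")`
writes `table.tsv`, `graph.graphml`, `graph.sif` and `graph.json`.

The same works from the command line:

```sh
Rscript inst/exec/chemenrich fixtures --classes 200 --molecules 120 --seed 1 --out fx/
Rscript inst/exec/chemenrich run --ontology fx/ontology.obo --input fx/sample.tsv \
    --mode plain --out out/
```

(weighted input is `id<TAB>weight` per line; bare numeric ids are
normalised to `CHEBI:` CURIEs).

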