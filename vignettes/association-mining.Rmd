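---
title: "Mining chemical–biomedical associations from literature knowledge graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining chemical–biomedical associations from literature knowledge graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemesh)
```

## The problem

Interpreting a metabolic signature — a list of compounds that discriminate an
experimental condition — requires surveying the literature that links each
compound to diseases, processes, anatomy and organisms. PubMed articles are
indexed by trained curators with MeSH descriptors, and chemical databases
cross-reference articles to the compounds they discuss. `chemesh` models this
federation as a knowledge graph over four node types (articles, compounds,
chemical classes, MeSH descriptors) and five edge relations, and asks, for
every chemical-entity/descriptor pair, whether the two are mentioned together
in more articles than independence would predict.

The statistical core is over-representation analysis: for a pair with
propagated corpora of sizes $n_{chem}$ and $n_{mesh}$ and joint support $a$
within a universe of $N$ articles, the right-tailed Fisher exact test scores

$$p = P(X \ge a), \qquad X \sim
\mathrm{Hypergeom}(N,\; n_{mesh},\; n_{chem}),$$

p-values are adjusted with Benjamini–Hochberg across all tested pairs, and
pairs with $q < 10^{-6}$ are instantiated as `skos:related` triples. The
odds ratio $ad/bc$ and the Pearson $\chi^2$ statistic are reported as
effect-size and ranking aids: when thousands of q-values underflow to zero,
$\chi^2$ still orders them.

## The true-path rule

Annotation hierarchies obey the true-path rule: an article indexed with
*Diabetes Mellitus, Type 2* is implicitly about the broader *Glucose
Metabolism Disorders*; an article discussing glucose implicitly supports the
class of monosaccharides. `build_corpus_index()` therefore computes two
corpora per entity. The *explicit* corpus comes straight from the edges. The
*propagated* corpus is the union of explicit corpora over the entity's
descendant closure: descriptors are closed over dot-prefix extension of
their MeSH tree numbers (the parent of `C18.452.394` is `C18.452`;
polyhierarchical descriptors union over all their tree numbers), classes
over the inverse of `rdfs:subClassOf`. Propagation runs bottom-up over a
topological order with set-union memoisation; the result is contractually
identical to a per-node closure union, and the test suite checks that
equivalence against a brute-force oracle on random graphs.

Both analysis modes are exposed (`use_propagation` in
`enrichment_config()`), because the comparison itself is informative:
`compare_association_sets()` partitions significant pairs into those *lost*
by propagation (inflated descriptor corpora deflate spurious hits — the
water/eukaryota pattern), *shared*, *new*, and the *novel* subset of new
pairs that have zero explicit co-occurrence and are discoverable only
through the hierarchy.

## Fragility and corpus profiling

A q-value threshold says nothing about how many articles an association
actually rests on. Two complements are computed for each significant pair:

* **Fragility index** (`fragility_index()`): the minimal number of
  supporting articles whose removal pushes the Fisher p-value above the
  $10^{-6}$ threshold. A removed article is deleted from the literature
  entirely — $a$, both margins and $N$ all decrement — modelling the
  retraction of spurious or salami-sliced publications. The scan is bounded
  by the Jeffreys interval of the co-occurrence proportion $a/n_{ref}$ with
  $n_{ref} = \min(n_{chem}, n_{mesh})$: quantiles of
  $\mathrm{Beta}(a + \tfrac12,\, n_{ref} - a + \tfrac12)$ at level 0.95. At
  most $r_{max} = a - \lceil \mathrm{low} \cdot n_{ref}\rceil$ removals are
  entertained; an association still significant there is reported with a
  robust-cap marker (`>=r_max` in the results table). The alternative
  removal model — the article keeps its single-entity annotations, so only
  $a$ and one margin move — was considered and rejected as inconsistent
  with the retraction motivation; this is a package design choice.
* **Importance profile** (`importance_scores()`): for the articles in cell
  $a$, every explicitly annotated descriptor is scored
  $tf \cdot idf$ with $tf$ its within-corpus frequency and
  $idf = \ln(N / |\text{explicit corpus}|)$. Natural log over the explicit
  (not propagated) descriptor corpus is used: the profile asks what the
  curators actually wrote on these articles, and widely distributed terms
  must rank low however frequent they are. The top 20 are reported by
  default. The exact base/smoothing of the published score is not
  recoverable from its description; the tests therefore pin the formula
  above, not external values.

## The synthetic generator as study design

`generate_synthetic_kg()` emulates the federation's shape so the whole
pipeline is testable without any download: a forest of descriptor trees
(one per MeSH category letter), a chemical-class DAG with occasional
multiple inheritance, compounds attached to leaf classes, and independent
Bernoulli annotation of articles by leaf descriptors and compounds. A
planted pair replaces independence by a joint law with
$P(\text{both}) = \lambda\, p_c p_d$ (capped at the smaller marginal) while
preserving both marginal rates, so the planted signal is exactly the
dependence the Fisher test measures and enrichment is parameterised by the
true odds multiplier $\lambda$. Identical seeds regenerate identical
graphs, and the caller's RNG state is left untouched.

Defaults were fixed once as the study conditions: 2000 articles, depth-3 /
branching-3 trees under categories C and D, 60 compounds, a 3×4 class DAG
and 5% base annotation rates — small enough for interactive use, dense
enough that every relation type occurs. The recovery suites use 2500
articles with 20% rates so that planted corpora reach ≥500 articles, and
the oracle-equivalence suites use graphs of roughly 60–120 nodes; these
sizes are the package's chosen benchmark conditions. What the generator
deliberately does **not** model: citation dynamics, publication dates,
topic imbalance, and annotation noise correlated across descriptors. A
passing recovery suite therefore demonstrates correctness of the counting
and testing machinery under clean sampling assumptions, not performance on
real PubMed metadata.

`evaluate_recovery()` credits ancestor-level hits as true: if (compound,
leaf descriptor) is planted, every (ancestor chemical entity, ancestor
descriptor) combination genuinely satisfies the planted dependence under
the true-path rule, so only hits outside that grid count toward the false
discovery proportion.

## Numerical and filtering choices

* Hypergeometric tails go through the log-space survival function, stable
  for universes up to at least $10^7$ articles; below the double-precision
  floor (~1e-320) the p-value underflows to exactly 0, which by convention
  means "smaller than representable" and hands ranking to $\chi^2$.
* $\chi^2$ is computed without continuity correction (it ranks, it does not
  infer) and defined as 0 when a margin is empty.
* Odds ratios at zero cells get the Haldane–Anscombe +0.5 correction with
  an explicit flag column.
* Candidate pairs require ≥1 propagated co-occurrence by default
  (`min_support = 1`): a zero-support pair has $p = 1$ under a right tail,
  so testing it only dilutes the BH family.
* Descriptors are filtered to the MeSH categories relevant for chemical
  interpretation — tree letters A, B, C, D, F, G, I, J (Anatomy, Organisms,
  Diseases, Chemicals and Drugs, Psychiatry and Psychology, Phenomena and
  Processes, Anthropology/Education/Sociology, Technology/Industry/
  Agriculture) — configurable via `allowed_categories`.
* Chemical classes with ≥1000 transitive member compounds are excluded as
  uninformatively broad (`class_size_cap`).
* BH adjustment defaults to one global family per run; `bh_scope =
  "per-entity-kind"` adjusts compound–MeSH, class–MeSH and MeSH–MeSH
  families separately, since the family structure of a production release
  split across ontologies is a legitimate alternative.
* The corpus universe $N$ defaults to all articles in the graph; a
  `mesh_annotated` mode restricts it to articles with at least one
  descriptor, for corpora harvested without guaranteed indexing.
* Output ordering is deterministic — $\chi^2$ descending, ties by
  (chem, mesh) — so result tables diff cleanly, and all writers are
  idempotent.
* Explicit `meshv:parentTreeNumber` assertions are parsed and checked
  against dot-prefix parentage; disagreement is a validation violation
  rather than a second source of hierarchy, keeping TSV ingestion (which
  has no such assertions) semantically identical to RDF ingestion.

## Degenerate inputs

Empty graphs validate vacuously and enrich to an empty record set. A
descriptor mentioned in annotations but lacking any tree number is parsed,
flagged by `validate_kg()`, excluded from category filtering and propagates
nothing beyond its explicit corpus. Classes isolated from every edge
survive round trips through explicit declaration rows/triples. Articles
without annotations count in $N$ (they are evidence of absence) but cannot
survive an RDF round trip, which only carries edges; the TSV codec keeps
them via `articles.tsv`.

## Known limitations

* The RDF reader implements a deliberately small dialect — one statement
  per line, `@prefix`/`PREFIX`, comments, IRIs or CURIEs, plain or typed
  literals — sufficient for the files the package writes and for
  line-oriented exports of the modelled predicates, not a general Turtle
  parser.
* MeSH qualifier terms and supplementary concept records are not modelled;
  only main descriptors participate.
* Compound metadata (mass, InChIKey, stereoisomer links) is ignored at
  parse time.
* Fragility assumes the p-sequence over removals is monotone (verified for
  every scanned table; a detected violation falls back to the global
  minimum crossing), and its Jeffreys reference denominator
  $\min(n_{chem}, n_{mesh})$ is one defensible reading of an
  under-specified published definition; the cap is reported explicitly so
  downstream users can recompute under other conventions.

## A worked run

```{r}
sim <- generate_synthetic_kg(synthetic_config(
  planted = data.frame(chem = 1, mesh = 1, lambda = 20), seed = 7))
records <- run_enrichment(sim$kg)
head(records[records$significant,
             c("chem_id", "mesh_id", "support", "p_value", "q_value",
               "odds_ratio", "chi2", "fragility")])
evaluate_recovery(records, sim$truth, sim$kg)[c("power", "fdp")]
```

The planted compound–descriptor pair is recovered together with its
ancestor class and ancestor descriptors — the abstraction levels the
true-path rule is meant to surface.
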