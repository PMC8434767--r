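---
title: "Nested-collection queries, shredding, and skew-aware execution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested-collection queries, shredding, and skew-aware execution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrcshred)
```

## The problem

Integrative cancer analyses combine flat tables (clinical samples, gene
copy numbers, expression) with nested collections: a bag of annotated
somatic mutation occurrences, each carrying a bag of candidate-gene
annotations, each carrying a bag of sequence-ontology consequence terms.
Distributed dataflow engines distribute such data by *top-level* tuples, so
few top-level tuples or large inner collections defeat parallelism, and the
conventional workaround — flattening the nesting before joining — is both
lossy (parents with empty inner collections vanish) and explosive (a
chromosome-scale variant table with per-sample genotypes flattens to
billions of rows; see `outer_flatten_cardinality()`).

This package implements, at desk scale, a query system for a nested
relational calculus (NRC) over bags of tuples, with two compilation routes
to a flat dataflow algebra and a simulated partitioned runtime that
accounts data movement. The point is not wall-clock speed — partitions are
evaluated sequentially — but *placement and volume fidelity*: the package
measures what a distributed engine would shuffle, broadcast, and pile onto
single partitions, and verifies that all routes compute identical bags.

## The language

Programs are comprehensions over bags of tuples
(see `inst/GRAMMAR.md` for the grammar):

```{r}
cat(program_source("OccurAgg"))
```

`sumBy[k; v](e)` sums `v` per distinct `k` over a flat input; `groupBy[k ->
g](e)` nests the non-key attributes per key (sugar for a deduplicated key
bag plus a filtered comprehension — `desugar_groupby()` makes that
explicit); `dedup` removes duplicates by deep multiset equality; `++` is
additive bag union. Conditionals live in bag positions only: a false
condition contributes the empty bag. The reference interpreter
`eval_reference()` gives these constructs their direct nested semantics and
is the oracle both compilers are tested against. (Internally it hash-indexes
input scans on equality-guarded attributes and memoizes input-sourced
comprehensions on their free variables; both are pure caching and change no
semantics.)

## Standard (flattening) compilation

`compile_standard()` unnests a program level by level into a plan of flat
operators (scan, select, project, dense-id assignment, outer-flatten, join,
keyed sum, group, reattach, distinct, union). Equality conjuncts between a
new generator and already-bound variables become join keys; generators over
nested attributes become outer-flattens whose NULL-padded rows stand for
empty bags; each level is indexed with dense ids, and every nested output
attribute is regrouped onto its parent by that maintained id prefix with a
*left-outer* reattachment. This is the correctness-critical design choice:
predicates and joins inside a child level may drop all of a parent's rows,
and the outer reattachment restores that parent with an empty bag, exactly
as the nested semantics requires. The ids are internal; they never appear
in results. `compile_standard(naive = TRUE)` builds the lossy diagnostic
variant (inner flatten, inner reattachment) that reproduces the classic
flattening defect — parents with empty inner collections disappear.

Two algebraic rewrites are provided. `push_projections()` computes, per
plan edge, which columns — and for bag columns, which element subfields —
are used downstream, and prunes every scan accordingly (a scan of the
occurrences source in the aggregation example retains only the sample id
and the candidates' gene/impact subfields). `push_partial_aggregates()`
rewrites a keyed sum of a product with one factor per side of an inner
equi-join: within each join-key group the joined pairs form a cross
product, so the sum factorizes and the left factor can be pre-summed
*locally* (a combiner, no shuffle of its own) before the join, shrinking
the relation entering the join's shuffle. Both rewrites are applied
explicitly and verified result-equivalent; compilation itself stays
rewrite-free so plans remain easy to read.

## Shredded compilation

`shred_type()` encodes a nested type as flat relations in database style:
one relation per collection level, every bag attribute replaced by a label
field that acts as a foreign key into the child level's dictionary.
`shred_value()` encodes values against that schema (empty inner bags become
empty dictionary entries, never dropped; with `sharing = TRUE`, parents
with identical inner bags share one entry), and `unshred_value()` inverts
it, treating a dangling label as a hard integrity error.

`shred_program()` transforms a program into flat components, one per output
collection level. The top component replaces each bag-valued field with a
label expression whose context is the *minimal binding set*: the free
outer-variable projections of the child expression. We compute that set
syntactically (every `var.attr` the child mentions from an enclosing
level); this is the package's own reading of label minimality, and a test
verifies that widening a context never changes the unshredded output.
Because labels are content-addressed — a label *is* its level plus its
binding values — two parents with equal bindings share one label, and each
child level is computed once per *distinct* label: the label domain is
materialized as a deduplicated `<level>_dom` assignment that the child
component iterates. Generators over nested input attributes become
label-equality joins against the input's dictionary relations. The result
is an ordered *flat* program, evaluable by the same interpreter and
compilable by the same standard compiler onto the partitioned runtime;
per-assignment shredded values are reassembled from the component results,
with dictionary key sets taken from the label domains so empty children
survive.

Label sharing is what makes the representation succinct: when the
occurrences source is rebuilt by joining mutations to their shared
annotations, the flattened nested result repeats each shared annotation per
sample, while the candidates dictionary holds each annotation once — the
dictionary coincides with the unique annotations input, and the gap widens
with the sharing rate.

## The simulated runtime and skew handling

A `partitioned_bag()` is an ordered list of relations with an optional
co-residency guarantee. Placement is round-robin; key shuffles use a seeded
polynomial string hash of the canonicalized key tuple, so placement,
results and statistics are bit-reproducible given the configuration's
`hash_seed`. "Load" is measured in tuple counts (tuples nested inside bag
columns count too, since they travel with their parents); an optional
per-partition cap turns overload into a simulated spill error. Statistics
track shuffled tuples (tuples whose hash target differs from their origin),
broadcast tuples (relation size times partition count), per-operator
partition loads, and the maximum partition load.

Key-based shuffles concentrate all tuples of a key on one partition, so a
dominant key — a tumor site with most of the cohort, a pathway holding most
mutated genes — overloads a single worker. `detect_heavy_keys()` implements
four detection strategies (exact `full`; per-partition `partial`; seeded
`sample`, default 10% per partition; `slice` over each partition's first
1,000 tuples), classifying a key as heavy when its tuple share reaches the
threshold (default 2.5%, ties heavy; shares are tuple counts, not bytes —
the package's documented reading of the threshold). `skew_aware_join()`
shuffles light keys normally but leaves heavy-key tuples in place and
broadcasts the matching other side, so the union equals the skew-unaware
join with a strictly lower maximum load under skew. `skew_aware_group()`
keeps heavy groups as distributed bags (the dictionary-style representation
of a group) rather than materializing them on one partition; aggregation
over them proceeds from per-partition partials.

## The analysis programs

Seventeen programs ship as parsed ASTs (`program_suite()`), spanning the
projection/join/aggregation family over occurrences and copy number, the
mutational-burden programs (per-gene allele-dosage burden over VCF-backed
variants; per-pathway impact burden with a raw-count mode for
classification features; the labeled feature matrix), the five-stage
driver-gene pipeline, the clinical exploration programs, and the
annotation-sharing construction. Design choices worth stating:

* **Impact encoding.** The occurrences schema stores the candidate impact
  as a numeric score in `[0, 1]`; qualitative VEP levels are encoded at
  generation/ingest time via `score_params()` (defaults HIGH 0.8, MODERATE
  0.5, LOW 0.3, MODIFIER 0.15 — package defaults, not literature values).
  Consequence terms are scored relationally through the SOImpact lookup
  table, which keeps conditionals in bag positions.
* **Hybrid-score arithmetic.** The staged scores are: hybrid = sum over
  candidates and consequences of impact x consequence score x copy number;
  network node score = sum over edges of source-gene hybrid x edge
  distance; effect = node score + own hybrid; connection = effect x FPKM;
  connectivity = connection summed over samples. The exact weighting is
  this package's documented interpretation of the staged integration; it
  is parameterized by the inputs, and the tests pin it with a closed form
  ((h·d + h)·f for a one-gene, self-edge system) rather than literature
  values.
* **Coordinates.** Gene intervals are 1-based and inclusive on both ends
  (the VCF convention); the variant-to-gene flanking region is symmetric,
  default 0.
* **Aggregates.** Summed attributes are real-typed regardless of summand
  kind, and accuracy percentages from confusion counts are truncated (not
  rounded) at two decimals.

## Synthetic data

`generate_dataset()` emulates the *structural and statistical* shape the
methods exercise, not biological content: Zipf-skewed tumor-site assignment
(exponent 1.0 by default, 1.5 in the `skewed` preset — the dominant site
then far exceeds the heavy-key threshold), an empty-candidates probability
(0.3 by default, the empty inner bags that break naive flattening), an
annotation-sharing rate (0.5 in the `sharing` preset: a new mutation event
reuses an existing shared mutation with that probability), Poisson mutation
counts (mean 2 per sample), candidate bags of 1–3 entries, 0/1/2 genotype
calls with probabilities 0.6/0.3/0.1, log-normal FPKM, and uniform small
copy numbers. Everything is deterministic given the seed, referentially
closed (`validate_dataset()`), and round-trips through its native formats
(TSV, JSON lines, minimal VCF v4.2 with GT-only genotype columns, GMT).

What passing tests on this generator do and do not show: they establish
that the two compilation routes implement the same semantics as the nested
interpreter across empty bags, skewed keys and shared annotations, and that
the movement statistics behave as the method predicts. They do not
establish biological realism — real annotation structures (multi-aliquot
samples, multi-allelic sites beyond the VCF reader's splitting, correlated
expression) are out of the generator's scope — and measured tuple counts
are a proxy, not byte-accurate memory modeling.

## Problem sizes and numerical choices

The shipped test suite runs the three-way equivalence over all seventeen
programs on the `tiny` (50 samples) and `skewed` (200 samples) presets,
the skew checks on a 10,000-tuple Zipf(1.2) fixture over 8 partitions, the
sharing experiment on the `sharing` preset (60 samples), and the planted
driver-gene recovery over 20 seeds at 20 samples x 15 genes; these sizes
are the package's chosen study conditions. Multiset equality
(`bag_equal()`) compares numerics after rounding to 8 significant digits
so that sums accumulated in different orders across routes compare equal;
division by zero is an error everywhere; unknown predicates over NULL
(outer-flatten padding) evaluate to unknown and select nothing. Ties at
the heavy-key threshold count as heavy; the `sample` detector uses seeded
sampling without replacement per partition.

## Known limitations

The compilers support the comprehension fragment the shipped programs and
the randomized property tests exercise: generators over inputs and nested
attributes, equality and range predicates, nested tuple heads, `sumBy`,
`groupBy`, `dedup` and bag union. Whole-bag copies of a nested input
attribute pass through the standard route but are not supported by the
shredding transformation (the programs rebuild nested output explicitly).
There is no recursion, no user-defined functions, and no scalar-position
conditional. The runtime is sequential by design; only ordinal
relationships between the routes' movement statistics are meaningful, not
absolute volumes.
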