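# nrcshred

Nested-collection query compilation with shredding and skew-aware
execution, at desk scale, for multi-omics data integration.

Integrative cancer analyses join flat tables (clinical samples, gene copy
numbers, expression) with nested collections — annotated somatic mutation
occurrences carrying bags of candidate-gene annotations, which carry bags
of consequence terms. Distributed engines distribute such data by
top-level tuples, so large or skewed inner collections defeat parallelism,
and the usual workaround — flattening before joining — loses parents with
empty inner bags and explodes in size. This package implements the query
machinery that addresses this, small enough to study on one machine:

* a **nested relational calculus** (NRC) over bags of tuples, with a
  textual surface syntax (`nrc_parse()`, grammar in `inst/GRAMMAR.md`), a
  typechecker, and a reference interpreter (`eval_reference()`) that is
  the semantic oracle;
* **standard (flattening) compilation** (`compile_standard()`): unnesting
  into a flat dataflow plan with NULL-padding outer-flatten, dense unique
  ids, and left-outer regrouping so empty inner bags survive — plus a
  lossy `naive = TRUE` diagnostic that reproduces the classic flattening
  defect, and result-preserving rewrites `push_projections()` and
  `push_partial_aggregates()`;
* **shredded compilation** (`shred_type()`, `shred_value()`,
  `shred_program()`, `unshred_value()`): nested types, values and programs
  become flat relations and flat per-level programs linked by label
  dictionaries with foreign-key semantics, so inner collections stay
  distributed and shared annotations are stored once;
* a **simulated partitioned runtime** (`cluster_config()`,
  `execute_standard()`, `execute_shredded()`): round-robin placement,
  seeded hash shuffles, broadcast, and deterministic accounting of
  shuffled/broadcast tuples and per-partition load;
* **skew-resilient processing** (`detect_heavy_keys()` with full /
  partial / sample / slice strategies, `skew_aware_join()`,
  `skew_aware_group()`): keys holding at least 2.5% of the tuples are
  handled by broadcast instead of shuffling, leaving their tuples in
  place;
* the **multi-omics program suite** (`program_suite()`, 17 programs):
  projection/join/aggregation over occurrences and copy number, gene and
  pathway mutational burden (`gene_burden()`, `pathway_burden()`,
  `burden_features()`), the five-stage driver-gene pipeline
  (`driver_pipeline()`), clinical exploration queries, and the
  shared-annotation construction;
* a **synthetic data generator** (`generate_dataset()`, presets `tiny`,
  `skewed`, `sharing`) with controllable nesting sizes, empty-bag
  probability, Zipf key skew and annotation sharing, plus readers/writers
  for TSV, JSON lines, minimal VCF and GMT.

## Worked example

The tumor-site-grouped hybrid-score analysis groups per-sample, per-gene
scores (mutation impact x copy number) by tumor site — a three-level
nested output — and is run through all three routes:

```r
library(nrcshred)

ds   <- generate_dataset(gen_preset("tiny", seed = 1))
sch  <- omics_schemas()
prog <- program_suite("TGHybridScores")$TGHybridScores

ref <- eval_reference(prog, ds$data)$TGHybridScores
std <- run_standard(prog, sch, ds$data, cluster_config(n_partitions = 4))
shr <- run_shredded(prog, sch, ds$data)

length(ref)                                        # 9 tumor sites
bag_equal(ref, std$results$TGHybridScores)         # TRUE
bag_equal(ref, shr$results$TGHybridScores)         # TRUE
std$stats
#> shuffled_tuples:     1408
#> broadcast_tuples:    0
#> max_partition_load:  155
```

The movement statistics are what a distributed engine would shuffle and
hold per partition (in tuples), computed deterministically from the
cluster configuration's hash seed. Shredding the same program yields one
flat component per output collection level:

```r
sp <- shred_program(prog, sch)
sp$components$TGHybridScores
#> "TGHybridScores_top"  "TGHybridScores_samples"  "TGHybridScores_samples_scores"
```

and the components are themselves a flat program (`print(sp)`) in which
the samples-level label carries only the tumor-site binding and the
scores-level label only the sample id. Two one-liners reproduce printed
arithmetic: the chromosome-scale flattening blow-up and classifier
accuracy from confusion counts:

```r
outer_flatten_cardinality(1103600, rep(2504, 1103600))$outer
#> 2763414400
accuracy_from_counts(444, 1049)
#> 42.32
```

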