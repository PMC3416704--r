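# idbos

Confidence scoring of aggregated protein–protein interactions (PPIs) by
occurrence-preserving shuffling.

## The problem

Literature-aggregated human PPI collections pool reports from many primary
databases. The raw number of times a pair was reported ("occurrence",
O<sub>ij</sub>) is a poor confidence score: the large majority of pairs are
reported exactly once, and heavily studied proteins accumulate reports —
genuine and spurious — in proportion to their popularity rather than their
biology.

`idbos` implements an unsupervised scheme (IDBOS, *interaction detection
based on shuffling*): compare each pair's observed occurrence with its
distribution over randomized record lists in which every protein keeps its
total report count N<sub>i</sub> and self-interactions are forbidden. Per
pair this yields

* a permutation Z-score, Z<sub>ij</sub> = (O<sub>ij</sub> −
  ⟨R<sub>ij</sub>⟩) / σ<sub>R</sub>, and
* an empirical upper-tail p-value, p<sub>ij</sub> ≈ (1/M) Σ<sub>n</sub>
  1[R<sub>ij</sub>(n) ≥ O<sub>ij</sub>]

over M shuffled realizations; the final confidence ranking is the average
of the fractional ranks of the two metrics. The package also provides the
comparator schemes (hypergeometric-test ranking, occurrence ranking,
random-rank and degree-preserving rewired controls), the full evaluation
harness (judgeable/true labelling, accuracy–coverage curves, average
accuracy ⟨A⟩ = (1/N) Σ<sub>r</sub> accuracy(r)·n(r), percent gain over
random ranking, top-k overlap, domain–domain-interaction enrichment),
reference-set construction statistics (ontology ancestor closure,
co-annotation hypergeometric score, tissue-specificity Z-scores,
co-expression scores, top-percent selection), and a synthetic generator of
popularity-biased record streams over a planted interactome so everything
runs without downloads.

It is aimed at anyone who needs high-confidence subsets of aggregated
interaction data, or a popularity-corrected null model for co-occurrence
counts in general.

## Worked example

Simulate a popularity-biased record stream over a planted interactome,
score it, and evaluate the rankings against the planted truth:

```r
library(idbos)

cfg     <- synthetic_config(n_proteins = 60, n_true_pairs = 120,
                            n_records = 600, false_rate = 0.4,
                            popularity_exponent = 1.5, seed = 7)
truth   <- generate_truth(cfg)
records <- generate_records(cfg, truth)
network <- aggregate_records(deduplicate(records[, 1:4]))
network
#> ppi_network: 54 proteins, 125 unique pairs, 600 records

scored <- idbos_score(network, M = 10000, seed = 8)
head(scored[, c(1:3, 4:8)], 5)
#>   protein_a protein_b occurrence      z p z_rank p_rank avg_rank
#> 1     P0006     P0009         10 15.271 0      3      7      5.0
#> 2     P0003     P0020          6 10.664 0      5      7      6.0
#> 3     P0004     P0037          5 10.644 0      6      7      6.5
#> 4     P0002     P0015         10 10.585 0      7      7      7.0
#> 5     P0001     P0007        126  9.712 0      8      7      7.5
```

The top of the list is telling: P0001–P0007, reported 126 times between
the two most popular proteins, ranks *below* P0006–P0009 with only 10
reports — its huge occurrence is largely explained by popularity, which is
exactly the bias the shuffle null removes. Note the p = 0 tie group
(p-values are bounded by 1/M); it is resolved by the Z-ranks through
averaging.

```r
summ <- evaluate_rankings(
  list(idbos = scored,
       occurrence = occurrence_rank(network),
       random = random_rank(network, seed = 9)),
  list(truth = truth))
summ
#>       scheme refset     A A_random gain_pct
#> 1      idbos  truth 0.764    0.296  158.224
#> 2 occurrence  truth 0.468    0.296   58.033
#> 3     random  truth 0.298    0.296    0.543
```

⟨A⟩ is the mean accuracy-at-inclusion over planted true pairs: shuffle
scoring recovers the planted interactome far better than occurrence
ranking (gain 158% vs 58% over the random baseline), and a random ranking
gains nothing.

The same pipeline is available from the shell via the installed
`exec/idbos` script (`simulate`, `score`, `evaluate`, `refset-score`
subcommands; `--help` documents flags and file shapes). All I/O is plain
TSV, and every run writes a JSON manifest with its parameters and seed.

## Package layout

* `R/records.R` — record I/O, deduplication, aggregation into an
  occurrence-weighted network, degrees.
* `R/shuffle.R`, `src/shuffle.cpp` — the randomization engine, Z/p
  scoring, fractional ranking, the exact enumeration oracle.
* `R/ranking.R` — comparator schemes and controls.
* `R/evaluate.R` — reference sets, curves, ⟨A⟩, gain, overlap, DDI
  enrichment.
* `R/refsets.R` — ancestor closure, co-annotation and co-expression
  statistics, top-percent selection.
* `R/synthetic.R` — the generator.
* `R/cli.R`, `exec/idbos` — command-line surface.
* `vignettes/idbos-methods.Rmd` — the model, its assumptions, parameter
  choices and limitations.
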