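---
title: "Scoring aggregated protein interactions by occurrence-preserving shuffling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring aggregated protein interactions by occurrence-preserving shuffling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Aggregated collections of human protein–protein interactions (PPIs) pool
reports from many primary databases and thousands of publications. Two
distortions make the raw report count O_ij (how often pair *i–j* was
reported) a poor confidence score. First, most pairs are reported exactly
once, so occurrence cannot rank-order the bulk of the data at all. Second,
report counts reflect *popularity*: heavily studied proteins accumulate
reports — genuine and spurious — simply because they are assayed more
often, so a moderate O_ij between two famous proteins is far less
surprising than the same count between two rarely studied ones.

`idbos` scores each pair by comparing its observed occurrence with the
distribution of occurrences it attains in randomized versions of the whole
record list, under two constraints: every protein keeps its total report
count N_i (counting multiplicity — this is *not* the degree), and no
protein is ever paired with itself.

## The null model and its sampler

A network with N records is represented as 2N endpoint "stubs" (protein
*i* contributes N_i stubs). A null realization is a uniform draw from all
pairings of the stubs that contain no self-pair. Over M realizations the
engine accumulates, per observed pair, the ensemble mean ⟨R_ij⟩ and
standard deviation σ_R of the randomized occurrence, and the exceedance
count. The two scores are

* the permutation Z-score, Z_ij = (O_ij − ⟨R_ij⟩) / σ_R, and
* the empirical upper-tail p-value, p_ij = #{realizations with
  R_ij ≥ O_ij} / M.

Both metrics carry information the other lacks at finite M (p saturates at
0 for strongly supported pairs; Z is noisy for weakly constrained ones),
so the final score converts each to a fractional rank (ties share the mean
of the ordinal positions they span) and averages the two ranks. Pairs with
identical average rank form an equivalence group and should be treated as
interchangeable downstream; their file order is lexicographic only to keep
outputs byte-stable.

### Sampling without self-pairs, uniformly

A Fisher–Yates shuffle of the stub list paired off consecutively is
uniform over *all* pairings, but conditioning on "no self-pairs" by local
repair (swapping one endpoint of each self-pair with a random stub until
none remain) is measurably biased: on networks small enough to enumerate
exhaustively, repair-only sampling deviates from the exact conditional
distribution by tens of Monte-Carlo standard errors at M = 2×10⁵. The
engine therefore follows repair with `mix_sweeps` Metropolis sweeps (each
sweep proposes 2N random stub transpositions and rejects any that would
create a self-pair). The proposal is symmetric and the chain's stationary
law is exactly uniform over valid pairings; empirically two sweeps already
make the sampler statistically indistinguishable from the enumeration
oracle, and the default is three. `matching_pdf_oracle()` provides the
exact distribution for networks with 2N ≤ 14 and is what the test suite
validates the engine against.

Feasibility requires max_i N_i ≤ N (no protein may hold more than half of
all endpoint slots); the engine refuses infeasible networks explicitly.

## Tunable parameters

* `M` (randomizations): the resolution of p is 1/M and the Monte-Carlo
  error of Z shrinks as 1/√M. 10⁴ is comfortable for desk-scale networks
  (thousands of records); 10⁶ matches the scale used for full
  literature-aggregated corpora. Unitless counts; default in the CLI is
  10⁴.
* `mix_sweeps` (default 3): see above. Increasing it buys insurance at
  linear cost; decreasing below 2 is not recommended.
* `pseudo_count` (default off): replaces k/M by (k+1)/(M+1). The plain
  estimator is the default and is what the empirical-tail definition
  above states — the resulting large tie group at p = 0 is resolved by
  the Z-rank through averaging. The
  pseudo-count variant is available for users who need strictly positive
  p-values.
* σ_R uses the sample (n−1) normalization. With M ≥ 10⁴ the difference
  from the population normalization appears only around the fourth
  significant digit of Z.
* When σ_R = 0 the Z-score is defined as 0 if O_ij equals ⟨R_ij⟩ and
  otherwise as sign(O_ij − ⟨R_ij⟩) × (largest finite Z in the run + 1):
  the pair sorts beyond every finite-Z pair without inventing a
  magnitude. Such pairs are reported with a message.

## Comparator rankings

* **Hypergeometric test**: the probability of observing O_ij or more
  co-occurrences when protein *i*'s N_i endpoint slots are drawn from the
  2N total slots, N_j of which belong to *j*:
  p = Σ_{n=O_ij}^{min(N_i,N_j)} C(N_j,n)·C(2N−N_j, N_i−n) / C(2N, N_i),
  valid for N ≫ N_i·N_j. Crucially, this
  background assigns positive probability to self-pairings — roughly
  proportional to N_i² — which deflates the null occurrence of non-self
  pairs involving popular proteins and therefore inflates their apparent
  significance. The minimal two-stub network {A:1, B:1} shows the
  mechanism in isolation: the shuffle null forces A–B (tail mass 1), the
  hypergeometric gives 0.5.
* **Occurrence**: fractional ranks on O_ij directly.
* **Random-rank control**: the pairs keep their identity but receive a
  random permutation of ranks.
* **Rewired control**: degree-preserving double-edge swaps on the
  unique-pair graph (self-pairs and duplicate edges rejected). The control
  operates on unique pairs; occurrence multiplicities are deliberately not
  carried over, since its role is to destroy the interaction identities.

## Evaluation harness

Against a reference set (a protein universe plus listed "true" pairs), a
scored pair is *judgeable* when both proteins are in the universe and
*true* when the pair is listed. Sweeping the rank threshold from best to
worst — tie groups always enter together — yields an accuracy–coverage
curve; the summary statistic is the average accuracy
⟨A⟩ = (1/N) Σ_r accuracy(r)·n(r), where n(r) counts the true pairs first
included at threshold r, i.e. the mean accuracy-at-inclusion over true
pairs. Scheme quality is reported as the percent gain
(⟨A⟩ − ⟨A_R⟩)/⟨A_R⟩ × 100 over the random baseline.

The default baseline ⟨A_R⟩ is analytic: the fraction of true pairs among
judgeable pairs, which is the accuracy of every threshold under no
ranking information and the large-n limit of a sampled random ranking's
⟨A⟩. The two are *not* identical at finite n: the exact expectation of a
sampled ranking's ⟨A⟩ is (1/n) Σ_k (1 + (k−1)(T−1)/(n−1))/k, which sits
an O(log n / n) harmonic term above T/n because the first few ranks have
high variance in accuracy. The test suite checks the sampled control
against this exact expression and tolerates the (sub-2-percent at the
sizes used here) offset when asserting that random ranking gains nothing.

Two further read-outs mirror common practice: the overlap of two schemes'
top-k sets (tie groups straddling position k are included wholly, with
the larger included size as denominator), and domain–domain interaction
(DDI) enrichment — the fraction of known DDIs among all candidate domain
pairs (unordered cross-products, self-domain pairs allowed, since domains
do interact with their own kind in structure-derived DDI sets) of the
judgeable pairs above a threshold.

## Reference-set statistics

For building co-annotation and co-expression reference sets the package
provides: a generic ancestor closure over a child→parent edge list
(a plain-TSV stand-in for a full ontology parser — a documented
limitation, chosen to keep the statistic testable in isolation); the
overlap-hypergeometric score for two genes sharing n_gh of T terms
(used as −log p; the term universe T is the one observed across the
closed annotation sets); tissue-specificity Z-scores
Z_k(g) = (e_k(g) − E(g)q_k)/√(E(g)q_k(1−q_k)) with q_k the tissue's share
of total expression (genes or tissues with zero totals are excluded, not
imputed — the score is undefined there); and the co-expression score
C_gh = Σ_m Z_m(g)Z_m(h). Top-percent selection keeps whole tie groups at
the cut, so it is deterministic and monotone in the threshold.

Both hypergeometric tails share one kernel (`stats::phyper`, log-space
capable); the test suite validates them against direct combinatorial
summation.

## The synthetic generator

`synthetic_config()` defaults describe the regime the package is designed
for and are the conditions under which the recovery property is asserted:
300 proteins, 600 planted true pairs, 3000 records, false-report rate
0.4, popularity exponent 1.5. Popularity weights w_i ∝ rank^−1.5 are the
simplest heavy-tail model that reproduces hub-like extremes (a few
proteins holding thousands of reports while the median protein holds a
handful); a false rate of 0.4 reflects that a large minority of
aggregated literature reports are not reproducible physical interactions.
True records sample planted pairs ∝ w_i·w_j; false records sample
non-true pairs the same way, which is exactly the popularity-driven
spurious-report mechanism the scoring is meant to undo. Ground-truth
labels are never written into the record stream; they travel in a
separate file so the pipeline cannot leak truth.

What the generator does *not* emulate: database-specific redundancy
structure (every synthetic record has a unique publication ID),
experiment-type heterogeneity, and any fit to the real corpus's degree
distribution. Passing the recovery test therefore shows that the method
removes popularity bias of this mechanism — not that it matches any
particular real-world benchmark value.

The expression generator gives each planted pair a shared random subset
of 4 of 32 tissues with 8-fold elevated abundance over a log-normal
background, producing the co-expression contrast the tissue statistics
are tested against.

## Numerical and degenerate-input choices

* All pair identity is canonical (lexicographically smaller identifier
  first, byte-wise ordering independent of locale).
* Self-reports are dropped at load (with a count), not errors: the null
  model itself excludes self-interactions. Records without a publication
  identifier are rejected — a record *is* one report in one publication.
* Ensemble mean/variance use one-pass sums, exact for small-integer
  counts; M = 1 yields σ_R = 0 and falls to the degenerate-Z rule.
* Rank sums are validated as n(n+1)/2 on every scoring run; NaN scores
  are refused rather than silently ranked.
* Problem sizes in the test suite (networks of 25–300 proteins, M up to
  2×10⁵ for oracle comparisons, 10 seeds for the recovery property) were
  chosen so the whole suite exercises every statistical claim at
  meaningful power on a single core.

## Known limitations

* The shuffle engine's uniformity is exact only in the stationary limit;
  with the default 3 sweeps no deviation is detectable at 4 Monte-Carlo
  standard errors on enumerable networks, but pathological compositions
  (one protein near the N_i = N feasibility boundary) may mix more
  slowly.
* p-values are bounded below by 1/M; strongly supported pairs tie at
  p = 0 and are separated only by their Z-ranks.
* The rewired control preserves unique-pair degrees, not occurrence
  multiplicities.
* Identifier namespaces are opaque: no aliasing or ortholog mapping is
  attempted, and pairs differing only by synonymous identifiers are
  distinct.
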