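# Benchmarking harness: judgeable/true labelling against a reference set,
# accuracy-coverage curves, average accuracy, gain over random ranking,
# top-rank overlap, and domain-domain interaction enrichment.

#' Construct a reference set
#'
#' A protein universe plus the set of "true" pairs used for judging. A
#' scored pair is *judgeable* if both proteins are in the universe and
#' *true* if additionally the pair is listed.
#'
#' @param universe character vector of protein identifiers.
#' @param true_pairs data.frame with columns `protein_a`, `protein_b`.
#' @return object of class `reference_set`.
#' @export
reference_set <- function(universe, true_pairs) {
  universe <- unique(as.character(universe))
  tp <- canonical_pairs(true_pairs$protein_a, true_pairs$protein_b)
  if (any(tp$protein_a == tp$protein_b))
    stop("reference set contains self-pairs")
  if (!all(c(tp$protein_a, tp$protein_b) %in% universe))
    stop("reference pairs must be contained in the universe")
  tp <- tp[!duplicated(paste(tp$protein_a, tp$protein_b, sep = "\r")), ,
           drop = FALSE]
  rownames(tp) <- NULL
  structure(list(universe = universe, true_pairs = tp),
            class = "reference_set")
}

#' Read a reference set from TSV files
#'
#' @param pairs_path two-column TSV of true pairs (no header).
#' @param universe_path one-column file of universe proteins; if `NULL`,
#'   the universe is the proteins appearing in the pairs.
#' @return a `reference_set`.
#' @export
read_reference_set <- function(pairs_path, universe_path = NULL) {
  tp <- read.delim(pairs_path, header = FALSE, stringsAsFactors = FALSE)
  names(tp)[1:2] <- c("protein_a", "protein_b")
  universe <- if (is.null(universe_path)) {
    unique(c(tp[[1L]], tp[[2L]]))
  } else {
    trimws(readLines(universe_path))
  }
  reference_set(universe[universe != ""], tp)
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", length(x$universe), "proteins,",
      nrow(x$true_pairs), "true pairs\n")
  invisible(x)
}

#' Restrict a ranking to judgeable pairs and label the true ones
#'
#' @param ranked data.frame with `protein_a`, `protein_b` and a `rank` or
#'   `avg_rank` column (smaller rank = better).
#' @param refset a `reference_set`.
#' @return the judgeable sublist in input order, with columns `rank` and
#'   logical `true`.
#' @export
judgeable <- function(ranked, refset) {
  ranked <- as.data.frame(ranked)
  if (!"rank" %in% names(ranked)) {
    if (!"avg_rank" %in% names(ranked))
      stop("ranking needs a 'rank' or 'avg_rank' column")
    ranked$rank <- ranked$avg_rank
  }
  keep <- ranked$protein_a %in% refset$universe &
    ranked$protein_b %in% refset$universe
  out <- ranked[keep, , drop = FALSE]
  truth <- paste(refset$true_pairs$protein_a, refset$true_pairs$protein_b,
                 sep = "\r")
  out$true <- paste(out$protein_a, out$protein_b, sep = "\r") %in% truth
  rownames(out) <- NULL
  out
}

#' Accuracy-coverage curve over rank thresholds
#'
#' One point per distinct rank value, from best (smallest) to worst.
#' Pairs tied at a rank enter the threshold together and are never split.
#' At each threshold: `judgeable` = pairs included so far, `coverage` =
#' true pairs included, `accuracy` = coverage / judgeable.
#'
#' @param labeled output of [judgeable()].
#' @return data.frame `rank`, `coverage`, `judgeable`, `accuracy`.
#' @export
accuracy_coverage_curve <- function(labeled) {
  if (nrow(labeled) == 0L) stop("no judgeable pairs")
  ord <- order(labeled$rank)
  r <- labeled$rank[ord]
  tr <- labeled$true[ord]
  n_at <- tapply(rep(1L, length(r)), r, sum)
  t_at <- tapply(as.integer(tr), r, sum)
  thresholds <- as.numeric(names(n_at))
  data.frame(rank = thresholds,
             coverage = cumsum(as.integer(t_at)),
             judgeable = cumsum(as.integer(n_at)),
             accuracy = cumsum(as.integer(t_at)) /
               cumsum(as.integer(n_at)))
}

#' Average accuracy over ranks
#'
#' `<A> = (1/N) * sum_r accuracy(r) * n(r)` where `n(r)` is the number of
#' true pairs whose rank equals r (newly included at that threshold) and N
#' is the total number of true pairs: the mean accuracy-at-inclusion over
#' true pairs.
#'
#' @param curve data.frame from [accuracy_coverage_curve()].
#' @return `<A>` in `(0, 1]`.
#' @export
average_accuracy <- function(curve) {
  n_r <- diff(c(0L, curve$coverage))
  N <- sum(n_r)
  if (N == 0L) stop("no true pairs: average accuracy undefined")
  sum(curve$accuracy * n_r) / N
}

#' Percent gain of a ranking over the random-ranking baseline
#'
#' `(A - A_random) / A_random * 100`.
#'
#' @param A average accuracy of the ranking.
#' @param A_random average accuracy of the random-ranking control.
#' @return gain in percent (vectorized).
#' @export
gain <- function(A, A_random) {
  if (any(A_random <= 0)) stop("A_random must be positive")
  (A - A_random) / A_random * 100
}

#' Analytic random-ranking baseline
#'
#' Under a uniformly random ranking the expected accuracy at any coverage
#' is the overall fraction of true pairs among judgeable pairs, which is
#' also the expectation of `<A>`.
#'
#' @param labeled output of [judgeable()].
#' @return expected average accuracy.
#' @export
expected_random_accuracy <- function(labeled) {
  if (nrow(labeled) == 0L) stop("no judgeable pairs")
  mean(labeled$true)
}

#' Overlap of the top-k pairs of two rankings
#'
#' Takes the best-ranked pairs of each ranking; a tie group straddling
#' position k is included wholly, and the denominator is the larger of the
#' two included set sizes (so identical rankings always score 1).
#'
#' @param ranking_a,ranking_b data.frames over the same pair set with a
#'   `rank` or `avg_rank` column.
#' @param k nominal top-set size.
#' @return overlap fraction in `[0, 1]`.
#' @export
top_overlap <- function(ranking_a, ranking_b, k) {
  top_keys <- function(df) {
    df <- as.data.frame(df)
    r <- if ("rank" %in% names(df)) df$rank else df$avg_rank
    if (k > length(r)) stop("k exceeds the number of pairs")
    cut <- sort(r)[k]
    paste(df$protein_a, df$protein_b, sep = "\r")[r <= cut]
  }
  ta <- top_keys(ranking_a)
  tb <- top_keys(ranking_b)
  length(intersect(ta, tb)) / max(length(ta), length(tb))
}

#' Known domain-domain interaction enrichment of a ranked PPI set
#'
#' For the judgeable pairs at or better than a rank threshold, enumerates
#' every candidate domain pair (unordered cross-product of the two
#' proteins' domain sets, self-domain pairs allowed) and returns the
#' fraction of candidates present in the known DDI list. Only protein
#' pairs whose domains all appear in the known-DDI domain universe are
#' judgeable; proteins without any domain annotation are excluded and
#' reported with a message.
#'
#' @param ranked data.frame with `protein_a`, `protein_b` and `rank` (or
#'   `avg_rank`).
#' @param domain_annotation named list: protein -> character vector of
#'   domains.
#' @param known_ddis data.frame of unordered domain pairs (`domain_a`,
#'   `domain_b`).
#' @param rank_threshold include pairs with rank <= threshold
#'   (default: all).
#' @return fraction of candidate domain pairs that are known DDIs.
#' @export
ddi_enrichment <- function(ranked, domain_annotation, known_ddis,
                           rank_threshold = Inf) {
  ranked <- as.data.frame(ranked)
  if (!"rank" %in% names(ranked)) ranked$rank <- ranked$avg_rank
  dd <- canonical_pairs(known_ddis$domain_a, known_ddis$domain_b)
  ddi_keys <- paste(dd$protein_a, dd$protein_b, sep = "\r")
  dom_universe <- unique(c(dd$protein_a, dd$protein_b))
  annotated <- function(p) {
    !is.null(domain_annotation[[p]]) && length(domain_annotation[[p]]) > 0L
  }
  has_ann_a <- vapply(ranked$protein_a, annotated, TRUE)
  has_ann_b <- vapply(ranked$protein_b, annotated, TRUE)
  n_missing <- sum(!has_ann_a | !has_ann_b)
  if (n_missing > 0L)
    message(n_missing, " pair(s) excluded: protein without domain annotation")
  ranked <- ranked[has_ann_a & has_ann_b, , drop = FALSE]
  judge <- vapply(seq_len(nrow(ranked)), function(i) {
    all(c(domain_annotation[[ranked$protein_a[i]]],
          domain_annotation[[ranked$protein_b[i]]]) %in% dom_universe)
  }, TRUE)
  ranked <- ranked[judge & ranked$rank <= rank_threshold, , drop = FALSE]
  if (nrow(ranked) == 0L) stop("no judgeable pairs at this threshold")
  hits <- 0L
  total <- 0L
  for (i in seq_len(nrow(ranked))) {
    da <- domain_annotation[[ranked$protein_a[i]]]
    db <- domain_annotation[[ranked$protein_b[i]]]
    cand <- unique(paste(pmin(rep(da, each = length(db)), db),
                         pmax(rep(da, each = length(db)), db), sep = "\r"))
    total <- total + length(cand)
    hits <- hits + sum(cand %in% ddi_keys)
  }
  hits / total
}

#' Evaluate rankings against reference sets
#'
#' One row per (scheme, reference set) with the average accuracy, the
#' analytic random baseline and the percent gain. Reference sets with no
#' judgeable true pair are flagged (`NA` values) rather than fatal.
#'
#' @param rankings named list of ranking data.frames.
#' @param refsets named list of `reference_set` objects.
#' @return data.frame `scheme`, `refset`, `A`, `A_random`, `gain_pct`.
#' @export
evaluate_rankings <- function(rankings, refsets) {
  rows <- list()
  for (rs in names(refsets)) {
    for (sch in names(rankings)) {
      lab <- judgeable(rankings[[sch]], refsets[[rs]])
      if (nrow(lab) == 0L || !any(lab$true)) {
        rows[[length(rows) + 1L]] <-
          data.frame(scheme = sch, refset = rs, A = NA_real_,
                     A_random = NA_real_, gain_pct = NA_real_)
        next
      }
      A <- average_accuracy(accuracy_coverage_curve(lab))
      Ar <- expected_random_accuracy(lab)
      rows[[length(rows) + 1L]] <-
        data.frame(scheme = sch, refset = rs, A = A, A_random = Ar,
                   gain_pct = gain(A, Ar))
    }
  }
  do.call(rbind, rows)
}

#' Recompute gains for a published-style evaluation table
#'
#' Utility for tables holding per-(scheme, reference set) average
#' accuracies and their random baselines: adds the recomputed percent gain
#' column.
#'
#' @param tab data.frame with numeric columns `avg_accuracy` and
#'   `random_accuracy`.
#' @return the table with a `gain_pct` column appended.
#' @export
gain_table <- function(tab) {
  tab$gain_pct <- gain(tab$avg_accuracy, tab$random_accuracy)
  tab
}

#' Bundled published benchmark table
#'
#' Average accuracies of the shuffle-based (IDBOS), hypergeometric-test and
#' occurrence rankings of the literature-aggregated human PPI corpus
#' against eleven independent reference sets (direct-interaction
#' benchmarks, domain-domain interactions, and biological co-annotation
#' sets), together with the random-ranking baselines and the reported
#' percent gains, as published with the original evaluation of the method.
#'
#' @return data.frame `reference_set`, `scheme`, `avg_accuracy`,
#'   `random_accuracy`, `reported_gain_pct`.
#' @export
published_benchmark <- function() {
  path <- system.file("extdata", "benchmark_accuracy.tsv", package = "idbos")
  read.delim(path, stringsAsFactors = FALSE)
}
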