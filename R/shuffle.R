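# IDBOS core: occurrence-preserving randomization and scoring.
#
# The null model keeps every protein's total report count N_i fixed and
# forbids self-interactions. A realization is a uniform draw from all
# pairings of the 2N endpoint "stubs" that contain no self-pair; comparing
# each observed occurrence O_ij against the ensemble yields a permutation
# Z-score and an empirical upper-tail p-value per pair.

stub_index <- function(network) {
  ni <- network$protein_occurrence
  proteins <- names(ni)
  n <- network$total_records
  if (max(ni) > n)
    stop("infeasible network: protein '", proteins[which.max(ni)],
         "' occurs in more than half of all endpoint slots, ",
         "a self-pair-free pairing does not exist")
  list(proteins = proteins,
       stubs = rep(seq_along(ni) - 1L, times = ni),
       pa = match(network$pairs$protein_a, proteins) - 1L,
       pb = match(network$pairs$protein_b, proteins) - 1L)
}

#' One occurrence-preserving shuffle of a network
#'
#' Draws a single randomized interaction list: every protein i appears in
#' exactly N_i endpoint slots, no self-pairs, duplicate pairs allowed with
#' multiplicity. Uses the current RNG state; call [set.seed()] upstream for
#' reproducibility.
#'
#' @param network a `ppi_network`.
#' @param mix_sweeps Metropolis mixing sweeps after the self-pair repair
#'   stage (each sweep proposes 2N stub transpositions, rejecting any that
#'   would create a self-pair). The default of 3 makes the sampler
#'   indistinguishable from the exact uniform law on enumerable networks.
#' @return data.frame of N canonical pairs (a multiset).
#' @export
shuffle_once <- function(network, mix_sweeps = 3L) {
  if (network$total_records < 1L) stop("empty network")
  si <- stub_index(network)
  s <- shuffle_stubs_cpp(si$stubs, as.integer(mix_sweeps))
  a <- si$proteins[s[c(TRUE, FALSE)] + 1L]
  b <- si$proteins[s[c(FALSE, TRUE)] + 1L]
  canonical_pairs(a, b)
}

#' Ensemble statistics over M randomized networks
#'
#' Runs M occurrence-preserving shuffles and accumulates, for every observed
#' pair, the running mean `<R_ij>` and standard deviation `sd_R` of its
#' randomized occurrence, plus the number of realizations with
#' `R_ij >= O_ij` (the numerator of the empirical p-value). One-pass sums
#' are exact here because the counts are small integers.
#'
#' @param network a `ppi_network`.
#' @param M number of realizations (>= 1).
#' @param seed integer seed; the result is deterministic given
#'   (network, M, seed, mix_sweeps).
#' @param mix_sweeps see [shuffle_once()].
#' @return object of class `idbos_randomization`: the pair table with
#'   columns `mean_R`, `sd_R` (sample normalization), `exceed_count`, plus
#'   fields `M` and `seed`.
#' @export
randomize <- function(network, M, seed = 1L, mix_sweeps = 3L) {
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  si <- stub_index(network)
  set.seed(seed)
  res <- randomize_cpp(si$stubs, si$pa, si$pb,
                       as.integer(network$pairs$occurrence),
                       M, length(si$proteins), as.integer(mix_sweeps))
  pairs <- network$pairs
  pairs$mean_R <- res$sum / M
  pairs$sd_R <- if (M > 1L) {
    sqrt(pmax(0, (res$sumsq - res$sum^2 / M) / (M - 1)))
  } else {
    rep(0, nrow(pairs))
  }
  pairs$exceed_count <- res$exceed
  structure(list(pairs = pairs, M = M, seed = seed,
                 mix_sweeps = mix_sweeps),
            class = "idbos_randomization")
}

#' @export
print.idbos_randomization <- function(x, ...) {
  cat("idbos_randomization:", nrow(x$pairs), "pairs, M =", x$M,
      ", seed =", x$seed, "\n")
  invisible(x)
}

#' Permutation Z-score of an observed occurrence
#'
#' `(O - <R>) / sd_R`. When `sd_R` is exactly zero the ratio is undefined;
#' the rule used is: Z = 0 if O equals the ensemble mean, otherwise
#' `sign(O - <R>) * (largest finite Z in the run + 1)`, which places the
#' pair beyond every finite-Z pair without inventing a magnitude. Degenerate
#' cases are reported with a message.
#'
#' @param O observed occurrences (vector).
#' @param mean_R,sd_R ensemble mean and standard deviation (vectors).
#' @return numeric Z-scores.
#' @export
z_score <- function(O, mean_R, sd_R) {
  if (any(sd_R < 0)) stop("sd_R must be >= 0")
  z <- rep(NA_real_, length(O))
  ok <- sd_R > 0
  z[ok] <- (O[ok] - mean_R[ok]) / sd_R[ok]
  if (any(!ok)) {
    cap <- if (any(ok)) max(z[ok]) else 0
    degen <- !ok
    z[degen] <- ifelse(O[degen] == mean_R[degen], 0,
                       sign(O[degen] - mean_R[degen]) * (cap + 1))
    message(sum(degen), " pair(s) with sd_R = 0 scored by the degenerate",
            " rule (0 at the mean, beyond the largest finite Z otherwise)")
  }
  z
}

#' Empirical upper-tail p-value
#'
#' Fraction of realizations with `R_ij >= O_ij`. With `pseudo_count = TRUE`
#' the `(k + 1) / (M + 1)` estimator is used instead, which avoids exact
#' zeros at finite M.
#'
#' @param exceed_count realizations meeting or exceeding the observation.
#' @param M number of realizations.
#' @param pseudo_count use the add-one estimator.
#' @return numeric p-values in `[0, 1]`.
#' @export
p_value <- function(exceed_count, M, pseudo_count = FALSE) {
  if (any(M == 0)) stop("M must be positive")
  if (any(exceed_count < 0 | exceed_count > M))
    stop("exceed_count must lie in [0, M]")
  if (pseudo_count) (exceed_count + 1) / (M + 1) else exceed_count / M
}

#' Exact occurrence distribution by matching enumeration
#'
#' Brute-force oracle for the null distribution of `R_ij`: enumerates every
#' pairing of the 2N labeled stubs, discards pairings containing a
#' self-pair, and tallies how often the queried pair occurs. Tractable only
#' for tiny networks (2N <= 14); used to validate the shuffle engine.
#'
#' @param network a `ppi_network`.
#' @param pair character vector of length 2 (the queried proteins).
#' @return named numeric vector: probability of `R_ij = 0, 1, ...`
#'   (trailing zeros trimmed); masses sum to 1.
#' @export
matching_pdf_oracle <- function(network, pair) {
  ni <- network$protein_occurrence
  if (2L * network$total_records > 14L)
    stop("network too large for exhaustive enumeration (2N > 14)")
  stubs <- rep(names(ni), times = ni)
  pa <- pair[[1L]]; pb <- pair[[2L]]
  add <- function(x, y) {
    n <- max(length(x), length(y))
    c(x, numeric(n - length(x))) + c(y, numeric(n - length(y)))
  }
  rec <- function(s) {
    if (length(s) == 0L) return(1)
    a <- s[1L]
    rest <- s[-1L]
    out <- 0
    for (j in seq_along(rest)) {
      b <- rest[j]
      if (a == b) next
      sub <- rec(rest[-j])
      if ((a == pa && b == pb) || (a == pb && b == pa)) sub <- c(0, sub)
      out <- add(out, sub)
    }
    out
  }
  counts <- rec(stubs)
  total <- sum(counts)
  if (total == 0) stop("no self-pair-free pairing exists for this network")
  pdf <- counts / total
  names(pdf) <- seq_along(pdf) - 1L
  pdf[seq_len(max(which(pdf > 0)))]
}

#' Fractional ranking
#'
#' Best value receives rank 1; tied values share the mean of the ordinal
#' positions they span, so ranks always sum to n(n+1)/2.
#'
#' @param values numeric vector (no NA/NaN).
#' @param direction `"larger"` if larger values are better, `"smaller"`
#'   otherwise.
#' @return numeric vector of fractional ranks.
#' @export
fractional_rank <- function(values, direction = c("larger", "smaller")) {
  direction <- match.arg(direction)
  if (length(values) == 0L) stop("empty value vector")
  if (any(is.na(values))) stop("NA/NaN values cannot be ranked")
  if (direction == "larger") {
    rank(-values, ties.method = "average")
  } else {
    rank(values, ties.method = "average")
  }
}

#' Score and rank a network by occurrence-preserving shuffling
#'
#' Full IDBOS scoring: runs [randomize()], converts each pair's Z-score and
#' p-value to fractional ranks (larger Z better, smaller p better) and
#' averages the two ranks. Pairs sharing an identical average rank form an
#' equivalence group (`rank_group`); their relative output order is
#' lexicographic by pair, which keeps files deterministic.
#'
#' @inheritParams randomize
#' @param pseudo_count passed to [p_value()].
#' @return data.frame sorted by `avg_rank` with columns `protein_a`,
#'   `protein_b`, `occurrence`, `z`, `p`, `z_rank`, `p_rank`, `avg_rank`,
#'   `rank_group`; attributes `M` and `seed`.
#' @export
idbos_score <- function(network, M, seed = 1L, mix_sweeps = 3L,
                        pseudo_count = FALSE) {
  rnd <- randomize(network, M, seed, mix_sweeps)
  sc <- rnd$pairs
  sc$z <- z_score(sc$occurrence, sc$mean_R, sc$sd_R)
  sc$p <- p_value(sc$exceed_count, rnd$M, pseudo_count)
  sc$z_rank <- fractional_rank(sc$z, "larger")
  sc$p_rank <- fractional_rank(sc$p, "smaller")
  sc$avg_rank <- (sc$z_rank + sc$p_rank) / 2
  ord <- order(sc$avg_rank, sc$protein_a, sc$protein_b, method = "radix")
  sc <- sc[ord, c("protein_a", "protein_b", "occurrence", "z", "p",
                  "z_rank", "p_rank", "avg_rank")]
  sc$rank_group <- match(sc$avg_rank, unique(sc$avg_rank))
  rownames(sc) <- NULL
  attr(sc, "M") <- rnd$M
  attr(sc, "seed") <- rnd$seed
  sc
}
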