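# Comparator ranking schemes: hypergeometric test, raw occurrence,
# random-rank control, degree-preserving rewired control.

#' Hypergeometric interaction test
#'
#' Upper-tail probability of seeing `N_ij` or more co-occurrences of two
#' proteins by chance, modelled as drawing protein i's `N_i` endpoint slots
#' from the `2N` total slots, of which `N_j` belong to protein j:
#' `p = sum_{n = N_ij}^{min(N_i, N_j)} C(N_j, n) C(2N - N_j, N_i - n) /
#' C(2N, N_i)`. Unlike the shuffle null, this background assigns positive
#' probability to self-pairings, which deflates the expected occurrence of
#' non-self pairs involving heavily reported proteins. Valid in the limit
#' `N >> N_i * N_j`. Evaluated via [stats::phyper()] (log-space capable).
#'
#' @param N_ij observed co-occurrences (>= 1).
#' @param N_i,N_j per-protein report counts.
#' @param N total record count.
#' @param log_p return log probabilities.
#' @return upper-tail probabilities in `(0, 1]` (vectorized).
#' @export
hypergeometric_pvalue <- function(N_ij, N_i, N_j, N, log_p = FALSE) {
  if (any(N_ij < 1) || any(N_ij > pmin(N_i, N_j)))
    stop("N_ij must satisfy 1 <= N_ij <= min(N_i, N_j)")
  if (any(N_i > N) || any(N_j > N))
    stop("per-protein counts cannot exceed the total record count")
  phyper(N_ij - 1, m = N_j, n = 2 * N - N_j, k = N_i,
         lower.tail = FALSE, log.p = log_p)
}

#' Rank a network by the hypergeometric test
#'
#' @param network a `ppi_network`.
#' @return data.frame with `protein_a`, `protein_b`, `occurrence`, `method`,
#'   `score` (the tail probability; smaller is better) and fractional `rank`.
#' @export
hypergeometric_rank <- function(network) {
  df <- network$pairs
  ni <- network$protein_occurrence
  df$method <- "hypergeometric"
  df$score <- hypergeometric_pvalue(df$occurrence,
                                    ni[df$protein_a], ni[df$protein_b],
                                    network$total_records)
  df$rank <- fractional_rank(df$score, "smaller")
  sort_ranked(df)
}

#' Rank a network by raw occurrence
#'
#' Fractional ranks on O_ij, larger is better. Because most aggregated
#' pairs are singletons, huge tie groups are expected.
#'
#' @param network a `ppi_network`.
#' @return same shape as [hypergeometric_rank()], `method = "occurrence"`.
#' @export
occurrence_rank <- function(network) {
  df <- network$pairs
  df$method <- "occurrence"
  df$score <- as.numeric(df$occurrence)
  df$rank <- fractional_rank(df$score, "larger")
  sort_ranked(df)
}

#' Random-rank control
#'
#' Keeps the pairs but assigns a uniform random permutation of ranks 1..n.
#'
#' @param pairs data.frame with `protein_a`, `protein_b` (and optionally
#'   `occurrence`), or a `ppi_network`.
#' @param seed integer seed.
#' @return same shape as [hypergeometric_rank()], `method = "random_rank"`.
#' @export
random_rank <- function(pairs, seed = 1L) {
  if (inherits(pairs, "ppi_network")) pairs <- pairs$pairs
  df <- pairs
  set.seed(seed)
  df$method <- "random_rank"
  df$rank <- as.numeric(sample.int(nrow(df)))
  df$score <- -df$rank
  sort_ranked(df)
}

sort_ranked <- function(df) {
  ord <- order(df$rank, df$protein_a, df$protein_b, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Degree-preserving random rewiring
#'
#' Double-edge-swap control on the unique-pair graph: repeatedly picks two
#' edges and exchanges endpoints; swaps that would create a self-pair or a
#' duplicate edge are rejected and resampled. Per-protein degree is exactly
#' preserved. Occurrence multiplicities are not carried over (the control
#' operates on unique pairs).
#'
#' @param pairs data.frame of unique unordered pairs (`protein_a`,
#'   `protein_b`), or a `ppi_network`.
#' @param n_swaps number of attempted swaps; the default 10x the edge count
#'   mixes well in practice.
#' @param seed integer seed.
#' @return data.frame of rewired canonical pairs.
#' @export
rewire_pairs <- function(pairs, n_swaps = NULL, seed = 1L) {
  if (inherits(pairs, "ppi_network")) pairs <- pairs$pairs
  a <- pairs$protein_a
  b <- pairs$protein_b
  ne <- length(a)
  if (ne < 2L) return(canonical_pairs(a, b))
  if (is.null(n_swaps)) n_swaps <- 10L * ne
  set.seed(seed)
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  edge_set <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(a, b)) assign(k, TRUE, envir = edge_set)
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(ne, 2L)
    i <- ij[1L]; j <- ij[2L]
    # two orientations of the swap; pick one at random
    if (runif(1) < 0.5) {
      na1 <- a[i]; nb1 <- b[j]; na2 <- a[j]; nb2 <- b[i]
    } else {
      na1 <- a[i]; nb1 <- a[j]; na2 <- b[i]; nb2 <- b[j]
    }
    if (na1 == nb1 || na2 == nb2) next
    k1 <- key(na1, nb1); k2 <- key(na2, nb2)
    if (k1 == k2) next
    if (exists(k1, envir = edge_set) || exists(k2, envir = edge_set)) next
    rm(list = c(key(a[i], b[i]), key(a[j], b[j])), envir = edge_set)
    assign(k1, TRUE, envir = edge_set)
    assign(k2, TRUE, envir = edge_set)
    a[i] <- na1; b[i] <- nb1; a[j] <- na2; b[j] <- nb2
  }
  canonical_pairs(a, b)
}

#' Write a scored/ranked pair table as TSV
#'
#' @param scores data.frame from [idbos_score()], [hypergeometric_rank()],
#'   [occurrence_rank()] or [random_rank()].
#' @param path output path.
#' @export
write_scored <- function(scores, path) {
  df <- as.data.frame(scores)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           format(x, digits = 10, scientific = FALSE, trim = TRUE))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
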