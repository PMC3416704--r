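# Synthetic data: popularity-biased literature record streams over a
# planted true interactome, with matched reference sets and expression
# matrices, so the full scoring and evaluation pipeline runs end to end
# with no external inputs.

#' Configuration of the synthetic generator
#'
#' The generator emulates the dominant distortion of aggregated literature
#' PPI data: study frequency ("popularity") varies enormously across
#' proteins, so heavily studied proteins accumulate reports - both genuine
#' re-observations and spurious ones - far beyond their biology. Proteins
#' receive heavy-tailed popularity weights `w_i` proportional to
#' `rank^-popularity_exponent`; every record picks a true pair with
#' probability `1 - false_rate` (weighted by endpoint popularity) and
#' otherwise a popularity-weighted non-true pair.
#'
#' @param n_proteins number of proteins.
#' @param popularity_exponent power-law exponent of the study-intensity
#'   weights (0 = uniform).
#' @param n_true_pairs size of the planted interactome.
#' @param n_records number of literature reports to emit.
#' @param false_rate fraction of records drawn from non-true pairs, in
#'   `[0, 1)`.
#' @param seed integer seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 300L, popularity_exponent = 1.5,
                             n_true_pairs = 600L, n_records = 3000L,
                             false_rate = 0.4, seed = 1L) {
  n_proteins <- as.integer(n_proteins)
  n_true_pairs <- as.integer(n_true_pairs)
  n_records <- as.integer(n_records)
  if (n_proteins < 2L) stop("need at least two proteins")
  if (n_true_pairs < 1L ||
      n_true_pairs > n_proteins * (n_proteins - 1) / 2)
    stop("n_true_pairs must be in [1, choose(n_proteins, 2)]")
  if (false_rate < 0 || false_rate >= 1)
    stop("false_rate must be in [0, 1)")
  if (popularity_exponent < 0) stop("popularity_exponent must be >= 0")
  structure(list(n_proteins = n_proteins,
                 popularity_exponent = popularity_exponent,
                 n_true_pairs = n_true_pairs,
                 n_records = n_records,
                 false_rate = false_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

protein_names <- function(n) sprintf("P%04d", seq_len(n))

popularity_weights <- function(config) {
  w <- seq_len(config$n_proteins)^(-config$popularity_exponent)
  w / sum(w)
}

# bijection between pair index 1..choose(n,2) and (i < j), row-major
unrank_pair <- function(idx, n) {
  counts <- (n - 1L):1L
  i <- rep.int(seq_len(n - 1L), times = counts)[idx]
  first <- cumsum(c(0L, counts[-length(counts)])) + 1L
  j <- i + (idx - first[i]) + 1L
  cbind(i, j)
}

#' Plant a true interactome
#'
#' Samples `n_true_pairs` distinct canonical pairs uniformly without
#' replacement; deterministic per seed.
#'
#' @param config a `synthetic_config`.
#' @return a [reference_set()] whose universe is all proteins.
#' @export
generate_truth <- function(config) {
  set.seed(config$seed)
  n <- config$n_proteins
  total <- n * (n - 1) / 2
  idx <- sample.int(total, config$n_true_pairs)
  ij <- unrank_pair(sort(idx), n)
  nm <- protein_names(n)
  reference_set(nm, data.frame(protein_a = nm[ij[, 1L]],
                               protein_b = nm[ij[, 2L]],
                               stringsAsFactors = FALSE))
}

#' Emit a popularity-biased record stream
#'
#' Each record is, with probability `1 - false_rate`, a true pair sampled
#' proportionally to the product of its endpoint popularity weights, and
#' otherwise a popularity-weighted random non-true pair (a spurious
#' report). Publication identifiers are unique per record, so every record
#' counts once after deduplication. The ground-truth label travels in the
#' `is_true` column, which [write_records()] strips: downstream scoring
#' never sees it.
#'
#' @param config a `synthetic_config`.
#' @param truth the matching [generate_truth()] output.
#' @return records data.frame (`protein_a`, `protein_b`, `publication_id`,
#'   `source_db`, `is_true`).
#' @export
generate_records <- function(config, truth) {
  set.seed(config$seed + 1L)
  n <- config$n_proteins
  nm <- protein_names(n)
  w <- popularity_weights(config)
  tp <- truth$true_pairs
  wi <- w[match(tp$protein_a, nm)] * w[match(tp$protein_b, nm)]
  truth_keys <- paste(tp$protein_a, tp$protein_b, sep = "\r")
  is_true <- runif(config$n_records) >= config$false_rate
  n_true <- sum(is_true)
  a <- character(config$n_records)
  b <- character(config$n_records)
  if (n_true > 0L) {
    pick <- sample.int(nrow(tp), n_true, replace = TRUE, prob = wi)
    a[is_true] <- tp$protein_a[pick]
    b[is_true] <- tp$protein_b[pick]
  }
  n_false <- config$n_records - n_true
  if (n_false > 0L) {
    fa <- character(0)
    fb <- character(0)
    while (length(fa) < n_false) {
      need <- (n_false - length(fa)) * 2L + 16L
      ca <- nm[sample.int(n, need, replace = TRUE, prob = w)]
      cb <- nm[sample.int(n, need, replace = TRUE, prob = w)]
      keep <- ca != cb &
        !(paste(pmin(ca, cb), pmax(ca, cb), sep = "\r") %in% truth_keys)
      fa <- c(fa, ca[keep])
      fb <- c(fb, cb[keep])
    }
    a[!is_true] <- fa[seq_len(n_false)]
    b[!is_true] <- fb[seq_len(n_false)]
  }
  pairs <- canonical_pairs(a, b)
  out <- data.frame(pairs,
                    publication_id = sprintf("PUB%06d",
                                             seq_len(config$n_records)),
                    source_db = "synthetic",
                    is_true = is_true,
                    stringsAsFactors = FALSE)
  ni <- table(c(out$protein_a, out$protein_b))
  if (max(ni) > config$n_records)
    stop("generated stream is infeasible for self-pair-free shuffling; ",
         "lower popularity_exponent or raise n_proteins")
  out
}

#' Generate a matched expression matrix
#'
#' Background: log-normal baseline abundance per gene spread over tissues
#' with mild independent noise. Signal: each true pair is assigned a
#' common random subset of tissues in which both genes are strongly
#' elevated, so planted partners co-vary across tissues while background
#' pairs do not.
#'
#' @param config a `synthetic_config`.
#' @param truth the matching [generate_truth()] output; `NULL` for an
#'   all-background matrix.
#' @param n_tissues number of tissues (columns).
#' @param signal_tissues tissues elevated per true pair.
#' @param boost multiplicative elevation in signal tissues.
#' @return genes x tissues abundance matrix.
#' @export
generate_expression <- function(config, truth = NULL, n_tissues = 32L,
                                signal_tissues = 4L, boost = 8) {
  set.seed(config$seed + 2L)
  n <- config$n_proteins
  nm <- protein_names(n)
  base <- rlnorm(n, meanlog = 3, sdlog = 0.6)
  mat <- matrix(base, n, n_tissues) *
    matrix(rlnorm(n * n_tissues, 0, 0.4), n, n_tissues)
  rownames(mat) <- nm
  colnames(mat) <- sprintf("tissue%02d", seq_len(n_tissues))
  if (!is.null(truth)) {
    tp <- truth$true_pairs
    for (i in seq_len(nrow(tp))) {
      ts <- sample.int(n_tissues, signal_tissues)
      mat[tp$protein_a[i], ts] <- mat[tp$protein_a[i], ts] * boost
      mat[tp$protein_b[i], ts] <- mat[tp$protein_b[i], ts] * boost
    }
  }
  mat
}
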