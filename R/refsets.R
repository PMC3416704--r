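# Reference-set construction statistics: ontology ancestor closure,
# co-annotation significance, tissue-specificity Z-scores, co-expression
# scores, and top-percent pair selection.

#' Close annotation sets under ontology ancestry
#'
#' Expands each gene's term set with every ancestor reachable through a
#' child -> parent edge list (a DAG closure; the input need not be a full
#' ontology). Cycles are rejected with an error naming a member.
#'
#' @param annotations named list: gene -> character vector of terms.
#' @param dag_edges data.frame with columns `child`, `parent`.
#' @return list with `annotations` (closed sets), `n_terms` (T, distinct
#'   terms across all closed sets).
#' @export
ancestor_closure <- function(annotations, dag_edges) {
  parents <- split(as.character(dag_edges$parent),
                   as.character(dag_edges$child))
  anc_cache <- new.env(hash = TRUE, parent = emptyenv())
  state <- new.env(hash = TRUE, parent = emptyenv())  # 1 = in stack, 2 = done
  ancestors <- function(term) {
    hit <- get0(term, envir = anc_cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    st <- get0(term, envir = state, inherits = FALSE)
    if (!is.null(st) && st == 1L)
      stop("cycle detected in ontology edges involving term '", term, "'")
    assign(term, 1L, envir = state)
    ps <- parents[[term]]
    res <- character(0)
    for (p in ps) res <- union(res, c(p, ancestors(p)))
    assign(term, 2L, envir = state)
    assign(term, res, envir = anc_cache)
    res
  }
  closed <- lapply(annotations, function(terms) {
    terms <- unique(as.character(terms))
    out <- terms
    for (t in terms) out <- union(out, ancestors(t))
    sort(out, method = "radix")
  })
  list(annotations = closed,
       n_terms = length(unique(unlist(closed, use.names = FALSE))))
}

#' Co-annotation overlap significance
#'
#' Upper-tail hypergeometric probability that two genes with `N_g` and
#' `N_h` terms (out of `T` total) share `n_gh` or more terms by chance.
#' Shares its tail kernel with [hypergeometric_pvalue()] via
#' [stats::phyper()]. The recommended score is `-log(p)`.
#'
#' @param n_gh observed shared terms (>= 0).
#' @param N_g,N_h term-set sizes of the two genes.
#' @param T_total total number of distinct terms.
#' @param log_p return log probabilities.
#' @return tail probabilities (1 when `n_gh` is 0).
#' @export
coannotation_pvalue <- function(n_gh, N_g, N_h, T_total, log_p = FALSE) {
  if (any(n_gh < 0) || any(n_gh > pmin(N_g, N_h)))
    stop("n_gh must satisfy 0 <= n_gh <= min(N_g, N_h)")
  if (any(pmax(N_g, N_h) > T_total))
    stop("term-set sizes cannot exceed the total term count")
  phyper(n_gh - 1, m = N_h, n = T_total - N_h, k = N_g,
         lower.tail = FALSE, log.p = log_p)
}

#' Score all gene pairs by co-annotation significance
#'
#' @param closed output of [ancestor_closure()].
#' @return data.frame `gene_a`, `gene_b`, `n_shared`, `p`, `score`
#'   (`-log(p)`), all unordered gene pairs.
#' @export
coannotation_scores <- function(closed) {
  genes <- names(closed$annotations)
  if (length(genes) < 2L) stop("need at least two annotated genes")
  sizes <- lengths(closed$annotations)
  idx <- utils::combn(length(genes), 2L)
  n_shared <- vapply(seq_len(ncol(idx)), function(k) {
    length(intersect(closed$annotations[[idx[1L, k]]],
                     closed$annotations[[idx[2L, k]]]))
  }, 1L)
  logp <- coannotation_pvalue(n_shared, sizes[idx[1L, ]], sizes[idx[2L, ]],
                              closed$n_terms, log_p = TRUE)
  pairs <- canonical_pairs(genes[idx[1L, ]], genes[idx[2L, ]])
  data.frame(gene_a = pairs$protein_a, gene_b = pairs$protein_b,
             n_shared = n_shared, p = exp(logp), score = -logp)
}

#' Tissue-specificity Z-scores of an expression matrix
#'
#' For a genes x tissues matrix of non-negative abundances, models gene
#' g's total expression `E(g)` as thrown across tissues with probabilities
#' `q_k = E_k / sum_m E_m` (tissue totals over the grand total) and scores
#' each cell as `Z_k(g) = (e_k(g) - E(g) q_k) / sqrt(E(g) q_k (1 - q_k))`,
#' the standardized deviation from proportional expression. Genes with
#' zero total expression and tissues with zero total are excluded (the
#' score is undefined there) and reported with a message.
#'
#' @param mat numeric matrix, genes in rows, tissues in columns.
#' @return matrix of Z-scores for the retained genes/tissues, with the
#'   tissue weights in attribute `"q"` (they sum to 1).
#' @export
tissue_specificity <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("expression values must be non-negative")
  Ek <- colSums(mat)
  if (any(Ek == 0)) {
    message(sum(Ek == 0), " tissue(s) with zero total expression excluded")
    mat <- mat[, Ek > 0, drop = FALSE]
    Ek <- Ek[Ek > 0]
  }
  Eg <- rowSums(mat)
  if (any(Eg == 0)) {
    message(sum(Eg == 0), " gene(s) with zero total expression excluded")
    mat <- mat[Eg > 0, , drop = FALSE]
    Eg <- Eg[Eg > 0]
  }
  q <- Ek / sum(Ek)
  if (any(q >= 1))
    stop("tissue specificity needs at least two expressed tissues")
  mu <- outer(Eg, q)
  z <- (mat - mu) / sqrt(outer(Eg, q * (1 - q)))
  attr(z, "q") <- q
  z
}

#' Tissue co-expression score of two genes
#'
#' Dot product of the two genes' tissue-specificity Z-score vectors.
#'
#' @param z_g,z_h equal-length numeric vectors.
#' @return the score `sum_m Z_m(g) Z_m(h)`.
#' @export
coexpression_score <- function(z_g, z_h) {
  if (length(z_g) != length(z_h))
    stop("tissue vectors must have equal length")
  sum(z_g * z_h)
}

#' Co-expression scores for all gene pairs
#'
#' @param z matrix from [tissue_specificity()].
#' @return data.frame `gene_a`, `gene_b`, `score`.
#' @export
coexpression_scores <- function(z) {
  genes <- rownames(z)
  if (is.null(genes)) genes <- sprintf("G%d", seq_len(nrow(z)))
  cg <- tcrossprod(z)
  idx <- which(upper.tri(cg), arr.ind = TRUE)
  pairs <- canonical_pairs(genes[idx[, 1L]], genes[idx[, 2L]])
  data.frame(gene_a = pairs$protein_a, gene_b = pairs$protein_b,
             score = cg[idx])
}

#' Select the top percent of scored pairs
#'
#' Keeps pairs whose score reaches the score of the nominal cut position;
#' ties at the cut are included wholly, so the selection is deterministic
#' and monotone in the threshold. The realized size and tie surplus are
#' reported with a message.
#'
#' @param scored data.frame with a numeric `score` column (larger = better).
#' @param percent value in `(0, 100]`.
#' @return the selected rows, best score first.
#' @export
top_percent_pairs <- function(scored, percent = 1) {
  if (nrow(scored) == 0L) stop("no scored pairs")
  if (percent <= 0 || percent > 100) stop("percent must be in (0, 100]")
  m <- ceiling(nrow(scored) * percent / 100)
  s <- sort(scored$score, decreasing = TRUE)
  cutoff <- s[m]
  out <- scored[scored$score >= cutoff, , drop = FALSE]
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  message("selected ", nrow(out), " pair(s) at the top ", percent,
          "% cut (nominal ", m, ", +", nrow(out) - m, " tied)")
  out
}

#' Read annotation, ontology-edge and expression inputs
#'
#' `read_annotations`: two-column TSV (gene, term) -> named list.
#' `read_dag_edges`: two-column TSV (child, parent) -> data.frame.
#' `read_expression`: TSV with header and gene identifiers in the first
#' column -> numeric matrix.
#'
#' @param path input path.
#' @return see details.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' @rdname read_annotations
#' @export
read_dag_edges <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(child = as.character(df[[1L]]),
             parent = as.character(df[[2L]]), stringsAsFactors = FALSE)
}

#' @rdname read_annotations
#' @export
read_expression <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
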