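# Shared fixtures: all test data is built in code.

# records data.frame from parallel vectors (already canonical unless stated)
make_records <- function(a, b, pub = sprintf("P%d", seq_along(a)),
                         src = "") {
  data.frame(protein_a = a, protein_b = b, publication_id = pub,
             source_db = src, stringsAsFactors = FALSE)
}

# network from an explicit multiset of pairs (one record per entry)
net_from_pairs <- function(a, b) {
  aggregate_records(make_records(a, b))
}

# toy with counts {A:2, B:2, C:1, D:1} used in several enumeration checks
toy_net_4 <- function() net_from_pairs(c("A", "A", "C"), c("B", "B", "D"))

# random small synthetic network via the generator (always shuffle-feasible)
random_small_net <- function(seed, n_proteins = 25L, n_true = 40L,
                             n_records = 120L) {
  cfg <- synthetic_config(n_proteins = n_proteins, n_true_pairs = n_true,
                          n_records = n_records, false_rate = 0.3,
                          popularity_exponent = 1, seed = seed)
  truth <- generate_truth(cfg)
  recs <- generate_records(cfg, truth)
  aggregate_records(deduplicate(recs[, 1:4]))
}

# write a records data.frame to a temp TSV and return the path
records_file <- function(records, header = FALSE) {
  path <- tempfile(fileext = ".tsv")
  write.table(records, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  path
}

# direct combinatorial summation oracle for hypergeometric upper tails
tail_sum_oracle <- function(k_min, m_white, k_draw, n_total) {
  n <- k_min:min(k_draw, m_white)
  sum(exp(lchoose(m_white, n) + lchoose(n_total - m_white, k_draw - n) -
            lchoose(n_total, k_draw)))
}

# independent brute-force average accuracy: mean over true pairs of the
# accuracy of the judgeable prefix that first includes them
brute_force_avg_accuracy <- function(labeled) {
  acc <- numeric(0)
  for (i in which(labeled$true)) {
    inc <- labeled$rank <= labeled$rank[i]
    acc <- c(acc, sum(labeled$true[inc]) / sum(inc))
  }
  mean(acc)
}
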