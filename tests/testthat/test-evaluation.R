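ranked3 <- data.frame(protein_a = c("A", "A", "B"),
                      protein_b = c("B", "D", "C"),
                      rank = c(1, 2, 3), stringsAsFactors = FALSE)
refs3 <- reference_set(c("A", "B", "C"),
                       data.frame(protein_a = "A", protein_b = "B"))

test_that("judgeable keeps in-universe pairs and labels the true ones", {
  lab <- judgeable(ranked3, refs3)
  expect_equal(nrow(lab), 2L)  # (A,D) not judgeable
  expect_equal(lab$true, c(TRUE, FALSE))
  empty <- reference_set(character(0),
                         data.frame(protein_a = character(0),
                                    protein_b = character(0)))
  expect_equal(nrow(judgeable(ranked3, empty)), 0L)
})

test_that("accuracy-coverage curves step per distinct rank, ties atomic", {
  lab <- data.frame(rank = 1:3, true = c(TRUE, FALSE, TRUE))
  cv <- accuracy_coverage_curve(lab)
  expect_equal(cv$coverage, c(1L, 1L, 2L))
  expect_equal(cv$judgeable, c(1L, 2L, 3L))
  expect_equal(cv$accuracy, c(1, 0.5, 2 / 3))

  tied <- data.frame(rank = c(1.5, 1.5), true = c(TRUE, FALSE))
  cvt <- accuracy_coverage_curve(tied)
  expect_equal(nrow(cvt), 1L)
  expect_equal(cvt$accuracy, 0.5)

  allf <- data.frame(rank = 1:4, true = rep(FALSE, 4))
  expect_true(all(accuracy_coverage_curve(allf)$accuracy == 0))
})

test_that("average accuracy is the true-pair-weighted mean accuracy", {
  lab <- data.frame(rank = 1:3, true = c(TRUE, FALSE, TRUE))
  expect_equal(average_accuracy(accuracy_coverage_curve(lab)),
               (1 + 2 / 3) / 2)
  allt <- data.frame(rank = 1:5, true = rep(TRUE, 5))
  expect_equal(average_accuracy(accuracy_coverage_curve(allt)), 1)
  lastt <- data.frame(rank = 1:6, true = c(rep(FALSE, 5), TRUE))
  expect_equal(average_accuracy(accuracy_coverage_curve(lastt)), 1 / 6)
  expect_error(
    average_accuracy(accuracy_coverage_curve(
      data.frame(rank = 1:2, true = c(FALSE, FALSE)))),
    "undefined")
})

test_that("average accuracy equals an independent brute-force pass", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    lab <- data.frame(rank = fractional_rank(runif(n), "smaller"),
                      true = runif(n) < 0.4)
    # inject tie groups
    lab$rank <- ceiling(lab$rank / sample(1:3, 1))
    if (!any(lab$true)) lab$true[1] <- TRUE
    expect_equal(average_accuracy(accuracy_coverage_curve(lab)),
                 brute_force_avg_accuracy(lab))
  }
})

test_that("gain is the percent improvement over the random baseline", {
  expect_equal(gain(0.842, 0.235), 258.3, tolerance = 1e-3)
  expect_equal(gain(0.409, 0.144), 184.0, tolerance = 1e-3)
  expect_equal(gain(0.5, 0.5), 0)
  expect_error(gain(0.5, 0), "positive")
})

test_that("analytic random baseline matches sampled random rankings", {
  lab <- data.frame(rank = 1:12, true = c(rep(TRUE, 4), rep(FALSE, 8)))
  expect_equal(expected_random_accuracy(lab), 1 / 3)
  expect_equal(expected_random_accuracy(
    data.frame(rank = 1:3, true = rep(TRUE, 3))), 1)
  # Monte-Carlo mean of <A> under random permutation of ranks matches the
  # exact finite-n expectation: a true pair lands at position k uniformly
  # and sees accuracy (1 + (k-1)(T-1)/(n-1)) / k there; the analytic
  # baseline T/n is its large-n limit
  n <- nrow(lab)
  T_true <- sum(lab$true)
  k <- seq_len(n)
  exact <- mean((1 + (k - 1) * (T_true - 1) / (n - 1)) / k)
  set.seed(23)
  sims <- replicate(1000, {
    shuf <- lab
    shuf$rank <- sample(nrow(lab))
    average_accuracy(accuracy_coverage_curve(shuf))
  })
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - exact), 3 * se)
  expect_gt(exact, expected_random_accuracy(lab))  # small-n offset is positive
  # gain of the analytic baseline against itself is exactly zero
  expect_equal(gain(expected_random_accuracy(lab),
                    expected_random_accuracy(lab)), 0)
})

test_that("accuracy at the loosest threshold equals the random baseline", {
  net <- random_small_net(6)
  truth <- generate_truth(synthetic_config(n_proteins = 25L,
                                           n_true_pairs = 40L,
                                           n_records = 120L,
                                           false_rate = 0.3,
                                           popularity_exponent = 1,
                                           seed = 6))
  for (ranking in list(occurrence_rank(net), random_rank(net, 3))) {
    lab <- judgeable(ranking, truth)
    cv <- accuracy_coverage_curve(lab)
    expect_equal(cv$accuracy[nrow(cv)], expected_random_accuracy(lab))
  }
})

test_that("top-rank overlap handles ties and behaves at the extremes", {
  a <- data.frame(protein_a = letters[1:10], protein_b = LETTERS[1:10],
                  rank = 1:10)
  expect_equal(top_overlap(a, a, 3), 1)
  expect_equal(top_overlap(a, a, 10), 1)
  b <- a
  b$rank <- 10:1
  expect_equal(top_overlap(a, b, 4), 0)
  # straddling tie group is included wholly
  tied <- a
  tied$rank <- c(1, 2, rep(3, 4), 7:10)
  expect_equal(top_overlap(tied, tied, 3), 1)
  # independent random rankings overlap about k/n
  set.seed(31)
  ov <- replicate(300, {
    x <- a; y <- a
    x$rank <- sample(10); y$rank <- sample(10)
    top_overlap(x, y, 5)
  })
  expect_lt(abs(mean(ov) - 0.5), 0.05)
})

test_that("DDI enrichment counts candidate domain pairs above a threshold", {
  ann <- list(p1 = "d1", p2 = "d2", p3 = c("d1", "d3"), p4 = "d3")
  ddis <- data.frame(domain_a = c("d1", "d2"), domain_b = c("d2", "d3"))
  one <- data.frame(protein_a = "p1", protein_b = "p2", rank = 1)
  expect_equal(ddi_enrichment(one, ann, ddis), 1)
  miss <- data.frame(protein_a = "p1", protein_b = "p4", rank = 1)
  expect_equal(ddi_enrichment(miss, ann, ddis), 0)  # (d1,d3) unknown
  # protein without any annotation is excluded with a message
  two <- data.frame(protein_a = c("p1", "p1"), protein_b = c("p2", "p9"),
                    rank = c(1, 2))
  expect_message(frac <- ddi_enrichment(two, ann, ddis), "excluded")
  expect_equal(frac, 1)
  # tighter thresholds on a truth-ranked list cannot dilute enrichment
  ranked <- data.frame(protein_a = c("p1", "p2", "p1"),
                       protein_b = c("p2", "p3", "p3"),
                       rank = 1:3)
  e_all <- ddi_enrichment(ranked, ann, ddis, rank_threshold = 3)
  e_top <- ddi_enrichment(ranked, ann, ddis, rank_threshold = 1)
  expect_gte(e_top, e_all)
})

test_that("evaluate_rankings summarizes scheme x refset with flagged gaps", {
  net <- random_small_net(9)
  cfg <- synthetic_config(n_proteins = 25L, n_true_pairs = 40L,
                          n_records = 120L, false_rate = 0.3,
                          popularity_exponent = 1, seed = 9)
  truth <- generate_truth(cfg)
  disjoint <- reference_set(c("zz1", "zz2"),
                            data.frame(protein_a = "zz1",
                                       protein_b = "zz2"))
  out <- evaluate_rankings(list(occurrence = occurrence_rank(net),
                                random = random_rank(net, 2)),
                           list(truth = truth, empty = disjoint))
  expect_equal(nrow(out), 4L)
  expect_true(all(is.na(out$A[out$refset == "empty"])))
  good <- out[out$refset == "truth", ]
  expect_true(all(good$A > 0 & good$A <= 1))
  expect_equal(good$A_random[1], good$A_random[2])
})
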