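test_that("rank MAE matches hand-derived cases and reversal formulas", {
  expect_identical(rank_mae(1:5, 1:5), 0)
  expect_identical(rank_mae(4:1, 1:4), 2.0)          # full reversal, n = 4
  expect_identical(rank_mae(c(1, 2, 4, 3, 5), c(1, 2, 3, 4, 5)), 0.4)
  for (n in c(2, 4, 6, 8, 12)) {
    expect_equal(rank_mae(n:1, 1:n), n / 2)
  }
  for (n in c(3, 5, 7, 11)) {
    expect_equal(rank_mae(n:1, 1:n), (n^2 - 1) / (2 * n))
  }
  expect_error(rank_mae(1:3, 1:4), "length")
})

test_that("spearman matches the no-tie closed form on random permutations", {
  expect_equal(spearman(1:6, 1:6), 1, tolerance = 1e-12)
  expect_equal(spearman(6:1, 1:6), -1, tolerance = 1e-12)
  expect_equal(spearman(c(1, 2, 4, 3, 5), 1:5), 0.9, tolerance = 1e-12)
  set.seed(77)
  for (k in 1:500) {
    n <- sample(2:12, 1)
    a <- sample(n); b <- sample(n)
    closed <- 1 - 6 * sum((a - b)^2) / (n * (n^2 - 1))
    expect_equal(spearman(a, b), closed, tolerance = 1e-12)
  }
  # ties get average ranks; zero variance is undefined
  expect_equal(spearman(c(1, 1, 2), c(1, 2, 3)),
               stats::cor(c(1.5, 1.5, 3), c(1, 2, 3)), tolerance = 1e-12)
  expect_true(is.na(spearman(c(2, 2, 2), c(1, 2, 3))))
})

test_that("nDCG follows the linear-gain log2-discount convention", {
  expect_identical(ndcg(1:5), 1)
  expect_identical(ndcg(1), 1)
  expect_equal(ndcg(c(2, 1)), 1 / log2(3), tolerance = 1e-12)
  # exhaustively: the maximum 1 is attained exactly by orderings that sort
  # true relevance non-increasingly (true rank non-decreasingly)
  for (n in 2:6) {
    perms <- as.matrix(expand.grid(rep(list(1:n), n)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                   drop = FALSE]
    vals <- apply(perms, 1, ndcg)
    is_sorted <- apply(perms, 1, function(p) !is.unsorted(p))
    expect_true(all(vals <= 1 + 1e-12))
    expect_identical(vals >= 1 - 1e-12, is_sorted)
  }
})

test_that("top-1 frequency counts groups whose predicted best is truly best", {
  mk <- function(first_true_rank, true_ranks) {
    data.frame(group_id = "g", structure_id = letters[seq_along(true_ranks)],
               score = seq_along(true_ranks),
               pred_rank = seq_along(true_ranks),
               true_rank = c(first_true_rank,
                             setdiff(true_ranks, first_true_rank)))
  }
  hits <- list(mk(1, 1:4), mk(1, 1:4), mk(1, 1:4), mk(2, 1:4))
  expect_identical(top1_frequency(hits), 0.75)
  expect_identical(top1_frequency(hits[1:3]), 1.0)
  expect_identical(top1_frequency(hits[4]), 0.0)
  # a tie for the true minimum counts as correct
  tied <- data.frame(group_id = "g", structure_id = c("a", "b"),
                     score = 1:2, pred_rank = 1:2,
                     true_rank = c(1.5, 1.5))
  expect_identical(top1_frequency(list(tied)), 1.0)
})

test_that("metric summaries report mean, sd and normal 95% CI", {
  s <- summarize_metric(c(0, 1))
  expect_identical(s$mean, 0.5)
  expect_equal(s$sd, 0.7071068, tolerance = 1e-6)
  expect_equal(s$ci95, 1.96 * s$sd / sqrt(2), tolerance = 1e-12)
  expect_identical(summarize_metric(rep(0.3, 5))$ci95, 0)
  s2 <- summarize_metric(c(0.1, NA, 0.5, NA))
  expect_identical(s2$n, 2L)
  expect_identical(s2$n_missing, 2L)
})

test_that("rank_group sorts by branch score with a stable tiebreak", {
  g <- small_group(5, seed = 21)
  truth <- vapply(g$structures, function(s) s$properties$energy, numeric(1))
  oracle <- function(s) s$properties$energy
  rr <- rank_group(oracle, g, "energy")
  expect_identical(rr$pred_rank, 1:5)
  expect_identical(rr$structure_id[1],
                   g$structures[[which.min(truth)]]$structure_id)
  expect_equal(rr$true_rank, rr$pred_rank)  # oracle scorer is perfect
  # descending orientation exactly reverses the predicted order
  rd <- rank_group(oracle, g, "energy", orientation = "descending")
  expect_identical(rd$structure_id, rev(rr$structure_id))
  # single-member group
  g1 <- conformer_group(g$group_id, g$structures[1])
  expect_identical(rank_group(oracle, g1, "energy")$pred_rank, 1L)
})

test_that("ranking by branch scores equals pairwise-probability aggregation", {
  m <- tiny_model(seed = 31)
  for (k in 1:6) {
    g <- small_group(sample(3:8, 1), n_atoms = 4, seed = 600 + k)
    rr <- rank_group(m, g, "energy")
    sc <- score_structures(m, g$structures)
    # brute force over all ordered pairs: total outranking probability
    n <- length(sc)
    agg <- vapply(seq_len(n), function(i) {
      sum(vapply(setdiff(seq_len(n), i), function(j) {
        pairwise_probability(sc[i], sc[j])
      }, numeric(1)))
    }, numeric(1))
    ids <- vapply(g$structures, function(s) s$structure_id, character(1))
    expect_identical(rr$structure_id, ids[order(agg)])
  }
})

test_that("evaluate_ranking aggregates the four metrics over groups", {
  groups <- lapply(1:4, function(i) small_group(4, seed = 700 + i,
                                                gid = paste0("g", i)))
  oracle <- function(s) s$properties$energy
  mr <- evaluate_ranking(oracle, groups, "energy")
  expect_identical(nrow(mr$report), 4L)
  expect_setequal(mr$report$metric,
                  c("rank_mae", "spearman", "ndcg", "top1"))
  expect_equal(metric_mean(mr, "rank_mae"), 0)
  expect_equal(metric_mean(mr, "spearman"), 1)
  expect_equal(metric_mean(mr, "ndcg"), 1)
  expect_equal(metric_mean(mr, "top1"), 1)
  anti <- function(s) -s$properties$energy
  expect_equal(metric_mean(evaluate_ranking(anti, groups, "energy"),
                           "spearman"), -1)
})
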