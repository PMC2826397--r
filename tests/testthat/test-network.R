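# ROC / precision-recall evaluation with analytic truncation completion.

test_that("confusion curves reproduce the hand-counted worked cases", {
  cv <- confusion_from_ranks(c(TRUE, FALSE, TRUE, FALSE), 2, 4)
  expect_equal(cv$tp, c(1, 1, 2, 2))
  expect_equal(cv$precision, c(1, 0.5, 2 / 3, 0.5))
  expect_equal(cv$recall[4], 1)
  expect_equal(cv$fpr[4], 1)
  expect_equal(auroc(cv), 0.75)
  expect_equal(aupr(cv), 5 / 6)

  # truncated after one correct positive: expected tail counts
  cvt <- confusion_from_ranks(TRUE, 2, 4)
  expect_equal(cvt$tp[2], 1 + 1 / 3)
  expect_equal(cvt$tp[4], 2)
  expect_equal(auroc(cvt), 0.75)

  # empty list over P = 1, N = 1
  cve <- confusion_from_ranks(logical(0), 1, 2)
  expect_equal(aupr(cve), 0.75)
  expect_equal(auroc(cve), 0.5)

  # perfect full-length list
  cvp <- confusion_from_ranks(c(TRUE, TRUE, rep(FALSE, 4)), 2, 6)
  expect_equal(auroc(cvp), 1)
  expect_equal(aupr(cvp), 1)
  expect_true(all(cvp$precision[cvp$recall < 1] == 1))
})

test_that("confusion_curves validates against the gold universe", {
  gold <- gold_network(c("a", "b", "c"),
                       data.frame(source = c("a", "b"), target = c("b", "c")))
  pl <- prediction_list(c("a", "c"), c("b", "a"), universe = gold)
  cv <- confusion_curves(pl, gold)
  expect_equal(cv$n_candidates, 6)
  expect_equal(cv$k_t, 2)
  outsider <- prediction_list("a", "z")
  expect_error(confusion_curves(outsider, gold), "universe",
               class = "dreambench_validation_error")
})

test_that("trapezoid AUROC equals pair counting on random full lists", {
  set.seed(99)
  for (i in 1:25) {
    R <- sample(6:40, 1)
    P <- sample(seq_len(R - 1), 1)
    pos <- sort(sample.int(R, P))
    is_pos <- seq_len(R) %in% pos
    cv <- confusion_from_ranks(is_pos, P, R)
    m <- oracle_full_metrics(pos, P, R)
    expect_equal(auroc(cv), m$auroc, tolerance = 1e-12)
    expect_equal(aupr(cv), m$aupr, tolerance = 1e-12)
  }
})

test_that("reversing a full list maps AUROC to 1 - AUROC", {
  set.seed(4)
  for (i in 1:10) {
    R <- 20; P <- 7
    is_pos <- seq_len(R) %in% sample.int(R, P)
    a1 <- auroc(confusion_from_ranks(is_pos, P, R))
    a2 <- auroc(confusion_from_ranks(rev(is_pos), P, R))
    expect_equal(a1 + a2, 1, tolerance = 1e-12)
  }
})

test_that("appending noise after full recall changes neither area", {
  full <- confusion_from_ranks(c(TRUE, TRUE, TRUE, rep(FALSE, 9)), 3, 12)
  trunc <- confusion_from_ranks(c(TRUE, TRUE, TRUE), 3, 12)
  expect_equal(auroc(full), auroc(trunc))
  expect_equal(aupr(full), aupr(trunc))
  expect_equal(auroc(full), 1)
})

test_that("analytic completion equals Monte-Carlo tail shuffles", {
  set.seed(123)
  cases <- list(
    list(is_pos = c(TRUE, FALSE, TRUE), P = 5, R = 20),
    list(is_pos = logical(0), P = 4, R = 12),
    list(is_pos = c(FALSE, FALSE, TRUE), P = 3, R = 30),
    list(is_pos = rep(TRUE, 2), P = 6, R = 25)
  )
  for (cs in cases) {
    cv <- confusion_from_ranks(cs$is_pos, cs$P, cs$R)
    mc <- oracle_mc_tail(cs$is_pos, cs$P, cs$R, n_reps = 2e4,
                         seed = 17 + cs$R)
    expect_lt(abs(auroc(cv) - mc$auroc), 0.005)
    expect_lt(abs(aupr(cv) - mc$aupr), 0.005)
  }
})

test_that("network_null is seeded, symmetric and enumerable at P=1,N=1", {
  gold <- gold_network(c("a", "b"), data.frame(source = "a", target = "b"))
  nul <- network_null(gold, n_reps = 4000, seed = 9)
  expect_setequal(unique(nul$auroc), c(0, 1))
  expect_lt(abs(mean(nul$auroc) - 0.5), 3 * 0.5 / sqrt(4000))
  nul2 <- network_null(gold, n_reps = 4000, seed = 9)
  expect_identical(nul, nul2)

  g2 <- gold_network(sprintf("n%d", 1:6),
                     data.frame(source = c("n1", "n2", "n3"),
                                target = c("n2", "n3", "n4")))
  nul3 <- network_null(g2, n_reps = 5000, seed = 2)
  se <- stats::sd(nul3$auroc) / sqrt(5000)
  expect_lt(abs(mean(nul3$auroc) - 0.5), 3 * se)
  expect_true(all(nul3$aupr >= 0 & nul3$aupr <= 1))
})

test_that("metric_pvalue smooths inside the range and extrapolates outside", {
  set.seed(6)
  nul <- rbeta(5000, 5, 5)
  p_med <- metric_pvalue(stats::median(nul), nul)
  expect_lt(abs(as.numeric(p_med) - 0.5), 0.03)
  p_out <- metric_pvalue(1.5, nul)  # beyond the sample maximum
  expect_gt(as.numeric(p_out), 0)
  expect_lt(as.numeric(p_out), 1 / 5000)
})

test_that("network_overall_score condenses five networks per metric", {
  rep0 <- network_overall_score(rep(1, 5), rep(1, 5))
  expect_equal(rep0$overall_score, 0)
  rep4 <- network_overall_score(rep(1e-4, 5), rep(1e-4, 5))
  expect_equal(rep4$overall_score, 4)
  rep_mix <- network_overall_score(rep(1e-6, 5), rep(1e-2, 5))
  expect_equal(rep_mix$overall_score, 4)
  expect_error(network_overall_score(rep(0.5, 4), rep(0.5, 4)),
               class = "dreambench_validation_error")
  expect_equal(network_overall_score(rep(0.5, 4), rep(0.5, 4),
                                     require_n = NA)$overall_score,
               -log10(0.5), tolerance = 1e-12)
})

test_that("score_network_set runs the full per-network pipeline", {
  set.seed(55)
  cfg <- sim_config(n_nodes = 8, n_edges = 7, n_regulators = 3, seed = 21,
                    noise_sd = 0.02, n_trajectories = 2)
  golds <- lapply(1:2, function(i) {
    generate_network(sim_config(n_nodes = 8, n_edges = 7, n_regulators = 3,
                                seed = 21 + i, noise_sd = 0.02,
                                n_trajectories = 2))
  })
  preds <- lapply(golds, function(g) {
    cfg_i <- sim_config(n_nodes = 8, n_edges = 7, n_regulators = 3,
                        seed = 100, noise_sd = 0.02, n_trajectories = 2)
    null_mutant_zscores(simulate_dataset(g, cfg_i))
  })
  rep <- score_network_set(preds, golds, n_reps = 2000, seed = 3)
  tab <- rep$extra$per_network
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$auroc >= 0 & tab$auroc <= 1))
  expect_true(all(tab$p_auroc > 0 & tab$p_auroc <= 1))
  expect_gte(rep$overall_score, 0)
})
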