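# Rank-sum consensus and community analytics.

test_that("rank-sum consensus reproduces the hand-summed example", {
  # universe of 3 edges realized over nodes {a, b}? use an abstract 2-node
  # universe is too small; take 3 specific pairs over 3 nodes and leave the
  # rest unsubmitted equally in both lists so they cannot interfere
  l1 <- prediction_list(c("a", "b", "c"), c("b", "c", "a"), universe = 3)
  l2 <- prediction_list(c("b", "a", "c"), c("c", "b", "a"), universe = 3)
  cons <- rank_sum_consensus(list(l1, l2), universe = attr(l1, "nodes"))
  # e1 = a->b and e2 = b->c tie with rank sum 3; lexicographic break: a->b first
  expect_equal(cons$source[1], "a"); expect_equal(cons$target[1], "b")
  expect_equal(cons$source[2], "b"); expect_equal(cons$target[2], "c")
  expect_equal(cons$source[3], "c"); expect_equal(cons$target[3], "a")
  expect_equal(nrow(cons), 6)  # completed to the full universe

  # consensus of k copies of one full list is that list
  full <- rank_sum_consensus(list(cons, cons, cons), attr(cons, "nodes"))
  expect_equal(as.data.frame(full)[c("source", "target")],
               as.data.frame(cons)[c("source", "target")])

  expect_error(rank_sum_consensus(list(l1), 3),
               class = "dreambench_validation_error")
})

test_that("a perfect and a reversed list cancel to the tie-break order", {
  nodes <- c("a", "b", "c")
  pairs <- expand.grid(s = nodes, t = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  fwd <- prediction_list(pairs$s, pairs$t, universe = nodes)
  rev_ <- prediction_list(rev(pairs$s), rev(pairs$t), universe = nodes)
  cons <- rank_sum_consensus(list(fwd, rev_), nodes)
  lex <- order(cons$source, cons$target, method = "radix")
  expect_equal(lex, seq_len(nrow(cons)))  # pure lexicographic order
})

test_that("identifiability counts teams per gold edge with random completion", {
  gold <- gold_network(sprintf("n%d", 1:5),
                       data.frame(source = c("n1", "n2", "n3"),
                                  target = c("n2", "n3", "n4")))
  # no teams: everything in bin 0
  h0 <- identifiability(list(), gold)
  expect_equal(unname(h0$bins[["0"]]), 3)

  perfect <- prediction_list(gold$edges$source, gold$edges$target,
                             universe = gold)
  h <- identifiability(list(perfect, perfect), gold, cutoff = 6)
  expect_equal(unname(h$bins[["2"]]), 3)
  expect_equal(sum(h$bins), gold$n_positives)

  # deterministic under a fixed seed even with truncated lists
  short <- prediction_list("n5", "n1", universe = gold)
  h1 <- identifiability(list(short), gold, cutoff = 10, seed = 42)
  h2 <- identifiability(list(short), gold, cutoff = 10, seed = 42)
  expect_identical(h1$bins, h2$bins)
})

test_that("random communities match the independence calculation", {
  gold <- gold_network(sprintf("n%d", 1:8),
                       data.frame(source = sprintf("n%d", 1:6),
                                  target = sprintf("n%d", c(2:7))))
  cutoff <- 12
  R <- gold$n_candidates
  ref <- random_community_reference(gold, n_teams = 5, cutoff = cutoff,
                                    n_reps = 3000, seed = 13)
  frac0 <- ref$bins_mean[["0"]] / gold$n_positives
  expected <- (1 - cutoff / R)^5
  se <- stats::sd(ref$bins[, "0"] / gold$n_positives) / sqrt(nrow(ref$bins))
  expect_lt(abs(frac0 - expected), 3 * se + 1e-9)

  full <- random_community_reference(gold, n_teams = 3, cutoff = R,
                                     n_reps = 10, seed = 1)
  expect_equal(unname(full$bins_mean[["3"]]), gold$n_positives)
})

test_that("identifiability of random teams is binomial per edge", {
  set.seed(61)
  gold <- gold_network(sprintf("n%d", 1:7),
                       data.frame(source = sprintf("n%d", 1:5),
                                  target = sprintf("n%d", 2:6)))
  R <- gold$n_candidates
  cutoff <- 2L * gold$n_positives
  pairs <- expand.grid(s = gold$nodes, t = gold$nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  n_teams <- 6
  votes <- unlist(lapply(1:60, function(rep) {
    preds <- lapply(1:n_teams, function(i) {
      ord <- sample.int(R)
      prediction_list(pairs$s[ord], pairs$t[ord], universe = gold$nodes)
    })
    identifiability(preds, gold, cutoff = cutoff)$edge_votes
  }))
  emp_cdf <- stats::ecdf(votes)
  theo <- stats::pbinom(0:n_teams, n_teams, cutoff / R)
  D <- max(abs(emp_cdf(0:n_teams) - theo))
  expect_lt(D, 0.1)
})

test_that("ks_two_sample matches enumeration and the reference implementation", {
  res <- ks_two_sample(1:3, 4:6)
  expect_equal(res$D, 1)
  expect_equal(res$p, 0.1)

  same <- ks_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)

  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(5); b <- rnorm(6)
    ours <- ks_two_sample(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = TRUE))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  # asymptotic branch stays within [0,1] and tracks the reference
  a <- rnorm(40); b <- rnorm(35, 0.5)
  ours <- ks_two_sample(a, b)
  ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 0.01)
  expect_true(ours$D >= 0 && ours$D <= 1)
})

test_that("topology classification flags shortcuts and co-regulation", {
  chain <- gold_network(c("A", "B", "C", "D"),
                        data.frame(source = c("A", "B"), target = c("B", "C")))
  topo <- classify_topologies(chain)
  row_ac <- topo[topo$source == "A" & topo$target == "C", ]
  expect_true(row_ac$shortcut)
  expect_false(row_ac$co_regulated)
  row_da <- topo[topo$source == "D" & topo$target == "A", ]
  expect_false(row_da$special)
  expect_equal(nrow(topo), chain$n_candidates - chain$n_positives)

  fan <- gold_network(c("A", "B", "C"),
                      data.frame(source = c("A", "A"), target = c("B", "C")))
  tf <- classify_topologies(fan)
  for (pp in list(c("B", "C"), c("C", "B"))) {
    r <- tf[tf$source == pp[1] & tf$target == pp[2], ]
    expect_true(r$co_regulated)
    expect_false(r$shortcut)
  }
})

test_that("fisher_exact_2x2 matches the hypergeometric reference everywhere", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, 2)),
               0.485714285714, tolerance = 1e-9)
  # exhaustive small tables + seeded larger ones vs stats::fisher.test
  tabs <- list()
  for (a in 0:4) for (b in 0:4) for (cc in 0:4) for (d in 0:4) {
    if (a + b + cc + d > 0) tabs[[length(tabs) + 1]] <- matrix(c(a, cc, b, d), 2, 2)
  }
  set.seed(19)
  for (i in 1:60) {
    tabs[[length(tabs) + 1]] <- matrix(sample.int(11, 4) - 1 + sample.int(8, 4), 2, 2)
  }
  for (tab in tabs) {
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(fisher_exact_2x2(tab), ref, tolerance = 1e-10,
                 info = paste(tab, collapse = ","))
  }
})

test_that("systematic FP analysis builds a full-margin contingency table", {
  set.seed(31)
  cfg <- sim_config(n_nodes = 12, n_edges = 14, n_regulators = 4, seed = 8,
                    noise_sd = 0.05, n_trajectories = 1)
  gold <- generate_network(cfg)
  dat <- simulate_dataset(gold, cfg)
  strong <- null_mutant_zscores(dat)
  pairs <- all_pairs_for(gold)
  preds <- c(list(strong, strong), lapply(1:3, function(i) {
    ord <- sample.int(nrow(pairs))
    prediction_list(pairs$source[ord], pairs$target[ord], universe = gold$nodes)
  }))
  res <- systematic_fp_analysis(preds, gold, top_fraction = 0.05, seed = 3)
  expect_equal(sum(res$table), gold$n_candidates - gold$n_positives)
  expect_gte(res$n_systematic, res$n_systematic_nominal)
  expect_true(res$fisher_p > 0 && res$fisher_p <= 1)
  expect_equal(unname(res$ratios),
               unname(res$table[, "special"] / res$table[, "generic"]))
})

test_that("the printed contingency ratios round as published", {
  tab <- matrix(c(51, 920, 47, 8757), 2, 2,
                dimnames = list(c("systematic", "rare"),
                                c("special", "generic")))
  r <- contingency_ratios(tab)
  expect_equal(round(unname(r["systematic"]), 2), 1.09)
  expect_equal(round(unname(r["rare"]), 2), 0.11)
})

test_that("consensus degrades slower than the worst member", {
  # one informative predictor plus progressively more random lists,
  # over several simulated networks
  set.seed(91)
  n_nets <- 12
  deltas <- vapply(seq_len(n_nets), function(s) {
    cfg <- sim_config(n_nodes = 10, n_edges = 11, n_regulators = 5,
                      seed = 500 + s, noise_sd = 0.05, n_trajectories = 1)
    gold <- generate_network(cfg)
    dat <- simulate_dataset(gold, cfg)
    strong <- null_mutant_zscores(dat)
    pairs <- all_pairs_for(gold)
    rand_lists <- lapply(1:3, function(i) {
      ord <- sample.int(nrow(pairs))
      prediction_list(pairs$source[ord], pairs$target[ord],
                      universe = gold$nodes)
    })
    cons <- rank_sum_consensus(c(list(strong), rand_lists), gold$nodes)
    au_cons <- auroc(confusion_curves(cons, gold))
    au_worst <- min(vapply(rand_lists, function(p) {
      auroc(confusion_curves(p, gold))
    }, 0))
    au_cons - au_worst
  }, 0)
  expect_gt(mean(deltas), 0)
  expect_gt(mean(deltas > 0), 0.75)
})
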