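# Community analytics: rank-sum consensus, identifiability of gold edges,
# systematic false positives, and the supporting KS and Fisher tests.

# All ordered non-self pairs over a node set, in lexicographic order.
all_ordered_pairs <- function(nodes) {
  grid <- expand.grid(target = nodes, source = nodes,
                      stringsAsFactors = FALSE)[, 2:1]
  grid <- grid[grid$source != grid$target, ]
  grid <- grid[order(grid$source, grid$target, method = "radix"), ]
  rownames(grid) <- NULL
  grid
}

pair_key <- function(source, target) paste(source, target, sep = "\r")

#' Rank-sum consensus of several ranked edge lists
#'
#' Each edge's ranks across lists are summed and the edges re-ranked by
#' ascending rank sum.  A truncated list contributes, for every edge it
#' omits, the average of the unfilled rank positions `(k_t + 1 + R) / 2`,
#' which makes the consensus deterministic.  Rank-sum ties break
#' lexicographically by (source, target).
#'
#' @param preds list (>= 2) of [prediction_list()] objects over a shared
#'   universe.
#' @param universe a [gold_network()], node count, or node-id vector.
#' @return A full-length [prediction_list()].
#' @export
rank_sum_consensus <- function(preds, universe) {
  if (length(preds) < 2) db_stop("need at least two prediction lists")
  nodes <- resolve_universe(universe, unlist(lapply(preds, function(p) {
    c(p$source, p$target)
  })))
  pairs <- all_ordered_pairs(nodes)
  keys <- pair_key(pairs$source, pairs$target)
  R <- nrow(pairs)
  total <- numeric(R)
  for (p in preds) {
    k_t <- nrow(p)
    if (k_t > R) db_stop("prediction longer than the candidate universe")
    rank_of <- rep((k_t + 1 + R) / 2, R)
    idx <- match(pair_key(p$source, p$target), keys)
    if (anyNA(idx)) db_stop("prediction contains a pair outside the universe")
    rank_of[idx] <- seq_len(k_t)
    total <- total + rank_of
  }
  ord <- order(total, pairs$source, pairs$target, method = "radix")
  rng <- range(total)
  conf <- if (diff(rng) > 0) (rng[2] - total[ord]) / diff(rng) else rep(1, R)
  prediction_list(pairs$source[ord], pairs$target[ord],
                  confidence = conf, universe = nodes)
}

# Top-`cutoff` edge keys of one list, completing a truncated list with a
# random ordering of the missing pairs (shared RNG stream of the caller).
top_cutoff_keys <- function(pred, keys, cutoff) {
  k_t <- nrow(pred)
  sub <- pair_key(pred$source, pred$target)
  if (anyNA(match(sub, keys))) db_stop("prediction contains a pair outside the universe")
  if (k_t >= cutoff) return(sub[seq_len(cutoff)])
  missing <- setdiff(keys, sub)
  c(sub, sample(missing))[seq_len(cutoff)]
}

#' Identifiability distribution of the gold-standard edges
#'
#' For each gold edge, counts how many teams placed it within the top
#' `cutoff` entries of their list (default cutoff `2P`).  Truncated lists
#' are completed with a seeded random ordering of the missing pairs before
#' thresholding.
#'
#' @param preds list of [prediction_list()] objects.
#' @param gold a [gold_network()].
#' @param cutoff edge-count threshold (default `2 * P`, capped at `R`).
#' @param seed integer seed for random completion of truncated lists.
#' @return Object of class `identifiability_histogram`: list with `cutoff`,
#'   `bins` (named counts over 0..n_teams, summing to P) and `edge_votes`
#'   (per gold edge).
#' @export
identifiability <- function(preds, gold, cutoff = NULL, seed = 1L) {
  stopifnot(inherits(gold, "gold_network"))
  cutoff <- as.integer(cutoff %||% min(2L * gold$n_positives, gold$n_candidates))
  if (cutoff < 1 || cutoff > gold$n_candidates) {
    db_stop("cutoff must lie in 1..R")
  }
  pairs <- all_ordered_pairs(gold$nodes)
  keys <- pair_key(pairs$source, pairs$target)
  gold_keys <- pair_key(gold$edges$source, gold$edges$target)
  votes <- stats::setNames(integer(length(gold_keys)), gold_keys)
  with_seed(seed, {
    for (p in preds) {
      top <- top_cutoff_keys(p, keys, cutoff)
      hit <- gold_keys %in% top
      votes[hit] <- votes[hit] + 1L
    }
  })
  bins <- tabulate(votes + 1L, nbins = length(preds) + 1L)
  structure(list(
    cutoff = cutoff,
    bins = stats::setNames(bins, 0:length(preds)),
    edge_votes = votes,
    n_teams = length(preds)
  ), class = "identifiability_histogram")
}

#' @export
print.identifiability_histogram <- function(x, ...) {
  cat(sprintf("<identifiability_histogram> cutoff=%d, %d teams\n",
              x$cutoff, x$n_teams))
  print(x$bins)
  invisible(x)
}

#' Identifiability of a community of random prediction lists
#'
#' Simulates `n_reps` communities of `n_teams` uniformly random full-length
#' lists and records each community's identifiability histogram.
#'
#' @inheritParams identifiability
#' @param n_teams number of random teams per community.
#' @param n_reps number of simulated communities.
#' @return List with `bins_mean` (average histogram, names 0..n_teams) and
#'   `bins` (n_reps x (n_teams + 1) count matrix).
#' @export
random_community_reference <- function(gold, n_teams, cutoff = NULL,
                                       n_reps = 100L, seed = 1L) {
  stopifnot(inherits(gold, "gold_network"))
  cutoff <- as.integer(cutoff %||% min(2L * gold$n_positives, gold$n_candidates))
  P <- gold$n_positives
  R <- gold$n_candidates
  if (cutoff < 1 || cutoff > R) db_stop("cutoff must lie in 1..R")
  with_seed(seed, {
    bins <- matrix(0L, n_reps, n_teams + 1L,
                   dimnames = list(NULL, 0:n_teams))
    for (r in seq_len(n_reps)) {
      votes <- integer(P)
      for (tm in seq_len(n_teams)) {
        # a random list's top-cutoff is a uniform cutoff-subset of the R pairs;
        # gold edges occupy the labels 1..P
        s <- sample.int(R, cutoff)
        hit_edges <- s[s <= P]
        votes[hit_edges] <- votes[hit_edges] + 1L
      }
      bins[r, ] <- tabulate(votes + 1L, nbins = n_teams + 1L)
    }
    list(bins_mean = colMeans(bins), bins = bins)
  })
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute ECDF difference.  The p-value is
#' exact by enumeration of all label assignments for `m + n <= 12`, and the
#' asymptotic Kolmogorov tail otherwise.
#'
#' @param a,b numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) db_stop("both samples must be non-empty")
  D <- ks_statistic(a, b)
  m <- length(a); n <- length(b)
  if (m + n <= 12L) {
    pooled <- c(a, b)
    combs <- utils::combn(m + n, m)
    ds <- apply(combs, 2, function(ia) {
      ks_statistic(pooled[ia], pooled[-ia])
    })
    p <- mean(ds >= D - 1e-12)
  } else {
    lambda <- sqrt(m * n / (m + n)) * D
    j <- 1:100
    p <- min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
  }
  list(D = D, p = p)
}

ks_statistic <- function(a, b) {
  t <- sort(unique(c(a, b)))
  fa <- vapply(t, function(v) mean(a <= v), 0)
  fb <- vapply(t, function(v) mean(b <= v), 0)
  max(abs(fa - fb))
}

#' Classify negative pairs by confusable topology
#'
#' A negative ordered pair (A, B) is a *shortcut* when a directed path
#' `A -> ... -> B` of length >= 2 exists in the gold network (predicting it
#' confuses indirect with direct regulation), and *co-regulated* when some
#' node C regulates both A and B.  `special` is the union of the two.
#'
#' @param gold a [gold_network()].
#' @return Data frame over all `R - P` negatives with columns `source`,
#'   `target`, `shortcut`, `co_regulated`, `special`.
#' @export
classify_topologies <- function(gold) {
  stopifnot(inherits(gold, "gold_network"))
  nodes <- gold$nodes
  g <- igraph::graph_from_data_frame(gold$edges, directed = TRUE,
                                     vertices = nodes)
  dist <- igraph::distances(g, mode = "out")
  dist <- dist[nodes, nodes]
  adj <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  adj[cbind(gold$edges$source, gold$edges$target)] <- 1L
  common_in <- crossprod(adj)  # [a, b] = number of shared regulators
  pairs <- all_ordered_pairs(nodes)
  is_edge <- pair_key(pairs$source, pairs$target) %in%
    pair_key(gold$edges$source, gold$edges$target)
  neg <- pairs[!is_edge, ]
  ij <- cbind(neg$source, neg$target)
  neg$shortcut <- is.finite(dist[ij]) & dist[ij] >= 2
  neg$co_regulated <- common_in[ij] > 0
  neg$special <- neg$shortcut | neg$co_regulated
  rownames(neg) <- NULL
  neg
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Point-probability method: the p-value sums the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table.
#'
#' @param tab 2x2 integer matrix (or something coercible).
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2)
  if (any(tab < 0) || any(tab != round(tab))) db_stop("table must be non-negative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Systematic false positives vs confusable topology
#'
#' Negatives are ranked by how many teams predicted them within the top
#' `cutoff` entries (truncated lists randomly completed, as in
#' [identifiability()]).  The top `top_fraction` of negatives by vote count
#' are the *systematic* false positives; the rest are *rare*.  Both groups
#' are cross-classified against special/generic topology
#' ([classify_topologies()]) into a 2x2 table whose entries sum to the
#' number of negatives.  Vote ties straddling the boundary are all included
#' (the systematic group may slightly exceed the nominal fraction; this is
#' recorded in the output).
#'
#' @inheritParams identifiability
#' @param top_fraction fraction of negatives called systematic (default 0.01).
#' @return List with `table` (2x2: rows systematic/rare, cols
#'   special/generic), `ratios` (special:generic per row), `fisher_p`,
#'   `n_systematic_nominal`, `n_systematic` and `votes` per negative pair.
#' @export
systematic_fp_analysis <- function(preds, gold, cutoff = NULL,
                                   top_fraction = 0.01, seed = 1L) {
  stopifnot(inherits(gold, "gold_network"))
  if (top_fraction <= 0 || top_fraction >= 1) db_stop("top_fraction must be in (0, 1)")
  cutoff <- as.integer(cutoff %||% min(2L * gold$n_positives, gold$n_candidates))
  topo <- classify_topologies(gold)
  keys_all <- pair_key(all_ordered_pairs(gold$nodes)$source,
                       all_ordered_pairs(gold$nodes)$target)
  neg_keys <- pair_key(topo$source, topo$target)
  votes <- stats::setNames(integer(length(neg_keys)), neg_keys)
  with_seed(seed, {
    for (p in preds) {
      top <- top_cutoff_keys(p, keys_all, cutoff)
      hit <- neg_keys %in% top
      votes[hit] <- votes[hit] + 1L
    }
  })
  n_neg <- length(neg_keys)
  n_top <- max(1L, ceiling(top_fraction * n_neg))
  thr <- sort(votes, decreasing = TRUE)[n_top]
  systematic <- votes >= thr
  tab <- rbind(
    systematic = c(special = sum(systematic & topo$special),
                   generic = sum(systematic & !topo$special)),
    rare = c(special = sum(!systematic & topo$special),
             generic = sum(!systematic & !topo$special))
  )
  list(
    table = tab,
    ratios = contingency_ratios(tab),
    fisher_p = fisher_exact_2x2(tab),
    n_systematic_nominal = n_top,
    n_systematic = sum(systematic),
    vote_threshold = thr,
    votes = votes,
    topology = topo
  )
}

#' Special-to-generic ratios of a 2x2 contingency table
#' @param tab 2x2 matrix, columns (special, generic).
#' @return numeric vector of per-row ratios `special / generic`.
#' @export
contingency_ratios <- function(tab) {
  tab <- matrix(as.numeric(tab), 2, 2,
                dimnames = dimnames(tab) %||%
                  list(c("systematic", "rare"), c("special", "generic")))
  stats::setNames(tab[, 1] / tab[, 2], rownames(tab))
}
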