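# Independent oracles used to freeze expected values.  These deliberately
# brute-force what the package computes in closed form.

# All injective maps from 1..m into 1..s, as an (s!/(s-m)!) x m matrix.
enumerate_injective_maps <- function(s, m) {
  grow <- function(prefix) {
    if (length(prefix) == m) return(list(prefix))
    unlist(lapply(setdiff(seq_len(s), prefix),
                  function(k) grow(c(prefix, k))), recursive = FALSE)
  }
  do.call(rbind, grow(integer(0)))
}

# Brute-force match distribution against a reference injective map.
oracle_match_counts <- function(s, m, reference = seq_len(m)) {
  maps <- enumerate_injective_maps(s, m)
  matches <- rowSums(maps == matrix(reference, nrow(maps), m, byrow = TRUE))
  counts <- tabulate(matches + 1L, nbins = m + 1L)
  stats::setNames(counts, 0:m)
}

# AUROC / AUPR of a full-length list given the rank positions of positives.
oracle_full_metrics <- function(pos_ranks, P, R) {
  N <- R - P
  pos_ranks <- sort(pos_ranks)
  list(
    auroc = (P * N + P * (P + 1) / 2 - sum(pos_ranks)) / (P * N),
    aupr = mean(seq_len(P) / pos_ranks)
  )
}

# Monte-Carlo mean AUROC/AUPR over random tail completions of a truncated
# list.  `is_positive` marks the submitted prefix; the remaining
# P_r positives and N_r negatives are appended in random order.
oracle_mc_tail <- function(is_positive, P, R, n_reps, seed) {
  k_t <- length(is_positive)
  tp_t <- sum(is_positive)
  p_r <- P - tp_t
  n_r <- (R - P) - (k_t - tp_t)
  sub_pos <- which(is_positive)
  set.seed(seed)
  roc <- pr <- numeric(n_reps)
  tail_labels <- c(rep(TRUE, p_r), rep(FALSE, n_r))
  for (i in seq_len(n_reps)) {
    tail <- sample(tail_labels)
    pos_ranks <- c(sub_pos, k_t + which(tail))
    m <- oracle_full_metrics(pos_ranks, P, R)
    roc[i] <- m$auroc
    pr[i] <- m$aupr
  }
  list(auroc = mean(roc), aupr = mean(pr))
}

# Spearman upper-tail p by direct enumeration (independent of the package's
# cached D2 distribution code path).
oracle_spearman_p <- function(rho_obs, n) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  rhos <- vapply(perms(seq_len(n)),
                 function(p) suppressWarnings(cor(p, seq_len(n), method = "spearman")),
                 0)
  mean(rhos >= rho_obs - 1e-12)
}

geometric_mean_oracle <- function(x) prod(x)^(1 / length(x))

# All ordered non-self pairs of a gold network's nodes.
all_pairs_for <- function(gold) {
  grid <- expand.grid(target = gold$nodes, source = gold$nodes,
                      stringsAsFactors = FALSE)[, 2:1]
  grid[grid$source != grid$target, ]
}

# A small measurement-table pair (training with holes + full truth).
make_response_fixture <- function() {
  truth_vals <- matrix(c(1000, 450, 800, 1200, 300, 950), 2, 3,
                       dimnames = list(c("condA", "condB"),
                                       c("akt", "erk", "jnk")))
  mask <- matrix(FALSE, 2, 3, dimnames = dimnames(truth_vals))
  mask[1, 1] <- TRUE
  mask[2, 3] <- TRUE
  train_vals <- truth_vals
  train_vals[mask] <- NA
  list(
    train = measurement_table(train_vals),
    truth = measurement_table(truth_vals, mask = mask)
  )
}

# Larger measurement fixture with enough donor values per column for a
# non-degenerate resampling null.
make_response_fixture_big <- function() {
  set.seed(940)
  vals <- matrix(round(stats::rlnorm(8 * 4, log(800), 0.6)), 8, 4,
                 dimnames = list(sprintf("cond%02d", 1:8),
                                 c("akt", "erk", "jnk", "stat3")))
  mask <- matrix(FALSE, 8, 4, dimnames = dimnames(vals))
  mask[cbind(c(1, 3, 6, 8), c(1, 2, 3, 4))] <- TRUE
  train_vals <- vals
  train_vals[mask] <- NA
  list(train = measurement_table(train_vals),
       truth = measurement_table(vals, mask = mask))
}

# A small strain panel with hand-set values (no simulator involvement).
make_toy_strain_data <- function() {
  genes <- c("A", "B", "C")
  wt <- c(A = 10, B = 10, C = 5)
  # deleted strain in columns, measured gene in rows; B's panel across
  # (WT, KO_A, KO_B, KO_C) is (10, 2, 10, 10): mean 8, sample sd 4
  ko <- matrix(c(
    0, 10, 10,   # A
    2, 10, 10,   # B
    5,  5,  0    # C
  ), 3, 3, byrow = TRUE, dimnames = list(genes, genes))
  strain_expression(genes, wt, ko)
}
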