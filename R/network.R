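# ROC / precision-recall evaluation of ranked edge lists.
#
# A prediction is scored by sweeping the decision threshold k = 1..R over
# the ranked list (R = N(N-1) candidate ordered pairs).  Truncated lists
# are completed analytically: the unsubmitted edges are treated as appended
# in uniformly random order and every count beyond the truncation depth is
# replaced by its expectation, so scores are deterministic.  With P_r
# unsubmitted positives and N_r unsubmitted negatives, the expected
# per-step gain in TP is P_r / (P_r + N_r).

#' Confusion-curve bookkeeping for a ranked edge list
#'
#' @param pred a [prediction_list()] whose edges lie in the candidate
#'   universe of `gold`.
#' @param gold a [gold_network()].
#' @return Object of class `confusion_curves`: vectors `tp`, `fp`,
#'   `precision`, `recall`, `tpr`, `fpr` over depths `k = 1..R` (fractional
#'   beyond the truncation depth `k_t`), plus `k_t`, `n_positives`,
#'   `n_negatives`, `n_candidates` and the per-rank indicator `is_positive`
#'   (length `k_t`).
#' @export
confusion_curves <- function(pred, gold) {
  stopifnot(inherits(pred, "prediction_list"), inherits(gold, "gold_network"))
  P <- gold$n_positives
  R <- gold$n_candidates
  N <- R - P
  if (N <= 0) db_stop("gold network has no negatives (all pairs are edges)")
  outside <- !(pred$source %in% gold$nodes) | !(pred$target %in% gold$nodes)
  if (any(outside)) {
    i <- which(outside)[1]
    db_stop("predicted edge outside the gold universe at rank %d (%s -> %s)",
            i, pred$source[i], pred$target[i])
  }
  pos_keys <- paste(gold$edges$source, gold$edges$target, sep = "\r")
  is_pos <- paste(pred$source, pred$target, sep = "\r") %in% pos_keys
  confusion_from_ranks(is_pos, P, R)
}

#' Confusion curves from abstract rank indicators
#'
#' Lower-level constructor used by [confusion_curves()]: the submitted part
#' of a ranked list is reduced to a logical vector marking which ranks hold
#' positives, together with the positive count and universe size.  Useful
#' for worked examples and oracles where the universe is given as bare
#' counts rather than a node set.
#'
#' @param is_positive logical vector over submitted ranks `1..k_t`.
#' @param n_positives total positives P in the universe.
#' @param n_candidates universe size R (so negatives are `R - P`).
#' @return A `confusion_curves` object.
#' @export
confusion_from_ranks <- function(is_positive, n_positives, n_candidates) {
  P <- n_positives
  R <- n_candidates
  N <- R - P
  k_t <- length(is_positive)
  if (P < 1 || N < 1) db_stop("need at least one positive and one negative")
  if (k_t > R) db_stop("more submitted ranks than candidate pairs")
  if (sum(is_positive) > P || (k_t - sum(is_positive)) > N) {
    db_stop("submitted ranks contain more positives/negatives than the universe")
  }
  tp <- numeric(R)
  tp[seq_len(k_t)] <- cumsum(is_positive)
  if (k_t < R) {
    tp_t <- if (k_t > 0) tp[k_t] else 0
    p_r <- P - tp_t
    n_r <- N - (k_t - tp_t)
    rho <- p_r / (p_r + n_r)
    tp[(k_t + 1L):R] <- tp_t + seq_len(R - k_t) * rho
  }
  k <- seq_len(R)
  fp <- k - tp
  structure(list(
    tp = tp, fp = fp,
    precision = tp / k, recall = tp / P,
    tpr = tp / P, fpr = fp / N,
    k_t = k_t, is_positive = is_positive,
    n_positives = P, n_negatives = N, n_candidates = R
  ), class = "confusion_curves")
}

#' @export
print.confusion_curves <- function(x, ...) {
  cat(sprintf(
    "<confusion_curves> R=%d, P=%d, submitted depth k_t=%d (TP at k_t: %g)\n",
    x$n_candidates, x$n_positives, x$k_t, x$tp[x$k_t]))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of TPR against FPR from the origin.  On a
#' full-length list this equals the concordant-pair (Mann-Whitney) formula
#' exactly; on a truncated list the linear expected tail makes the trapezoid
#' equal to the exact expected AUROC under random completion.
#'
#' @param curves a [confusion_curves()].
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(curves) {
  stopifnot(inherits(curves, "confusion_curves"))
  fpr <- c(0, curves$fpr)
  tpr <- c(0, curves$tpr)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve (average precision)
#'
#' Defined as the mean, over positive-retrieval events, of the precision at
#' retrieval: `AUPR = (1/P) * sum_k w(k) * precision*(k)`.  For submitted
#' ranks, `w(k)` indicates a positive at rank k and `precision*(k) =
#' TP(k)/k`.  Beyond the truncation depth, `w(k) = P_r/(P_r + N_r)` and the
#' precision is conditioned on a positive landing at rank k:
#' `E[TP(k) | positive at k] = TP(k_t) + 1 + (k - k_t - 1)(P_r - 1)/(P_r + N_r - 1)`.
#'
#' @param curves a [confusion_curves()].
#' @return AUPR in `[0, 1]`.
#' @export
aupr <- function(curves) {
  stopifnot(inherits(curves, "confusion_curves"))
  P <- curves$n_positives
  k_t <- curves$k_t
  R <- curves$n_candidates
  ks <- seq_len(k_t)
  total <- sum(curves$tp[ks][curves$is_positive] / ks[curves$is_positive])
  if (k_t < R) {
    tp_t <- if (k_t > 0) curves$tp[k_t] else 0
    p_r <- P - tp_t
    if (p_r > 0) {
      n_r <- (R - P) - (k_t - tp_t)
      rho <- p_r / (p_r + n_r)
      k <- (k_t + 1L):R
      gain <- if (p_r + n_r > 1) (p_r - 1) / (p_r + n_r - 1) else 0
      cond_tp <- tp_t + 1 + (k - k_t - 1) * gain
      total <- total + sum(rho * cond_tp / k)
    }
  }
  total / P
}

#' Null distribution of (AUROC, AUPR) for random rankings
#'
#' Simulates uniformly random full-length orderings of the candidate edges
#' of `gold`.  Only the rank positions of the positives matter, so each
#' replicate draws `P` positions from `1..R` without replacement and applies
#' the closed-form pair-counting AUROC and average-precision AUPR.
#'
#' @param gold a [gold_network()].
#' @param n_reps number of random lists.
#' @param seed integer seed.
#' @return List with numeric vectors `auroc` and `aupr` of length `n_reps`.
#' @export
network_null <- function(gold, n_reps = 1e5, seed = 1L) {
  stopifnot(inherits(gold, "gold_network"))
  if (n_reps < 1) db_stop("n_reps must be >= 1")
  P <- gold$n_positives
  R <- gold$n_candidates
  N <- R - P
  if (N <= 0) db_stop("gold network has no negatives")
  with_seed(seed, {
    roc <- numeric(n_reps)
    pr <- numeric(n_reps)
    for (i in seq_len(n_reps)) {
      pos <- sort.int(sample.int(R, P))
      roc[i] <- (P * N + P * (P + 1) / 2 - sum(pos)) / (P * N)
      pr[i] <- mean(seq_len(P) / pos)
    }
    list(auroc = roc, aupr = pr)
  })
}

#' P-value of a metric against its empirical null
#'
#' Upper-tail probability that a random prediction scores at least as well.
#' Inside the null sample range the smoothed empirical fraction
#' `(r + 1)/(n + 1)` is used; outside the range, the two-sided
#' stretched-exponential fit is integrated so that exceptional predictions
#' still receive a finite, extrapolated p-value.
#'
#' @param observed observed metric value.
#' @param null_sample numeric null sample.
#' @param fit_tails `"auto"` (fit only when observed is outside the sample
#'   range), `TRUE` (always fit) or `FALSE` (never).
#' @return p-value in (0, 1]; may carry a `below_precision` attribute.
#' @export
metric_pvalue <- function(observed, null_sample, fit_tails = "auto") {
  if (length(null_sample) < 1) db_stop("empty null sample")
  outside <- observed > max(null_sample) || observed < min(null_sample)
  use_fit <- isTRUE(fit_tails) || (identical(fit_tails, "auto") && outside)
  empirical <- (sum(null_sample >= observed) + 1) / (length(null_sample) + 1)
  if (use_fit) {
    fit <- tryCatch(fit_stretched_exponential(null_sample),
                    dreambench_error = function(e) {
                      db_warn("tail fit unavailable (%s); using the smoothed empirical fraction",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) return(empirical)
    tail_pvalue(fit, observed, side = "upper")
  } else {
    empirical
  }
}

#' Overall network-inference score from per-network p-values
#'
#' The per-network AUPR p-values are condensed by their geometric mean, as
#' are the AUROC p-values, and the overall score is
#' `-log10(sqrt(p_aupr_summary * p_auroc_summary))`.
#'
#' @param p_aupr,p_auroc numeric vectors of per-network p-values in (0, 1].
#' @param require_n required number of networks per subchallenge (default
#'   5); use `NA` to accept any count.
#' @return A [score_report()].
#' @export
network_overall_score <- function(p_aupr, p_auroc, require_n = 5L) {
  if (length(p_aupr) != length(p_auroc)) db_stop("p-value vectors differ in length")
  if (!is.na(require_n) && length(p_aupr) != require_n) {
    db_stop("expected %d networks per subchallenge, got %d",
            require_n, length(p_aupr))
  }
  if (any(c(p_aupr, p_auroc) <= 0 | c(p_aupr, p_auroc) > 1)) {
    db_stop("p-values must lie in (0, 1]")
  }
  score_report(
    metrics = list(),
    pvalues = list(p_aupr = p_aupr, p_auroc = p_auroc),
    summary_pvalues = c(p_aupr = geometric_mean(p_aupr),
                        p_auroc = geometric_mean(p_auroc))
  )
}

#' Score a set of ranked edge lists against their gold networks
#'
#' Full pipeline for one subchallenge: per-network AUROC and AUPR, empirical
#' null p-values, summary p-values and the overall score.
#'
#' @param preds list of [prediction_list()] objects.
#' @param golds list of [gold_network()] objects (same length and order).
#' @param n_reps null-model replicates per network.
#' @param seed integer seed (one independent stream per network).
#' @param fit_tails passed to [metric_pvalue()].
#' @return A [score_report()]; `extra$per_network` holds a data frame of
#'   per-network AUROC, AUPR and p-values.
#' @export
score_network_set <- function(preds, golds, n_reps = 1e4, seed = 1L,
                              fit_tails = "auto") {
  if (length(preds) != length(golds)) db_stop("preds and golds differ in length")
  rows <- lapply(seq_along(preds), function(i) {
    cv <- confusion_curves(preds[[i]], golds[[i]])
    a_roc <- auroc(cv); a_pr <- aupr(cv)
    nul <- network_null(golds[[i]], n_reps = n_reps, seed = seed + i - 1L)
    data.frame(
      network = i, auroc = a_roc, aupr = a_pr,
      p_auroc = as.numeric(metric_pvalue(a_roc, nul$auroc, fit_tails)),
      p_aupr = as.numeric(metric_pvalue(a_pr, nul$aupr, fit_tails))
    )
  })
  tab <- do.call(rbind, rows)
  rep <- network_overall_score(tab$p_aupr, tab$p_auroc,
                               require_n = length(preds))
  rep$extra$per_network <- tab
  rep
}
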