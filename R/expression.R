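# Spearman profile scoring of rank-matrix predictions.
#
# A prediction is a genes x time-points matrix of ranks (each column a
# permutation of 1..G).  It is compared to the gold standard along both
# axes: per-time-point ("time profiles", vectors of length G) and per-gene
# ("gene profiles", vectors of length T).  Each profile yields a Spearman
# rho and a one-sided p-value under the permutation null; per-axis p-values
# are condensed by their geometric mean, and the overall score is
# -log10 of the geometric mean of the two summary p-values.

# Cache of exact null distributions of D2 = sum of squared rank differences.
.spearman_cache <- new.env(parent = emptyenv())

permutations_int <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_int(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- ((k - 1L) * nrow(sub) + 1L):(k * nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# Exact null distribution of D2 over all n! permutations (n <= 9):
# named count table, names = D2 values.
spearman_d2_null <- function(n) {
  key <- as.character(n)
  if (!is.null(.spearman_cache[[key]])) return(.spearman_cache[[key]])
  if (n > 9L) db_stop("exact Spearman null limited to n <= 9")
  p <- permutations_int(n)
  d2 <- rowSums((p - matrix(seq_len(n), nrow(p), n, byrow = TRUE))^2)
  tab <- table(d2)
  .spearman_cache[[key]] <- tab
  tab
}

#' Spearman rank correlation of two vectors
#'
#' Ties receive average ranks.
#'
#' @param a,b numeric vectors of equal length `n >= 2`.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) db_stop("vectors must have equal length")
  if (length(a) < 2) db_stop("need n >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    db_stop("rho undefined for a constant vector")
  }
  stats::cor(a, b, method = "spearman")
}

#' One-sided p-value for a Spearman correlation
#'
#' Upper-tail probability `P(rho_null >= rho)` under the null that the
#' predicted ranks are a uniformly random permutation.  Exact by enumeration
#' of the n! permutations for `n <= 9`; for larger n, the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` df is used, except
#' at the boundary `|rho| = 1` where the exact tail `1/n!` (or 1) applies.
#'
#' @param rho observed correlation.
#' @param n profile length, `n >= 3`.
#' @return p-value in (0, 1].
#' @export
spearman_pvalue <- function(rho, n) {
  if (n < 3) db_stop("need n >= 3")
  if (!is.finite(rho) || abs(rho) > 1 + 1e-12) db_stop("rho must lie in [-1, 1]")
  rho <- max(-1, min(1, rho))
  if (n <= 9L) {
    tab <- spearman_d2_null(n)
    d2_obs <- (1 - rho) * n * (n^2 - 1) / 6
    vals <- as.numeric(names(tab))
    sum(tab[vals <= d2_obs + 1e-9]) / factorial(n)
  } else {
    if (rho >= 1) return(1 / factorial(n))
    if (rho <= -1) return(1)
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    stats::pt(t, df = n - 2, lower.tail = FALSE)
  }
}

#' Profile scores along one axis of a rank-matrix prediction
#'
#' @param pred,gold [rank_matrix()] objects of identical shape and labels.
#' @param axis `"time"` scores each column (length-G profiles), `"gene"`
#'   scores each row (length-T profiles).
#' @return Object of class `profile_score`: list with `axis`, `rho`, `p`
#'   (named per profile) and `summary_p` (geometric mean of `p`).
#' @export
profile_scores <- function(pred, gold, axis = c("time", "gene")) {
  axis <- match.arg(axis)
  stopifnot(inherits(pred, "rank_matrix"), inherits(gold, "rank_matrix"))
  if (!identical(dim(pred), dim(gold)) ||
      !identical(dimnames(pred), dimnames(gold))) {
    db_stop("prediction and gold rank matrices must have identical shape and labels")
  }
  idx <- if (axis == "time") seq_len(ncol(gold)) else seq_len(nrow(gold))
  get_prof <- function(m, i) if (axis == "time") m[, i] else m[i, ]
  rho <- vapply(idx, function(i) spearman_rho(get_prof(pred, i), get_prof(gold, i)), 0)
  n <- if (axis == "time") nrow(gold) else ncol(gold)
  p <- vapply(rho, spearman_pvalue, n = n, FUN.VALUE = 0)
  nm <- if (axis == "time") colnames(gold) else rownames(gold)
  structure(list(axis = axis,
                 rho = stats::setNames(rho, nm),
                 p = stats::setNames(p, nm),
                 summary_p = geometric_mean(p)),
            class = "profile_score")
}

#' @export
print.profile_score <- function(x, ...) {
  cat(sprintf("<profile_score> axis=%s, %d profiles, summary p = %.3g\n",
              x$axis, length(x$rho), x$summary_p))
  invisible(x)
}

#' Overall expression-prediction score
#'
#' `-log10(sqrt(p_time * p_gene))`: minus log10 of the geometric mean of the
#' two summary p-values.  A difference of one in the score is an order of
#' magnitude in significance.
#'
#' @param p_time,p_gene summary p-values in (0, 1].
#' @return Non-negative score.
#' @export
expression_overall_score <- function(p_time, p_gene) {
  if (p_time <= 0 || p_time > 1 || p_gene <= 0 || p_gene > 1) {
    db_stop("summary p-values must lie in (0, 1]")
  }
  -log10(sqrt(p_time * p_gene))
}

#' Score a rank-matrix prediction against the gold standard
#'
#' Convenience wrapper running both axes and the overall score.
#'
#' @inheritParams profile_scores
#' @return A [score_report()] with per-axis profile scores in `extra`.
#' @export
score_expression <- function(pred, gold) {
  ts <- profile_scores(pred, gold, "time")
  gs <- profile_scores(pred, gold, "gene")
  score_report(
    metrics = list(rho_time = ts$rho, rho_gene = gs$rho),
    pvalues = list(p_time = ts$p, p_gene = gs$p),
    summary_pvalues = c(p_time = ts$summary_p, p_gene = gs$summary_p),
    extra = list(time = ts, gene = gs)
  )
}

#' Per-gene difficulty across a community of predictions
#'
#' The geometric mean, over teams, of each gene's gene-profile p-value;
#' low values mark genes the community predicted well.
#'
#' @param preds list of [rank_matrix()] predictions.
#' @param gold the gold-standard [rank_matrix()].
#' @return Named numeric vector (one value per gene), sortable into
#'   best-/worst-predicted lists.
#' @export
gene_difficulty <- function(preds, gold) {
  if (length(preds) < 1) db_stop("need at least one prediction")
  ps <- vapply(preds, function(pr) profile_scores(pr, gold, "gene")$p,
               numeric(nrow(gold)))
  ps <- matrix(ps, nrow = nrow(gold))
  stats::setNames(apply(ps, 1, geometric_mean), rownames(gold))
}
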