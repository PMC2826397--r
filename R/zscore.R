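# Null-mutant z-score network inference.
#
# For a candidate regulatory interaction A -> B, the z-score is the
# expression of B in the A-knockout strain, standardized by the mean and
# standard deviation of B across the strain panel (wild type plus the
# knockout strains; knockdown strains can optionally be included).  Direct
# regulators produce large deletion-induced shifts, so ranking all ordered
# pairs by |z| descending yields a network prediction.

#' Signed z-score matrix from a knockout panel
#'
#' Entry `[a, b]` is `z(A -> B) = (x_B^(deltaA) - mean_B) / sd_B`, where the
#' mean and sd of gene B are taken across the wild type and all knockout
#' strains (columns of the panel); the diagonal is `NA` (self-regulation is
#' not scored).  Pairs whose target has zero variance across strains score 0
#' with a warning.
#'
#' @param data a [strain_expression()].
#' @param include_knockdowns also pool the knockdown strains into the
#'   mean/sd (default `FALSE`).
#' @param sd_type `"sample"` (divisor n-1, default) or `"population"`.
#' @return `G x G` numeric matrix, rows = deleted gene A, cols = target B.
#' @export
zscore_matrix <- function(data, include_knockdowns = FALSE,
                          sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(data, "strain_expression"))
  genes <- data$genes
  g <- length(genes)
  if (g < 2) db_stop("need at least two genes")
  # panel: gene x strain, strains = WT + one KO per gene (+ optional KDs)
  panel <- cbind(WT = data$wildtype, data$knockouts)
  if (include_knockdowns) {
    if (is.null(data$knockdowns)) db_stop("no knockdown strains in the data")
    panel <- cbind(panel, data$knockdowns)
  }
  if (ncol(panel) < 3) db_stop("need at least 3 strains")
  mu <- rowMeans(panel)
  n <- ncol(panel)
  ss <- rowSums((panel - mu)^2)
  sd <- if (sd_type == "sample") sqrt(ss / (n - 1)) else sqrt(ss / n)
  z <- matrix(NA_real_, g, g, dimnames = list(regulator = genes, target = genes))
  zero_sd <- sd == 0
  if (any(zero_sd)) {
    db_warn("%d gene(s) constant across all strains; their incoming z-scores are 0",
            sum(zero_sd))
  }
  for (b in seq_len(g)) {
    if (zero_sd[b]) {
      z[, b] <- 0
    } else {
      # x_B in each deletion strain, standardized
      z[, b] <- (data$knockouts[b, ] - mu[b]) / sd[b]
    }
  }
  diag(z) <- NA_real_
  z
}

#' Rank candidate edges by null-mutant |z|
#'
#' Produces a full-length [prediction_list()] over all `G(G-1)` ordered
#' pairs, sorted by decreasing `|z|`; ties break lexicographically by
#' (source, target) so the output is deterministic.  Confidences are
#' `|z| / max |z|`.
#'
#' @inheritParams zscore_matrix
#' @return A [prediction_list()] of length `G(G-1)`.
#' @export
null_mutant_zscores <- function(data, include_knockdowns = FALSE,
                                sd_type = c("sample", "population")) {
  z <- zscore_matrix(data, include_knockdowns, sd_type)
  genes <- rownames(z)
  idx <- which(row(z) != col(z), arr.ind = TRUE)
  src <- genes[idx[, 1]]
  tgt <- genes[idx[, 2]]
  score <- abs(z[idx])
  ord <- order(-score, src, tgt, method = "radix")
  conf <- if (max(score) > 0) score[ord] / max(score) else rep(0, length(score))
  prediction_list(src[ord], tgt[ord], confidence = conf, universe = genes)
}
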