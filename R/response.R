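# Variance-normalized squared-error scoring of predicted measurements.
#
# Each withheld cell contributes (x - p)^2 / (sigma_tech^2 + (cv * x)^2):
# the squared prediction error normalized by an estimate of the measurement
# variance, the sum of a technical floor and a biological term proportional
# to the measured value.  The null model re-fills the withheld cells with
# values resampled (with replacement) from the observed entries of the same
# analyte column, so random predictions live on each analyte's own scale.

#' Solicited prediction-cell counts for a response subchallenge
#'
#' The number of withheld cells a subchallenge solicits: one prediction per
#' analyte, cell type, time point and held-out stimulus/inhibitor
#' combination.  With the challenge defaults this gives 476 phosphoprotein
#' predictions (17 x 2 x 2 x 7) and 560 cytokine predictions
#' (20 x 2 x 2 x 7).
#'
#' @param n_analytes number of measured analytes (17 phosphoproteins or 20
#'   cytokines).
#' @param n_cell_types number of cell types (default 2: normal, carcinoma).
#' @param n_time_points number of post-baseline time points scored
#'   (default 2).
#' @param n_test_conditions number of held-out stimulus/inhibitor
#'   combinations (default 7).
#' @return Integer cell count.
#' @export
prediction_cell_count <- function(n_analytes, n_cell_types = 2L,
                                  n_time_points = 2L, n_test_conditions = 7L) {
  as.integer(n_analytes) * as.integer(n_cell_types) *
    as.integer(n_time_points) * as.integer(n_test_conditions)
}

#' Size of the stimulus/inhibitor perturbation grid
#'
#' All pairwise combinations of stimuli and inhibitors, both including a
#' zero-concentration ("none") level: 8 x 8 = 64 with the challenge
#' defaults.
#'
#' @param n_stimuli stimuli including "none" (default 8).
#' @param n_inhibitors inhibitors including "none" (default 8).
#' @return Integer number of combinations.
#' @export
stimulus_inhibitor_grid <- function(n_stimuli = 8L, n_inhibitors = 8L) {
  as.integer(n_stimuli) * as.integer(n_inhibitors)
}

#' Measurement error model
#'
#' @param sigma_tech technical noise floor, in fluorescence units
#'   (default 300, the minimum sensitivity of a bead-based detector).
#' @param cv biological coefficient of variation (default 0.8); the
#'   biological standard deviation of cell i is `cv * x_i`.
#' @return Object of class `error_model`.
#' @export
error_model <- function(sigma_tech = 300, cv = 0.8) {
  if (sigma_tech <= 0 || cv <= 0) db_stop("sigma_tech and cv must be positive")
  structure(list(sigma_tech = sigma_tech, cv = cv), class = "error_model")
}

#' Normalized squared error over the withheld cells
#'
#' `sum_i (x_i - p_i)^2 / (sigma_tech^2 + (cv * x_i)^2)`, summed over the
#' masked cells of `obs` only.  The truth `x_i` (not the prediction)
#' parameterizes the biological variance.
#'
#' @param pred [measurement_table()] supplying a value for every masked cell
#'   of `obs` (its own mask is ignored).
#' @param obs [measurement_table()] holding the true values; its `mask`
#'   marks the cells that are scored.
#' @param model an [error_model()].
#' @return Non-negative scalar; additive over disjoint cell sets.
#' @export
normalized_squared_error <- function(pred, obs, model = error_model()) {
  stopifnot(inherits(pred, "measurement_table"),
            inherits(obs, "measurement_table"),
            inherits(model, "error_model"))
  rows <- rownames(obs$values); cols <- colnames(obs$values)
  if (!all(rows %in% rownames(pred$values)) ||
      !all(cols %in% colnames(pred$values))) {
    db_stop("prediction table is missing rows/columns of the observation table")
  }
  pv <- pred$values[rows, cols, drop = FALSE]
  cells <- which(obs$mask, arr.ind = TRUE)
  if (nrow(cells) == 0) return(0)
  p <- pv[cells]
  if (anyNA(p)) {
    missing <- cells[is.na(p), , drop = FALSE]
    db_stop("missing prediction for masked cell(s): %s",
            paste(rows[missing[, 1]], cols[missing[, 2]],
                  sep = "/", collapse = ", "))
  }
  x <- obs$values[cells]
  if (anyNA(x)) db_stop("observation table has no value for a masked cell")
  sum((x - p)^2 / (model$sigma_tech^2 + (model$cv * x)^2))
}

#' Column-resampling null sample of the error metric
#'
#' Repeatedly "fills in" the masked cells of the training table by drawing,
#' with replacement, from the observed values in the same analyte column,
#' and scores each random fill against the truth.
#'
#' @param training [measurement_table()] as given to participants: masked
#'   cells are the prediction targets, unmasked cells are the donor pool.
#' @param truth [measurement_table()] holding true values for the masked
#'   cells (same mask as `training`).
#' @param n_reps number of random fills.
#' @param seed integer seed; the same seed reproduces the same sample.
#' @param model an [error_model()].
#' @return Numeric vector of `n_reps` metric values.
#' @export
resample_null <- function(training, truth, n_reps = 1e5, seed = 1L,
                          model = error_model()) {
  stopifnot(inherits(training, "measurement_table"),
            inherits(truth, "measurement_table"))
  if (n_reps < 1) db_stop("n_reps must be >= 1")
  cells <- which(training$mask, arr.ind = TRUE)
  if (nrow(cells) == 0) db_stop("training table has no masked cells")
  x <- truth$values[rownames(training$values), colnames(training$values),
                    drop = FALSE][cells]
  if (anyNA(x)) db_stop("truth table has no value for a masked cell")
  denom <- model$sigma_tech^2 + (model$cv * x)^2
  pools <- lapply(seq_len(nrow(cells)), function(i) {
    j <- cells[i, 2]
    pool <- training$values[, j][!training$mask[, j]]
    pool <- pool[!is.na(pool)]
    if (length(pool) == 0) {
      db_stop("column '%s' has masked cells but no observed values",
              colnames(training$values)[j])
    }
    pool
  })
  with_seed(seed, {
    total <- numeric(n_reps)
    for (i in seq_along(pools)) {
      pool <- pools[[i]]
      fill <- pool[sample.int(length(pool), n_reps, replace = TRUE)]
      total <- total + (x[i] - fill)^2 / denom[i]
    }
    total
  })
}

#' P-value of an observed error against the resampling null
#'
#' Small error is good, so the p-value is the lower-tail probability of the
#' null at the observed metric.  With `fit_tails = TRUE` the two-sided
#' stretched-exponential density is fitted to the null histogram and the
#' lower tail of the fit is integrated, allowing extrapolation beyond the
#' sample range; otherwise the smoothed empirical fraction
#' `(#{null <= observed} + 1) / (n + 1)` is returned.
#'
#' @param observed_metric observed normalized squared error.
#' @param null_sample numeric vector from [resample_null()].
#' @param fit_tails logical; fit the parametric tail model (requires
#'   `length(null_sample) >= 1000`).
#' @return p-value in (0, 1]; with `fit_tails`, carries the
#'   `below_precision` attribute of [tail_pvalue()].
#' @export
response_pvalue <- function(observed_metric, null_sample, fit_tails = FALSE) {
  if (length(null_sample) < 1) db_stop("empty null sample")
  if (stats::sd(null_sample) == 0) db_stop("degenerate null sample (zero variance)")
  if (is.na(observed_metric)) db_stop("observed metric is NA")
  if (observed_metric == Inf) return(1)
  if (fit_tails) {
    fit <- fit_stretched_exponential(null_sample)
    tail_pvalue(fit, observed_metric, side = "lower")
  } else {
    (sum(null_sample <= observed_metric) + 1) / (length(null_sample) + 1)
  }
}
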