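# Exact scoring of measurement-to-species assignment tables.
#
# A submission assigns each of M measurements to one of S molecular species,
# injectively.  There are S!/(S-M)! possible tables; with S = 7, M = 4 that
# is 840.  A submission is scored by the probability that a uniformly random
# table agrees with the gold standard on at least as many assignments.

#' Exact distribution of correct assignments under a random table
#'
#' Counts, over all injective assignment tables of `n_measurements`
#' measurements into `n_species` species, how many tables agree with a fixed
#' reference table in exactly m positions, for m = 0..M.  By symmetry the
#' counts do not depend on the choice of reference.  Counts are computed in
#' closed form by inclusion-exclusion over forced agreements:
#' `N_m = sum_{j>=m} (-1)^(j-m) C(j,m) C(M,j) (S-j)!/(S-M)!`.
#'
#' @param n_species number of species S (catalog size), `1 <= S <= 12`.
#' @param n_measurements number of measurements M, `M <= S`.
#' @return Object of class `match_distribution`: list with `total_tables`
#'   and `count_by_matches` (named integer vector, names "0".."M").
#' @examples
#' d <- match_distribution(7, 4)
#' d$total_tables        # 840
#' d$count_by_matches    # 465 284 78 12 1
#' @export
match_distribution <- function(n_species, n_measurements) {
  S <- as.integer(n_species); M <- as.integer(n_measurements)
  if (M < 1 || M > S) db_stop("need 1 <= n_measurements <= n_species")
  if (S > 12) db_stop("exact enumeration is limited to n_species <= 12")
  total <- falling_factorial(S, M)
  counts <- vapply(0:M, function(m) {
    j <- m:M
    sum((-1)^(j - m) * choose(j, m) * choose(M, j) *
          vapply(j, function(jj) falling_factorial(S - jj, M - jj), 0))
  }, 0)
  counts <- round(counts)
  stopifnot(sum(counts) == total)
  structure(list(total_tables = total,
                 count_by_matches = stats::setNames(counts, 0:M)),
            class = "match_distribution")
}

#' @export
print.match_distribution <- function(x, ...) {
  cat(sprintf("<match_distribution> %d tables\n", x$total_tables))
  print(x$count_by_matches)
  invisible(x)
}

#' Tail probability of at least m correct assignments
#' @param dist a [match_distribution()].
#' @param m number of correct assignments.
#' @return `P(matches >= m)` under a uniform random table.
#' @export
match_tail_probability <- function(dist, m) {
  stopifnot(inherits(dist, "match_distribution"))
  counts <- dist$count_by_matches
  mm <- as.integer(names(counts))
  sum(counts[mm >= m]) / dist$total_tables
}

#' Score a submitted assignment table against the gold standard
#'
#' @param submitted,gold [assignment_table()] objects over the same
#'   measurement and species catalogs.
#' @return List with `n_correct` and `p`, the probability that a random
#'   table achieves at least as many correct identifications.
#' @examples
#' sp <- letters[1:7]
#' gold <- assignment_table(c(x1 = "a", x2 = "b", x3 = "c", x4 = "d"), sp)
#' sub  <- assignment_table(c(x1 = "a", x2 = "b", x3 = "d", x4 = "e"), sp)
#' score_assignment(sub, gold)  # 2 correct, p = 91/840
#' @export
score_assignment <- function(submitted, gold) {
  stopifnot(inherits(submitted, "assignment_table"),
            inherits(gold, "assignment_table"))
  if (!setequal(submitted$measurements, gold$measurements) ||
      !setequal(submitted$species, gold$species)) {
    db_stop("submitted and gold tables use different catalogs")
  }
  n_correct <- sum(submitted$mapping[gold$measurements] == gold$mapping)
  dist <- match_distribution(length(gold$species), length(gold$measurements))
  list(n_correct = n_correct, p = match_tail_probability(dist, n_correct))
}

#' Probability that a random table agrees on s specified cells
#'
#' The chance that a uniformly random injective table reproduces `n_cells`
#' given (measurement, species) assignments:
#' `q(s) = (S-s)!/(S-M)! / (S!/(S-M)!) = 1 / (S * (S-1) * ... * (S-s+1))`.
#'
#' @inheritParams match_distribution
#' @param n_cells number of specified cells s, `0 <= s <= M`.
#' @return The probability q(s).
#' @export
cell_match_probability <- function(n_species, n_measurements, n_cells) {
  S <- as.integer(n_species); M <- as.integer(n_measurements)
  s <- as.integer(n_cells)
  if (M < 1 || M > S) db_stop("need 1 <= n_measurements <= n_species")
  if (s < 0 || s > M) db_stop("need 0 <= n_cells <= n_measurements")
  falling_factorial(S - s, M - s) / falling_factorial(S, M)
}

#' Binomial p-value for a community-wide concentration of guesses
#'
#' Probability, assuming independent teams each guessing uniformly at
#' random, that at least `n_hits` of `n_teams` teams hit an event of
#' per-team probability `q` (upper binomial tail).
#'
#' @param n_teams number of teams.
#' @param n_hits observed number of teams making the call.
#' @param q per-team probability of the event under the random-table null.
#' @return `P(X >= n_hits)` for `X ~ Binomial(n_teams, q)`.
#' @export
community_pvalue <- function(n_teams, n_hits, q) {
  if (n_hits < 0 || n_hits > n_teams) db_stop("need 0 <= n_hits <= n_teams")
  if (q <= 0 || q >= 1) db_stop("q must lie in (0, 1)")
  if (n_hits == 0) return(1)
  stats::pbinom(n_hits - 1L, n_teams, q, lower.tail = FALSE)
}

#' Overlay of the community's assignment tables
#'
#' Counts, for every (measurement, species) cell, how many teams made that
#' assignment, and attaches a binomial p-value for such a concentration of
#' random guesses in the same cell (using `q = cell_match_probability(s=1)`).
#'
#' @param tables list of [assignment_table()] submissions (shared catalogs).
#' @param gold the gold-standard [assignment_table()].
#' @return List with `votes` (measurement x species integer matrix),
#'   `pvalues` (same shape; NA for cells with zero votes), and `correct`
#'   (logical matrix marking gold cells).
#' @export
community_overlay <- function(tables, gold) {
  if (length(tables) < 1) db_stop("need at least one assignment table")
  stopifnot(inherits(gold, "assignment_table"))
  meas <- gold$measurements; spec <- gold$species
  votes <- matrix(0L, length(meas), length(spec),
                  dimnames = list(measurement = meas, species = spec))
  for (tb in tables) {
    if (!setequal(tb$measurements, meas) || !setequal(tb$species, spec)) {
      db_stop("catalog mismatch between submissions and gold standard")
    }
    for (m in meas) votes[m, tb$mapping[[m]]] <- votes[m, tb$mapping[[m]]] + 1L
  }
  q1 <- cell_match_probability(length(spec), length(meas), 1L)
  pvals <- matrix(NA_real_, length(meas), length(spec),
                  dimnames = dimnames(votes))
  nz <- votes > 0
  pvals[nz] <- vapply(votes[nz], community_pvalue,
                      n_teams = length(tables), q = q1, FUN.VALUE = 0)
  correct <- matrix(FALSE, length(meas), length(spec), dimnames = dimnames(votes))
  for (m in meas) correct[m, gold$mapping[[m]]] <- TRUE
  list(votes = votes, pvalues = pvals, correct = correct)
}
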