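# Domain types and file readers/writers.
#
# Every file the toolkit touches is a plain TSV: tab-separated, UTF-8,
# '#' comment lines ignored, no quoting.  All validation lives here;
# malformed input raises a condition of class "dreambench_validation_error",
# never a silent repair.

# ---------------------------------------------------------------------------
# GoldNetwork -----------------------------------------------------------------

#' Gold-standard directed network
#'
#' A set of nodes plus a set of directed edges.  The candidate universe for
#' scoring is all `N * (N - 1)` ordered non-self pairs over the node set;
#' pairs absent from the edge set are negatives.
#'
#' @param nodes character vector of node ids (unique, case-sensitive).
#' @param edges two-column data frame (source, target) of directed edges.
#' @return An object of class `gold_network` with elements `nodes` and
#'   `edges`, plus helper counts `n_nodes`, `n_positives`, `n_candidates`.
#' @examples
#' g <- gold_network(c("A", "B", "C"), data.frame(source = "A", target = "B"))
#' g$n_candidates # 6 ordered pairs
#' @export
gold_network <- function(nodes, edges) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) db_stop("duplicate node ids")
  edges <- data.frame(
    source = as.character(edges[[1]]),
    target = as.character(edges[[2]]),
    stringsAsFactors = FALSE
  )
  if (nrow(edges) < 1) db_stop("gold network must contain at least one edge")
  if (any(edges$source == edges$target)) db_stop("self-edge in gold network")
  if (length(nodes) < 2) db_stop("a network needs at least two nodes")
  bad <- !(edges$source %in% nodes) | !(edges$target %in% nodes)
  if (any(bad)) {
    db_stop("edge endpoints outside node set: %s",
            paste(edges$source[bad], edges$target[bad], collapse = ", "))
  }
  if (anyDuplicated(paste(edges$source, edges$target, sep = "\r"))) {
    db_stop("duplicate edge in gold network")
  }
  structure(
    list(
      nodes = nodes, edges = edges,
      n_nodes = length(nodes),
      n_positives = nrow(edges),
      n_candidates = length(nodes) * (length(nodes) - 1L)
    ),
    class = "gold_network"
  )
}

#' @export
print.gold_network <- function(x, ...) {
  cat(sprintf("<gold_network> %d nodes, %d edges (%d candidate pairs)\n",
              x$n_nodes, x$n_positives, x$n_candidates))
  invisible(x)
}

#' Read a gold-standard network from an edge-list TSV
#'
#' Format: `source<TAB>target[<TAB>label]`.  A third column of 1/0 labels is
#' accepted: rows labelled 1 are edges, rows labelled 0 are explicit
#' negatives (checked for consistency, then dropped — pairs absent from the
#' file are negatives anyway).
#'
#' @param path file path.
#' @param nodes optional character vector fixing the node universe; defaults
#'   to the union of ids seen in the file.
#' @return A [gold_network()].
#' @export
read_gold_network <- function(path, nodes = NULL) {
  df <- read_tsv_raw(path, header = FALSE)
  if (nrow(df) == 0) db_stop("no edges in %s", path)
  df[[1]] <- as.character(df[[1]])
  if (ncol(df) >= 2) df[[2]] <- as.character(df[[2]])
  if (ncol(df) < 2) db_stop("gold network TSV needs >= 2 columns: %s", path)
  lab <- if (ncol(df) >= 3) suppressWarnings(as.numeric(df[[3]])) else rep(1, nrow(df))
  if (any(is.na(lab)) || !all(lab %in% c(0, 1))) {
    db_stop("gold network labels must be 0/1 in %s", path)
  }
  pos <- df[lab == 1, 1:2]
  neg <- df[lab == 0, 1:2]
  if (nrow(pos) == 0) db_stop("no positive edges in %s", path)
  key <- function(d) paste(d[[1]], d[[2]], sep = "\r")
  if (length(intersect(key(pos), key(neg)))) {
    db_stop("pair listed both as edge and non-edge in %s", path)
  }
  nodes <- nodes %||% sort(unique(c(df[[1]], df[[2]])))
  gold_network(nodes, pos)
}

#' Write a gold network to TSV
#' @param x a [gold_network()].
#' @param path output file.
#' @export
write_gold_network <- function(x, path) {
  stopifnot(inherits(x, "gold_network"))
  df <- data.frame(x$edges$source, x$edges$target, 1L)
  write_tsv_raw(df, path, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# PredictionList --------------------------------------------------------------

#' Ranked edge-list prediction
#'
#' An ordered sequence of candidate directed edges, ranked from most to
#' least confident.  The list order is the authoritative ranking; the
#' optional confidence column is advisory and must be non-increasing.
#'
#' @param source,target character vectors of node ids.
#' @param confidence optional numeric vector in `[0, 1]`, non-increasing.
#' @param universe a [gold_network()], a node count, or a character vector of
#'   node ids, declaring the candidate universe.
#' @return An object of class `prediction_list`: a data frame with columns
#'   `source`, `target` (and `confidence` if supplied), attribute `nodes`.
#' @export
prediction_list <- function(source, target, confidence = NULL, universe = NULL) {
  source <- as.character(source)
  target <- as.character(target)
  if (length(source) != length(target)) db_stop("source/target length mismatch")
  if (length(source) == 0) db_stop("no edges")
  if (any(source == target)) {
    i <- which(source == target)[1]
    db_stop("self-edge at row %d (%s)", i, source[i])
  }
  key <- paste(source, target, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    db_stop("duplicate edge at row %d (%s -> %s)", i, source[i], target[i])
  }
  nodes <- resolve_universe(universe, c(source, target))
  if (!is.null(nodes)) {
    bad <- !(source %in% nodes) | !(target %in% nodes)
    if (any(bad)) {
      i <- which(bad)[1]
      db_stop("edge outside declared universe at row %d (%s -> %s)",
              i, source[i], target[i])
    }
    r_max <- length(nodes) * (length(nodes) - 1L)
    if (length(source) > r_max) {
      db_stop("list has %d rows but the universe only has %d ordered pairs",
              length(source), r_max)
    }
  }
  df <- data.frame(source = source, target = target, stringsAsFactors = FALSE)
  if (!is.null(confidence)) {
    confidence <- as.numeric(confidence)
    if (length(confidence) != length(source)) db_stop("confidence length mismatch")
    if (any(!is.finite(confidence)) || any(confidence < 0 | confidence > 1)) {
      db_stop("confidence values must be finite and in [0, 1]")
    }
    if (any(diff(confidence) > 1e-12)) {
      i <- which(diff(confidence) > 1e-12)[1] + 1L
      db_stop("confidence increases at row %d (%.4g after %.4g)",
              i, confidence[i], confidence[i - 1L])
    }
    df$confidence <- confidence
  }
  structure(df, nodes = nodes,
            class = c("prediction_list", "data.frame"))
}

resolve_universe <- function(universe, seen_ids) {
  if (is.null(universe)) return(sort(unique(seen_ids)))
  if (inherits(universe, "gold_network")) return(universe$nodes)
  if (is.numeric(universe) && length(universe) == 1) {
    n <- as.integer(universe)
    seen <- sort(unique(seen_ids))
    if (length(seen) > n) db_stop("more node ids than declared node count")
    # pad with synthetic ids so the universe really has n nodes
    extra <- setdiff(sprintf("G%d", seq_len(n)), seen)
    return(c(seen, extra[seq_len(n - length(seen))]))
  }
  as.character(universe)
}

#' @export
print.prediction_list <- function(x, ...) {
  cat(sprintf("<prediction_list> %d ranked edges over %d nodes\n",
              nrow(x), length(attr(x, "nodes"))))
  utils::head(as.data.frame(x))
  invisible(x)
}

#' Read a ranked edge-list prediction
#'
#' Format: `source<TAB>target[<TAB>confidence]`, ranked from most to least
#' confident.  Rows are never reordered: rank equals line order, even when
#' confidences tie.
#'
#' @param path file path.
#' @inheritParams prediction_list
#' @return A [prediction_list()].
#' @export
read_prediction_list <- function(path, universe = NULL) {
  df <- read_tsv_raw(path, header = FALSE)
  if (nrow(df) == 0) db_stop("no edges in %s", path)
  if (ncol(df) < 2 || ncol(df) > 3) {
    db_stop("prediction TSV must have 2 or 3 columns: %s", path)
  }
  conf <- if (ncol(df) == 3) df[[3]] else NULL
  prediction_list(df[[1]], df[[2]], conf, universe = universe)
}

#' Write a ranked edge list to TSV
#' @param x a [prediction_list()].
#' @param path output file.
#' @export
write_prediction_list <- function(x, path) {
  stopifnot(inherits(x, "prediction_list"))
  write_tsv_raw(as.data.frame(x), path, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# MeasurementTable -------------------------------------------------------------

#' Condition-by-analyte measurement table
#'
#' Non-negative fluorescence values (arbitrary units) for a grid of
#' experimental conditions (rows) and analytes (columns), with a logical
#' mask marking cells that are withheld prediction targets.
#'
#' @param values numeric matrix, conditions x analytes, with unique dimnames.
#'   `NA` entries are taken as masked.
#' @param mask optional logical matrix of the same shape; defaults to
#'   `is.na(values)`.
#' @param conditions optional data frame of condition descriptors (one row
#'   per table row).
#' @return Object of class `measurement_table` with elements `values`,
#'   `mask`, `conditions`.
#' @export
measurement_table <- function(values, mask = NULL, conditions = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) rownames(values) <- sprintf("r%d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("c%d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) db_stop("duplicate row labels")
  if (anyDuplicated(colnames(values))) db_stop("duplicate column labels")
  if (is.null(mask)) mask <- is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values))) db_stop("mask shape mismatch")
  if (any(values[!mask] < 0, na.rm = TRUE)) {
    db_stop("negative measurement value (fluorescence must be >= 0)")
  }
  if (any(is.na(values[!mask]))) db_stop("NA value in an unmasked cell")
  dimnames(mask) <- dimnames(values)
  structure(list(values = values, mask = mask, conditions = conditions),
            class = "measurement_table")
}

#' @export
print.measurement_table <- function(x, ...) {
  cat(sprintf("<measurement_table> %d conditions x %d analytes, %d masked cells\n",
              nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

#' Read a measurement table from TSV
#'
#' The header names the analytes; any maximal run of leading non-numeric
#' columns is kept as condition descriptors.  Cells spelled `NA`, `NaN` or
#' left empty become masked prediction targets.
#'
#' @param path file path.
#' @return A [measurement_table()].
#' @export
read_measurement_table <- function(path) {
  df <- read_tsv_raw(path, header = TRUE)
  if (nrow(df) == 0) db_stop("empty measurement table: %s", path)
  is_num <- vapply(df, function(col) {
    is.numeric(col) || all(is.na(col))
  }, logical(1))
  n_desc <- if (any(is_num)) which(is_num)[1] - 1L else ncol(df)
  if (n_desc >= ncol(df)) db_stop("no numeric analyte columns in %s", path)
  vals <- as.matrix(df[, (n_desc + 1L):ncol(df), drop = FALSE])
  if (!is.numeric(vals)) db_stop("non-numeric cell in analyte columns of %s", path)
  conditions <- if (n_desc > 0) df[, seq_len(n_desc), drop = FALSE] else NULL
  rn <- if (n_desc > 0) {
    apply(df[, seq_len(n_desc), drop = FALSE], 1, paste, collapse = "|")
  } else sprintf("r%d", seq_len(nrow(df)))
  if (anyDuplicated(rn)) db_stop("duplicate condition rows in %s", path)
  rownames(vals) <- rn
  measurement_table(vals, conditions = conditions)
}

#' Write a measurement table to TSV (masked cells written as NA)
#' @param x a [measurement_table()].
#' @param path output file.
#' @export
write_measurement_table <- function(x, path) {
  stopifnot(inherits(x, "measurement_table"))
  vals <- x$values
  vals[x$mask] <- NA
  df <- if (!is.null(x$conditions)) {
    cbind(x$conditions, as.data.frame(vals, check.names = FALSE))
  } else {
    cbind(data.frame(condition = rownames(vals)),
          as.data.frame(vals, check.names = FALSE))
  }
  write_tsv_raw(df, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# RankMatrix ------------------------------------------------------------------

#' Gene-by-time rank matrix
#'
#' Integer ranks with every column a permutation of `1..G`; rank 1 is the
#' most induced gene, rank `G` the most repressed.
#'
#' @param values integer matrix, genes x time points.
#' @return Object of class `rank_matrix` (an integer matrix).
#' @export
rank_matrix <- function(values) {
  values <- as.matrix(values)
  if (any(values != round(values), na.rm = TRUE) || anyNA(values)) {
    db_stop("rank matrix must be all integer")
  }
  storage.mode(values) <- "integer"
  g <- nrow(values)
  for (j in seq_len(ncol(values))) {
    if (!identical(sort(unname(values[, j])), seq_len(g))) {
      db_stop("column %s is not a permutation of 1..%d",
              colnames(values)[j] %||% as.character(j), g)
    }
  }
  if (is.null(rownames(values))) rownames(values) <- sprintf("g%d", seq_len(g))
  if (is.null(colnames(values))) colnames(values) <- sprintf("t%d", seq_len(ncol(values)))
  structure(values, class = c("rank_matrix", "matrix", "array"))
}

#' Read a rank matrix from TSV
#'
#' Expects a header of time-point labels; a first non-numeric column is used
#' as gene ids.
#'
#' @param path file path.
#' @return A [rank_matrix()].
#' @export
read_rank_matrix <- function(path) {
  df <- read_tsv_raw(path, header = TRUE)
  if (nrow(df) == 0) db_stop("empty rank matrix: %s", path)
  rn <- NULL
  if (!is.numeric(df[[1]])) {
    rn <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) db_stop("non-numeric cell in rank matrix %s", path)
  if (!is.null(rn)) rownames(m) <- rn
  rank_matrix(m)
}

#' Write a rank matrix to TSV
#' @param x a [rank_matrix()].
#' @param path output file.
#' @export
write_rank_matrix <- function(x, path) {
  stopifnot(inherits(x, "rank_matrix"))
  df <- cbind(data.frame(gene = rownames(x)),
              as.data.frame(unclass(x), check.names = FALSE))
  write_tsv_raw(df, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# AssignmentTable -------------------------------------------------------------

#' Measurement-to-species assignment table
#'
#' An injective mapping from measurements to molecular species: each
#' measurement is assigned exactly one species and no species is assigned
#' twice.
#'
#' @param mapping named character vector, `names = measurement ids`,
#'   `values = species ids`.
#' @param species full species catalog (superset of assigned species).
#' @param measurements full measurement catalog; defaults to `names(mapping)`.
#' @return Object of class `assignment_table`.
#' @export
assignment_table <- function(mapping, species, measurements = NULL) {
  mapping <- stats::setNames(as.character(mapping), names(mapping))
  measurements <- measurements %||% names(mapping)
  species <- as.character(species)
  if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    db_stop("mapping must be a named vector (measurement -> species)")
  }
  if (anyDuplicated(names(mapping))) db_stop("measurement assigned twice")
  if (anyDuplicated(mapping)) db_stop("species assigned twice (mapping must be injective)")
  if (!setequal(names(mapping), measurements)) {
    db_stop("every measurement must be assigned exactly once")
  }
  if (!all(mapping %in% species)) db_stop("assigned species missing from catalog")
  if (length(measurements) > length(species)) {
    db_stop("more measurements than species")
  }
  structure(list(mapping = mapping[measurements],
                 measurements = measurements, species = species),
            class = "assignment_table")
}

#' Read an assignment table (`measurement<TAB>species`)
#' @param path file path.
#' @param species optional species catalog; defaults to the species seen.
#' @return An [assignment_table()].
#' @export
read_assignment_table <- function(path, species = NULL) {
  df <- read_tsv_raw(path, header = FALSE,
                     colClasses = c("character", "character"))
  if (nrow(df) == 0) db_stop("empty assignment table: %s", path)
  if (ncol(df) != 2) db_stop("assignment TSV must have 2 columns: %s", path)
  mapping <- stats::setNames(df[[2]], df[[1]])
  assignment_table(mapping, species = species %||% sort(unique(df[[2]])))
}

#' Write an assignment table to TSV
#' @param x an [assignment_table()].
#' @param path output file.
#' @export
write_assignment_table <- function(x, path) {
  stopifnot(inherits(x, "assignment_table"))
  write_tsv_raw(data.frame(names(x$mapping), unname(x$mapping)),
                path, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# StrainExpressionMatrix -------------------------------------------------------

#' Gene-by-strain steady-state expression with time courses
#'
#' Steady-state expression of `G` genes in the wild type plus one knockdown
#' and one knockout strain per gene, and optional wild-type trajectories
#' from random initial states.
#'
#' @param genes character vector of gene ids.
#' @param wildtype numeric vector of wild-type steady states, named by gene.
#' @param knockouts numeric `G x G` matrix: entry `[b, a]` is the expression
#'   of gene `b` in the strain where gene `a` was knocked out.
#' @param knockdowns like `knockouts`, for heterozygous knockdown strains
#'   (may be `NULL`).
#' @param trajectories list of trajectories, each a list with elements
#'   `time` (increasing numeric) and `values` (time x gene matrix).
#' @return Object of class `strain_expression`.
#' @export
strain_expression <- function(genes, wildtype, knockouts, knockdowns = NULL,
                              trajectories = list()) {
  genes <- as.character(genes)
  g <- length(genes)
  if (anyDuplicated(genes)) db_stop("duplicate gene ids")
  wildtype <- as.numeric(wildtype[genes])
  names(wildtype) <- genes
  check_mat <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!identical(dim(m), c(g, g))) db_stop("%s matrix must be %d x %d", what, g, g)
    if (any(!is.finite(m))) db_stop("non-finite value in %s matrix", what)
    dimnames(m) <- list(gene = genes, deleted = genes)
    m
  }
  if (any(!is.finite(wildtype))) db_stop("non-finite wild-type value")
  knockouts <- check_mat(knockouts, "knockout")
  if (is.null(knockouts)) db_stop("missing knockout data (one strain per gene required)")
  knockdowns <- check_mat(knockdowns, "knockdown")
  for (tr in trajectories) {
    if (!is.list(tr) || is.null(tr$time) || is.null(tr$values)) {
      db_stop("each trajectory needs elements 'time' and 'values'")
    }
    if (any(diff(tr$time) <= 0)) db_stop("trajectory time grid must increase")
    if (ncol(tr$values) != g || nrow(tr$values) != length(tr$time)) {
      db_stop("trajectory values must be (time x gene)")
    }
  }
  structure(list(genes = genes, wildtype = wildtype, knockouts = knockouts,
                 knockdowns = knockdowns, trajectories = trajectories),
            class = "strain_expression")
}

#' @export
print.strain_expression <- function(x, ...) {
  cat(sprintf(
    "<strain_expression> %d genes; WT + %d KO%s strains; %d trajectories\n",
    length(x$genes), ncol(x$knockouts),
    if (!is.null(x$knockdowns)) sprintf(" + %d KD", ncol(x$knockdowns)) else "",
    length(x$trajectories)))
  invisible(x)
}

#' Read a strain-expression bundle written by [write_challenge_bundle()]
#'
#' @param dir directory containing `wildtype.tsv`, `knockouts.tsv`, optional
#'   `knockdowns.tsv` and a `trajectories/` subdirectory.
#' @return A [strain_expression()].
#' @export
read_strain_expression <- function(dir) {
  rd <- function(f) read_tsv_raw(file.path(dir, f), header = TRUE)
  wt_df <- rd("wildtype.tsv")
  genes <- colnames(wt_df)
  wildtype <- stats::setNames(as.numeric(wt_df[1, ]), genes)
  read_strain_mat <- function(f) {
    df <- rd(f)
    if (colnames(df)[1] != "strain") db_stop("%s must start with a 'strain' column", f)
    deleted <- sub("^(KO|KD)_", "", df[[1]])
    m <- t(as.matrix(df[, -1, drop = FALSE]))  # gene x strain
    colnames(m) <- deleted
    m[genes, genes, drop = FALSE]
  }
  knockouts <- read_strain_mat("knockouts.tsv")
  knockdowns <- if (file.exists(file.path(dir, "knockdowns.tsv"))) {
    read_strain_mat("knockdowns.tsv")
  }
  traj_dir <- file.path(dir, "trajectories")
  trajectories <- list()
  if (dir.exists(traj_dir)) {
    for (f in sort(list.files(traj_dir, pattern = "\\.tsv$", full.names = TRUE))) {
      df <- read_tsv_raw(f, header = TRUE)
      trajectories[[length(trajectories) + 1L]] <-
        list(time = df$time, values = as.matrix(df[, genes, drop = FALSE]))
    }
  }
  strain_expression(genes, wildtype, knockouts, knockdowns, trajectories)
}

# ---------------------------------------------------------------------------
# ScoreReport -----------------------------------------------------------------

#' Challenge score report
#'
#' Per-item metrics and p-values, summary p-values, and the overall score
#' `-log10(geometric mean of the summary p-values)`.  One unit of score is
#' one order of magnitude of significance.
#'
#' @param metrics named list/vector of per-item metric values.
#' @param pvalues named list/vector of per-item p-values, each in `(0, 1]`.
#' @param summary_pvalues named numeric vector of summary p-values.
#' @param extra optional list of additional payload carried along.
#' @return Object of class `score_report` with an `overall_score` element.
#' @export
score_report <- function(metrics, pvalues, summary_pvalues, extra = list()) {
  sp <- unlist(summary_pvalues)
  if (any(sp <= 0 | sp > 1)) db_stop("summary p-values must lie in (0, 1]")
  structure(list(
    metrics = metrics, pvalues = pvalues,
    summary_pvalues = sp,
    overall_score = -log10(geometric_mean(sp)),
    extra = extra
  ), class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("<score_report>\n  summary p-values:",
      paste(sprintf("%s=%.3g", names(x$summary_pvalues), x$summary_pvalues),
            collapse = ", "),
      sprintf("\n  overall score: %.2f\n", x$overall_score))
  invisible(x)
}
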