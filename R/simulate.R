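# In-silico gene-network simulator for challenge fixtures.
#
# Deliberately simplified dynamics (additive saturating activation /
# repression with linear decay) stand in for the thermodynamic generative
# model used to build the original challenge data; the simulator's job is
# to produce fixtures with the challenge's strain conventions:
#   * acyclic directed networks with a minority of regulator nodes,
#   * wild-type steady state,
#   * knockdown strains  = gene clamped to half its wild-type level,
#   * knockout strains   = gene clamped to zero,
#   * wild-type trajectories from random initial states,
#   * independent additive Gaussian noise on every reported value.
# Steady states on a DAG are solved exactly in topological order, so the
# residual max|dx/dt| at a reported equilibrium is at machine precision.

#' Simulation configuration
#'
#' @param n_nodes number of genes.
#' @param n_edges number of directed edges (must fit an acyclic graph whose
#'   sources are the regulator nodes).
#' @param n_regulators number of regulator nodes (default: 26% of nodes,
#'   matching the edge-sparse presets).
#' @param n_trajectories number of wild-type time courses.
#' @param time_grid increasing time grid for trajectories.
#' @param noise_sd additive Gaussian noise sd, in expression units
#'   (default 0.05, about 5% of the typical dynamic range of 1).
#' @param knockdown_factor fraction of wild-type level a heterozygous
#'   knockdown retains (default 0.5).
#' @param seed integer seed controlling network, parameters, initial states
#'   and noise.
#' @param decay linear decay rate of every gene.
#' @param hill_k,hill_n activation threshold and steepness of the
#'   saturating regulation function.
#' @param weight_range range of interaction strengths (uniform draw).
#' @param activation_prob probability that an edge is activating
#'   (remainder are repressing).
#' @param basal basal production of regulated genes; unregulated genes
#'   produce at rate 1.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_nodes = 10L, n_edges = 11L, n_regulators = NULL,
                       n_trajectories = 4L,
                       time_grid = seq(0, 10, by = 0.5),
                       noise_sd = 0.05, knockdown_factor = 0.5, seed = 1L,
                       decay = 1, hill_k = 0.5, hill_n = 2,
                       weight_range = c(0.5, 1.5), activation_prob = 0.8,
                       basal = 0.1) {
  n_regulators <- as.integer(n_regulators %||% max(1L, ceiling(0.26 * n_nodes)))
  if (noise_sd < 0) db_stop("noise_sd must be >= 0")
  if (any(diff(time_grid) <= 0)) db_stop("time_grid must increase")
  if (n_regulators >= n_nodes) db_stop("regulators must be a strict subset of nodes")
  max_edges <- sum(n_nodes - seq_len(n_regulators))
  if (n_edges < 1 || n_edges > max_edges) {
    db_stop("n_edges must lie in 1..%d for %d regulators over %d nodes",
            max_edges, n_regulators, n_nodes)
  }
  structure(list(
    n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
    n_regulators = n_regulators, n_trajectories = as.integer(n_trajectories),
    time_grid = time_grid, noise_sd = noise_sd,
    knockdown_factor = knockdown_factor, seed = as.integer(seed),
    decay = decay, hill_k = hill_k, hill_n = hill_n,
    weight_range = weight_range, activation_prob = activation_prob,
    basal = basal
  ), class = "sim_config")
}

#' Preset configurations mirroring the challenge subchallenge shapes
#'
#' `size10`, `size50` and `size100` reproduce the node counts, the
#' edge-sparse network shape (Ecoli1 rows: 11/62/125 edges, 5/13/26
#' regulators) and the 4/23/46 trajectory counts of the three subchallenges.
#'
#' @param preset one of `"size10"`, `"size50"`, `"size100"`.
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(preset = c("size10", "size50", "size100"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    size10 = list(n_nodes = 10L, n_edges = 11L, n_regulators = 5L,
                  n_trajectories = 4L),
    size50 = list(n_nodes = 50L, n_edges = 62L, n_regulators = 13L,
                  n_trajectories = 23L),
    size100 = list(n_nodes = 100L, n_edges = 125L, n_regulators = 26L,
                   n_trajectories = 46L)
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' Generate a seeded random acyclic gene network
#'
#' Nodes are assigned a random topological order; the `n_regulators` nodes
#' earliest in that order are the potential sources, and `n_edges` forward
#' pairs are sampled with gamma-distributed per-regulator propensities so
#' that out-degree is heterogeneous.  The construction is cycle-free by
#' topological order.
#'
#' @param config a [sim_config()].
#' @return A [gold_network()] with attribute `"topo_order"`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_nodes
  nodes <- sprintf("G%d", seq_len(n))
  with_seed(config$seed, {
    topo <- sample(nodes)  # topo[1] is most upstream
    regs <- topo[seq_len(config$n_regulators)]
    cand_src <- character(0); cand_tgt <- character(0)
    for (i in seq_len(config$n_regulators)) {
      downstream <- topo[(i + 1L):n]
      cand_src <- c(cand_src, rep(topo[i], length(downstream)))
      cand_tgt <- c(cand_tgt, downstream)
    }
    propensity <- stats::setNames(stats::rgamma(length(regs), shape = 1.5), regs)
    w <- propensity[cand_src]
    pick <- sample.int(length(cand_src), config$n_edges, prob = w)
    edges <- data.frame(source = cand_src[pick], target = cand_tgt[pick],
                        stringsAsFactors = FALSE)
    g <- gold_network(nodes, edges)
    attr(g, "topo_order") <- topo
    g
  })
}

# Regulation function: saturating Hill activation / repression.
hill_term <- function(x, sign, k, h) {
  a <- x^h / (k^h + x^h)
  ifelse(sign > 0, a, 1 - a)
}

# Build the parameterized dynamical system for a network (seeded draws).
build_system <- function(network, config) {
  edges <- network$edges
  n_e <- nrow(edges)
  signs <- ifelse(stats::runif(n_e) < config$activation_prob, 1, -1)
  weights <- stats::runif(n_e, config$weight_range[1], config$weight_range[2])
  regulated <- unique(edges$target)
  basal_vec <- stats::setNames(rep(1, length(network$nodes)), network$nodes)
  basal_vec[regulated] <- config$basal
  list(nodes = network$nodes, edges = edges, signs = signs, weights = weights,
       basal_vec = basal_vec, decay = config$decay,
       hill_k = config$hill_k, hill_n = config$hill_n,
       topo = attr(network, "topo_order") %||% topo_sort_nodes(network))
}

topo_sort_nodes <- function(network) {
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = network$nodes)
  ord <- tryCatch(igraph::topo_sort(g, mode = "out"),
                  error = function(e) db_stop("network is not acyclic"))
  names(ord)
}

# Steady state with an optional clamped gene, solved exactly in topological
# order (valid because the graph is a DAG).
steady_state <- function(sys, clamp_gene = NULL, clamp_value = 0) {
  x <- stats::setNames(numeric(length(sys$nodes)), sys$nodes)
  for (gname in sys$topo) {
    if (!is.null(clamp_gene) && gname == clamp_gene) {
      x[gname] <- clamp_value
      next
    }
    sel <- sys$edges$target == gname
    m <- sys$basal_vec[[gname]]
    if (any(sel)) {
      m <- m + sum(sys$weights[sel] *
                     hill_term(x[sys$edges$source[sel]], sys$signs[sel],
                               sys$hill_k, sys$hill_n))
    }
    x[gname] <- m / sys$decay
  }
  x
}

# Max |dx/dt| at state x (diagnostic; clamped genes contribute 0).
steady_state_residual <- function(sys, x, clamp_gene = NULL) {
  dx <- vapply(sys$nodes, function(gname) {
    sel <- sys$edges$target == gname
    m <- sys$basal_vec[[gname]]
    if (any(sel)) {
      m <- m + sum(sys$weights[sel] *
                     hill_term(x[sys$edges$source[sel]], sys$signs[sel],
                               sys$hill_k, sys$hill_n))
    }
    m - sys$decay * x[[gname]]
  }, 0)
  if (!is.null(clamp_gene)) dx[clamp_gene] <- 0
  max(abs(dx))
}

# RK4 integration of the wild-type system over a time grid.
integrate_trajectory <- function(sys, x0, time_grid, n_substeps = 4L) {
  deriv <- function(x) {
    dx <- numeric(length(x)); names(dx) <- names(x)
    for (gname in sys$nodes) {
      sel <- sys$edges$target == gname
      m <- sys$basal_vec[[gname]]
      if (any(sel)) {
        m <- m + sum(sys$weights[sel] *
                       hill_term(x[sys$edges$source[sel]], sys$signs[sel],
                                 sys$hill_k, sys$hill_n))
      }
      dx[gname] <- m - sys$decay * x[[gname]]
    }
    dx
  }
  out <- matrix(0, length(time_grid), length(sys$nodes),
                dimnames = list(NULL, sys$nodes))
  x <- x0
  out[1, ] <- x
  for (i in seq_along(time_grid)[-1]) {
    h_total <- time_grid[i] - time_grid[i - 1]
    h <- h_total / n_substeps
    for (s in seq_len(n_substeps)) {
      k1 <- deriv(x)
      k2 <- deriv(pmax(x + h / 2 * k1, 0))
      k3 <- deriv(pmax(x + h / 2 * k2, 0))
      k4 <- deriv(pmax(x + h * k3, 0))
      x <- pmax(x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    }
    out[i, ] <- x
  }
  out
}

#' Simulate a full strain panel from a network
#'
#' Wild-type steady state; per-gene knockout strains (gene clamped to zero,
#' system re-equilibrated); per-gene knockdown strains (gene clamped to
#' `knockdown_factor` times its wild-type level); `n_trajectories` wild-type
#' time courses from random initial states.  Independent Gaussian noise of
#' sd `noise_sd` is added to every reported value.
#'
#' @param network a [gold_network()] from [generate_network()].
#' @param config the [sim_config()] used to generate it.
#' @return A [strain_expression()].
#' @export
simulate_dataset <- function(network, config) {
  stopifnot(inherits(network, "gold_network"), inherits(config, "sim_config"))
  genes <- network$nodes
  g <- length(genes)
  with_seed(config$seed + 1L, {
    sys <- build_system(network, config)
    wt <- steady_state(sys)
    if (steady_state_residual(sys, wt) > 1e-8) {
      db_stop("steady-state residual above 1e-8 (max |dx/dt| = %.3g)",
              steady_state_residual(sys, wt))
    }
    ko <- kd <- matrix(0, g, g, dimnames = list(gene = genes, deleted = genes))
    for (a in genes) {
      ko[, a] <- steady_state(sys, clamp_gene = a, clamp_value = 0)
      kd[, a] <- steady_state(sys, clamp_gene = a,
                              clamp_value = config$knockdown_factor * wt[[a]])
    }
    trajectories <- lapply(seq_len(config$n_trajectories), function(i) {
      x0 <- stats::runif(g, 0, 2 * pmax(wt, 0.25))
      names(x0) <- genes
      list(time = config$time_grid,
           values = integrate_trajectory(sys, x0, config$time_grid))
    })
    if (config$noise_sd > 0) {
      addn <- function(v) v + stats::rnorm(length(v), 0, config$noise_sd)
      wt <- addn(wt)
      ko[] <- addn(as.numeric(ko))
      kd[] <- addn(as.numeric(kd))
      trajectories <- lapply(trajectories, function(tr) {
        tr$values[] <- addn(as.numeric(tr$values))
        tr
      })
    }
    strain_expression(genes, wt, ko, kd, trajectories)
  })
}

#' Write a simulated dataset as a challenge file bundle
#'
#' Emits `wildtype.tsv`, `knockouts.tsv`, `knockdowns.tsv`,
#' `trajectories/trajectory_XX.tsv` and `gold_standard.tsv` in the
#' toolkit's TSV dialect.  Deterministic bytes for fixed inputs.
#'
#' @param data a [strain_expression()].
#' @param network the generating [gold_network()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_challenge_bundle <- function(data, network, out_dir) {
  stopifnot(inherits(data, "strain_expression"),
            inherits(network, "gold_network"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "trajectories"), showWarnings = FALSE)
  genes <- data$genes
  wt <- as.data.frame(as.list(data$wildtype), check.names = FALSE)
  write_tsv_raw(wt, file.path(out_dir, "wildtype.tsv"))
  strain_df <- function(m, prefix) {
    df <- as.data.frame(t(m), check.names = FALSE)  # strain x gene
    cbind(data.frame(strain = paste0(prefix, "_", colnames(m))), df)
  }
  write_tsv_raw(strain_df(data$knockouts, "KO"),
                file.path(out_dir, "knockouts.tsv"))
  if (!is.null(data$knockdowns)) {
    write_tsv_raw(strain_df(data$knockdowns, "KD"),
                  file.path(out_dir, "knockdowns.tsv"))
  }
  for (i in seq_along(data$trajectories)) {
    tr <- data$trajectories[[i]]
    df <- cbind(data.frame(time = tr$time),
                as.data.frame(tr$values, check.names = FALSE))
    write_tsv_raw(df, file.path(out_dir, "trajectories",
                                sprintf("trajectory_%02d.tsv", i)))
  }
  write_gold_network(network, file.path(out_dir, "gold_standard.tsv"))
  invisible(out_dir)
}
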