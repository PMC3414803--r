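# Markov clustering of the similarity graph, ICCC model selection, and
# size-ranked family numbering.

#' Numerical controls for the MCL iteration
#'
#' @param self_loop `"max_incident"` (default: each node's self-loop weight
#'   is its maximum incident edge weight, 1 for isolated nodes) or `"unit"`.
#' @param prune_threshold Entries below this are zeroed after each inflation
#'   step, followed by column renormalisation.
#' @param convergence_tol Iteration stops when the largest entry change
#'   between successive iterates falls below this.
#' @param max_iterations Hard cap on expansion/inflation rounds.
#' @export
mcl_options <- function(self_loop = c("max_incident", "unit"),
                        prune_threshold = 1e-5, convergence_tol = 1e-8,
                        max_iterations = 200L) {
  self_loop <- match.arg(self_loop)
  if (prune_threshold <= 0 || convergence_tol <= 0) {
    abort("thresholds must be positive")
  }
  if (max_iterations < 1) abort("max_iterations must be >= 1")
  list(self_loop = self_loop, prune_threshold = prune_threshold,
       convergence_tol = convergence_tol,
       max_iterations = as.integer(max_iterations))
}

#' Inflation-factor grid
#'
#' The default grid runs from 1.2 to 8.0 in steps of 0.2 (35 points).
#'
#' @param if_min,if_max,if_step Grid limits and step.
#' @return Numeric vector of inflation values, generated inclusively.
#' @export
sweep_grid <- function(if_min = 1.2, if_max = 8.0, if_step = 0.2) {
  if (if_min <= 1.0) abort("inflation must exceed 1.0")
  k <- round((if_max - if_min) / if_step)
  if_min + if_step * (0:k)
}

# Column-stochastic start matrix: weights plus self-loops, columns normalised.
mcl_start_matrix <- function(graph, opts) {
  m <- graph_matrix(graph)
  n <- nrow(m)
  if (n == 0) abort("graph is empty")
  loop <- if (opts$self_loop == "max_incident") {
    apply(m, 2, function(col) max(col, 1e-300))
  } else {
    rep(1, n)
  }
  loop[loop < 1] <- 1  # isolated nodes (and weights < 1) get a unit loop
  diag(m) <- loop
  sweep(m, 2, colSums(m), "/")
}

normalise_columns <- function(m) {
  cs <- colSums(m)
  dead <- cs <= 0
  if (any(dead)) {      # a fully pruned column restarts at its self-loop
    m[cbind(which(dead), which(dead))] <- 1
    cs[dead] <- 1
  }
  sweep(m, 2, cs, "/")
}

#' Markov clustering of a similarity graph
#'
#' Alternates expansion (matrix squaring) and inflation (entrywise power
#' followed by column renormalisation) on the column-stochastic matrix built
#' from the graph, pruning small entries, until the iterate stabilises.
#' Clusters are read from the limit matrix: attractors (positive diagonal)
#' are grouped into attractor systems, and every node joins the system
#' holding most of its column mass (ties go to the system with the
#' lowest-indexed attractor).
#'
#' @param graph A [build_graph()] result.
#' @param inflation Inflation factor (> 1); larger values give finer
#'   clusters.
#' @param opts [mcl_options()].
#' @return A `famint_partition` (see [rank_families()]) with families
#'   numbered by decreasing size; `converged` records whether the iteration
#'   stabilised within `max_iterations` (a warning is raised otherwise).
#' @export
mcl <- function(graph, inflation, opts = mcl_options()) {
  if (inflation <= 1.0) abort("inflation must exceed 1.0")
  m <- mcl_start_matrix(graph, opts)
  converged <- FALSE
  iterations <- 0L
  col_sum_dev <- max(abs(colSums(m) - 1))
  for (it in seq_len(opts$max_iterations)) {
    iterations <- it
    m2 <- m %*% m
    m2 <- normalise_columns(m2^inflation)
    # prune on the stochastic scale, then renormalise
    m2[m2 < opts$prune_threshold] <- 0
    m2 <- normalise_columns(m2)
    col_sum_dev <- max(col_sum_dev, abs(colSums(m2) - 1))
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < opts$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("MCL did not converge in %d iterations (inflation %.2f)",
                 opts$max_iterations, inflation))
  }
  clusters <- mcl_interpret(m, graph$nodes)
  out <- rank_families(clusters, inflation = inflation,
                       converged = converged, iterations = iterations)
  out$col_sum_dev <- col_sum_dev  # worst column-stochasticity deviation seen
  out
}

# Read clusters from the (near-)limit matrix.  m[i, j] is the mass node j
# sends to node i.
mcl_interpret <- function(m, nodes) {
  n <- length(nodes)
  eps <- 1e-9
  attractors <- which(diag(m) > eps)
  if (length(attractors) == 0) attractors <- seq_len(n)  # degenerate fallback
  # Attractor systems: attractors connected by positive limit mass.
  sys_id <- seq_along(attractors)
  find <- function(x) { while (sys_id[x] != x) x <- sys_id[x]; x }
  if (length(attractors) > 1) {
    for (ai in seq_along(attractors)) {
      for (bi in seq_along(attractors)) {
        if (ai < bi) {
          a <- attractors[ai]; b <- attractors[bi]
          if (m[a, b] > eps || m[b, a] > eps) {
            ra <- find(ai); rb <- find(bi)
            if (ra != rb) sys_id[max(ra, rb)] <- min(ra, rb)
          }
        }
      }
    }
  }
  roots <- vapply(seq_along(attractors), find, integer(1))
  systems <- split(attractors, roots)
  # Assign every node to the system receiving most of its column mass.
  assign <- integer(n)
  for (j in seq_len(n)) {
    mass <- vapply(systems, function(s) sum(m[s, j]), numeric(1))
    if (max(mass) <= eps) {
      assign[j] <- NA_integer_
    } else {
      best <- which(mass == max(mass))
      assign[j] <- best[1]  # split() orders by root, i.e. lowest attractor
    }
  }
  clusters <- lapply(split(seq_len(n), assign), function(ix) nodes[ix])
  orphans <- which(is.na(assign))
  c(unname(clusters), lapply(orphans, function(i) nodes[i]))
}

#' Number clusters as size-ranked families
#'
#' Families are sorted by decreasing size, ties broken by the
#' lexicographically smallest member id, and numbered from 0 (so family 0 is
#' always the largest).
#'
#' @param clusters List of character vectors partitioning the node set.
#' @param inflation,converged,iterations Metadata recorded on the result.
#' @return An object of class `famint_partition`: list with `assignment`
#'   (tibble `protein_id`, `famint`), `family_sizes`, `inflation`, `iccc`
#'   (NA until [iccc()] is attached), `converged`.
#' @export
rank_families <- function(clusters, inflation = NA_real_, converged = TRUE,
                          iterations = NA_integer_) {
  sizes <- lengths(clusters)
  smallest <- vapply(clusters, function(x) sort(x)[1], character(1))
  ord <- order(-sizes, smallest)
  clusters <- clusters[ord]
  assignment <- tibble(
    protein_id = unlist(clusters, use.names = FALSE),
    famint = rep(seq_along(clusters) - 1L, lengths(clusters)))
  structure(list(assignment = assignment,
                 family_sizes = unname(lengths(clusters)),
                 inflation = inflation, iccc = NA_real_,
                 converged = converged, iterations = iterations),
            class = "famint_partition")
}

#' @export
print.famint_partition <- function(x, ...) {
  cat("<famint_partition> ", nrow(x$assignment), " proteins in ",
      length(x$family_sizes), " families (largest ",
      max(x$family_sizes), "); inflation=", format(x$inflation),
      " iccc=", format(x$iccc), "\n", sep = "")
  invisible(x)
}

# Members of each family, as a named list of id vectors.
partition_members <- function(partition) {
  split(partition$assignment$protein_id, partition$assignment$famint)
}

#' Intra-cluster clustering coefficient of a partition
#'
#' Intra-cluster edges are binarised (an edge either is or is not in the
#' similarity graph).  For every node of a cluster with at least 3 members,
#' the local clustering coefficient is the fraction of its intra-cluster
#' neighbour pairs that are themselves connected (nodes with intra-cluster
#' degree < 2 contribute 0).  The ICCC is the mean over all such nodes;
#' clusters of size < 3 are excluded, and the result is 0 when none qualify.
#'
#' @param partition A `famint_partition` covering the graph nodes.
#' @param graph The [build_graph()] similarity graph.
#' @param variant `"unweighted"` (default, the formula above) or
#'   `"density"`: the size-weighted mean intra-cluster edge density.
#' @return A value in \[0, 1\].
#' @export
iccc <- function(partition, graph, variant = c("unweighted", "density")) {
  variant <- match.arg(variant)
  members <- partition_members(partition)
  members <- members[lengths(members) >= 3]
  if (length(members) == 0) return(0)
  edges <- graph$edges
  key <- paste(edges$from, edges$to, sep = "\r")
  has_edge <- function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "\r") %in% key
  }
  if (variant == "density") {
    dens <- vapply(members, function(ids) {
      pairs <- utils::combn(sort(ids), 2)
      mean(has_edge(pairs[1, ], pairs[2, ]))
    }, numeric(1))
    return(sum(lengths(members) * dens) / sum(lengths(members)))
  }
  coeffs <- unlist(lapply(members, function(ids) {
    ids <- sort(ids)
    k <- length(ids)
    adj <- matrix(FALSE, k, k)
    pairs <- utils::combn(seq_len(k), 2)
    present <- has_edge(ids[pairs[1, ]], ids[pairs[2, ]])
    adj[t(pairs[, present, drop = FALSE])] <- TRUE
    adj <- adj | t(adj)
    vapply(seq_len(k), function(v) {
      nb <- which(adj[v, ])
      if (length(nb) < 2) return(0)
      np <- utils::combn(nb, 2)
      mean(adj[t(np)])
    }, numeric(1))
  }), use.names = FALSE)
  mean(coeffs)
}

#' Inflation-factor sweep with ICCC selection
#'
#' Runs [mcl()] at every grid point, scores each partition with [iccc()],
#' and selects the inflation with the highest ICCC (ties broken toward the
#' lowest inflation).  Deterministic: the whole sweep is a pure function of
#' the graph and options.
#'
#' @param graph A [build_graph()] similarity graph.
#' @param grid Numeric vector of inflation values, see [sweep_grid()].
#' @param opts [mcl_options()].
#' @param iccc_variant Passed to [iccc()]; recorded on the result.
#' @return An object of class `famint_sweep`: tibble of per-point summaries
#'   (`inflation`, `n_families`, `n_singletons`, `iccc`, `converged`) with
#'   the partitions in a list column, plus attributes `selected_inflation`
#'   and `selected_partition` (its `iccc` field filled in).
#' @export
inflation_sweep <- function(graph, grid = sweep_grid(), opts = mcl_options(),
                            iccc_variant = "unweighted") {
  runs <- lapply(grid, function(r) {
    p <- mcl(graph, r, opts)
    p$iccc <- iccc(p, graph, variant = iccc_variant)
    p
  })
  res <- tibble(
    inflation = grid,
    n_families = vapply(runs, function(p) length(p$family_sizes), integer(1)),
    n_singletons = vapply(runs, function(p) sum(p$family_sizes == 1L),
                          integer(1)),
    iccc = vapply(runs, function(p) p$iccc, numeric(1)),
    converged = vapply(runs, function(p) p$converged, logical(1)),
    partition = runs)
  best <- which(res$iccc == max(res$iccc))[1]  # lowest inflation on ties
  structure(res, class = c("famint_sweep", class(res)),
            selected_inflation = grid[best],
            selected_partition = runs[[best]],
            iccc_variant = iccc_variant)
}

#' Selected partition of an inflation sweep
#' @param sweep A `famint_sweep`.
#' @export
selected_partition <- function(sweep) attr(sweep, "selected_partition")

#' @export
print.famint_sweep <- function(x, ...) {
  cat("<famint_sweep> ", nrow(x), " inflation values; selected ",
      attr(x, "selected_inflation"), " (ICCC ",
      format(attr(x, "selected_partition")$iccc, digits = 4), ")\n", sep = "")
  NextMethod()
}
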