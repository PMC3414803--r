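# Independent reference implementations used as oracles.  These are written
# as plain, direct transcriptions of the definitions and share no code with
# the package internals.

# Brute-force affine-gap Smith-Waterman score (Gotoh recurrences, full
# matrices, no pruning).  Gap of length L costs open + L * ext.
oracle_sw_score <- function(a, b, sub, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      F[i, j] <- max(H[i - 1, j] - open - ext, F[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

random_aa_string <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), len,
               replace = TRUE), collapse = "")
}

# Unpruned dense reference MCL.  Cluster readout differs from the package's
# attractor-system path: connected components of the symmetrised positive
# limit matrix.
oracle_mcl <- function(w, inflation, self_loop_max_incident = TRUE,
                       tol = 1e-12, max_iter = 500) {
  n <- nrow(w)
  loop <- if (self_loop_max_incident) {
    pmax(apply(w, 2, max), 1)
  } else {
    rep(1, n)
  }
  diag(w) <- loop
  m <- sweep(w, 2, colSums(w), "/")
  for (it in seq_len(max_iter)) {
    m2 <- (m %*% m)^inflation
    m2 <- sweep(m2, 2, colSums(m2), "/")
    if (max(abs(m2 - m)) < tol) { m <- m2; break }
    m <- m2
  }
  adj <- (m > 1e-9) | t(m > 1e-9)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# Random connected-ish weighted graph on `n` nodes as a similarity_graph.
random_similarity_graph <- function(n, p = 0.4, wmax = 60) {
  ids <- sprintf("n%02d", seq_len(n))
  from <- character(0); to <- character(0); w <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (runif(1) < p) {
        from <- c(from, ids[i]); to <- c(to, ids[j])
        w <- c(w, runif(1, 2, wmax))
      }
    }
  }
  hits <- tibble::tibble(query_id = from, subject_id = to,
                         e_value = 10^(-w))
  famintr::build_graph(hits, nodes = ids)
}

# Union-find connected components over an edge list.
oracle_components <- function(labels, from, to) {
  parent <- stats::setNames(labels, labels)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(labels, find, character(1))
  unname(lapply(split(labels, roots), sort))
}

# Partition comparison up to family relabelling.
same_partition <- function(f1, f2) {
  length(unique(paste(f1, f2))) == length(unique(f1)) &&
    length(unique(f1)) == length(unique(f2))
}

# Memoised default study corpus + pipeline run shared by the acceptance
# tests (generating and sweeping it once keeps the suite fast).
.corpus_cache <- new.env(parent = emptyenv())
acceptance_corpus <- function() {
  if (is.null(.corpus_cache$corpus)) {
    .corpus_cache$corpus <- famintr::generate_protein_set(
      famintr::synth_params(seed = 1L))
  }
  .corpus_cache$corpus
}
acceptance_run <- function() {
  if (is.null(.corpus_cache$run)) {
    gs <- acceptance_corpus()
    .corpus_cache$run <- famintr::run_pipeline(proteins = gs$proteins)
  }
  .corpus_cache$run
}
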