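# Independent oracles used across the suite: a hand-coded augmenting-path
# bipartite matcher and exhaustive-subset minimizers for domination,
# vertex cover and feedback vertex set. Deliberately written without the
# package's solvers (or igraph's matching) so they certify them.

# Maximum bipartite matching size via augmenting-path search.
# adj: list over left vertices of integer right-neighbor vectors.
oracle_matching_size <- function(adj, n_right) {
  match_r <- rep(0L, n_right)
  try_aug <- function(u, seen) {
    for (v in adj[[u]]) {
      if (seen[v]) next
      seen[v] <- TRUE
      if (match_r[v] == 0L || Recall(match_r[v], seen)) {
        match_r[v] <<- u
        return(TRUE)
      }
    }
    FALSE
  }
  size <- 0L
  for (u in seq_along(adj))
    if (length(adj[[u]]) && try_aug(u, rep(FALSE, n_right)))
      size <- size + 1L
  size
}

# Maximum matching of the node-split bipartite graph of a directed
# edge list (2-column integer matrix), i.e. the MMS matching.
oracle_mms_matching <- function(el, n) {
  adj <- lapply(seq_len(n), function(u) sort(unique(el[el[, 1] == u, 2])))
  oracle_matching_size(adj, n)
}

# Smallest subset size satisfying `feasible` (exhaustive, n <= ~15).
oracle_min_subset <- function(n, feasible) {
  for (k in 0:n) {
    if (k == 0) {
      if (feasible(integer(0))) return(0L)
      next
    }
    cm <- utils::combn(n, k)
    for (j in seq_len(ncol(cm)))
      if (feasible(cm[, j])) return(k)
  }
  stop("no feasible subset")
}

# Minimum dominating set size of an undirected adjacency matrix.
oracle_mds_size <- function(A) {
  n <- nrow(A)
  closed <- A | diag(TRUE, n)
  oracle_min_subset(n, function(S) {
    if (!length(S)) return(n == 0)
    all(rowSums(closed[, S, drop = FALSE]) > 0)
  })
}

# Minimum vertex cover size of an undirected edge list.
oracle_vc_size <- function(el, n) {
  if (!nrow(el)) return(0L)
  oracle_min_subset(n, function(S)
    all(el[, 1] %in% S | el[, 2] %in% S))
}

# Is the directed graph on vertices `keep` (edges el) acyclic?
# Peels vertices with no incoming edge; self-loops are cycles.
oracle_is_acyclic <- function(el, keep) {
  el <- el[el[, 1] %in% keep & el[, 2] %in% keep, , drop = FALSE]
  if (any(el[, 1] == el[, 2])) return(FALSE)
  active <- keep
  repeat {
    if (!length(active)) return(TRUE)
    has_in <- unique(el[el[, 1] %in% active, 2])
    peel <- setdiff(active, has_in)
    if (!length(peel)) return(FALSE)
    active <- setdiff(active, peel)
    el <- el[el[, 1] %in% active & el[, 2] %in% active, , drop = FALSE]
  }
}

# Minimum feedback vertex set size of a directed edge list.
oracle_fvs_size <- function(el, n) {
  oracle_min_subset(n, function(S)
    oracle_is_acyclic(el, setdiff(seq_len(n), S)))
}

# Direct recomputation of the single-sample perturbation Z statistic.
oracle_ssn_z <- function(ref_x, ref_y, new_x, new_y) {
  n <- length(ref_x)
  p0 <- cor(ref_x, ref_y)
  p1 <- cor(c(ref_x, new_x), c(ref_y, new_y))
  abs(p1 - p0) / ((1 - p0^2) / (n - 1))
}

# Named random graph helpers ------------------------------------------------

rand_directed_graph <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p, directed = TRUE))
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

rand_undirected_graph <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p, directed = FALSE))
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

named_ring <- function(n, directed = FALSE) {
  g <- igraph::make_ring(n, directed = directed)
  igraph::V(g)$name <- letters[seq_len(n)]
  g
}

# A small paired-design expression fixture used by several files.
make_paired_expr <- function(n_genes = 6, n_ref = 20, seed = 42) {
  withr::with_seed(seed, {
    genes <- paste0("g", seq_len(n_genes))
    refs <- paste0("n", seq_len(n_ref))
    cases <- c("t1", "t2")
    m <- matrix(rnorm(n_genes * (n_ref + 2)), n_genes,
                dimnames = list(genes, c(refs, cases)))
    labels <- data.frame(
      sample_id = c(refs, cases),
      group = rep(c("reference", "case"), c(n_ref, 2)),
      pair_id = c("p1", "p2", rep(NA, n_ref - 2), "p1", "p2"),
      time = NA_real_)
    ssc_expression(m, labels)
  })
}
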