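# Driver-node identification on a (sample-specific) network: maximum
# matching (MMS), minimum dominating set (MDS), directed feedback vertex
# set plus sources (DFVS), and minimum node cover of the node-edge
# bipartite incidence (NCUA, equivalently a minimum vertex cover).
# MDS and NCUA are set-cover instances solved by one exact
# branch-and-bound; DFVS branches on shortest cycles. Past a work cap the
# incumbent (greedy-initialized) solution is returned with
# optimal = FALSE.

#' Driver node set
#'
#' @param owner_id identifier of the analyzed network (sample id or
#'   network name).
#' @param method control method tag: `"MMS"`, `"MDS"`, `"DFVS"`,
#'   `"NCUA"`.
#' @param drivers character vector of driver node ids.
#' @param optimal logical; `TRUE` when the solver proved minimality.
#' @return an object of class `driver_set`; `objective` is the set size.
#' @export
driver_set <- function(owner_id, method, drivers, optimal = TRUE) {
  structure(list(owner_id = owner_id, method = method,
                 drivers = sort(unique(drivers)), optimal = optimal,
                 objective = length(unique(drivers))),
            class = "driver_set")
}

#' @export
print.driver_set <- function(x, ...) {
  cat("Driver set [", x$method, "] for '", x$owner_id, "': ",
      x$objective, " nodes",
      if (!x$optimal) " (minimality not proven)", "\n", sep = "")
  invisible(x)
}

# Coerce a sample_network or igraph to the orientation a control method
# expects. Undirected inputs to directed methods become bidirected
# (mutual) edges; directed inputs to undirected methods are symmetrized.
as_control_graph <- function(net, directed) {
  g <- if (inherits(net, "sample_network")) as_igraph(net)
       else if (igraph::is_igraph(net)) net
       else stop("expected a sample_network or an igraph graph")
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  if (directed && !igraph::is_directed(g))
    g <- igraph::as_directed(g, mode = "mutual")
  if (!directed && igraph::is_directed(g))
    g <- igraph::as_undirected(g, mode = "collapse")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
}

net_owner <- function(net, default = "network") {
  if (inherits(net, "sample_network")) net$sample_id else default
}

# ---- exact set cover -------------------------------------------------------

# sets: list over items, each an integer vector of covered universe
# elements. Branch on the uncovered element covered by fewest items;
# any feasible cover must pick one of them.
set_cover_bb <- function(sets, n_universe, max_expand = 2e5) {
  greedy <- function() {
    covered <- rep(FALSE, n_universe); sel <- integer(0)
    while (!all(covered)) {
      gains <- vapply(sets, function(s) sum(!covered[s]), integer(1))
      i <- which.max(gains)
      if (gains[i] == 0) stop("universe element not coverable by any set")
      sel <- c(sel, i); covered[sets[[i]]] <- TRUE
    }
    sel
  }
  st <- new.env(parent = emptyenv())
  st$best <- greedy()
  st$expand <- 0L; st$capped <- FALSE
  cover_by <- vector("list", n_universe)
  for (i in seq_along(sets)) for (e in sets[[i]])
    cover_by[[e]] <- c(cover_by[[e]], i)
  max_size <- max(vapply(sets, length, integer(1)), 1L)
  rec <- function(covered, sel) {
    if (st$capped) return()
    st$expand <- st$expand + 1L
    if (st$expand > max_expand) { st$capped <- TRUE; return() }
    unc <- which(!covered)
    if (!length(unc)) {
      if (length(sel) < length(st$best)) st$best <- sel
      return()
    }
    if (length(sel) + ceiling(length(unc) / max_size) >= length(st$best))
      return()
    e <- unc[which.min(lengths(cover_by[unc]))]
    for (i in cover_by[[e]]) {
      cov2 <- covered; cov2[sets[[i]]] <- TRUE
      rec(cov2, c(sel, i))
    }
  }
  rec(rep(FALSE, n_universe), integer(0))
  list(selected = st$best, optimal = !st$capped)
}

# ---- MMS -------------------------------------------------------------------

# Node-split bipartite representation: out-copy u+ on the left, in-copy
# v- on the right; a directed edge u -> v becomes (u+, v-).
mms_bipartite <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  bg <- igraph::make_empty_graph(2 * n, directed = FALSE)
  igraph::V(bg)$type <- rep(c(FALSE, TRUE), each = n)
  if (nrow(el))
    bg <- igraph::add_edges(bg, rbind(el[, 1], n + el[, 2]))
  bg
}

#' Driver nodes by maximum matching (MMS)
#'
#' Splits every node into an out-copy and an in-copy, computes a maximum
#' matching of the resulting bipartite graph, and returns the nodes whose
#' in-copy is unmatched; those nodes must receive independent control
#' signals for structural controllability of the linear dynamics. When a
#' perfect matching exists any single node suffices and the first node is
#' returned.
#'
#' @param net directed [sample_network] or igraph graph (undirected input
#'   is expanded to bidirected edges).
#' @param owner_id label recorded on the result.
#' @return a [driver_set]; `objective` equals
#'   `max(N - |maximum matching|, 1)`.
#' @export
mms_drivers <- function(net, owner_id = net_owner(net)) {
  g <- as_control_graph(net, directed = TRUE)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty node set")
  mm <- igraph::max_bipartite_match(mms_bipartite(g))
  matched_in <- !is.na(mm$matching[n + seq_len(n)])
  drivers <- igraph::V(g)$name[!matched_in]
  if (!length(drivers)) drivers <- igraph::V(g)$name[1]
  driver_set(owner_id, "MMS", drivers, optimal = TRUE)
}

# ---- MDS -------------------------------------------------------------------

#' Driver nodes by minimum dominating set (MDS)
#'
#' Every node must either be a driver or be adjacent to one
#' (`x_i + sum_{j in N(i)} x_j >= 1` for all i, minimizing the set size).
#' Solved exactly by branch and bound on the closed-neighborhood set-cover
#' formulation; past the work cap the incumbent is returned with
#' `optimal = FALSE`.
#'
#' @param net undirected [sample_network] or igraph graph (directed input
#'   is symmetrized).
#' @param owner_id label recorded on the result.
#' @param max_expand branch-and-bound node budget.
#' @return a [driver_set].
#' @export
mds_drivers <- function(net, owner_id = net_owner(net), max_expand = 2e5) {
  g <- as_control_graph(net, directed = FALSE)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty node set")
  adj <- igraph::as_adj_list(g, mode = "all")
  sets <- lapply(seq_len(n), function(i)
    unique(c(i, as.integer(adj[[i]]))))
  sol <- set_cover_bb(sets, n, max_expand)
  driver_set(owner_id, "MDS", igraph::V(g)$name[sol$selected],
             optimal = sol$optimal)
}

# ---- NCUA ------------------------------------------------------------------

#' Node-edge bipartite incidence of an undirected graph
#'
#' Top nodes are the graph's nodes, bottom nodes its edges; a top node is
#' linked to every bottom node (edge) it is an endpoint of. The control
#' problem selects a minimum top set dominating all bottom nodes.
#'
#' @param g undirected igraph graph.
#' @return list with `top` (node names), `bottom` (edge labels), and
#'   `incidence` (list over nodes of incident edge indices).
#' @export
bipartite_cover_instance <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  inc <- vector("list", n)
  for (e in seq_len(nrow(el))) {
    inc[[el[e, 1]]] <- c(inc[[el[e, 1]]], e)
    if (el[e, 2] != el[e, 1]) inc[[el[e, 2]]] <- c(inc[[el[e, 2]]], e)
  }
  list(top = igraph::V(g)$name,
       bottom = paste(igraph::V(g)$name[el[, 1]],
                      igraph::V(g)$name[el[, 2]], sep = "--"),
       incidence = inc)
}

#' Driver nodes for nonlinear control of undirected networks (NCUA)
#'
#' Converts the (bidirected) network into its node-edge bipartite
#' incidence and selects a minimum node set covering every edge -- a
#' minimum vertex cover -- by exact branch and bound.
#'
#' @param net undirected [sample_network] or igraph graph with at least
#'   one edge (directed input is symmetrized).
#' @param owner_id label recorded on the result.
#' @param max_expand branch-and-bound node budget.
#' @return a [driver_set].
#' @export
ncua_drivers <- function(net, owner_id = net_owner(net), max_expand = 2e5) {
  g <- as_control_graph(net, directed = FALSE)
  if (igraph::vcount(g) == 0) stop("empty node set")
  if (igraph::ecount(g) == 0) stop("NCUA needs at least one edge")
  inst <- bipartite_cover_instance(g)
  sol <- set_cover_bb(inst$incidence, length(inst$bottom), max_expand)
  driver_set(owner_id, "NCUA", inst$top[sol$selected],
             optimal = sol$optimal)
}

# ---- DFVS ------------------------------------------------------------------

# Vertices in no cycle (zero in- or out-degree) can never be in a minimum
# FVS; trim them repeatedly.
trim_acyclic_parts <- function(g) {
  repeat {
    din <- igraph::degree(g, mode = "in")
    dout <- igraph::degree(g, mode = "out")
    drop <- which(din == 0 | dout == 0)
    if (!length(drop)) return(g)
    g <- igraph::delete_vertices(g, drop)
  }
}

# A shortest directed cycle, as vertex names (self-loops first).
shortest_cycle <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  loops <- el[el[, 1] == el[, 2], 1]
  if (length(loops)) return(igraph::V(g)$name[loops[1]])
  best <- NULL; best_len <- Inf
  for (v in seq_len(igraph::vcount(g))) {
    succ <- as.integer(igraph::neighbors(g, v, mode = "out"))
    if (!length(succ)) next
    d <- suppressWarnings(igraph::distances(g, v = succ, to = v,
                                            mode = "out"))
    i <- which.min(d)
    if (is.finite(d[i]) && d[i] + 1 < best_len) {
      best_len <- d[i] + 1
      sp <- igraph::shortest_paths(g, from = succ[i], to = v,
                                   mode = "out")$vpath[[1]]
      best <- c(igraph::V(g)$name[v], igraph::V(g)$name[as.integer(sp)])
    }
  }
  unique(best)
}

greedy_fvs <- function(g) {
  sel <- character(0)
  repeat {
    g <- trim_acyclic_parts(g)
    if (igraph::vcount(g) == 0) return(sel)
    score <- igraph::degree(g, mode = "in") *
      igraph::degree(g, mode = "out")
    v <- which.max(score)
    sel <- c(sel, igraph::V(g)$name[v])
    g <- igraph::delete_vertices(g, v)
  }
}

fvs_bb <- function(g, max_expand = 2e5) {
  st <- new.env(parent = emptyenv())
  st$best <- greedy_fvs(g)
  st$expand <- 0L; st$capped <- FALSE
  rec <- function(g, cur) {
    if (st$capped) return()
    st$expand <- st$expand + 1L
    if (st$expand > max_expand) { st$capped <- TRUE; return() }
    g <- trim_acyclic_parts(g)
    if (igraph::vcount(g) == 0) {
      if (length(cur) < length(st$best)) st$best <- cur
      return()
    }
    # after trimming a nonempty graph always contains a cycle
    if (length(cur) + 1 >= length(st$best)) return()
    for (v in shortest_cycle(g))
      rec(igraph::delete_vertices(g, v), c(cur, v))
  }
  rec(g, character(0))
  list(fvs = st$best, optimal = !st$capped)
}

#' Driver nodes by directed feedback vertex set (DFVS)
#'
#' The long-term dynamics of a nonlinear directed network are pinned down
#' by its cycle structure and its source nodes: the drivers are a minimum
#' vertex set whose removal leaves the graph acyclic, together with all
#' nodes of in-degree zero. The FVS is found by exact cycle-branching
#' search (greedy incumbent, `optimal = FALSE` past the work cap).
#'
#' @param net directed [sample_network] or igraph graph (undirected input
#'   is expanded to bidirected edges).
#' @param owner_id label recorded on the result.
#' @param include_sources include in-degree-0 nodes in the driver set
#'   (default `TRUE`).
#' @param max_expand search node budget.
#' @return a [driver_set]; the FVS alone is attached as attribute
#'   `"fvs"`.
#' @export
dfvs_drivers <- function(net, owner_id = net_owner(net),
                         include_sources = TRUE, max_expand = 2e5) {
  g <- as_control_graph(net, directed = TRUE)
  if (igraph::vcount(g) == 0) stop("empty node set")
  sol <- fvs_bb(g, max_expand)
  sources <- igraph::V(g)$name[igraph::degree(g, mode = "in") == 0]
  drivers <- if (include_sources) union(sol$fvs, sources) else sol$fvs
  out <- driver_set(owner_id, "DFVS", drivers, optimal = sol$optimal)
  attr(out, "fvs") <- sort(sol$fvs)
  out
}

# ---- verification and sampling --------------------------------------------

#' Verify a driver set against its control condition
#'
#' Independent certificate checks: MMS -- the bipartite node-split graph
#' restricted to in-copies of non-drivers admits a matching saturating
#' all of them; MDS -- domination; DFVS -- removing the drivers leaves
#' the graph acyclic and all source nodes are included; NCUA -- every
#' edge has an endpoint in the set.
#'
#' @param net the analyzed network ([sample_network] or igraph).
#' @param method method tag.
#' @param drivers character vector of node ids.
#' @return `TRUE` or `FALSE`.
#' @export
verify_driver_set <- function(net, method, drivers) {
  method <- match.arg(method, c("MMS", "MDS", "DFVS", "NCUA"))
  directed <- method %in% c("MMS", "DFVS")
  g <- as_control_graph(net, directed = directed)
  nodes <- igraph::V(g)$name
  if (!all(drivers %in% nodes)) return(FALSE)
  switch(method,
    MMS = {
      n <- igraph::vcount(g)
      bg <- mms_bipartite(g)
      need <- setdiff(nodes, drivers)
      keep <- c(seq_len(n), n + match(need, nodes))
      sub <- igraph::induced_subgraph(bg, keep)
      mm <- igraph::max_bipartite_match(sub)
      mm$matching_size == length(need)
    },
    MDS = {
      adj <- igraph::as_adj_list(g, mode = "all")
      idx <- nodes %in% drivers
      all(vapply(seq_along(nodes), function(i)
        idx[i] || any(idx[as.integer(adj[[i]])]), logical(1)))
    },
    DFVS = {
      sources <- nodes[igraph::degree(g, mode = "in") == 0]
      if (!all(sources %in% drivers)) return(FALSE)
      h <- igraph::delete_vertices(g, match(drivers, nodes))
      el <- igraph::as_edgelist(h, names = FALSE)
      if (any(el[, 1] == el[, 2])) return(FALSE)
      igraph::is_dag(igraph::simplify(h, remove.loops = TRUE))
    },
    NCUA = {
      el <- igraph::as_edgelist(g, names = TRUE)
      if (!nrow(el)) return(TRUE)
      all(el[, 1] %in% drivers | el[, 2] %in% drivers)
    })
}

#' Sample alternative minimum driver configurations
#'
#' Markov-chain exploration of the (usually non-unique) minimum driver
#' sets for MMS and NCUA. Each step removes a uniformly chosen member
#' `w` and adds a uniformly chosen non-member `v` restoring the method's
#' cover/matching condition at the same cardinality; the proposal is
#' accepted with probability `accept_prob`. Steps with no valid swap are
#' skipped.
#'
#' @param net the analyzed network.
#' @param method `"MMS"` or `"NCUA"` (alternative-configuration theory
#'   does not exist for MDS/DFVS).
#' @param n_steps number of chain steps.
#' @param seed integer seed (the chain is deterministic given it).
#' @param accept_prob acceptance probability for a valid proposal.
#' @return list of distinct [driver_set]s visited (the initial solver
#'   optimum first).
#' @export
sample_driver_configurations <- function(net, method = c("MMS", "NCUA"),
                                         n_steps = 100, seed = 1L,
                                         accept_prob = 0.5) {
  method <- match.arg(method)
  init <- if (method == "MMS") mms_drivers(net) else ncua_drivers(net)
  g <- as_control_graph(net, directed = method == "MMS")
  nodes <- igraph::V(g)$name
  seen <- list(init$drivers)
  cur <- init$drivers
  withr::with_seed(seed, {
    for (step in seq_len(n_steps)) {
      w <- sample(cur, 1)
      cand <- setdiff(nodes, cur)
      valid <- cand[vapply(cand, function(v)
        verify_driver_set(g, method, c(setdiff(cur, w), v)), logical(1))]
      if (!length(valid)) next
      v <- if (length(valid) == 1) valid else sample(valid, 1)
      if (stats::runif(1) < accept_prob) {
        cur <- sort(c(setdiff(cur, w), v))
        if (!any(vapply(seen, identical, logical(1), cur)))
          seen <- c(seen, list(cur))
      }
    }
  })
  lapply(seen, function(d)
    driver_set(init$owner_id, method, d, optimal = init$optimal))
}

#' Dispatch a control method by tag
#'
#' @param net the analyzed network.
#' @param method `"MMS"`, `"MDS"`, `"DFVS"`, or `"NCUA"`.
#' @param ... passed to the method-specific solver.
#' @return a [driver_set].
#' @export
find_drivers <- function(net, method = c("MMS", "MDS", "DFVS", "NCUA"),
                         ...) {
  method <- match.arg(method)
  switch(method,
         MMS = mms_drivers(net, ...),
         MDS = mds_drivers(net, ...),
         DFVS = dfvs_drivers(net, ...),
         NCUA = ncua_drivers(net, ...))
}
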