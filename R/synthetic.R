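#' Generate a synthetic reference interaction network
#'
#' Emulates the role of a curated directed gene/protein interaction
#' scaffold. Erdos-Renyi graphs take `density_param` as the edge
#' probability; preferential-attachment graphs take it as the (integer)
#' number of edges added per node.
#'
#' @param n_nodes number of genes (>= 2); vertices are named `g1..gN`.
#' @param model `"erdos_renyi"` or `"preferential_attachment"`.
#' @param density_param edge probability in \[0,1\] (ER) or edges-per-node
#'   (PA).
#' @param directed logical.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return an `igraph` graph with named vertices.
#' @export
gen_reference_network <- function(n_nodes,
                                  model = c("erdos_renyi",
                                            "preferential_attachment"),
                                  density_param = 0.05, directed = TRUE,
                                  seed = 1L) {
  model <- match.arg(model)
  if (n_nodes < 2) stop("need n_nodes >= 2")
  if (model == "erdos_renyi" &&
      (density_param < 0 || density_param > 1))
    stop("erdos_renyi density must be a probability in [0,1]")
  if (model == "preferential_attachment" && density_param < 1)
    stop("preferential_attachment needs >= 1 edge per node")
  g <- withr::with_seed(seed, {
    if (model == "erdos_renyi")
      igraph::sample_gnp(n_nodes, density_param, directed = directed,
                         loops = FALSE)
    else
      igraph::sample_pa(n_nodes, m = round(density_param),
                        directed = directed)
  })
  igraph::V(g)$name <- paste0("g", seq_len(n_nodes))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = FALSE)
}

#' Specification of planted correlation structure
#'
#' @param n_planted number of vertex-disjoint reference-network edges to
#'   plant as co-expressed pairs.
#' @param r_base baseline correlation of planted pairs in (-1, 1).
#' @param r_alt correlation each perturbed pair is switched to in a case
#'   sample. The default flips a strong co-expression (0.8) to independence
#'   (0), the canonical differential-edge event the single-sample
#'   statistics are built to detect.
#' @param perturb_frac fraction of planted pairs perturbed per case sample.
#' @return a list with class `truth_spec`.
#' @export
truth_spec <- function(n_planted = 10, r_base = 0.8, r_alt = 0.0,
                       perturb_frac = 0.5) {
  if (abs(r_base) >= 1 || abs(r_alt) >= 1)
    stop("planted correlations must have |r| < 1 (positive definite 2x2)")
  if (perturb_frac < 0 || perturb_frac > 1) stop("perturb_frac in [0,1]")
  structure(list(n_planted = n_planted, r_base = r_base, r_alt = r_alt,
                 perturb_frac = perturb_frac), class = "truth_spec")
}

# Vertex-disjoint subset of reference edges, greedy over a seeded shuffle,
# so each planted pair's correlation can be realized exactly.
pick_disjoint_edges <- function(ref, n_planted, seed) {
  el <- igraph::as_edgelist(ref, names = TRUE)
  el <- el[el[, 1] != el[, 2], , drop = FALSE]
  ord <- withr::with_seed(seed, sample.int(nrow(el)))
  used <- character(0)
  picked <- matrix(character(0), 0, 2)
  for (i in ord) {
    if (el[i, 1] %in% used || el[i, 2] %in% used) next
    picked <- rbind(picked, el[i, ])
    used <- c(used, el[i, ])
    if (nrow(picked) >= n_planted) break
  }
  picked
}

#' Generate expression data with planted differential co-expression
#'
#' Draws reference samples in which planted gene pairs have a baseline
#' correlation `r_base`, and case samples in which a per-sample subset of
#' those pairs is switched to `r_alt`; all other genes are independent.
#' Every gene is marginally Gaussian with standard deviation `noise_sd`;
#' planted pairs are drawn jointly bivariate-normal at exactly the
#' requested correlation. Case samples are paired one-to-one with the
#' first `n_case_samples` reference samples (shared `pair_id`), emulating
#' matched normal/tumor designs.
#'
#' @param ref reference network (igraph) whose edges host planted pairs.
#' @param n_ref_samples number of reference-group samples.
#' @param n_case_samples number of case samples (each gets its own
#'   perturbed pair subset).
#' @param spec a [truth_spec].
#' @param noise_sd marginal standard deviation of every gene (> 0).
#' @param seed integer seed.
#' @return list with `expr` (an [ssc_expression]) and `truth` (class
#'   `synthetic_truth`: `planted_edges`, `perturbed`, `driver_genes`,
#'   `seed`).
#' @export
gen_expression <- function(ref, n_ref_samples = 200, n_case_samples = 20,
                           spec = truth_spec(), noise_sd = 1, seed = 1L) {
  if (noise_sd <= 0)
    stop("noise_sd must be > 0: zero marginal spread makes the ",
         "covariance singular")
  planted <- pick_disjoint_edges(ref, spec$n_planted, seed)
  if (nrow(planted) < spec$n_planted)
    warning("only ", nrow(planted),
            " vertex-disjoint edges available for planting")
  genes <- igraph::V(ref)$name
  n_samp <- n_ref_samples + n_case_samples
  ids <- c(paste0("ref", seq_len(n_ref_samples)),
           paste0("case", seq_len(n_case_samples), recycle0 = TRUE))
  n_per_case <- ceiling(spec$perturb_frac * nrow(planted))
  out <- withr::with_seed(seed + 1L, {
    m <- matrix(stats::rnorm(length(genes) * n_samp, sd = noise_sd),
                nrow = length(genes),
                dimnames = list(genes, ids))
    perturbed <- vector("list", n_case_samples)
    names(perturbed) <- ids[n_ref_samples + seq_len(n_case_samples)]
    for (s in names(perturbed))
      perturbed[[s]] <- sort(sample.int(nrow(planted), n_per_case))
    for (e in seq_len(nrow(planted))) {
      gx <- planted[e, 1]; gy <- planted[e, 2]
      for (j in seq_len(n_samp)) {
        r <- spec$r_base
        if (j > n_ref_samples && e %in% perturbed[[ids[j]]]) r <- spec$r_alt
        z1 <- stats::rnorm(1); z2 <- stats::rnorm(1)
        m[gx, j] <- noise_sd * z1
        m[gy, j] <- noise_sd * (r * z1 + sqrt(1 - r^2) * z2)
      }
    }
    list(m = m, perturbed = perturbed)
  })
  pair_ids <- c(ifelse(seq_len(n_ref_samples) <= n_case_samples,
                       paste0("p", seq_len(n_ref_samples)), NA),
                paste0("p", seq_len(n_case_samples), recycle0 = TRUE))
  labels <- data.frame(
    sample_id = ids,
    group = rep(c("reference", "case"), c(n_ref_samples, n_case_samples)),
    pair_id = pair_ids, time = NA_real_, stringsAsFactors = FALSE)
  perturbed_pairs <- lapply(out$perturbed, function(idx)
    planted[idx, , drop = FALSE])
  driver_genes <- sort(unique(unlist(lapply(perturbed_pairs, c))))
  truth <- structure(list(planted_edges = planted,
                          r_base = spec$r_base, r_alt = spec$r_alt,
                          perturbed = perturbed_pairs,
                          driver_genes = driver_genes, seed = seed),
                     class = "synthetic_truth")
  list(expr = ssc_expression(out$m, labels), truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic truth:", nrow(x$planted_edges), "planted pairs (r_base =",
      x$r_base, "-> r_alt =", x$r_alt, "),",
      length(x$perturbed), "case samples,",
      length(x$driver_genes), "gold driver genes\n")
  invisible(x)
}

#' Build gold standards from a synthetic truth
#'
#' The gene list is the planted driver set (endpoints of perturbed edges).
#' A synthetic drug-combination map is built so that half of the combos
#' target at least one driver gene (labeled positive) and the rest target
#' none (labeled negative), supporting AUC evaluation end to end.
#'
#' @param truth a `synthetic_truth` from [gen_expression].
#' @param ref the reference network the truth was planted on.
#' @param n_combos number of synthetic drug combinations.
#' @param targets_per_combo genes per combination.
#' @param seed integer seed.
#' @return list of [ssc_gold] objects: `genes`, `drug_targets`, `labels`.
#' @export
gen_gold <- function(truth, ref, n_combos = 10, targets_per_combo = 3,
                     seed = 1L) {
  drivers <- truth$driver_genes
  if (!length(drivers)) stop("empty driver set in synthetic truth")
  genes <- igraph::V(ref)$name
  nondrivers <- setdiff(genes, drivers)
  n_pos <- ceiling(n_combos / 2)
  combos <- withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(n_combos)) {
      if (i <= n_pos) {
        hit <- sample(drivers, 1)
        rest <- sample(nondrivers, targets_per_combo - 1)
        out[[paste0("combo", i)]] <- c(hit, rest)
      } else {
        out[[paste0("combo", i)]] <- sample(nondrivers, targets_per_combo)
      }
    }
    out
  })
  labels <- stats::setNames(
    ifelse(vapply(combos, function(t) length(intersect(t, drivers)) > 0,
                  logical(1)), "positive", "negative"),
    names(combos))
  list(genes = ssc_gold("gene_list", gene_list = drivers),
       drug_targets = ssc_gold("drug_target_map", drug_target_map = combos),
       labels = ssc_gold("combo_labels", combo_labels = labels))
}
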