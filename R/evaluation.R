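# Assessment metrics for driver-gene predictions: F-measure, drug-combo
# AUC, Jaccard consensus/robustness, per-sample controllability,
# hypergeometric enrichment, z-scores against randomization baselines,
# centrality profiles, ARI, and dark-gene membership.

#' Precision, recall and F-measure of a predicted gene set
#'
#' `P = |pred & gold| / |pred|` (0 when nothing is predicted),
#' `R = |pred & gold| / |gold|`, `F = 2PR / (P + R)` (0 when both are 0).
#'
#' @param predicted character vector of predicted genes.
#' @param gold non-empty character vector of gold-standard genes.
#' @return named numeric vector `precision`, `recall`, `F`.
#' @export
precision_recall_f <- function(predicted, gold) {
  gold <- unique(gold)
  if (!length(gold)) stop("empty gold standard")
  predicted <- unique(predicted)
  tp <- length(intersect(predicted, gold))
  p <- if (length(predicted)) tp / length(predicted) else 0
  r <- tp / length(gold)
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, F = f)
}

# Mann-Whitney pair counting; ties score 1/2.
auc_from_scores <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  if (!length(pos) || !length(neg))
    stop("need at least one positive and one negative label")
  cmp <- outer(pos, neg, function(a, b)
    (a > b) + 0.5 * (a == b))
  mean(cmp)
}

#' AUC of driver-based drug-combination ranking
#'
#' Each drug combination is scored by how many of its target genes are
#' predicted drivers; combinations are rank-converted to probabilities
#' `p = 1 - rank / n_combos` (descending score, average rank on ties) and
#' the AUC is computed against the positive/negative combination labels.
#'
#' @param drivers a [driver_set] or character vector of driver genes.
#' @param drug_targets an [ssc_gold] of kind `drug_target_map`.
#' @param labels an [ssc_gold] of kind `combo_labels` covering the mapped
#'   combos.
#' @return the AUC in \[0, 1\].
#' @export
drug_combo_auc <- function(drivers, drug_targets, labels) {
  d <- if (inherits(drivers, "driver_set")) drivers$drivers else drivers
  combos <- names(drug_targets$drug_target_map)
  lab <- labels$combo_labels[combos]
  if (anyNA(lab)) stop("missing label for combo(s): ",
                       paste(combos[is.na(lab)], collapse = ", "))
  score <- vapply(drug_targets$drug_target_map, function(t)
    length(intersect(t, d)), numeric(1))
  prob <- 1 - rank(-score, ties.method = "average") / length(score)
  auc_from_scores(prob, lab == "positive")
}

#' Jaccard similarity of two gene sets
#'
#' Used both for the consensus of two control methods on the same data
#' and for the robustness of one method across two reference networks.
#'
#' @param set1,set2 character vectors; the union must be non-empty.
#' @return `|intersection| / |union|`.
#' @export
jaccard <- function(set1, set2) {
  u <- union(set1, set2)
  if (!length(u)) stop("both sets empty")
  length(intersect(set1, set2)) / length(u)
}

#' Per-sample controllability score
#'
#' `1 - |D| / |G|`: the fewer driver nodes a sample's state-transition
#' network needs, the easier its state is to change.
#'
#' @param drivers a [driver_set] or character vector.
#' @param gene_universe nodes of the sample's network (non-empty,
#'   containing the drivers).
#' @return value in \[0, 1\].
#' @export
controllability <- function(drivers, gene_universe) {
  d <- if (inherits(drivers, "driver_set")) drivers$drivers else drivers
  if (!length(gene_universe)) stop("empty gene universe")
  if (!all(d %in% gene_universe))
    stop("drivers must be contained in the gene universe")
  1 - length(unique(d)) / length(unique(gene_universe))
}

#' Hypergeometric enrichment of a prediction in a gold list
#'
#' Upper-tail probability `P(X >= k)` of drawing at least the observed
#' overlap when `|predicted|` genes are sampled without replacement from
#' a universe containing `|gold|` annotated genes.
#'
#' @param predicted predicted gene set.
#' @param gold gold-standard gene set.
#' @param universe_size number of genes in the universe.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_enrichment <- function(predicted, gold, universe_size) {
  predicted <- unique(predicted); gold <- unique(gold)
  if (length(predicted) > universe_size || length(gold) > universe_size)
    stop("set larger than the universe")
  k <- length(intersect(predicted, gold))
  stats::phyper(k - 1, length(gold), universe_size - length(gold),
                length(predicted), lower.tail = FALSE)
}

#' z-score of an observation against baseline draws
#'
#' `z = (observed - mean(baseline)) / sd(baseline)`; one-sided
#' significance at the 0.05 level corresponds to z > 1.645.
#'
#' @param observed scalar observation.
#' @param baseline_draws numeric vector (>= 2 values, positive spread).
#' @return the z value.
#' @export
zscore_vs_baseline <- function(observed, baseline_draws) {
  if (length(baseline_draws) < 2) stop("need at least 2 baseline draws")
  s <- stats::sd(baseline_draws)
  if (s == 0) stop("baseline draws have zero spread")
  (observed - mean(baseline_draws)) / s
}

#' One-sided normal critical value
#'
#' The z cut-off for one-sided significance at level `alpha`
#' (1.645 at alpha = 0.05).
#'
#' @param alpha significance level.
#' @return the critical z value.
#' @export
z_critical <- function(alpha = 0.05) stats::qnorm(1 - alpha)

#' Randomization baselines for driver predictions
#'
#' `uniform` mode draws `n_reps` gene sets of size `k` uniformly from the
#' network's nodes. `degree_preserved` mode rewires the network by
#' double-edge swaps that conserve every node's degree (rejecting
#' multi-edges and self-loops, `10 |E|` accepted swaps per replicate) and
#' re-runs the control method on each rewired network.
#'
#' @param net igraph network.
#' @param k driver-set size to match (uniform mode).
#' @param mode `"uniform"` or `"degree_preserved"`.
#' @param n_reps number of replicates (default 100).
#' @param seed integer seed.
#' @param method control method re-run on rewired networks
#'   (degree-preserved mode).
#' @return list of character vectors (uniform) or of [driver_set]s
#'   (degree-preserved).
#' @export
random_baseline <- function(net, k = NULL,
                            mode = c("uniform", "degree_preserved"),
                            n_reps = 100, seed = 1L, method = "NCUA") {
  mode <- match.arg(mode)
  nodes <- igraph::V(net)$name
  if (mode == "uniform") {
    if (is.null(k)) stop("uniform mode needs the set size k")
    if (k > length(nodes)) stop("k exceeds the number of nodes")
    return(withr::with_seed(seed, lapply(seq_len(n_reps), function(i)
      sample(nodes, k))))
  }
  nswap <- 10 * igraph::ecount(net)
  withr::with_seed(seed, lapply(seq_len(n_reps), function(i) {
    rg <- igraph::rewire(net, igraph::keeping_degseq(loops = FALSE,
                                                     niter = nswap))
    find_drivers(rg, method)
  }))
}

#' Significance score against a matched baseline
#'
#' Mean over conditions of the ratio observed / baseline; a value above 1
#' means the analysis beats the baseline on average. Conditions with a
#' zero baseline are skipped with a warning.
#'
#' @param observed_counts,baseline_counts equal-length numeric vectors.
#' @return the mean ratio.
#' @export
significance_score <- function(observed_counts, baseline_counts) {
  stopifnot(length(observed_counts) == length(baseline_counts))
  ok <- baseline_counts > 0
  if (!all(ok))
    warning(sum(!ok), " condition(s) with zero baseline skipped")
  if (!any(ok)) stop("no usable conditions")
  mean(observed_counts[ok] / baseline_counts[ok])
}

#' Centrality profile of a driver set
#'
#' Compares the mean degree, closeness, and betweenness centrality of the
#' drivers against `n_reps` uniformly drawn same-size node sets; reports
#' the z-score and one-sided p per centrality. Closeness is harmonic, so
#' disconnected graphs are handled without per-component bookkeeping.
#'
#' @param net igraph network.
#' @param drivers a [driver_set] or character vector.
#' @param n_reps number of random sets (default 100).
#' @param seed integer seed.
#' @return data.frame with columns `centrality`, `z`, `p` (3 rows).
#' @export
centrality_profile <- function(net, drivers, n_reps = 100, seed = 1L) {
  d <- if (inherits(drivers, "driver_set")) drivers$drivers else drivers
  nodes <- igraph::V(net)$name
  cent <- list(
    degree = igraph::degree(net, mode = "all"),
    closeness = igraph::harmonic_centrality(net, mode = "all"),
    betweenness = igraph::betweenness(net))
  sets <- withr::with_seed(seed, lapply(seq_len(n_reps), function(i)
    sample(nodes, length(d))))
  rows <- lapply(names(cent), function(nm) {
    v <- cent[[nm]]
    obs <- mean(v[d])
    base <- vapply(sets, function(s) mean(v[s]), numeric(1))
    z <- if (stats::sd(base) == 0) 0 else zscore_vs_baseline(obs, base)
    data.frame(centrality = nm, z = z,
               p = stats::pnorm(z, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Adjusted Rand index of two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' from the contingency-table closed form under the permutation model.
#'
#' @param labels_a,labels_b equal-length label vectors over the same
#'   items.
#' @return the ARI (1 for identical partitions, about 0 at chance).
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions must label the same items")
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(labels_a)
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(ifelse(sum_ij == max_idx, 1, 0))
  (sum_ij - expected) / (max_idx - expected)
}

#' Dark-gene metrics of a driver prediction
#'
#' Two modes. With a supplied dark-gene list, scores the drivers against
#' it directly. In `fold_change` mode the per-sample "dark-differential"
#' genes are the drivers whose expression changes less than two-fold
#' between the paired normal and tumor samples
#' (`|log2(tumor / normal)| < 1`, strict), i.e. drivers invisible to
#' differential expression.
#'
#' @param drivers a [driver_set] or character vector.
#' @param dark_list character vector of dark genes (list mode), or `NULL`.
#' @param tumor,normal named expression vectors of the paired samples
#'   (fold-change mode).
#' @return list with `dark_genes` (the qualifying drivers) and `metrics`
#'   ([precision_recall_f] against the dark list, list mode only).
#' @export
dark_gene_metrics <- function(drivers, dark_list = NULL, tumor = NULL,
                              normal = NULL) {
  d <- if (inherits(drivers, "driver_set")) drivers$drivers else drivers
  if (!is.null(dark_list)) {
    dark <- intersect(d, dark_list)
    return(list(dark_genes = dark,
                metrics = precision_recall_f(d, dark_list)))
  }
  if (is.null(tumor) || is.null(normal))
    stop("fold-change mode needs paired tumor and normal expression")
  if (!all(d %in% names(tumor)) || !all(d %in% names(normal)))
    stop("driver gene missing from the paired expression vectors")
  lfc <- log2(abs(tumor[d]) / abs(normal[d]))
  dark <- d[is.finite(lfc) & abs(lfc) < 1]
  list(dark_genes = dark, metrics = NULL)
}
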