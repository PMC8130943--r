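# The evaluation-metric suite.

test_that("precision/recall/F follow the set arithmetic", {
  expect_equal(unname(precision_recall_f(c("a", "b"), c("a", "b"))),
               c(1, 1, 1))
  expect_equal(unname(precision_recall_f(c("a", "b"), c("c", "d"))),
               c(0, 0, 0))
  expect_equal(unname(precision_recall_f(c("a", "b"), c("b", "c"))),
               c(0.5, 0.5, 0.5))
  expect_equal(unname(precision_recall_f(character(0), "a")), c(0, 0, 0))
  expect_error(precision_recall_f("a", character(0)), "empty gold")
})

test_that("drug-combination AUC matches the rank-sum oracle", {
  targets <- ssc_gold("drug_target_map", drug_target_map = list(
    c1 = c("g1", "g2"), c2 = c("g1", "g3"), c3 = c("g4", "g5"),
    c4 = c("g6", "g7")))
  labels <- ssc_gold("combo_labels", combo_labels = c(
    c1 = "positive", c2 = "positive", c3 = "negative", c4 = "negative"))
  # drivers hit c1 twice, c2 once, c3/c4 never: perfect separation
  expect_equal(drug_combo_auc(c("g1", "g2"), targets, labels), 1)
  # tie between a positive and a negative combo counts one half
  labels2 <- ssc_gold("combo_labels", combo_labels = c(
    c1 = "positive", c2 = "negative", c3 = "positive", c4 = "negative"))
  sc <- c(2, 1, 0, 0)  # c3 ties c4 at 0
  w <- stats::wilcox.test(sc[c(1, 3)], sc[c(2, 4)],
                          exact = FALSE)$statistic
  expect_equal(drug_combo_auc(c("g1", "g2"), targets, labels2),
               unname(w) / 4)
  expect_error(drug_combo_auc("g1", targets, ssc_gold(
    "combo_labels", combo_labels = c(c1 = "positive", c2 = "positive",
                                     c3 = "positive", c4 = "positive"))),
    "negative")
})

test_that("label-independent scores give a null AUC near one half", {
  targets <- ssc_gold("drug_target_map", drug_target_map = stats::setNames(
    lapply(1:8, function(i) paste0("x", i)), paste0("c", 1:8)))
  aucs <- vapply(1:200, function(i) {
    lab <- withr::with_seed(i, sample(rep(c("positive", "negative"), 4)))
    drug_combo_auc(paste0("x", withr::with_seed(i + 500, sample(8, 3))),
                   targets,
                   ssc_gold("combo_labels",
                            combo_labels = stats::setNames(
                              lab, paste0("c", 1:8))))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(200))
})

test_that("Jaccard and controllability follow their formulas", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard("a", "b"), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_error(jaccard(character(0), character(0)), "empty")
  expect_equal(controllability(letters[1:3], letters[1:10]), 0.7)
  expect_equal(controllability(letters[1:10], letters[1:10]), 0)
  expect_gt(controllability("a", letters[1:10]),
            controllability(c("a", "b"), letters[1:10]))
  expect_error(controllability("z", letters[1:3]), "contained")
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  # N=10, K=5, n=4: P(X >= 4) = choose(5,4)*choose(5,0)/choose(10,4)
  p <- hypergeom_enrichment(paste0("g", 1:4), paste0("g", 1:5), 10)
  expect_equal(p, 5 / 210, tolerance = 1e-12)
  # full enumeration oracle on a universe of 12
  uni <- paste0("u", 1:12)
  gold <- uni[1:5]
  pred <- uni[c(1, 2, 6, 7)]
  k <- length(intersect(pred, gold))
  draws <- utils::combn(12, length(pred))
  tail_p <- mean(apply(draws, 2, function(s)
    sum(uni[s] %in% gold) >= k))
  expect_equal(hypergeom_enrichment(pred, gold, 12), tail_p,
               tolerance = 1e-12)
  # zero overlap is certain
  expect_equal(hypergeom_enrichment("u6", uni[1:3], 12) <= 1, TRUE)
  expect_equal(hypergeom_enrichment(uni, uni, 12), 1)
  expect_error(hypergeom_enrichment(uni, uni, 5), "universe")
})

test_that("z-scores and the significance machinery behave", {
  base <- c(1, 2, 3, 4, 5)
  expect_equal(zscore_vs_baseline(3, base), 0)
  expect_equal(zscore_vs_baseline(3 + sd(base), base), 1)
  expect_error(zscore_vs_baseline(1, c(2, 2)), "zero spread")
  expect_equal(z_critical(0.05), qnorm(0.95))
  expect_equal(significance_score(c(2, 2), c(2, 2)), 1)
  expect_equal(significance_score(c(4, 2), c(2, 1)), 2)
  expect_equal(significance_score(c(2, 1), c(1, 2)), 1.25)
  expect_warning(s <- significance_score(c(2, 5), c(1, 0)), "skipped")
  expect_equal(s, 2)
})

test_that("random baselines match size and degree constraints", {
  g <- gen_reference_network(25, "erdos_renyi", 0.15, directed = FALSE,
                             seed = 8)
  sets <- random_baseline(g, k = 5, mode = "uniform", n_reps = 20,
                          seed = 1)
  expect_true(all(vapply(sets, length, integer(1)) == 5))
  expect_error(random_baseline(g, k = 99, mode = "uniform"), "exceeds")
  # degree-preserved rewiring conserves every node's degree
  base <- random_baseline(g, mode = "degree_preserved", n_reps = 3,
                          seed = 2, method = "NCUA")
  expect_length(base, 3)
  expect_true(all(vapply(base, inherits, logical(1), "driver_set")))
})

test_that("degree-preserving rewiring keeps the degree sequence", {
  g <- gen_reference_network(20, "erdos_renyi", 0.2, directed = FALSE,
                             seed = 9)
  rg <- withr::with_seed(3, igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE,
                              niter = 10 * igraph::ecount(g))))
  expect_equal(igraph::degree(rg), igraph::degree(g))
})

test_that("centrality profile flags hubs and stays null for random sets", {
  g <- gen_reference_network(60, "preferential_attachment", 2,
                             directed = FALSE, seed = 10)
  hubs <- names(sort(igraph::degree(g), decreasing = TRUE))[1:5]
  prof <- centrality_profile(g, hubs, n_reps = 100, seed = 1)
  expect_equal(nrow(prof), 3)
  expect_setequal(prof$centrality,
                  c("degree", "closeness", "betweenness"))
  expect_lt(prof$p[prof$centrality == "degree"], 0.05)
  # a uniformly random set is usually unremarkable
  ps <- vapply(1:20, function(i) {
    rnd <- withr::with_seed(100 + i, sample(igraph::V(g)$name, 5))
    min(centrality_profile(g, rnd, n_reps = 50, seed = i)$p)
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.5)
})

test_that("ARI matches the mclust reference implementation", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               1)
  for (i in 1:20) {
    a <- withr::with_seed(i, sample(1:3, 12, replace = TRUE))
    b <- withr::with_seed(i + 50, sample(1:4, 12, replace = TRUE))
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  # degenerate all-singletons vs one cluster stays bounded at <= 0
  expect_lte(adjusted_rand_index(1:6, rep(1, 6)), 0)
  expect_error(adjusted_rand_index(1:3, 1:4), "same items")
})

test_that("dark-gene calls respect the strict two-fold boundary", {
  tum <- c(gA = 10, gB = 20, gC = 39.9, gD = 5)
  nor <- c(gA = 10, gB = 10, gC = 10, gD = 40)
  out <- dark_gene_metrics(c("gA", "gB", "gC", "gD"), tumor = tum,
                           normal = nor)
  # gA unchanged (dark), gB exactly 2-fold (excluded), gC just under
  # 4-fold? no: 3.99-fold -> |log2| > 1 (excluded), gD 8-fold down
  expect_setequal(out$dark_genes, "gA")
  out2 <- dark_gene_metrics(c("gA", "gB"), tumor = c(gA = 3, gB = 3),
                            normal = c(gA = 3, gB = 3))
  expect_setequal(out2$dark_genes, c("gA", "gB"))
  lst <- dark_gene_metrics(c("gA", "gB"), dark_list = c("gB", "gX"))
  expect_equal(lst$dark_genes, "gB")
  expect_equal(unname(lst$metrics["precision"]), 0.5)
  expect_error(dark_gene_metrics("gA", tumor = c(gA = 1)), "paired")
})

test_that("bounded metrics stay in the unit interval on random inputs", {
  for (i in 1:30) {
    uni <- paste0("g", 1:15)
    a <- withr::with_seed(i, sample(uni, sample(1:10, 1)))
    b <- withr::with_seed(i + 99, sample(uni, sample(1:10, 1)))
    prf <- precision_recall_f(a, b)
    expect_true(all(prf >= 0 & prf <= 1))
    expect_true(jaccard(a, b) >= 0 && jaccard(a, b) <= 1)
    p <- hypergeom_enrichment(a, b, 15)
    expect_true(p >= 0 && p <= 1)
    expect_true(controllability(a, uni) >= 0 &&
                  controllability(a, uni) <= 1)
  }
})
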