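# Single-sample network statistics and the network-construction step.

test_that("CSN null parameters follow the closed form", {
  # sqrt(10*10*90*90 / (100^4 * 99))
  p <- csn_null_params(100, 10)
  expect_equal(p$mu, 0)
  expect_equal(p$sigma, 0.0090453403373329, tolerance = 1e-12)
  expect_error(csn_null_params(10, 10), "smaller than n")
})

test_that("CSN statistic detects dependence and flags constant genes", {
  n <- 100
  ids <- paste0("s", seq_len(n))
  x <- withr::with_seed(1, rnorm(n))
  m <- rbind(a = x, b = 2 * x, c = withr::with_seed(2, rnorm(n)),
             d = rep(1, n))
  colnames(m) <- ids
  e <- ssc_expression(m)
  dep <- csn_statistic(e, "s1", "a", "b")
  expect_equal(dep$n_x, 10)  # 0.1 * 100
  # identical boxes: n_xy = n_x, the largest attainable statistic
  expect_equal(dep$statistic, 10 / n - (10 / n)^2)
  expect_lt(dep$p_value, 0.01)
  flat <- csn_statistic(e, "s1", "a", "d")
  expect_true(is.na(flat$statistic))
  expect_equal(flat$p_value, 1)
})

test_that("CSN statistic is calibrated to its normal null at n = 500", {
  n <- 500
  stats <- vapply(1:200, function(i) {
    m <- withr::with_seed(i, matrix(runif(2 * n), 2, n,
                                    dimnames = list(c("a", "b"),
                                                    paste0("s", 1:n))))
    csn_statistic(ssc_expression(m), "s1", "a", "b")$statistic
  }, numeric(1))
  null <- csn_null_params(n, ceiling(0.1 * n))
  expect_lt(abs(mean(stats)), 3 * sd(stats) / sqrt(200))
  expect_gt(sd(stats) / null$sigma, 0.8)
  expect_lt(sd(stats) / null$sigma, 1.25)
})

test_that("SSN Z matches brute-force recomputation and handles edge cases", {
  for (seed in 1:20) {
    d <- withr::with_seed(seed, list(x = rnorm(8), y = rnorm(8),
                                     nx = rnorm(1), ny = rnorm(1)))
    m <- rbind(gx = d$x, gy = d$y)
    colnames(m) <- paste0("s", 1:8)
    r <- ssn_statistic(m, c(gx = d$nx, gy = d$ny), "gx", "gy")
    expect_equal(r$statistic, oracle_ssn_z(d$x, d$y, d$nx, d$ny),
                 tolerance = 1e-12)
    expect_equal(r$p_value, pnorm(r$statistic, lower.tail = FALSE))
  }
  # a new point that leaves the correlation untouched gives Z = 0
  m0 <- rbind(gx = c(-1, 1, -1, 1), gy = c(-1, -1, 1, 1))
  colnames(m0) <- paste0("s", 1:4)
  r0 <- ssn_statistic(m0, c(gx = 0, gy = 0), "gx", "gy")
  expect_equal(r0$delta, 0)
  expect_equal(r0$statistic, 0)
  # perfectly correlated reference: degenerate denominator is flagged
  m1 <- rbind(gx = c(1, 2, 3, 4), gy = c(2, 4, 6, 8))
  colnames(m1) <- paste0("s", 1:4)
  expect_true(is.na(ssn_statistic(m1, c(gx = 0, gy = 1), "gx",
                                  "gy")$p_value))
})

test_that("SPCC scores average to the Pearson correlation", {
  m <- withr::with_seed(3, matrix(rnorm(8 * 30), 8, 30,
                                  dimnames = list(paste0("g", 1:8),
                                                  paste0("s", 1:30))))
  e <- ssc_expression(m)
  pairs <- rbind(c("g1", "g2"), c("g3", "g7"), c("g4", "g8"))
  sc <- sapply(colnames(m), function(s)
    spcc_scores(e, s, pairs)$statistic)
  for (i in 1:3)
    expect_equal(mean(sc[i, ]), cor(m[pairs[i, 1], ], m[pairs[i, 2], ]),
                 tolerance = 1e-10)
})

test_that("SPCC hand arithmetic and zero-variance flagging", {
  m <- rbind(gi = c(1, 2, 3), gj = c(2, 2, 5), gz = c(7, 7, 7))
  colnames(m) <- paste0("s", 1:3)
  e <- ssc_expression(m)
  sc <- spcc_scores(e, "s1", rbind(c("gi", "gj"), c("gi", "gz")))
  # z_i(s1) = (1-2)/sqrt(2/3), z_j(s1) = (2-3)/sqrt(2) -> product sqrt(3)/2
  expect_equal(sc$statistic[1], sqrt(3) / 2, tolerance = 1e-12)
  expect_true(is.na(sc$statistic[2]))
  # a sample sitting at the group mean scores 0 on all its pairs
  sc2 <- spcc_scores(e, "s2", rbind(c("gi", "gj")))
  expect_equal(sc2$statistic[1], 0)
})

test_that("adaptive threshold is mean + 2 sd with degenerate warning", {
  expect_equal(adaptive_threshold(c(-1, 0, 1)), 2)  # mean 0, sd 1
  expect_warning(w <- adaptive_threshold(c(1, 1, 1, 1)), "degenerate")
  expect_equal(w, 1)
  expect_error(adaptive_threshold(3), "at least 2")
  # about 2.3% of standard-normal scores exceed mean + 2 sd
  s <- withr::with_seed(8, rnorm(2e4))
  frac <- mean(s > adaptive_threshold(s))
  expect_gt(frac, 0.015)
  expect_lt(frac, 0.033)
})

test_that("LIONESS interpolation identity and brute-force agreement", {
  # perfectly stable aggregate: every leave-one-out PCC equals the full
  x <- c(1, 2, 3, 4, 5)
  m <- rbind(gx = x, gy = 2 * x + 1, gz = c(2, 1, 4, 3, 6))
  colnames(m) <- paste0("s", 1:5)
  e <- ssc_expression(m)
  for (s in colnames(m)) {
    sc <- lioness_scores(e, s, rbind(c("gx", "gy")))
    expect_equal(sc$statistic, 1, tolerance = 1e-12)
  }
  # N = 4 toy vectors against direct recomputation of both PCC terms
  m2 <- withr::with_seed(5, matrix(rnorm(3 * 4), 3, 4,
                                   dimnames = list(c("a", "b", "c"),
                                                   paste0("s", 1:4))))
  e2 <- ssc_expression(m2)
  for (k in 1:4) {
    sc <- lioness_scores(e2, paste0("s", k), rbind(c("a", "c")))
    full <- cor(m2["a", ], m2["c", ])
    loo <- cor(m2["a", -k], m2["c", -k])
    expect_equal(sc$statistic, 4 * (full - loo) + loo, tolerance = 1e-12)
  }
})

test_that("paired SSN keeps edges significant in exactly one of the pair", {
  # synthetic p-value scenario driven through the XOR rule directly:
  # build data where the tumor sample perturbs one planted edge strongly
  ref <- gen_reference_network(16, "erdos_renyi", 0.35, seed = 6)
  sim <- gen_expression(ref, 150, 3,
                        spec = truth_spec(n_planted = 4, r_base = 0.85,
                                          r_alt = -0.85,
                                          perturb_frac = 1), seed = 7)
  nets <- build_sample_networks(sim$expr, "pairedSSN", ref = ref,
                                direction = "undirected")
  expect_length(nets, 3)
  refs <- reference_samples(sim$expr)
  ref_m <- sim$expr$values[, refs]
  for (s in names(nets)) {
    lab <- sim$expr$labels
    mate <- lab$sample_id[lab$pair_id %in%
                            lab$pair_id[lab$sample_id == s] &
                            lab$group == "reference"][1]
    for (i in seq_len(nrow(nets[[s]]$edges))) {
      ed <- nets[[s]]$edges[i, ]
      pt <- ssn_statistic(ref_m, sim$expr$values[, s], ed$source,
                          ed$target)$p_value
      pn <- ssn_statistic(ref_m, sim$expr$values[, mate], ed$source,
                          ed$target)$p_value
      expect_true(xor(pt < 0.05, pn < 0.05))
    }
  }
})

test_that("SSN networks recover planted differential edges", {
  ref <- gen_reference_network(30, "erdos_renyi", 0.2, seed = 2)
  hits <- 0; tot <- 0; fp <- 0; ftot <- 0
  for (seed in 1:25) {
    sim <- gen_expression(ref, 200, 1,
                          spec = truth_spec(n_planted = 5, r_base = 0.8,
                                            r_alt = 0), seed = seed)
    nets <- build_sample_networks(sim$expr, "SSN", ref = ref,
                                  direction = "undirected")
    s <- names(nets)[1]
    got <- paste(pmin(nets[[s]]$edges$source, nets[[s]]$edges$target),
                 pmax(nets[[s]]$edges$source, nets[[s]]$edges$target))
    pe <- sim$truth$perturbed[[s]]
    want <- paste(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2]))
    hits <- hits + sum(want %in% got); tot <- tot + length(want)
    # non-planted candidate edges are detected at about the alpha rate
    all_pairs <- candidate_pairs <- igraph::as_edgelist(ref)
    pl <- paste(pmin(sim$truth$planted_edges[, 1],
                     sim$truth$planted_edges[, 2]),
                pmax(sim$truth$planted_edges[, 1],
                     sim$truth$planted_edges[, 2]))
    others <- setdiff(paste(pmin(all_pairs[, 1], all_pairs[, 2]),
                            pmax(all_pairs[, 1], all_pairs[, 2])), pl)
    fp <- fp + sum(others %in% got); ftot <- ftot + length(others)
  }
  # detection of a flipped r = 0.8 -> 0 edge from a single added sample
  # is limited by the one-point influence on the PCC; it must beat the
  # background rate decisively but is far from certain per edge
  expect_gt(hits / tot, 0.25)
  expect_lt(fp / ftot, 0.15)
  expect_gt(hits / tot, 3 * fp / ftot)
})

test_that("reference filtering respects orientation and is idempotent", {
  ref <- igraph::make_graph(c("a", "b", "c", "b", "c", "d", "d", "c"),
                            directed = TRUE)
  e <- data.frame(source = c("a", "b", "c", "x"),
                  target = c("b", "c", "d", "y"),
                  statistic = 1:4, p_value = 0.01)
  net <- sample_network("s", e, "SSN")
  fd <- apply_reference_filter(net, ref, "directed")
  key <- paste(fd$edges$source, fd$edges$target)
  expect_setequal(key, c("a b", "c b", "c d", "d c"))  # b-c reversed,
  # c-d bidirected, x-y dropped
  fd2 <- apply_reference_filter(fd, ref, "directed")
  expect_setequal(paste(fd2$edges$source, fd2$edges$target), key)
  fu <- apply_reference_filter(net, ref, "undirected")
  expect_equal(nrow(fu$edges), 3)
  # empty intersection warns, does not error
  lone <- sample_network("s", e[4, ], "SSN")
  expect_warning(out <- apply_reference_filter(lone, ref, "directed"),
                 "no edges")
  expect_equal(nrow(out$edges), 0)
})

test_that("network deconvolution applies the spectral map", {
  z <- matrix(0, 4, 4)
  expect_identical(network_deconvolution(z), z)
  # rank-1 with scaled eigenvalue 0.5: output eigenvalue 1/3
  v <- c(1, 1, 0, 0) / sqrt(2)
  m <- outer(v, v)  # eigenvalue 1
  out <- network_deconvolution(m, scaling = 1 / 3)
  expect_equal(max(eigen(out, symmetric = TRUE)$values), 1 / 3,
               tolerance = 1e-10)
  r <- withr::with_seed(4, matrix(rnorm(25), 5))
  sym <- r + t(r)
  nd <- network_deconvolution(sym, 0.5)
  expect_equal(nd, t(nd), tolerance = 1e-10)
  expect_error(network_deconvolution(r), "symmetric")
})

test_that("degree matrix counts incident partners per sample", {
  mk <- function(s, src, tgt)
    sample_network(s, data.frame(source = src, target = tgt,
                                 statistic = rep(1, length(src)),
                                 p_value = rep(0.01, length(src))), "CSN")
  uni <- c("a", "b", "c", "d")
  nets <- list(mk("s1", c("a", "b", "c"), c("b", "c", "a")),  # triangle
               mk("s2", character(0), character(0)))
  dm <- degree_matrix(nets, uni)
  expect_equal(dm[, "s1"], c(a = 2, b = 2, c = 2, d = 0))
  expect_equal(sum(dm[, "s2"]), 0)
  expect_equal(colSums(dm), c(s1 = 6, s2 = 0))  # 2 x edge count
})

test_that("score-thresholded methods keep only extreme edges", {
  ref <- gen_reference_network(20, "erdos_renyi", 0.3, seed = 9)
  sim <- gen_expression(ref, 60, 3, spec = truth_spec(n_planted = 4),
                        seed = 10)
  for (meth in c("SPCC", "LIONESS")) {
    nets <- build_sample_networks(sim$expr, meth, ref = ref,
                                  direction = "undirected")
    expect_length(nets, 3)
    for (s in names(nets)) {
      scores <- if (meth == "SPCC")
        spcc_scores(sim$expr, s)$statistic
      else lioness_scores(sim$expr, s)$statistic
      # kept edges are a small extreme fraction of the score cloud
      expect_lt(nrow(nets[[s]]$edges),
                0.3 * sum(is.finite(scores)))
    }
  }
})
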