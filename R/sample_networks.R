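# Construction of single-sample co-expression networks: per-edge statistics
# (CSN, SSN, paired SSN, SPCC, LIONESS), adaptive score thresholding,
# reference-direction filtering, optional network deconvolution, and the
# gene network-degree matrix.

expr_values <- function(expr) {
  if (inherits(expr, "ssc_expression")) expr$values
  else if (is.matrix(expr)) expr
  else stop("expected an ssc_expression or a genes x samples matrix")
}

# Candidate unordered gene pairs: reference-network edges by default
# (the state-transition network is their intersection with significant
# differential co-expression), or all pairs when no prior is given.
candidate_pairs <- function(genes, ref = NULL, all_pairs = is.null(ref)) {
  if (all_pairs) {
    idx <- utils::combn(genes, 2)
    return(cbind(idx[1, ], idx[2, ]))
  }
  el <- igraph::as_edgelist(ref, names = TRUE)
  el <- el[el[, 1] %in% genes & el[, 2] %in% genes & el[, 1] != el[, 2], ,
           drop = FALSE]
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  keep <- !duplicated(paste(a, b, sep = "\r"))
  cbind(a[keep], b[keep])
}

#' Null parameters of the cell-specific network statistic
#'
#' Under independence of the two genes the box statistic is approximately
#' normal with mean 0 and standard deviation
#' `sqrt(nx * ny * (n - nx) * (n - ny) / (n^4 * (n - 1)))`.
#'
#' @param n number of samples.
#' @param n_x,n_y neighborhood box sizes (counts, < n).
#' @return list with `n`, `n_x`, `n_y`, `mu` (= 0) and `sigma`.
#' @export
csn_null_params <- function(n, n_x, n_y = n_x) {
  if (n_x >= n || n_y >= n) stop("box sizes must be smaller than n")
  sigma <- sqrt(n_x * n_y * (n - n_x) * (n - n_y) / (n^4 * (n - 1)))
  list(n = n, n_x = n_x, n_y = n_y, mu = 0, sigma = sigma)
}

# Index set of the `size` samples nearest to the k-th sample's own value,
# ties broken by sample order. The target sample is the box center and is
# not counted among the neighbors: counting it would force the
# intersection box to be non-empty and bias the null mean upward.
csn_box <- function(v, k, size) {
  ord <- order(abs(v - v[k]), seq_along(v))
  ord <- ord[ord != k]
  ord[seq_len(size)]
}

#' Cell-specific network (CSN) edge statistic
#'
#' For sample `k` and genes `x`, `y`, draws a box of the `box_fraction * n`
#' samples whose expression is nearest to the sample's own value on each
#' axis and tests whether the intersection box is more populated than
#' independence predicts: `rho = n_xy/n - (n_x/n) (n_y/n)`. The p-value is
#' the upper-tail normal probability under the independence null
#' ([csn_null_params]).
#'
#' @param expr an [ssc_expression] (all samples are used as the data
#'   cloud).
#' @param sample sample id.
#' @param gene_x,gene_y gene ids.
#' @param box_fraction fraction of samples per box (default 0.1, the
#'   conventional predetermined box size).
#' @return list with `statistic`, `p_value`, and the box sizes. A constant
#'   gene vector makes the boxes ill-defined: the edge is flagged with
#'   `statistic = NA`, `p_value = 1`.
#' @export
csn_statistic <- function(expr, sample, gene_x, gene_y, box_fraction = 0.1) {
  m <- expr_values(expr)
  n <- ncol(m)
  if (box_fraction * n < 1) stop("box_fraction * n must be >= 1")
  k <- match(sample, colnames(m))
  if (is.na(k)) stop("unknown sample '", sample, "'")
  x <- m[gene_x, ]; y <- m[gene_y, ]
  size <- ceiling(box_fraction * n)
  if (size >= n) stop("box size must be smaller than n")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(statistic = NA_real_, p_value = 1, n_x = size, n_y = size))
  bx <- csn_box(x, k, size)
  by <- csn_box(y, k, size)
  nxy <- length(intersect(bx, by))
  stat <- nxy / n - (size / n) * (size / n)
  null <- csn_null_params(n, size, size)
  p <- stats::pnorm(stat, mean = 0, sd = null$sigma, lower.tail = FALSE)
  list(statistic = stat, p_value = p, n_x = size, n_y = size)
}

#' Single-sample network (SSN) edge statistic
#'
#' Perturbs the reference group with one new sample and measures the
#' change in Pearson correlation: `dPCC = |PCC_{n+1} - PCC_n|`, with
#' `Z = dPCC / ((1 - PCC_n^2) / (n - 1))` and an upper-tail normal
#' p-value.
#'
#' @param ref_expr genes x samples matrix (or [ssc_expression]) of the
#'   reference group (n >= 3 samples).
#' @param new_sample named numeric vector with the new sample's expression
#'   (must include `gene_x` and `gene_y`).
#' @param gene_x,gene_y gene ids.
#' @return list with `pcc_ref`, `pcc_perturbed`, `delta`, `statistic`
#'   (the Z value), `p_value`. A reference correlation of exactly +-1 makes
#'   the denominator degenerate: the edge is flagged with `p_value = NA`.
#' @export
ssn_statistic <- function(ref_expr, new_sample, gene_x, gene_y) {
  m <- expr_values(ref_expr)
  n <- ncol(m)
  if (n < 3) stop("reference group needs at least 3 samples")
  x <- m[gene_x, ]; y <- m[gene_y, ]
  pcc_n <- stats::cor(x, y)
  pcc_n1 <- stats::cor(c(x, new_sample[[gene_x]]),
                       c(y, new_sample[[gene_y]]))
  delta <- abs(pcc_n1 - pcc_n)
  if (!is.finite(pcc_n) || abs(pcc_n) >= 1 - 1e-12)
    return(list(pcc_ref = pcc_n, pcc_perturbed = pcc_n1, delta = delta,
                statistic = NA_real_, p_value = NA_real_))
  z <- delta / ((1 - pcc_n^2) / (n - 1))
  list(pcc_ref = pcc_n, pcc_perturbed = pcc_n1, delta = delta,
       statistic = z, p_value = stats::pnorm(z, lower.tail = FALSE))
}

#' Single-sample PCC decomposition (SPCC) scores
#'
#' Decomposes the Pearson correlation into per-sample additive elements:
#' the score of pair (i, j) in sample `s` is the product of the two genes'
#' z-scores, using the group mean and the population (divide-by-n)
#' standard deviation, so that the scores of a pair average exactly to its
#' PCC across samples.
#'
#' @param expr an [ssc_expression].
#' @param sample sample id.
#' @param pairs optional 2-column character matrix of gene pairs; defaults
#'   to all pairs.
#' @return data.frame with `source`, `target`, `statistic` (NA for pairs
#'   involving a zero-variance gene, which are flagged and excluded from
#'   thresholding), `p_value` (all NA; SPCC edges are score-thresholded).
#' @export
spcc_scores <- function(expr, sample, pairs = NULL) {
  m <- expr_values(expr)
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (is.null(pairs)) pairs <- candidate_pairs(rownames(m), all_pairs = TRUE)
  mu <- rowMeans(m)
  sig <- sqrt(rowMeans((m - mu)^2))
  z <- (m[, sample] - mu) / sig
  z[sig == 0] <- NA_real_
  data.frame(source = pairs[, 1], target = pairs[, 2],
             statistic = z[pairs[, 1]] * z[pairs[, 2]],
             p_value = NA_real_, stringsAsFactors = FALSE)
}

#' LIONESS per-sample edge scores
#'
#' Linear interpolation between the aggregate estimate on all `N` samples
#' and the leave-one-out estimate without sample `s`:
#' `e_s = N (e_N - e_{N-s}) + e_{N-s}`, with the Pearson correlation as
#' the aggregate network estimator.
#'
#' @param expr an [ssc_expression] with N >= 3 samples.
#' @param sample sample id.
#' @param pairs optional 2-column character matrix of gene pairs.
#' @return data.frame with `source`, `target`, `statistic`, `p_value`
#'   (NA; LIONESS edges are score-thresholded). Pairs with a zero-variance
#'   gene in the full or leave-one-out data are flagged NA.
#' @export
lioness_scores <- function(expr, sample, pairs = NULL) {
  m <- expr_values(expr)
  n <- ncol(m)
  if (n < 3) stop("need at least 3 samples")
  if (is.null(pairs)) pairs <- candidate_pairs(rownames(m), all_pairs = TRUE)
  k <- match(sample, colnames(m))
  if (is.na(k)) stop("unknown sample '", sample, "'")
  full <- suppressWarnings(stats::cor(t(m)))
  loo <- suppressWarnings(stats::cor(t(m[, -k, drop = FALSE])))
  e_full <- full[cbind(pairs[, 1], pairs[, 2])]
  e_loo <- loo[cbind(pairs[, 1], pairs[, 2])]
  data.frame(source = pairs[, 1], target = pairs[, 2],
             statistic = n * (e_full - e_loo) + e_loo,
             p_value = NA_real_, stringsAsFactors = FALSE)
}

#' Adaptive score threshold
#'
#' The cut used to turn SPCC/LIONESS score distributions into edges:
#' `w = mean(S) + 2 sd(S)` over the score distribution `S`.
#'
#' @param scores numeric vector of at least 2 finite scores.
#' @return the threshold value.
#' @export
adaptive_threshold <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2) stop("need at least 2 finite scores")
  s <- stats::sd(scores)
  if (s == 0) warning("degenerate score spread: all scores identical")
  mean(scores) + 2 * s
}

ssn_edges_for_sample <- function(ref_m, new_sample, pairs) {
  n <- ncol(ref_m)
  cx <- ref_m[pairs[, 1], , drop = FALSE]
  cy <- ref_m[pairs[, 2], , drop = FALSE]
  # row-wise PCC of the reference group and of the group + new sample
  row_pcc <- function(a, b) {
    a <- a - rowMeans(a); b <- b - rowMeans(b)
    rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
  }
  pcc_n <- row_pcc(cx, cy)
  pcc_n1 <- row_pcc(cbind(cx, new_sample[pairs[, 1]]),
                    cbind(cy, new_sample[pairs[, 2]]))
  delta <- abs(pcc_n1 - pcc_n)
  denom <- (1 - pcc_n^2) / (n - 1)
  z <- ifelse(abs(pcc_n) >= 1 - 1e-12 | !is.finite(pcc_n), NA_real_,
              delta / denom)
  data.frame(source = pairs[, 1], target = pairs[, 2], statistic = z,
             p_value = stats::pnorm(z, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

threshold_scores <- function(stats_df) {
  ok <- is.finite(stats_df$statistic)
  w <- adaptive_threshold(abs(stats_df$statistic[ok]))
  stats_df[ok & abs(stats_df$statistic) >= w, , drop = FALSE]
}

#' Build sample-specific state-transition networks
#'
#' Runs one construction method over every case sample and returns one
#' [sample_network] per sample. CSN and SSN edges pass a p-value cut
#' (defaults 0.01 and 0.05 respectively); paired SSN keeps edges
#' significant at 0.05 in exactly one of the matched tumor/normal
#' single-sample networks (XOR rule); SPCC and LIONESS keep edges whose
#' absolute score exceeds the adaptive threshold ([adaptive_threshold])
#' computed over that sample's absolute scores. When a reference network
#' is supplied, candidate pairs are restricted to its edges and the output
#' is passed through [apply_reference_filter].
#'
#' @param expr an [ssc_expression]; SSN and paired SSN require group
#'   labels (and paired SSN additionally `pair_id`s).
#' @param method one of `"CSN"`, `"SSN"`, `"pairedSSN"`, `"SPCC"`,
#'   `"LIONESS"`.
#' @param ref optional reference network (igraph) restricting and
#'   orienting candidate edges.
#' @param alpha p-value threshold for CSN/SSN/pairedSSN (defaults: CSN
#'   0.01, SSN and pairedSSN 0.05).
#' @param box_fraction CSN box fraction.
#' @param direction `"directed"` or `"undirected"` reference filtering.
#' @param deconvolve apply [network_deconvolution] to each sample's
#'   statistic matrix before thresholding; deconvolved scores are cut by
#'   the adaptive threshold.
#' @param all_pairs enumerate all gene pairs even when `ref` is given.
#' @return list of [sample_network] objects, one per case sample.
#' @export
build_sample_networks <- function(expr,
                                  method = c("CSN", "SSN", "pairedSSN",
                                             "SPCC", "LIONESS"),
                                  ref = NULL, alpha = NULL,
                                  box_fraction = 0.1,
                                  direction = c("directed", "undirected"),
                                  deconvolve = FALSE, all_pairs = FALSE) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  if (is.null(alpha)) alpha <- if (method == "CSN") 0.01 else 0.05
  m <- expr_values(expr)
  genes <- rownames(m)
  pairs <- candidate_pairs(genes, ref, all_pairs = all_pairs || is.null(ref))
  cases <- case_samples(expr)
  if (method %in% c("SSN", "pairedSSN")) {
    if (is.null(expr$labels))
      stop(method, " requires sample group labels (reference group)")
    refs <- reference_samples(expr)
    if (length(refs) < 3) stop("reference group needs at least 3 samples")
    ref_m <- m[, refs, drop = FALSE]
  }
  nets <- lapply(cases, function(s) {
    edges <- switch(method,
      CSN = {
        st <- vapply(seq_len(nrow(pairs)), function(i) {
          r <- csn_statistic(expr, s, pairs[i, 1], pairs[i, 2],
                             box_fraction)
          c(r$statistic, r$p_value)
        }, numeric(2))
        data.frame(source = pairs[, 1], target = pairs[, 2],
                   statistic = st[1, ], p_value = st[2, ],
                   stringsAsFactors = FALSE)
      },
      SSN = ssn_edges_for_sample(ref_m, m[, s], pairs),
      pairedSSN = {
        pid <- expr$labels$pair_id[expr$labels$sample_id == s]
        mate <- if (length(pid) && !is.na(pid))
          expr$labels$sample_id[expr$labels$pair_id %in% pid &
                                  expr$labels$group == "reference"]
        else character(0)
        if (!length(mate))
          stop("pairedSSN: case sample '", s, "' has no paired ",
               "reference sample")
        tum <- ssn_edges_for_sample(ref_m, m[, s], pairs)
        nor <- ssn_edges_for_sample(ref_m, m[, mate[1]], pairs)
        sig_t <- !is.na(tum$p_value) & tum$p_value < alpha
        sig_n <- !is.na(nor$p_value) & nor$p_value < alpha
        tum$keep <- xor(sig_t, sig_n)
        tum
      },
      SPCC = spcc_scores(expr, s, pairs),
      LIONESS = lioness_scores(expr, s, pairs))
    if (deconvolve) {
      sm <- matrix(0, length(genes), length(genes),
                   dimnames = list(genes, genes))
      val <- ifelse(is.finite(edges$statistic), edges$statistic, 0)
      sm[cbind(edges$source, edges$target)] <- val
      sm[cbind(edges$target, edges$source)] <- val
      nd <- network_deconvolution(sm)
      edges$statistic <- nd[cbind(edges$source, edges$target)]
      edges$p_value <- NA_real_
    }
    kept <- if (method == "pairedSSN" && !deconvolve) {
      k <- edges[edges$keep, setdiff(names(edges), "keep"), drop = FALSE]
      k
    } else if (method %in% c("CSN", "SSN") && !deconvolve) {
      edges[!is.na(edges$p_value) & edges$p_value < alpha, , drop = FALSE]
    } else {
      threshold_scores(edges)
    }
    net <- sample_network(s, kept, method,
                          reference_tag = if (!is.null(ref)) "reference")
    if (!is.null(ref)) net <- apply_reference_filter(net, ref, direction)
    net
  })
  names(nets) <- cases
  nets
}

#' Filter a sample network against the reference interaction network
#'
#' Co-expression edges are unordered and are treated as bidirected
#' candidates; the reference network decides which orientations survive.
#' In directed mode an edge between a and b is kept once per orientation
#' present in the reference (both directions give two directed edges); in
#' undirected mode the unordered pair is kept if either orientation
#' exists.
#'
#' @param net a [sample_network].
#' @param ref reference network (igraph).
#' @param mode `"directed"` or `"undirected"`.
#' @return a filtered [sample_network]; empty result warns but is not an
#'   error.
#' @export
apply_reference_filter <- function(net, ref,
                                   mode = c("directed", "undirected")) {
  mode <- match.arg(mode)
  ref_el <- igraph::as_edgelist(ref, names = TRUE)
  if (!igraph::is_directed(ref))
    ref_el <- rbind(ref_el, ref_el[, 2:1, drop = FALSE])
  ref_key <- paste(ref_el[, 1], ref_el[, 2], sep = "\r")
  e <- net$edges
  fwd <- paste(e$source, e$target, sep = "\r") %in% ref_key
  rev <- paste(e$target, e$source, sep = "\r") %in% ref_key
  if (mode == "undirected") {
    out <- e[fwd | rev, , drop = FALSE]
    res <- sample_network(net$sample_id, out, net$method, directed = FALSE,
                          reference_tag = net$reference_tag)
  } else {
    keep_f <- e[fwd, , drop = FALSE]
    keep_r <- e[rev, , drop = FALSE]
    if (nrow(keep_r)) {
      tmp <- keep_r$source; keep_r$source <- keep_r$target
      keep_r$target <- tmp
    }
    out <- rbind(keep_f, keep_r)
    out <- out[!duplicated(paste(out$source, out$target, sep = "\r")), ,
               drop = FALSE]
    res <- sample_network(net$sample_id, out, net$method, directed = TRUE,
                          reference_tag = net$reference_tag)
  }
  if (!nrow(res$edges))
    warning("reference filter left no edges for sample '", net$sample_id,
            "'")
  res
}

#' Network deconvolution
#'
#' Removes transitive (indirect-path) contributions from a symmetric
#' association matrix by mapping each eigenvalue of the rescaled matrix
#' through `lambda / (1 + lambda)`. The input is first linearly rescaled
#' so that the largest transformed eigenvalue equals `scaling`, keeping
#' the inverse series convergent.
#'
#' @param assoc square symmetric finite matrix.
#' @param scaling target largest output eigenvalue, in (0, 1).
#' @return symmetric matrix of the same dimension (direct-effect scores).
#' @export
network_deconvolution <- function(assoc, scaling = 0.5) {
  if (!is.matrix(assoc) || nrow(assoc) != ncol(assoc))
    stop("association matrix must be square")
  if (max(abs(assoc - t(assoc))) > 1e-8)
    stop("association matrix must be symmetric")
  if (scaling <= 0 || scaling >= 1) stop("scaling must be in (0,1)")
  if (all(assoc == 0)) return(assoc)
  eig <- eigen((assoc + t(assoc)) / 2, symmetric = TRUE)
  lam <- eig$values
  lp <- max(lam, 0); ln <- abs(min(lam, 0))
  # rescale so the largest transformed eigenvalue is `scaling` and the
  # most negative stays above the -1 pole
  alpha <- Inf
  if (lp > 0) alpha <- min(alpha, scaling / ((1 - scaling) * lp))
  if (ln > 0) alpha <- min(alpha, scaling / ((1 + scaling) * ln))
  if (!is.finite(alpha)) alpha <- 1
  lam2 <- alpha * lam / (1 + alpha * lam)
  out <- eig$vectors %*% (lam2 * t(eig$vectors))
  dimnames(out) <- dimnames(assoc)
  (out + t(out)) / 2
}

#' Gene network-degree matrix
#'
#' Replaces expression values by connectivity: entry (g, s) is the number
#' of distinct partners of gene g in sample s's network, orientation
#' ignored. Used in place of the raw expression matrix for cell
#' clustering.
#'
#' @param nets list of [sample_network] objects.
#' @param gene_universe character vector of genes indexing the rows.
#' @return numeric matrix, genes x samples.
#' @export
degree_matrix <- function(nets, gene_universe) {
  out <- matrix(0, length(gene_universe), length(nets),
                dimnames = list(gene_universe,
                                vapply(nets, `[[`, "", "sample_id")))
  for (j in seq_along(nets)) {
    e <- nets[[j]]$edges
    if (!nrow(e)) next
    a <- pmin(e$source, e$target); b <- pmax(e$source, e$target)
    keep <- !duplicated(paste(a, b, sep = "\r"))
    tab <- table(c(a[keep], b[keep]))
    idx <- intersect(names(tab), gene_universe)
    out[idx, j] <- as.numeric(tab[idx])
  }
  out
}
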