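# End-to-end benchmark harness: enumerate construction x reference x
# control workflows, score every sample with the metric suite, and
# assemble consensus and robustness summaries.

#' Enumerate analysis workflows
#'
#' The cross product of sample-network construction methods and
#' structural control methods (optionally per reference network); the
#' canonical grid of 4 x 4 methods yields 16 workflows.
#'
#' @param construction_methods construction method tags.
#' @param control_methods control method tags.
#' @param reference_tags optional reference-network names.
#' @return data.frame with one row per workflow.
#' @export
enumerate_workflows <- function(construction_methods = c("CSN", "SSN",
                                                         "SPCC",
                                                         "LIONESS"),
                                control_methods = c("MMS", "MDS", "DFVS",
                                                    "NCUA"),
                                reference_tags = NULL) {
  if (is.null(reference_tags))
    return(expand.grid(construction = construction_methods,
                       control = control_methods,
                       stringsAsFactors = FALSE))
  expand.grid(construction = construction_methods,
              reference = reference_tags,
              control = control_methods, stringsAsFactors = FALSE)
}

drivers_for_net <- function(net, control) {
  if (!nrow(net$edges)) return(NULL)
  tryCatch(find_drivers(net, control),
           error = function(e) NULL)
}

#' Run the full evaluation benchmark
#'
#' Builds sample-specific networks for every construction method and
#' reference network, identifies drivers with every control method, and
#' scores each sample against the gold standards: F-measure (with
#' precision/recall), drug-combination AUC, controllability,
#' hypergeometric enrichment. Adds consensus (Jaccard between control
#' methods on the same networks) and robustness (Jaccard between
#' reference networks for the same method) summaries. Per-workflow
#' failures (e.g. an empty sample network) are isolated and recorded,
#' not fatal.
#'
#' @param expr an [ssc_expression] with group labels where SSN needs
#'   them.
#' @param ref_nets named list of reference networks (igraph).
#' @param construction_methods,control_methods method tags.
#' @param gold_genes optional [ssc_gold] gene list.
#' @param drug_targets,combo_labels optional [ssc_gold] objects for AUC.
#' @param alpha,box_fraction,direction passed to
#'   [build_sample_networks].
#' @return object of class `ssc_report`: `records` (long data.frame:
#'   sample, construction, reference, control, metric, value),
#'   `consensus`, `robustness`, `workflows`, `failures`.
#' @export
run_benchmark <- function(expr, ref_nets,
                          construction_methods = c("CSN", "SSN", "SPCC",
                                                   "LIONESS"),
                          control_methods = c("MMS", "MDS", "DFVS",
                                              "NCUA"),
                          gold_genes = NULL, drug_targets = NULL,
                          combo_labels = NULL, alpha = NULL,
                          box_fraction = 0.1, direction = "directed") {
  stopifnot(is.list(ref_nets), !is.null(names(ref_nets)))
  workflows <- enumerate_workflows(construction_methods, control_methods,
                                   names(ref_nets))
  records <- list()
  failures <- character(0)
  all_drivers <- list()  # [[ref]][[construction]][[control]][[sample]]
  for (rn in names(ref_nets)) {
    ref <- ref_nets[[rn]]
    universe <- length(igraph::V(ref))
    for (cm in construction_methods) {
      nets <- tryCatch(
        build_sample_networks(expr, cm, ref = ref, alpha = alpha,
                              box_fraction = box_fraction,
                              direction = direction),
        error = function(e) {
          failures <<- c(failures, paste0(cm, "_", rn, ": ",
                                          conditionMessage(e)))
          NULL
        })
      if (is.null(nets)) next
      for (ctl in control_methods) {
        for (s in names(nets)) {
          ds <- drivers_for_net(nets[[s]], ctl)
          if (is.null(ds)) {
            failures <- c(failures,
                          paste0(cm, "_", rn, "+", ctl, " sample ", s))
            next
          }
          all_drivers[[rn]][[cm]][[ctl]][[s]] <- ds$drivers
          vals <- c()
          if (!is.null(gold_genes)) {
            prf <- precision_recall_f(ds$drivers, gold_genes$gene_list)
            vals <- c(vals, precision = unname(prf["precision"]),
                      recall = unname(prf["recall"]),
                      F = unname(prf["F"]),
                      enrichment_p = hypergeom_enrichment(
                        ds$drivers, gold_genes$gene_list, universe))
          }
          if (!is.null(drug_targets) && !is.null(combo_labels))
            vals <- c(vals, auc = drug_combo_auc(ds, drug_targets,
                                                 combo_labels))
          g_nodes <- unique(c(nets[[s]]$edges$source,
                              nets[[s]]$edges$target))
          vals <- c(vals, controllability = controllability(
            intersect(ds$drivers, g_nodes), g_nodes),
            n_drivers = ds$objective)
          records[[length(records) + 1]] <- data.frame(
            sample = s, construction = cm, reference = rn, control = ctl,
            metric = names(vals), value = unname(vals),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(sample = character(0))
  consensus <- consensus_jaccard(all_drivers)
  robustness <- robustness_jaccard(all_drivers)
  structure(list(records = records, consensus = consensus,
                 robustness = robustness, workflows = workflows,
                 failures = failures),
            class = "ssc_report")
}

# Mean per-sample Jaccard between every pair of control methods, per
# construction method and reference network.
consensus_jaccard <- function(all_drivers) {
  rows <- list()
  for (rn in names(all_drivers)) for (cm in names(all_drivers[[rn]])) {
    ctls <- names(all_drivers[[rn]][[cm]])
    if (length(ctls) < 2) next
    prs <- utils::combn(ctls, 2)
    for (p in seq_len(ncol(prs))) {
      a <- all_drivers[[rn]][[cm]][[prs[1, p]]]
      b <- all_drivers[[rn]][[cm]][[prs[2, p]]]
      shared <- intersect(names(a), names(b))
      if (!length(shared)) next
      js <- vapply(shared, function(s) jaccard(a[[s]], b[[s]]), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        reference = rn, construction = cm,
        pair = paste(prs[1, p], prs[2, p], sep = "_"),
        jaccard = mean(js), stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

# Mean per-sample Jaccard of one control method across two reference
# networks, per construction method.
robustness_jaccard <- function(all_drivers) {
  rns <- names(all_drivers)
  if (length(rns) < 2) return(NULL)
  rows <- list()
  prs <- utils::combn(rns, 2)
  for (p in seq_len(ncol(prs))) {
    r1 <- all_drivers[[prs[1, p]]]; r2 <- all_drivers[[prs[2, p]]]
    for (cm in intersect(names(r1), names(r2)))
      for (ctl in intersect(names(r1[[cm]]), names(r2[[cm]]))) {
        a <- r1[[cm]][[ctl]]; b <- r2[[cm]][[ctl]]
        shared <- intersect(names(a), names(b))
        if (!length(shared)) next
        js <- vapply(shared, function(s) jaccard(a[[s]], b[[s]]),
                     numeric(1))
        rows[[length(rows) + 1]] <- data.frame(
          construction = cm, control = ctl,
          pair = paste(prs[1, p], prs[2, p], sep = "_"),
          jaccard = mean(js), stringsAsFactors = FALSE)
      }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Synthetic parameter-recovery benchmark
#'
#' The package's self-contained recovery study: generates `n_rep`
#' replicate synthetic datasets (50-gene directed scaffold, 200 reference
#' and `n_cases` case samples, ten planted co-expression pairs of which
#' half are flipped from r = 0.8 to independence per case sample, gold
#' drivers = perturbed-edge endpoints), runs SSN construction followed by
#' MDS and NCUA control on every case sample, and compares the pooled
#' mean F-measure against `n_baseline` uniform same-size random gene
#' sets via the one-sided z-score.
#'
#' @param n_rep number of replicate datasets.
#' @param n_cases case samples per dataset.
#' @param n_baseline uniform baseline repetitions.
#' @param seed integer seed; all stage seeds derive from it.
#' @return named numeric vector of z-scores for `MDS` and `NCUA`, with
#'   the pooled mean F values attached as attribute `"mean_F"` and the
#'   baseline means as `"baseline_F"`.
#' @export
ssn_recovery_z <- function(n_rep = 5, n_cases = 20, n_baseline = 100,
                           seed = 1L) {
  per_sample <- list(MDS = list(), NCUA = list())
  for (r in seq_len(n_rep)) {
    ref <- gen_reference_network(50, "erdos_renyi", 0.08,
                                 directed = TRUE, seed = seed + 100 + r)
    sim <- gen_expression(ref, 200, n_cases,
                          spec = truth_spec(n_planted = 10,
                                            r_base = 0.8, r_alt = 0),
                          seed = seed + 200 + r)
    gold <- sim$truth$driver_genes
    nodes <- igraph::V(ref)$name
    for (ctl in c("MDS", "NCUA")) {
      fit <- ssc(sim$expr, ref, construction = "SSN", control = ctl)
      for (s in names(fit$drivers))
        per_sample[[ctl]][[length(per_sample[[ctl]]) + 1]] <- list(
          f = unname(precision_recall_f(fit$drivers[[s]]$drivers,
                                        gold)["F"]),
          k = fit$drivers[[s]]$objective, nodes = nodes, gold = gold)
    }
  }
  out <- numeric(0); mf <- numeric(0); bf <- numeric(0)
  for (ctl in c("MDS", "NCUA")) {
    recs <- per_sample[[ctl]]
    obs <- mean(vapply(recs, `[[`, numeric(1), "f"))
    base <- withr::with_seed(seed + 777, vapply(seq_len(n_baseline),
      function(b) mean(vapply(recs, function(rc)
        unname(precision_recall_f(sample(rc$nodes, rc$k),
                                  rc$gold)["F"]), numeric(1))),
      numeric(1)))
    out[ctl] <- zscore_vs_baseline(obs, base)
    mf[ctl] <- obs; bf[ctl] <- mean(base)
  }
  attr(out, "mean_F") <- mf
  attr(out, "baseline_F") <- bf
  out
}

#' @export
print.ssc_report <- function(x, ...) {
  cat("Benchmark report:", nrow(x$workflows), "workflows,",
      length(unique(x$records$sample)), "samples,",
      nrow(x$records), "metric records\n")
  if (length(x$failures))
    cat("  ", length(x$failures), "isolated per-workflow failure(s)\n")
  invisible(x)
}

#' Write a benchmark report as tidy TSV plus JSON summary
#' @param report an `ssc_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$records, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$consensus))
    utils::write.table(report$consensus, file.path(dir, "consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$robustness))
    utils::write.table(report$robustness,
                       file.path(dir, "robustness.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  agg <- stats::aggregate(value ~ construction + reference + control +
                            metric, data = report$records, FUN = mean)
  jsonlite::write_json(list(workflows = nrow(report$workflows),
                            summary = agg, failures = report$failures),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
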