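#' Sample-specific network control analysis
#'
#' The main entry point: fits one complete analysis workflow -- a
#' single-sample network construction method followed by a structural
#' control method -- to an expression matrix, returning per-sample
#' state-transition networks, driver sets, and controllability scores.
#'
#' @param expr an [ssc_expression] (with group labels for SSN /
#'   pairedSSN).
#' @param reference optional reference interaction network (igraph) used
#'   to restrict and orient candidate edges.
#' @param construction construction method: `"CSN"`, `"SSN"`,
#'   `"pairedSSN"`, `"SPCC"`, `"LIONESS"`.
#' @param control control method: `"MMS"`, `"MDS"`, `"DFVS"`, `"NCUA"`.
#' @param alpha p-value cut for CSN/SSN (defaults 0.01 / 0.05).
#' @param box_fraction CSN box fraction.
#' @param direction reference-filter mode, `"directed"` or
#'   `"undirected"`.
#' @param deconvolve apply network deconvolution before thresholding.
#' @return an object of class `ssc` with elements `networks` (list of
#'   [sample_network]), `drivers` (list of [driver_set]),
#'   `controllability` (named numeric), `construction`, `control`,
#'   `failed` (samples whose network was empty or unsolvable).
#' @examples
#' ref <- gen_reference_network(30, "erdos_renyi", 0.15, seed = 1)
#' sim <- gen_expression(ref, n_ref_samples = 60, n_case_samples = 4,
#'                       spec = truth_spec(n_planted = 6), seed = 1)
#' fit <- ssc(sim$expr, ref, construction = "SSN", control = "NCUA")
#' fit
#' summary(fit)
#' @export
ssc <- function(expr, reference = NULL,
                construction = c("SSN", "CSN", "pairedSSN", "SPCC",
                                 "LIONESS"),
                control = c("NCUA", "MMS", "MDS", "DFVS"),
                alpha = NULL, box_fraction = 0.1,
                direction = c("directed", "undirected"),
                deconvolve = FALSE) {
  construction <- match.arg(construction)
  control <- match.arg(control)
  direction <- match.arg(direction)
  nets <- build_sample_networks(expr, construction, ref = reference,
                                alpha = alpha,
                                box_fraction = box_fraction,
                                direction = direction,
                                deconvolve = deconvolve)
  drivers <- list()
  ctrb <- numeric(0)
  failed <- character(0)
  for (s in names(nets)) {
    ds <- drivers_for_net(nets[[s]], control)
    if (is.null(ds)) { failed <- c(failed, s); next }
    drivers[[s]] <- ds
    nodes <- unique(c(nets[[s]]$edges$source, nets[[s]]$edges$target))
    ctrb[s] <- controllability(intersect(ds$drivers, nodes), nodes)
  }
  structure(list(networks = nets, drivers = drivers,
                 controllability = ctrb, construction = construction,
                 control = control, direction = direction,
                 reference = reference, failed = failed),
            class = "ssc")
}

#' @export
print.ssc <- function(x, ...) {
  cat("Sample-specific network control fit\n")
  cat("  workflow: ", x$construction, " + ", x$control, " (",
      x$direction, ")\n", sep = "")
  cat("  samples: ", length(x$networks), " (", length(x$failed),
      " failed)\n", sep = "")
  if (length(x$drivers)) {
    sizes <- vapply(x$drivers, `[[`, numeric(1), "objective")
    cat("  drivers per sample: median ", stats::median(sizes), " [",
        min(sizes), ", ", max(sizes), "]\n", sep = "")
    cat("  mean controllability: ",
        signif(mean(x$controllability), 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.ssc <- function(object, ...) {
  s <- names(object$drivers)
  df <- data.frame(
    sample = s,
    n_edges = vapply(object$networks[s], function(n) nrow(n$edges),
                     numeric(1)),
    n_drivers = vapply(object$drivers, `[[`, numeric(1), "objective"),
    controllability = object$controllability[s],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(workflow = paste(object$construction, object$control,
                                  sep = " + "),
                 table = df, failed = object$failed),
            class = "summary.ssc")
}

#' @export
print.summary.ssc <- function(x, ...) {
  cat("Workflow:", x$workflow, "\n")
  print(x$table, row.names = FALSE)
  if (length(x$failed))
    cat("Failed samples:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Driver-gene recurrence across samples
#'
#' The `coef`-style summary of an `ssc` fit: for each gene ever selected,
#' the fraction of (successfully analyzed) samples in which it is a
#' driver.
#'
#' @param object an `ssc` fit.
#' @param ... unused.
#' @return named numeric vector, sorted decreasing.
#' @export
coef.ssc <- function(object, ...) {
  if (!length(object$drivers)) return(numeric(0))
  tab <- table(unlist(lapply(object$drivers, `[[`, "drivers")))
  freq <- as.numeric(tab) / length(object$drivers)
  names(freq) <- names(tab)
  sort(freq, decreasing = TRUE)
}

#' Plot per-sample controllability of an ssc fit
#'
#' @param x an `ssc` fit.
#' @param ... passed to [graphics::barplot].
#' @return invisibly, the bar midpoints.
#' @export
plot.ssc <- function(x, ...) {
  if (!length(x$controllability)) stop("nothing to plot: no driver sets")
  graphics::barplot(x$controllability, las = 2,
                    ylab = "controllability (1 - |D|/|G|)",
                    main = paste(x$construction, "+", x$control), ...)
}

#' Extract driver sets from an ssc fit
#' @param object an `ssc` fit.
#' @return named list of [driver_set]s.
#' @export
drivers <- function(object) object$drivers
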