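#' Gold-standard annotation sets
#'
#' Holds the prior-knowledge inputs used to score driver predictions:
#' a flat gene list (e.g. census cancer genes, dark genes, embryonic
#' differentiation factors), a drug-combination to target-gene map, or
#' positive/negative labels for drug combinations.
#'
#' @param kind one of `"gene_list"`, `"drug_target_map"`, `"combo_labels"`.
#' @param gene_list character vector of gene ids (for `gene_list`).
#' @param drug_target_map named list: combo id -> character vector of
#'   target genes.
#' @param combo_labels named character vector: combo id -> `"positive"` or
#'   `"negative"`.
#' @return an object of class `ssc_gold`.
#' @export
ssc_gold <- function(kind = c("gene_list", "drug_target_map", "combo_labels"),
                     gene_list = NULL, drug_target_map = NULL,
                     combo_labels = NULL) {
  kind <- match.arg(kind)
  if (kind == "gene_list") {
    if (!length(gene_list)) stop("empty gene list")
    if (any(!nzchar(gene_list))) stop("empty gene identifier")
    gene_list <- unique(gene_list)
  }
  if (kind == "drug_target_map") {
    if (!length(drug_target_map)) stop("empty drug target map")
    drug_target_map <- lapply(drug_target_map, unique)
  }
  if (kind == "combo_labels") {
    if (!length(combo_labels)) stop("empty combo labels")
    if (!all(combo_labels %in% c("positive", "negative")))
      stop("combo labels must be 'positive' or 'negative'")
  }
  structure(list(kind = kind, gene_list = gene_list,
                 drug_target_map = drug_target_map,
                 combo_labels = combo_labels),
            class = "ssc_gold")
}

#' @export
print.ssc_gold <- function(x, ...) {
  cat("Gold standard [", x$kind, "]: ", sep = "")
  switch(x$kind,
         gene_list = cat(length(x$gene_list), "genes\n"),
         drug_target_map = cat(length(x$drug_target_map), "drug combos\n"),
         combo_labels = cat(length(x$combo_labels), "labeled combos\n"))
  invisible(x)
}

#' Read a gold-standard file
#'
#' `gene_list` files carry one identifier per line (`#` comments allowed).
#' `drug_target_map` and `combo_labels` files are 2-column TSVs
#' (combo id, gene / combo id, label).
#'
#' @param path input file.
#' @param kind which gold-standard kind to parse.
#' @return an [ssc_gold] object.
#' @export
read_gold <- function(path,
                      kind = c("gene_list", "drug_target_map",
                               "combo_labels")) {
  kind <- match.arg(kind)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gold-standard file '", path, "'")
  if (kind == "gene_list")
    return(ssc_gold("gene_list", gene_list = trimws(lines)))
  parts <- strsplit(lines, "\t")
  if (any(vapply(parts, length, integer(1)) < 2))
    stop("parse error in '", path, "': need 2 tab-separated columns")
  a <- vapply(parts, `[`, "", 1L)
  b <- vapply(parts, `[`, "", 2L)
  if (kind == "drug_target_map") {
    m <- split(b, a)
    return(ssc_gold("drug_target_map", drug_target_map = lapply(m, unique)))
  }
  if (anyDuplicated(a)) stop("duplicate combo label in '", path, "'")
  labels <- stats::setNames(b, a)
  ssc_gold("combo_labels", combo_labels = labels)
}

#' Write a gold standard back to its plain-text form
#' @param x an `ssc_gold` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gold <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  switch(x$kind,
         gene_list = writeLines(x$gene_list, con),
         drug_target_map = {
           for (combo in names(x$drug_target_map))
             writeLines(paste(combo, x$drug_target_map[[combo]], sep = "\t"),
                        con)
         },
         combo_labels = writeLines(
           paste(names(x$combo_labels), x$combo_labels, sep = "\t"), con))
  invisible(path)
}
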