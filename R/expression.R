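#' Expression matrix with optional sample labels
#'
#' Container for a genes x samples real-valued expression matrix. Row names
#' are gene identifiers, column names are sample identifiers; both are opaque
#' strings matched exactly. An optional label table assigns each sample a
#' group (`"reference"` or `"case"`), a patient `pair_id` linking matched
#' normal/tumor samples, and a numeric `time` point.
#'
#' @param values numeric matrix, genes in rows (row names required), samples
#'   in columns (column names required). All values must be finite; missing
#'   values are rejected (the downstream statistics assume complete vectors).
#' @param labels optional `data.frame` with columns `sample_id`, `group`
#'   (one of `"reference"`, `"case"`), and optionally `pair_id` and `time`.
#' @return an object of class `ssc_expression` with elements `values` and
#'   `labels`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(c("g1", "g2", "g3"),
#'                                             c("s1", "s2")))
#' ssc_expression(m)
#' @export
ssc_expression <- function(values, labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("`values` must carry gene row names and sample column names")
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g))
    stop("duplicate gene identifier(s): ", paste(unique(dup_g), collapse = ", "))
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s))
    stop("duplicate sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite expression value at gene '", gene_ids[bad[1, 1]],
         "', sample '", sample_ids[bad[1, 2]], "'")
  if (!is.null(labels)) labels <- validate_labels(labels, sample_ids)
  structure(list(values = values, labels = labels), class = "ssc_expression")
}

validate_labels <- function(labels, sample_ids) {
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(labels)))
    stop("label table needs columns 'sample_id' and 'group'")
  if (!all(labels$group %in% c("reference", "case")))
    stop("label 'group' must be 'reference' or 'case'")
  unknown <- setdiff(labels$sample_id, sample_ids)
  if (length(unknown))
    stop("label table refers to unknown sample(s): ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(labels$sample_id))
    stop("duplicate sample_id in label table")
  if (is.null(labels$pair_id)) labels$pair_id <- NA_character_
  if (is.null(labels$time)) labels$time <- NA_real_
  labels$time <- as.numeric(labels$time)
  labels[c("sample_id", "group", "pair_id", "time")]
}

#' @export
print.ssc_expression <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  if (!is.null(x$labels)) {
    tab <- table(x$labels$group)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.ssc_expression <- function(x, ...) x$values

#' @export
dim.ssc_expression <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x an `ssc_expression` object.
#' @return character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Samples labeled as the reference group
#'
#' @param x an `ssc_expression` object with labels.
#' @return character vector of reference sample ids.
#' @export
reference_samples <- function(x) {
  if (is.null(x$labels)) stop("expression matrix has no sample labels")
  x$labels$sample_id[x$labels$group == "reference"]
}

#' @rdname reference_samples
#' @export
case_samples <- function(x) {
  if (is.null(x$labels)) return(colnames(x$values))
  x$labels$sample_id[x$labels$group == "case"]
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers. Delimiter is inferred from the extension (`.csv` = comma,
#' otherwise tab). An optional label file is a TSV with columns
#' `sample_id`, `group`, and optionally `pair_id`, `time`.
#'
#' @param path expression file.
#' @param label_path optional sample label TSV.
#' @return an [ssc_expression] object.
#' @export
read_expression <- function(path, label_path = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2)
    stop("malformed expression file '", path, "': need gene column plus ",
         "at least one sample column")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicated gene row(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v) && !anyNA(vals[[j]])) {
      bad <- which(is.na(v))[1]
      stop("non-numeric cell in '", path, "' at gene '", genes[bad],
           "', column '", names(vals)[j], "'")
    }
    if (anyNA(v))
      stop("missing value in '", path, "', column '", names(vals)[j],
           "'; impute before loading")
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  labels <- NULL
  if (!is.null(label_path)) {
    labels <- utils::read.table(label_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE, comment.char = "#")
  }
  ssc_expression(m, labels)
}

#' Write an expression matrix (tab-delimited, UTF-8)
#'
#' @param x an `ssc_expression` object.
#' @param path output file for the matrix.
#' @param label_path optional output file for the sample labels.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, label_path = NULL) {
  # 17 significant digits so a write/read cycle reproduces doubles bitwise
  txt <- apply(x$values, 2, function(col) sprintf("%.17g", col))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(x$values))
  colnames(txt) <- colnames(x$values)
  df <- data.frame(gene_id = rownames(x$values), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(label_path)) {
    if (is.null(x$labels)) stop("no labels to write")
    utils::write.table(x$labels, label_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
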