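#' FPKM expression matrix with replicate-to-condition assignment
#'
#' Container for a features x replicates matrix of FPKM values together with
#' the condition label of each replicate column. This is the unit of input
#' for [consensus_de()]: each column is one biological replicate of one
#' condition (e.g. a strain), and every control x experiment replicate pair
#' will be compared.
#'
#' @param values numeric matrix of nonnegative FPKM values; rownames are
#'   feature (transcript or gene) ids, colnames are replicate sample ids.
#' @param conditions named character vector mapping every sample id (names)
#'   to its condition label (values). Order of samples need not match
#'   `values`; every column of `values` must be covered.
#'
#' @return An object of class `"expr_matrix"`: the validated matrix with a
#'   `conditions` attribute aligned to its columns.
#' @examples
#' m <- matrix(c(10, 20, 12, 18), nrow = 2,
#'             dimnames = list(c("gA", "gB"), c("s1", "s2")))
#' em <- expr_matrix(m, c(s1 = "control", s2 = "treated"))
#' conditions(em)
#' @export
expr_matrix <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_value("`values` must be a numeric matrix")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop_format("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(fid))
    stop_format("duplicate feature ids: ",
                paste(unique(fid[duplicated(fid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop_format("duplicate sample ids: ",
                paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values) || any(values < 0))
    stop_value("FPKM values must be nonnegative and non-missing")
  if (is.null(names(conditions)))
    stop_design("`conditions` must be a named character vector (sample -> condition)")
  missing <- setdiff(sid, names(conditions))
  if (length(missing))
    stop_design("samples without a condition assignment: ",
                paste(missing, collapse = ", "))
  structure(values,
            conditions = as.character(conditions[sid]),
            class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
conditions <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  stats::setNames(attr(x, "conditions"), colnames(x))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cond <- conditions(x)
  cat(sprintf("FPKM expression matrix: %d features x %d replicates\n",
              nrow(x), ncol(x)))
  for (cc in unique(cond))
    cat(sprintf("  condition %-12s %d replicate(s): %s\n", cc,
                sum(cond == cc), paste(names(cond)[cond == cc], collapse = ", ")))
  invisible(x)
}

replicates_of <- function(x, condition) {
  cond <- conditions(x)
  ids <- names(cond)[cond == condition]
  if (!length(ids))
    stop_design("condition not present in expression matrix: ", condition)
  ids
}

#' Read and write tab-delimited FPKM expression tables
#'
#' The file format is a plain UTF-8 TSV: a header row of replicate sample
#' ids, a first column of feature ids, one nonnegative FPKM value per cell;
#' lines starting with `#` are ignored.
#'
#' @param path file path.
#' @param conditions named character vector mapping each sample id in the
#'   file header to a condition label.
#' @return `read_expression_table()` returns an [expr_matrix()];
#'   `write_expression_table()` returns `path` invisibly.
#' @export
read_expression_table <- function(path, conditions) {
  df <- read_tsv_raw(path)
  if (ncol(df) < 2)
    stop_format("expression table needs a feature-id column plus >= 1 sample column")
  fid <- as.character(df[[1L]])
  vals <- df[-1L]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop_value("non-numeric expression values in column(s): ",
               paste(names(vals)[bad], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- fid
  expr_matrix(m, conditions)
}

#' @rdname read_expression_table
#' @param x an `expr_matrix` to serialize.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_raw(df, path)
  invisible(path)
}
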