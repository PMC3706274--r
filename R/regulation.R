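#' TF-target regulation tables
#'
#' A regulation table is a flat edge list of documented transcription-factor
#' to target-gene regulations, as exported from curated yeast regulation
#' databases: three tab-separated columns `tf`, `target`, `evidence`. The
#' recognised evidence labels are `documented-direct`, `documented-indirect`
#' and `potential`; by default only documented (direct or indirect)
#' regulations are retained, so that profiles are not dominated by general
#' TFs predicted to touch most of the genome.
#'
#' @param tf,target,evidence character vectors of equal length.
#' @return A `data.frame` of class `"regulation_table"` with unique
#'   `(tf, target, evidence)` rows.
#' @export
regulation_table <- function(tf = character(), target = character(),
                             evidence = character()) {
  tf <- as.character(tf); target <- as.character(target)
  evidence <- as.character(evidence)
  unknown <- setdiff(unique(evidence), regulation_evidence_labels)
  if (length(unknown))
    stop_format("unknown evidence label(s): ", paste(unknown, collapse = ", "))
  if (any(!nzchar(tf)) || any(!nzchar(target)))
    stop_format("empty tf or target name in regulation table")
  df <- unique(data.frame(tf = tf, target = target, evidence = evidence,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  structure(df, class = c("regulation_table", "data.frame"))
}

#' @rdname regulation_table
#' @export
regulation_evidence_labels <-
  c("documented-direct", "documented-indirect", "potential")

#' @rdname regulation_table
#' @param path file path.
#' @param evidence_filter evidence labels to keep; default documented
#'   regulations only.
#' @export
read_regulation_table <- function(path,
                                  evidence_filter = c("documented-direct",
                                                      "documented-indirect")) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!any(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")))
    return(regulation_table())
  df <- read_tsv_raw(path)
  need <- c("tf", "target", "evidence")
  if (!all(need %in% names(df)))
    stop_format("regulation table must have columns tf, target, evidence")
  tab <- regulation_table(df$tf, df$target, df$evidence)
  tab[tab$evidence %in% evidence_filter, , drop = FALSE]
}

#' @rdname regulation_table
#' @param x a `regulation_table`.
#' @export
write_regulation_table <- function(x, path) {
  stopifnot(inherits(x, "regulation_table"))
  write_tsv_raw(as.data.frame(x), path)
  invisible(path)
}

#' @export
print.regulation_table <- function(x, ...) {
  cat(sprintf("regulation table: %d edges, %d TFs, %d target genes\n",
              nrow(x), length(unique(x$tf)), length(unique(x$target))))
  invisible(x)
}

# targets of each TF as a named list of character vectors
tf_target_sets <- function(regulation) {
  stopifnot(inherits(regulation, "regulation_table"))
  split(regulation$target, regulation$tf)
}
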