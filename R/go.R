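#' Gene-to-GO-slim mappings
#'
#' A flat, offline mapping from gene to GO slim term: three tab-separated
#' columns `gene`, `go_id`, `go_description`. Genes may map to several
#' terms or to none; unmapped consensus genes are reported in a separate
#' "un-identified" bucket rather than dropped. No ontology traversal is
#' performed — the mapping file is taken as the vocabulary.
#'
#' @param gene,go_id,go_description character vectors of equal length.
#' @return A `data.frame` of class `"go_mapping"`.
#' @export
go_mapping <- function(gene = character(), go_id = character(),
                       go_description = character()) {
  gene <- as.character(gene); go_id <- as.character(go_id)
  go_description <- as.character(go_description)
  if (any(!nzchar(go_id)))
    stop_format("empty go_id in GO mapping")
  df <- unique(data.frame(gene = gene, go_id = go_id,
                          go_description = go_description,
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  structure(df, class = c("go_mapping", "data.frame"))
}

#' @rdname go_mapping
#' @param path file path.
#' @export
read_go_mapping <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!any(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")))
    return(go_mapping())
  df <- read_tsv_raw(path)
  need <- c("gene", "go_id", "go_description")
  if (!all(need %in% names(df)))
    stop_format("GO mapping must have columns gene, go_id, go_description")
  go_mapping(df$gene, df$go_id, df$go_description)
}

#' @rdname go_mapping
#' @param x a `go_mapping`.
#' @export
write_go_mapping <- function(x, path) {
  stopifnot(inherits(x, "go_mapping"))
  write_tsv_raw(as.data.frame(x), path)
  invisible(path)
}

#' Summarize consensus differential genes by GO term and direction
#'
#' Groups the selected genes of one comparison under every GO term they map
#' to. A gene with m terms is listed under all m terms but counted once in
#' the per-direction totals; genes mapping to no term are collected in the
#' `unidentified` bucket per direction.
#'
#' @param calls a `consensus_calls` table (see [consensus()]) or any
#'   data.frame with `feature_id`, `selected` and `consensus_direction`
#'   columns; only selected rows are summarized.
#' @param mapping a [go_mapping()].
#' @param label comparison label carried into the summary.
#' @return An object of class `"go_summary"`: list with `rows` (data.frame
#'   `go_id`, `description`, `direction`, `genes` — comma-separated, sorted
#'   by go_id then direction), `unidentified` (list of `up`/`down` gene
#'   vectors), `totals` (named counts of unique up/down genes) and `label`.
#' @export
summarize_go <- function(calls, mapping, label = "comparison") {
  stopifnot(inherits(mapping, "go_mapping"))
  calls <- as.data.frame(calls)
  calls <- calls[calls$selected, , drop = FALSE]
  genes_by_dir <- list(
    up = sort(unique(calls$feature_id[calls$consensus_direction == "up"])),
    down = sort(unique(calls$feature_id[calls$consensus_direction == "down"])))

  rows <- data.frame(go_id = character(), description = character(),
                     direction = character(), genes = character(),
                     stringsAsFactors = FALSE)
  unidentified <- list(up = character(), down = character())
  for (dir in c("up", "down")) {
    g <- genes_by_dir[[dir]]
    if (!length(g)) next
    hit <- mapping[mapping$gene %in% g, , drop = FALSE]
    unidentified[[dir]] <- sort(setdiff(g, hit$gene))
    if (nrow(hit)) {
      by_term <- split(hit, hit$go_id)
      rows <- rbind(rows, data.frame(
        go_id = names(by_term),
        description = vapply(by_term, function(d) d$go_description[1],
                             character(1)),
        direction = dir,
        genes = vapply(by_term,
                       function(d) paste(sort(unique(d$gene)), collapse = ", "),
                       character(1)),
        stringsAsFactors = FALSE))
    }
  }
  rows <- rows[order(rows$go_id, rows$direction), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows,
                 unidentified = unidentified,
                 totals = c(up = length(genes_by_dir$up),
                            down = length(genes_by_dir$down)),
                 label = label),
            class = "go_summary")
}

#' @export
print.go_summary <- function(x, ...) {
  cat(sprintf("GO summary [%s]: %d up, %d down (unique genes)\n",
              x$label, x$totals["up"], x$totals["down"]))
  if (nrow(x$rows)) {
    cat(sprintf("%d (term, direction) rows; e.g.\n", nrow(x$rows)))
    print(utils::head(x$rows, 5), right = FALSE)
  }
  for (dir in c("up", "down"))
    if (length(x$unidentified[[dir]]))
      cat(sprintf("un-identified, %s-regulated: %s\n", dir,
                  paste(x$unidentified[[dir]], collapse = ", ")))
  invisible(x)
}

#' @rdname summarize_go
#' @param x a `go_summary`.
#' @param path output TSV path; rows first, then a `# summary` footer with
#'   the per-direction totals and the un-identified gene lists.
#' @export
write_go_summary <- function(x, path) {
  stopifnot(inherits(x, "go_summary"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# comparison=%s", x$label), con)
  utils::write.table(x$rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  writeLines(c(sprintf("# summary up=%d down=%d",
                       x$totals["up"], x$totals["down"]),
               sprintf("# unidentified_up=%s",
                       paste(x$unidentified$up, collapse = ",")),
               sprintf("# unidentified_down=%s",
                       paste(x$unidentified$down, collapse = ","))), con)
  invisible(path)
}
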