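# Classed error conditions so callers (and tests) can distinguish malformed
# files, out-of-range values, and inconsistent analysis designs.

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("repcons_format_error", "error")))
}

stop_value <- function(...) {
  stop(errorCondition(paste0(...), class = c("repcons_value_error", "error")))
}

stop_design <- function(...) {
  stop(errorCondition(paste0(...), class = c("repcons_design_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("repcons_config_error", "error")))
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("repcons_input_error", "error")))
}

# Shared TSV conventions: UTF-8, tab-separated, '#' comment lines ignored.
read_tsv_raw <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

write_tsv_raw <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
}
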