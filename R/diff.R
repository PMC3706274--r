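#' Pairwise differential-expression tables
#'
#' One table records the comparison of a single control replicate against a
#' single experiment replicate. Direction follows one convention throughout
#' the package: `"up"` means increased in the EXPERIMENTAL group relative to
#' the control. Tables come either from [read_cuffdiff_diff()] (real
#' Cuffdiff runs) or from the built-in [fold_change_caller()].
#'
#' @param feature_id character vector of unique feature ids.
#' @param value_control,value_experiment nonnegative FPKM values.
#' @param log2_fold_change log2(experiment/control) (possibly shrunken).
#' @param p_value p-values in `[0, 1]`.
#' @param q_value FDR-adjusted p-values, or `NA` when the source table has
#'   none.
#' @param significant logical significance flag after thresholding.
#' @param pair_label length-2 character: control and experiment replicate id.
#' @return A `data.frame` of class `"pairwise_de"` with a `direction` column
#'   in `{"up", "down", "none"}` (`"none"` iff not significant) and a
#'   `pair_label` attribute.
#' @export
pairwise_de <- function(feature_id, value_control, value_experiment,
                        log2_fold_change, p_value, q_value = NA_real_,
                        significant, pair_label = c("control", "experiment")) {
  feature_id <- as.character(feature_id)
  if (anyDuplicated(feature_id))
    stop_format("duplicate feature ids in pairwise table")
  if (anyNA(p_value) || any(p_value < 0 | p_value > 1))
    stop_value("p_value outside [0, 1]")
  direction <- rep("none", length(feature_id))
  direction[significant & log2_fold_change > 0] <- "up"
  direction[significant & log2_fold_change < 0] <- "down"
  # a zero fold change carries no direction even if flagged
  significant <- direction != "none"
  structure(
    data.frame(feature_id = feature_id,
               value_control = value_control,
               value_experiment = value_experiment,
               log2_fold_change = log2_fold_change,
               p_value = p_value,
               q_value = rep_len(q_value, length(feature_id)),
               significant = significant,
               direction = direction,
               stringsAsFactors = FALSE),
    pair_label = pair_label,
    class = c("pairwise_de", "data.frame"))
}

#' Read a Cuffdiff-style .diff table
#'
#' Parses the tab-delimited output dialect of Cuffdiff 2.x. Required
#' columns: `test_id`, `value_1` (control FPKM), `value_2` (experiment
#' FPKM), `log2(fold_change)` (the spelling `log2_fold_change` is also
#' accepted), `p_value`, and `significant` (`yes`/`no`); `q_value` is used
#' when present and tolerated when absent. A record is significant iff the
#' file flags it `yes` AND its p-value is at most `alpha` — the conjunction
#' keeps the file's own multiple-testing decision while letting the caller
#' tighten the p-value cutoff.
#'
#' @param path path to the `.diff` file.
#' @param alpha p-value cutoff applied on top of the file's flag
#'   (default 0.05).
#' @param pair_label optional length-2 label (control id, experiment id);
#'   defaults to the file's `sample_1`/`sample_2` columns when present.
#' @return A [pairwise_de()] table.
#' @export
read_cuffdiff_diff <- function(path, alpha = 0.05, pair_label = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1)
    stop_config("`alpha` must be a single value in [0, 1]")
  df <- read_tsv_raw(path)
  lfc_col <- intersect(c("log2(fold_change)", "log2_fold_change"), names(df))
  required <- c("test_id", "value_1", "value_2", "p_value", "significant")
  missing <- setdiff(required, names(df))
  if (length(missing) || !length(lfc_col))
    stop_format(".diff file missing column(s): ",
                paste(c(missing,
                        if (!length(lfc_col)) "log2(fold_change)"),
                      collapse = ", "))
  if (is.null(pair_label)) {
    pair_label <- if (all(c("sample_1", "sample_2") %in% names(df)) && nrow(df))
      c(as.character(df$sample_1[1]), as.character(df$sample_2[1]))
    else c("control", "experiment")
  }
  flag <- tolower(as.character(df$significant)) == "yes"
  p <- as.numeric(df$p_value)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_value("p_value outside [0, 1] in ", path)
  pairwise_de(feature_id = df$test_id,
              value_control = as.numeric(df$value_1),
              value_experiment = as.numeric(df$value_2),
              log2_fold_change = as.numeric(df[[lfc_col[1]]]),
              p_value = p,
              q_value = if ("q_value" %in% names(df)) as.numeric(df$q_value)
                        else NA_real_,
              significant = flag & p <= alpha,
              pair_label = pair_label)
}

#' Read a directory of .diff files as one comparison's pairwise tables
#'
#' @param dir directory containing only the `.diff` files of one
#'   control-vs-experiment comparison (one file per replicate pair).
#' @inheritParams read_cuffdiff_diff
#' @return list of [pairwise_de()] tables, in lexicographic file order.
#' @export
read_cuffdiff_dir <- function(dir, alpha = 0.05) {
  files <- sort(list.files(dir, pattern = "\\.diff$", full.names = TRUE))
  if (!length(files))
    stop_input("no .diff files found under ", dir)
  lapply(files, read_cuffdiff_diff, alpha = alpha)
}
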