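#' Pairwise-caller configuration
#'
#' Parameters for the built-in threshold caller and for re-thresholding
#' Cuffdiff tables: `alpha` is the p-value cutoff (0.05 by default, the
#' conventional transcriptome-wide choice), `min_abs_log2fc` the absolute
#' log2 fold-change a pair must reach to be called (default 1, i.e.
#' two-fold), and `epsilon` the FPKM pseudocount that shrinks fold changes
#' of barely expressed features toward zero (default 1 FPKM).
#'
#' @param alpha significance threshold in `(0, 1]`.
#' @param min_abs_log2fc fold-change threshold, `>= 0` (may be `Inf`).
#' @param epsilon FPKM pseudocount, `> 0`.
#' @return list of class `"caller_config"`.
#' @export
caller_config <- function(alpha = 0.05, min_abs_log2fc = 1, epsilon = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop_config("alpha must be in (0, 1]")
  if (!is.numeric(min_abs_log2fc) || min_abs_log2fc < 0)
    stop_config("min_abs_log2fc must be >= 0")
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop_config("epsilon must be > 0")
  structure(list(alpha = alpha, min_abs_log2fc = min_abs_log2fc,
                 epsilon = epsilon),
            class = "caller_config")
}

#' Enumerate every control x experiment replicate pair
#'
#' The consensus design compares each replicate of the control condition
#' against each replicate of the experimental condition (the full Cartesian
#' product — nine comparisons for the usual 3 vs 3 design), rather than
#' pooling replicates into a single dispersion model.
#'
#' @param matrix an [expr_matrix()].
#' @param control,experiment condition labels present in the matrix.
#' @return data.frame with columns `control` and `experiment` (replicate
#'   sample ids), control-major order.
#' @export
enumerate_pairs <- function(matrix, control, experiment) {
  ctl <- replicates_of(matrix, control)
  exp <- replicates_of(matrix, experiment)
  data.frame(control = rep(ctl, each = length(exp)),
             experiment = rep(exp, times = length(ctl)),
             stringsAsFactors = FALSE)
}

#' Built-in threshold caller for one replicate pair
#'
#' A deliberately simple, deterministic stand-in for a count-model caller:
#' per feature it computes the pseudocounted log2 fold change
#' `log2((v_exp + eps) / (v_ctl + eps))` and flags the feature significant
#' when its magnitude reaches `min_abs_log2fc`. Because the call is a pure
#' threshold, the reported p-value is a placeholder (0 when called, 1
#' otherwise). Real Cuffdiff `.diff` tables can be substituted via
#' [read_cuffdiff_diff()]; the consensus stage is caller-agnostic.
#'
#' @param matrix an [expr_matrix()].
#' @param pair length-2 character (control replicate id, experiment
#'   replicate id), or one row of [enumerate_pairs()].
#' @param config a [caller_config()].
#' @return a [pairwise_de()] table over all features of `matrix`.
#' @export
fold_change_caller <- function(matrix, pair, config = caller_config()) {
  stopifnot(inherits(matrix, "expr_matrix"), inherits(config, "caller_config"))
  pair <- as.character(unlist(pair))
  if (!all(pair %in% colnames(matrix)))
    stop_design("replicate id(s) not in matrix: ",
                paste(setdiff(pair, colnames(matrix)), collapse = ", "))
  v_ctl <- unclass(matrix)[, pair[1]]
  v_exp <- unclass(matrix)[, pair[2]]
  lfc <- log2((v_exp + config$epsilon) / (v_ctl + config$epsilon))
  sig <- abs(lfc) >= config$min_abs_log2fc
  pairwise_de(feature_id = rownames(matrix),
              value_control = v_ctl, value_experiment = v_exp,
              log2_fold_change = lfc,
              p_value = ifelse(sig, 0, 1),
              significant = sig,
              pair_label = pair)
}

#' Tally consensus support over pairwise tables
#'
#' For each feature, counts in how many pairwise comparisons it was called
#' up (`n_up`) and down (`n_down`); `support = n_up + n_down`. Under the
#' default `direction_rule = "unanimous"`, a feature is selected at cut-off
#' `n` iff one direction has at least `n` calls and the opposite direction
#' has none — the strictest reading of "consistent behavior across the
#' comparisons". Under `"count"`, selection only requires
#' `support >= cutoff_n`, with the majority direction reported (a tie is
#' not selected).
#'
#' @param tables list of [pairwise_de()] tables over the same feature
#'   universe.
#' @param cutoff_n consensus cut-off, `1 <= cutoff_n <= length(tables)`.
#'   At 3 vs 3 replicates the strictest cut-off is 9.
#' @param direction_rule `"unanimous"` (default) or `"count"`.
#' @return data.frame of class `"consensus_calls"`, columns `feature_id`,
#'   `n_up`, `n_down`, `support`, `consensus_direction`, `selected`, sorted
#'   by support descending then feature id; attributes `cutoff_n`,
#'   `n_tables`, `direction_rule`.
#' @export
consensus <- function(tables, cutoff_n,
                      direction_rule = c("unanimous", "count")) {
  direction_rule <- match.arg(direction_rule)
  if (!length(tables))
    stop_config("no pairwise tables given")
  if (!is.numeric(cutoff_n) || cutoff_n < 1 || cutoff_n > length(tables))
    stop_config("cutoff_n must be between 1 and the number of tables (",
                length(tables), ")")
  feats <- sort(tables[[1]]$feature_id)
  for (t in tables)
    if (!identical(sort(t$feature_id), feats))
      stop_design("pairwise tables cover different feature universes")
  n_up <- n_down <- stats::setNames(integer(length(feats)), feats)
  for (t in tables) {
    idx <- match(t$feature_id, feats)
    n_up[idx] <- n_up[idx] + (t$direction == "up")
    n_down[idx] <- n_down[idx] + (t$direction == "down")
  }
  support <- n_up + n_down
  if (direction_rule == "unanimous") {
    sel_up <- n_up >= cutoff_n & n_down == 0L
    sel_down <- n_down >= cutoff_n & n_up == 0L
  } else {
    reach <- support >= cutoff_n
    sel_up <- reach & n_up > n_down
    sel_down <- reach & n_down > n_up
  }
  dir <- rep("none", length(feats))
  dir[sel_up] <- "up"; dir[sel_down] <- "down"
  out <- data.frame(feature_id = feats,
                    n_up = as.integer(n_up), n_down = as.integer(n_down),
                    support = as.integer(support),
                    consensus_direction = dir,
                    selected = sel_up | sel_down,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$support, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, cutoff_n = cutoff_n, n_tables = length(tables),
            direction_rule = direction_rule,
            class = c("consensus_calls", "data.frame"))
}

#' Consensus differential expression across all replicate pairs
#'
#' The central fit of the package: enumerates every control x experiment
#' replicate pair of an FPKM matrix, runs a pairwise caller on each pair,
#' and tallies consensus support, selecting features whose call is
#' consistent in at least `cutoff_n` of the pairwise comparisons. With
#' 3 vs 3 replicates and the default `cutoff_n = 9`, only features called
#' identically in all nine comparisons are selected — the qualitative,
#' replicate-noise-robust criterion this design exists for.
#'
#' @inheritParams enumerate_pairs
#' @param caller function `(matrix, pair, config) -> pairwise_de`; the
#'   default is [fold_change_caller()]. Precomputed Cuffdiff tables can be
#'   consensus-tallied directly with [consensus()].
#' @param config a [caller_config()] passed to the caller.
#' @param cutoff_n consensus cut-off (default 9, the strictest value for a
#'   3 vs 3 design).
#' @param direction_rule see [consensus()].
#' @return object of class `"consensus_de"`: list with `calls` (the
#'   `consensus_calls` table), `pairs`, `tables`, and the design metadata.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 300, seed = 7))
#' fit <- consensus_de(sim$matrix, "control", "experiment")
#' fit
#' head(summary(fit)$selected)
#' @export
consensus_de <- function(matrix, control, experiment,
                         caller = fold_change_caller,
                         config = caller_config(),
                         cutoff_n = 9,
                         direction_rule = c("unanimous", "count")) {
  direction_rule <- match.arg(direction_rule)
  pairs <- enumerate_pairs(matrix, control, experiment)
  if (cutoff_n > nrow(pairs))
    stop_config("cutoff_n (", cutoff_n, ") exceeds the number of replicate ",
                "pairs (", nrow(pairs), ")")
  tables <- lapply(seq_len(nrow(pairs)), function(i)
    caller(matrix, c(pairs$control[i], pairs$experiment[i]), config))
  calls <- consensus(tables, cutoff_n, direction_rule)
  structure(list(calls = calls, pairs = pairs, tables = tables,
                 control = control, experiment = experiment,
                 cutoff_n = cutoff_n, config = config,
                 direction_rule = direction_rule),
            class = "consensus_de")
}

#' @export
print.consensus_de <- function(x, ...) {
  sel <- x$calls[x$calls$selected, , drop = FALSE]
  cat(sprintf("Consensus differential expression: %s vs %s\n",
              x$control, x$experiment))
  cat(sprintf("  %d replicate pairs, cut-off n = %d (%s direction rule)\n",
              nrow(x$pairs), x$cutoff_n, x$direction_rule))
  cat(sprintf("  %d / %d features selected (%d up, %d down)\n",
              nrow(sel), nrow(x$calls),
              sum(sel$consensus_direction == "up"),
              sum(sel$consensus_direction == "down")))
  invisible(x)
}

#' @export
summary.consensus_de <- function(object, ...) {
  calls <- object$calls
  sel <- calls[calls$selected, , drop = FALSE]
  structure(list(control = object$control, experiment = object$experiment,
                 n_pairs = nrow(object$pairs), cutoff_n = object$cutoff_n,
                 n_features = nrow(calls),
                 n_selected = nrow(sel),
                 n_up = sum(sel$consensus_direction == "up"),
                 n_down = sum(sel$consensus_direction == "down"),
                 support_table = table(calls$support),
                 selected = sel),
            class = "summary.consensus_de")
}

#' @export
print.summary.consensus_de <- function(x, ...) {
  cat(sprintf("%s vs %s: %d selected of %d features at n = %d (%d up, %d down)\n",
              x$control, x$experiment, x$n_selected, x$n_features,
              x$cutoff_n, x$n_up, x$n_down))
  cat("support distribution:\n")
  print(x$support_table)
  invisible(x)
}

#' @export
as.data.frame.consensus_de <- function(x, ...) as.data.frame(x$calls)

#' @export
plot.consensus_de <- function(x, ...) {
  supp <- factor(x$calls$support, levels = 0:nrow(x$pairs))
  graphics::barplot(table(supp),
                    xlab = "consensus support (pairwise calls)",
                    ylab = "features",
                    main = sprintf("%s vs %s", x$control, x$experiment), ...)
  invisible(x)
}

#' Selected feature ids of a consensus fit
#' @param fit a `consensus_de` object or a `consensus_calls` table.
#' @param direction optional `"up"` or `"down"` to restrict.
#' @return character vector of selected feature ids.
#' @export
de_genes <- function(fit, direction = NULL) {
  calls <- if (inherits(fit, "consensus_de")) fit$calls else fit
  sel <- calls[calls$selected, , drop = FALSE]
  if (!is.null(direction))
    sel <- sel[sel$consensus_direction == direction, , drop = FALSE]
  sel$feature_id
}

#' @rdname consensus
#' @param x a `consensus_calls` table.
#' @param path output TSV path.
#' @export
write_consensus_calls <- function(x, path) {
  stopifnot(inherits(x, "consensus_calls"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# cutoff_n=%d n_tables=%d direction_rule=%s",
                     attr(x, "cutoff_n"), attr(x, "n_tables"),
                     attr(x, "direction_rule")), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
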