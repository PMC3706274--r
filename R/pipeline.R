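#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. Inputs may be given as
#' in-memory objects (an [expr_matrix()], [regulation_table()], ...) or as
#' file paths to the corresponding TSV formats; paths are read on entry.
#'
#' @param expression an `expr_matrix`, or a path to an expression TSV
#'   (requires `conditions`).
#' @param conditions named sample -> condition vector, used when
#'   `expression` is a path.
#' @param pairs list of length-2 character vectors
#'   `c(control_condition, experiment_condition)`; names become comparison
#'   labels (defaults to `"ctl vs exp"`).
#' @param regulation a `regulation_table` or path.
#' @param go a `go_mapping` or path, or `NULL` to skip GO summaries.
#' @param references named list of reference rankings (character vectors
#'   or one-column files), or `NULL` to skip distance reports.
#' @param cutoff_n consensus cut-off (default 9).
#' @param K TF profile cap (default 20).
#' @param n_ref_genes reference head size (default 250).
#' @param caller_config a [caller_config()].
#' @param direction_rule see [consensus()].
#' @param out_dir report directory (created if needed).
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when inputs are simulated).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(expression, pairs, regulation,
                            conditions = NULL, go = NULL,
                            references = NULL, cutoff_n = 9, K = 20,
                            n_ref_genes = 250,
                            caller_config = repcons::caller_config(),
                            direction_rule = "unanimous",
                            out_dir = tempfile("repcons_run_"),
                            seed = 1L) {
  if (is.character(expression)) {
    if (is.null(conditions))
      stop_config("`conditions` is required when `expression` is a path")
    expression <- read_expression_table(expression, conditions)
  }
  if (is.character(regulation))
    regulation <- read_regulation_table(regulation)
  if (is.character(go))
    go <- read_go_mapping(go)
  if (!is.null(references)) {
    references <- lapply(references, function(r) {
      if (is.character(r) && length(r) == 1 && file.exists(r))
        readLines(r, encoding = "UTF-8") else as.character(r)
    })
    if (is.null(names(references)))
      names(references) <- paste0("reference", seq_along(references))
  }
  if (is.null(names(pairs)) || any(!nzchar(names(pairs))))
    names(pairs) <- vapply(pairs, function(p) paste(p[1], "vs", p[2]),
                           character(1))
  structure(list(expression = expression, pairs = pairs,
                 regulation = regulation, go = go,
                 references = references, cutoff_n = cutoff_n, K = K,
                 n_ref_genes = n_ref_genes,
                 caller_config = caller_config,
                 direction_rule = direction_rule,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a YAML pipeline configuration file
#'
#' File-path fields (`expression`, `regulation`, `go`, `references`),
#' `conditions` as a mapping, `pairs` as a list of 2-element lists, and
#' the scalar parameters of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    list(expression = y$expression,
         conditions = if (!is.null(y$conditions)) unlist(y$conditions),
         pairs = lapply(y$pairs, unlist),
         regulation = y$regulation,
         go = y$go,
         references = y$references),
    y[intersect(names(y), c("cutoff_n", "K", "n_ref_genes",
                            "direction_rule", "out_dir", "seed"))]))
}

#' Run the full consensus / TF-profile / GO analysis
#'
#' For every configured condition pair: consensus differential expression
#' over all replicate pairs, a top-K TF profile of the selected genes, and
#' (when a GO mapping is given) a GO summary. Across pairs: the conserved
#' TF set, and (when reference rankings are given) the Euclidean distance
#' of every sample profile to every reference profile. All reports are
#' plain TSV under `config$out_dir`, plus a JSON run manifest; identical
#' configs produce byte-identical reports. A pair whose consensus selects
#' no genes gets an empty profile slot and is skipped in the conserved
#' intersection and distance table.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with `fits`, `profiles`, `go_summaries`,
#'   `conserved`, `distances`, `files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    files[[length(files) + 1]] <<- p
    p
  }

  fits <- list(); profiles <- list(); go_summaries <- list()
  for (lab in names(config$pairs)) {
    pr <- config$pairs[[lab]]
    fit <- consensus_de(config$expression, pr[1], pr[2],
                        config = config$caller_config,
                        cutoff_n = config$cutoff_n,
                        direction_rule = config$direction_rule)
    fits[[lab]] <- fit
    slug <- gsub("[^A-Za-z0-9]+", "_", lab)
    write_consensus_calls(fit$calls, out(sprintf("consensus_%s.tsv", slug)))
    sel <- de_genes(fit)
    if (length(sel)) {
      prof <- build_profile(sel, config$regulation, K = config$K,
                            label = lab)
      profiles[[lab]] <- prof
      write_tf_profile(prof, out(sprintf("profile_%s.tsv", slug)))
      if (!is.null(config$go)) {
        gs <- summarize_go(fit$calls, config$go, label = lab)
        go_summaries[[lab]] <- gs
        write_go_summary(gs, out(sprintf("go_%s.tsv", slug)))
      }
    }
  }

  nonempty <- profiles[vapply(profiles, nrow, integer(1)) > 0]
  conserved <- if (length(nonempty)) conserved_tfs(nonempty) else character()
  writeLines(c("# conserved TFs across all comparisons", conserved),
             out("conserved_tfs.tsv"))

  distances <- NULL
  if (!is.null(config$references) && length(nonempty)) {
    refs <- lapply(names(config$references), function(rn)
      build_reference_profile(config$references[[rn]], config$regulation,
                              n_ref_genes = config$n_ref_genes,
                              K = config$K, label = rn))
    names(refs) <- names(config$references)
    grid <- expand.grid(comparison = names(nonempty),
                        reference = names(refs),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$distance <- mapply(function(cmp, rf)
      tf_profile_distance(nonempty[[cmp]], refs[[rf]]),
      grid$comparison, grid$reference)
    distances <- grid
    write_tsv_raw(grid, out("distances.tsv"))
  }

  manifest <- list(
    package = "repcons",
    version = as.character(utils::packageVersion("repcons")),
    seed = config$seed,
    parameters = list(cutoff_n = config$cutoff_n, K = config$K,
                      n_ref_genes = config$n_ref_genes,
                      alpha = config$caller_config$alpha,
                      min_abs_log2fc = config$caller_config$min_abs_log2fc,
                      epsilon = config$caller_config$epsilon,
                      direction_rule = config$direction_rule),
    pairs = config$pairs,
    n_features = nrow(config$expression),
    outputs = basename(unlist(files)))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(fits = fits, profiles = profiles,
                 go_summaries = go_summaries, conserved = conserved,
                 distances = distances, files = unlist(files)))
}
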