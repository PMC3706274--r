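#' Configuration for the synthetic FPKM generator
#'
#' The generator emulates the statistical structure the consensus analysis
#' assumes: two conditions with a small number of biological replicates
#' each, lognormal expression (normal on the log2 scale), multiplicative
#' replicate noise tight enough that within-condition replicates correlate
#' at 0.99+ on the log2 scale (real, carefully controlled batch cultures
#' reach ~0.996), and a small set of planted differential genes shifted by
#' a fixed log2 fold change in the experimental condition.
#'
#' Defaults: 6000 genes (the order of the yeast transcriptome), 3
#' replicates per condition, baseline log2 FPKM ~ N(5, 2), replicate noise
#' sd 0.12 on log2 (giving expected within-condition replicate correlation
#' 4 / (4 + 0.12^2) ~ 0.996), 100 planted DE genes at |log2FC| = 2 with
#' random sign.
#'
#' @param n_genes number of genes.
#' @param n_replicates replicates per condition.
#' @param baseline_mean,baseline_sd log2-scale mean and sd of gene
#'   baselines.
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param n_de number of planted differential genes.
#' @param effect_log2fc planted absolute log2 fold change; sign is random
#'   per gene.
#' @param conditions length-2 character: control and experiment labels.
#' @param seed integer seed; identical seed gives bit-identical output.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 6000, n_replicates = 3,
                       baseline_mean = 5, baseline_sd = 2,
                       noise_sd = 0.12, n_de = 100, effect_log2fc = 2,
                       conditions = c("control", "experiment"),
                       seed = 1L) {
  if (n_genes < 0 || n_replicates < 0 || n_de < 0)
    stop_config("counts must be >= 0")
  if (baseline_sd <= 0 || noise_sd <= 0)
    stop_config("sds must be > 0")
  if (n_de > n_genes)
    stop_config("n_de (", n_de, ") exceeds n_genes (", n_genes, ")")
  if (length(conditions) != 2 || anyDuplicated(conditions))
    stop_config("`conditions` must be two distinct labels")
  structure(list(n_genes = n_genes, n_replicates = n_replicates,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, n_de = n_de,
                 effect_log2fc = effect_log2fc,
                 conditions = conditions, seed = as.integer(seed)),
            class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

# run expr with a local, restorable RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate an FPKM expression matrix with planted differential genes
#'
#' Per gene g and replicate r, the simulated log2 FPKM is
#' `baseline_g + shift_g * 1{condition = experiment} + noise_{g,r}` with
#' `baseline_g ~ N(baseline_mean, baseline_sd)`,
#' `shift_g = +/- effect_log2fc` for the `n_de` planted genes (0
#' otherwise) and `noise ~ N(0, noise_sd)` independent per cell; FPKM is
#' `2^log2`. The returned truth records exactly the planted genes and
#' their directions (`"up"` = increased in the experimental condition).
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (an [expr_matrix()]) and `truth` (class
#'   `"sim_truth"`: list with `de_genes`, a named character vector
#'   gene -> direction, and `conserved_tfs`, filled by
#'   [simulate_regulation()]).
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genes <- sim_gene_ids(config$n_genes)
    baseline <- stats::rnorm(config$n_genes, config$baseline_mean,
                             config$baseline_sd)
    de_idx <- sort(sample.int(config$n_genes, config$n_de))
    sign_de <- sample(c(1, -1), config$n_de, replace = TRUE)
    shift <- numeric(config$n_genes)
    shift[de_idx] <- sign_de * config$effect_log2fc
    n_rep <- config$n_replicates
    samples <- c(paste0(config$conditions[1], "_R", seq_len(n_rep)),
                 paste0(config$conditions[2], "_R", seq_len(n_rep)))
    cond <- stats::setNames(rep(config$conditions, each = n_rep), samples)
    log2v <- matrix(baseline, nrow = config$n_genes, ncol = 2 * n_rep)
    log2v[, seq_len(n_rep) + n_rep] <- log2v[, seq_len(n_rep) + n_rep] + shift
    log2v <- log2v + matrix(stats::rnorm(length(log2v), 0, config$noise_sd),
                            nrow = config$n_genes)
    vals <- 2^log2v
    dimnames(vals) <- list(genes, samples)
    truth <- structure(
      list(de_genes = stats::setNames(ifelse(sign_de > 0, "up", "down"),
                                      genes[de_idx]),
           conserved_tfs = character()),
      class = "sim_truth")
    list(matrix = expr_matrix(vals, cond), truth = truth)
  })
}

#' Merge the ground truths of several simulated experiments
#'
#' Used when one regulation network must be enriched for the planted genes
#' of several condition pairs: the merged truth's `de_genes` is the union
#' (first direction wins on the rare overlap).
#'
#' @param truths list of `sim_truth` objects.
#' @return a `sim_truth`.
#' @export
merge_truths <- function(truths) {
  de <- unlist(lapply(truths, function(t) t$de_genes))
  de <- de[!duplicated(names(de))]
  cons <- sort(unique(unlist(lapply(truths, function(t) t$conserved_tfs))))
  structure(list(de_genes = de, conserved_tfs = cons), class = "sim_truth")
}

#' Simulate a TF-target regulation network with planted conserved TFs
#'
#' Every TF receives a random target set of uniformly drawn size within
#' `target_size_range`. The first `n_conserved` TFs are planted as
#' conserved regulators: each additionally receives a random fraction
#' `enrichment` of the truth's planted differential genes as targets (its
#' random targets are drawn outside that planted set, so its edge count is
#' exactly random size + planted size). All edges carry evidence
#' `documented-direct`.
#'
#' @param genes character vector: the full gene universe.
#' @param truth a `sim_truth` (e.g. from [simulate_expression()] or
#'   [merge_truths()]); updated with the planted TF names.
#' @param n_tfs number of TFs.
#' @param target_size_range length-2 integer range of random target-set
#'   sizes.
#' @param n_conserved number of planted conserved TFs
#'   (`<= n_tfs`).
#' @param enrichment fraction of planted DE genes each conserved TF
#'   targets, in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `regulation` (a [regulation_table()]) and `truth`
#'   (updated `sim_truth` with `conserved_tfs` set).
#' @export
simulate_regulation <- function(genes, truth, n_tfs = 50,
                                target_size_range = c(20, 80),
                                n_conserved = 3, enrichment = 0.5,
                                seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_conserved > n_tfs)
    stop_config("n_conserved (", n_conserved, ") exceeds n_tfs (", n_tfs, ")")
  if (enrichment < 0 || enrichment > 1)
    stop_config("enrichment must be in [0, 1]")
  with_seed(seed, {
    tfs <- sprintf("TF%03d", seq_len(n_tfs))
    planted_tfs <- tfs[seq_len(n_conserved)]
    de <- names(truth$de_genes)
    edges_tf <- character(); edges_target <- character()
    for (i in seq_len(n_tfs)) {
      planted <- if (tfs[i] %in% planted_tfs && length(de))
        sample(de, round(enrichment * length(de))) else character()
      size <- if (target_size_range[1] == target_size_range[2])
        target_size_range[1]
      else sample(seq(target_size_range[1], target_size_range[2]), 1)
      pool <- setdiff(genes, planted)
      random <- sample(pool, min(size, length(pool)))
      tgt <- c(planted, random)
      edges_tf <- c(edges_tf, rep(tfs[i], length(tgt)))
      edges_target <- c(edges_target, tgt)
    }
    truth$conserved_tfs <- planted_tfs
    list(regulation = regulation_table(edges_tf, edges_target,
                                       rep("documented-direct",
                                           length(edges_tf))),
         truth = truth)
  })
}

#' Simulate a reference differential-expression ranking
#'
#' Produces a full ordering of the gene universe whose head is enriched
#' for the truth's planted differential genes, emulating an externally
#' ranked reference DE list whose top genes feed a reference TF profile.
#' Each gene gets a score `effect * 1{planted DE} + N(0, noise_sd)` and
#' genes are ranked by decreasing score; at `noise_sd = 0` all planted
#' genes strictly precede all others, and with no planted genes the
#' ranking is a uniform random permutation.
#'
#' @param genes character vector: the full gene universe.
#' @param truth a `sim_truth`.
#' @param effect score bonus of a planted gene (default 2, matching the
#'   default planted |log2FC|).
#' @param noise_sd ranking noise sd (default 0.5: the head stays
#'   DE-dominated but the order is noisy).
#' @param seed integer seed.
#' @return character vector: all of `genes`, ranked.
#' @export
simulate_reference_ranking <- function(genes, truth, effect = 2,
                                       noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  with_seed(seed, {
    score <- effect * (genes %in% names(truth$de_genes)) +
      stats::rnorm(length(genes), 0, noise_sd)
    genes[order(-score, genes)]
  })
}

#' @rdname simulate_expression
#' @param x a `sim_truth`.
#' @param path output TSV path (columns `kind`, `name`, `direction`).
#' @export
write_sim_truth <- function(x, path) {
  stopifnot(inherits(x, "sim_truth"))
  df <- rbind(
    data.frame(kind = "de_gene", name = names(x$de_genes),
               direction = unname(x$de_genes), stringsAsFactors = FALSE),
    data.frame(kind = "conserved_tf", name = x$conserved_tfs,
               direction = NA_character_, stringsAsFactors = FALSE))
  write_tsv_raw(df, path)
  invisible(path)
}

#' Simulate a multi-comparison study bundle
#'
#' Convenience wrapper tying the generators together the way the full
#' analysis consumes them: `n_pairs` independent two-condition expression
#' experiments over a shared gene universe (each with its own planted DE
#' genes), one regulation network whose planted conserved TFs are enriched
#' for every experiment's DE genes, and one reference ranking.
#' Sub-streams are derived deterministically from the single `seed`.
#'
#' @param config a [sim_config()] applied to every pair (conditions are
#'   labelled `ctl1`/`exp1` ... per pair).
#' @param n_pairs number of condition pairs.
#' @param n_tfs,target_size_range,n_conserved,enrichment passed to
#'   [simulate_regulation()].
#' @param seed master seed.
#' @return list with `experiments` (list of `list(matrix, truth, label)`),
#'   `regulation`, `truth` (merged, with `conserved_tfs`), `ranking`,
#'   `genes`.
#' @export
simulate_study <- function(config = sim_config(), n_pairs = 4,
                           n_tfs = 50, target_size_range = c(20, 80),
                           n_conserved = 3, enrichment = 0.5,
                           seed = 1L) {
  seed <- as.integer(seed)
  experiments <- lapply(seq_len(n_pairs), function(i) {
    cfg <- config
    cfg$seed <- seed + i
    cfg$conditions <- c(sprintf("ctl%d", i), sprintf("exp%d", i))
    sim <- simulate_expression(cfg)
    list(matrix = sim$matrix, truth = sim$truth,
         label = sprintf("pair%d", i))
  })
  genes <- sim_gene_ids(config$n_genes)
  merged <- merge_truths(lapply(experiments, `[[`, "truth"))
  reg <- simulate_regulation(genes, merged, n_tfs = n_tfs,
                             target_size_range = target_size_range,
                             n_conserved = n_conserved,
                             enrichment = enrichment,
                             seed = seed + n_pairs + 1L)
  ranking <- simulate_reference_ranking(genes, experiments[[1]]$truth,
                                        effect = config$effect_log2fc,
                                        seed = seed + n_pairs + 2L)
  list(experiments = experiments, regulation = reg$regulation,
       truth = reg$truth, ranking = ranking, genes = genes)
}

#' Combine a study bundle's experiments into one expression matrix
#'
#' Binds the per-pair two-condition matrices of [simulate_study()] into a
#' single [expr_matrix()] over the shared gene universe, together with the
#' pair list in the form [pipeline_config()] expects.
#'
#' @param study a [simulate_study()] result.
#' @return list with `matrix` and `pairs` (named list of
#'   `c(control, experiment)` condition labels).
#' @export
combine_experiments <- function(study) {
  mats <- lapply(study$experiments, `[[`, "matrix")
  vals <- do.call(cbind, lapply(mats, unclass))
  cond <- do.call(c, lapply(mats, conditions))
  pairs <- lapply(study$experiments, function(e) unname(unique(conditions(e$matrix))))
  names(pairs) <- vapply(study$experiments, `[[`, character(1), "label")
  list(matrix = expr_matrix(vals, cond), pairs = pairs)
}
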