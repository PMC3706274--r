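# Shared fixture builders. Everything is generated in code at test time.

# a tiny valid expression matrix with two conditions
tiny_matrix <- function(values = c(10, 20, 30, 40, 12, 18, 33, 44),
                        n_features = 2) {
  m <- matrix(values, nrow = n_features,
              dimnames = list(paste0("g", seq_len(n_features)),
                              c("c_R1", "c_R2", "e_R1", "e_R2")))
  expr_matrix(m, c(c_R1 = "ctl", c_R2 = "ctl", e_R1 = "exp", e_R2 = "exp"))
}

# write a Cuffdiff-2-dialect .diff file; rows is a data.frame with columns
# test_id, value_1, value_2, lfc, p, q, sig
write_diff_fixture <- function(rows, path = tempfile(fileext = ".diff"),
                               lfc_header = "log2(fold_change)",
                               drop = character()) {
  df <- data.frame(test_id = rows$test_id, gene_id = rows$test_id,
                   gene = rows$test_id, locus = "chr1:1-100",
                   sample_1 = "q1", sample_2 = "q2", status = "OK",
                   value_1 = rows$value_1, value_2 = rows$value_2,
                   lfc = rows$lfc, test_stat = 0,
                   p_value = rows$p, q_value = rows$q,
                   significant = rows$sig,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[names(df) == "lfc"] <- lfc_header
  df <- df[setdiff(names(df), drop)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random pairwise tables over a shared feature universe, for property tests
random_pairwise_tables <- function(n_tables, n_features, p_sig = 0.4) {
  feats <- paste0("f", seq_len(n_features))
  lapply(seq_len(n_tables), function(i) {
    lfc <- stats::rnorm(n_features)
    sig <- stats::runif(n_features) < p_sig
    pairwise_de(feature_id = feats,
                value_control = stats::runif(n_features, 0, 100),
                value_experiment = stats::runif(n_features, 0, 100),
                log2_fold_change = lfc,
                p_value = stats::runif(n_features),
                significant = sig,
                pair_label = c("c", paste0("e", i)))
  })
}

# independent brute-force tally: plain loops, no shared code with consensus()
brute_force_tally <- function(tables, cutoff_n) {
  feats <- sort(unique(unlist(lapply(tables, function(t) t$feature_id))))
  res <- data.frame(feature_id = feats, n_up = 0L, n_down = 0L,
                    stringsAsFactors = FALSE)
  for (t in tables) {
    for (i in seq_len(nrow(t))) {
      j <- which(res$feature_id == t$feature_id[i])
      if (t$direction[i] == "up") res$n_up[j] <- res$n_up[j] + 1L
      if (t$direction[i] == "down") res$n_down[j] <- res$n_down[j] + 1L
    }
  }
  res$selected <- (res$n_up >= cutoff_n & res$n_down == 0L) |
    (res$n_down >= cutoff_n & res$n_up == 0L)
  res
}

# a random top-K TF profile with positive counts
random_profile <- function(n_tf_pool = 12, n_de = 30, K = 20) {
  n <- sample(1:8, 1)
  tfs <- sample(sprintf("TF%02d", seq_len(n_tf_pool)), n)
  counts <- sample(1:n_de, n, replace = TRUE)
  reg <- regulation_table(rep(tfs, counts),
                          unlist(lapply(counts, function(k)
                            sample(paste0("g", 1:n_de), k))),
                          rep("documented-direct", sum(counts)))
  build_profile(paste0("g", 1:n_de), reg, K = K)
}
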