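test_that("pair enumeration is the full Cartesian product", {
  sim <- simulate_expression(sim_config(n_genes = 10, n_de = 2,
                                        n_replicates = 3, seed = 1))
  p <- enumerate_pairs(sim$matrix, "control", "experiment")
  expect_equal(nrow(p), 9)
  expect_equal(p$control, rep(paste0("control_R", 1:3), each = 3))

  m <- tiny_matrix()
  expect_equal(nrow(enumerate_pairs(m, "ctl", "exp")), 4)
  # 1 + 1 replicates give a single pair
  one <- expr_matrix(matrix(c(1, 2, 3, 4), 2,
                            dimnames = list(c("a", "b"), c("s1", "s2"))),
                     c(s1 = "x", s2 = "y"))
  expect_equal(nrow(enumerate_pairs(one, "x", "y")), 1)
  # 2 x 3 replicates give 6 ordered pairs
  sim23 <- simulate_expression(sim_config(n_genes = 5, n_de = 1,
                                          n_replicates = 3, seed = 1))
  m23 <- unclass(sim23$matrix)[, -1]
  em23 <- expr_matrix(m23, conditions(sim23$matrix)[colnames(m23)])
  expect_equal(nrow(enumerate_pairs(em23, "control", "experiment")), 6)

  expect_error(enumerate_pairs(m, "ctl", "nope"),
               class = "repcons_design_error")
})

test_that("the threshold caller computes pseudocounted fold changes", {
  m <- expr_matrix(matrix(c(1, 50, 7, 50), 2,
                          dimnames = list(c("gA", "gB"), c("c1", "e1"))),
                   c(c1 = "ctl", e1 = "exp"))
  tab <- fold_change_caller(m, c("c1", "e1"))
  # log2((7+1)/(1+1)) = 2 >= 1 -> significant, up
  a <- tab[tab$feature_id == "gA", ]
  expect_equal(a$log2_fold_change, 2)
  expect_true(a$significant)
  expect_equal(a$direction, "up")
  # identical values -> nothing called
  b <- tab[tab$feature_id == "gB", ]
  expect_false(b$significant)
  expect_equal(b$direction, "none")

  # infinite fold-change threshold disables every call
  inf <- fold_change_caller(m, c("c1", "e1"),
                            caller_config(min_abs_log2fc = Inf))
  expect_equal(sum(inf$significant), 0)
})

test_that("consensus applies the direction-consistency selection rule", {
  feats <- "G"
  mk <- function(dir) {
    lfc <- switch(dir, up = 2, down = -2, none = 0)
    pairwise_de("G", 1, 4, lfc, p_value = ifelse(dir == "none", 1, 0),
                significant = dir != "none")
  }
  all_up <- consensus(lapply(1:9, function(i) mk("up")), cutoff_n = 9)
  expect_equal(all_up$support, 9L)
  expect_true(all_up$selected)
  expect_equal(all_up$consensus_direction, "up")

  # 5 up + 4 down reaches support 9 but no single direction reaches 9
  mixed <- consensus(lapply(1:9, function(i) mk(if (i <= 5) "up" else "down")),
                     cutoff_n = 9)
  expect_equal(mixed$support, 9L)
  expect_false(mixed$selected)
  expect_equal(mixed$consensus_direction, "none")

  # unanimity rule: an opposing call blocks selection even below the cutoff
  opp <- consensus(lapply(1:9, function(i) mk(if (i <= 8) "up" else "down")),
                   cutoff_n = 5)
  expect_false(opp$selected)
  opp_count <- consensus(lapply(1:9,
                                function(i) mk(if (i <= 8) "up" else "down")),
                         cutoff_n = 5, direction_rule = "count")
  expect_true(opp_count$selected)
  expect_equal(opp_count$consensus_direction, "up")

  expect_error(consensus(list(mk("up")), cutoff_n = 2),
               class = "repcons_config_error")
  universe_a <- pairwise_de(c("x", "y"), c(1, 1), c(2, 2), c(1, 1),
                            c(0, 0), significant = c(TRUE, TRUE))
  universe_b <- pairwise_de("x", 1, 2, 1, 0, significant = TRUE)
  expect_error(consensus(list(universe_a, universe_b), cutoff_n = 1),
               class = "repcons_design_error")
})

test_that("consensus tallies match brute-force enumeration on small instances", {
  set.seed(101)
  for (i in 1:25) {
    n_tables <- sample(1:9, 1)
    tabs <- random_pairwise_tables(n_tables, n_features = sample(1:5, 1))
    cutoff <- sample(seq_len(n_tables), 1)
    got <- consensus(tabs, cutoff)
    oracle <- brute_force_tally(tabs, cutoff)
    got <- got[order(got$feature_id), ]
    expect_equal(got$n_up, oracle$n_up)
    expect_equal(got$n_down, oracle$n_down)
    expect_equal(got$selected, oracle$selected)
  }
})

test_that("selected sets shrink as the cut-off rises", {
  set.seed(55)
  tabs <- random_pairwise_tables(9, 40)
  sizes <- vapply(1:9, function(n) sum(consensus(tabs, n)$selected),
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  sel9 <- de_genes(consensus(tabs, 9))
  sel1 <- de_genes(consensus(tabs, 1))
  expect_true(all(sel9 %in% sel1))
})

test_that("consensus_de recovers planted truth on the default design", {
  sim <- simulate_expression(sim_config(seed = 21))
  fit <- consensus_de(sim$matrix, "control", "experiment")
  sel <- fit$calls[fit$calls$selected, ]
  truth <- sim$truth$de_genes
  # directions of recovered planted genes match the truth
  hit <- sel[sel$feature_id %in% names(truth), ]
  agree <- mean(hit$consensus_direction == truth[hit$feature_id])
  expect_gte(agree, 0.95)

  # identical conditions select nothing
  v <- unclass(sim$matrix)[1:50, 1:3]
  same <- expr_matrix(cbind(v, v2 = v[, 1], v3 = v[, 2], v4 = v[, 3]),
                      stats::setNames(rep(c("a", "b"), each = 3),
                                      c(colnames(v), "v2", "v3", "v4")))
  fit_same <- consensus_de(same, "a", "b")
  expect_equal(sum(fit_same$calls$selected), 0)
})

test_that("consensus_de methods print, summarize, and convert", {
  sim <- simulate_expression(sim_config(n_genes = 80, n_de = 5, seed = 31))
  fit <- consensus_de(sim$matrix, "control", "experiment")
  expect_output(print(fit), "cut-off n = 9")
  s <- summary(fit)
  expect_equal(s$n_selected, sum(fit$calls$selected))
  expect_output(print(s), "support distribution")
  df <- as.data.frame(fit)
  expect_true(all(c("feature_id", "n_up", "n_down", "support",
                    "consensus_direction", "selected") %in% names(df)))
  # output ordering: support descending, then feature id
  expect_true(all(diff(df$support) <= 0))
})
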