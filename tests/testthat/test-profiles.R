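test_that("profiles count DE targets and rank by count then name", {
  reg <- regulation_table(
    c("A", "A", "A", "B", "B", "C"),
    c("g1", "g2", "g3", "g4", "g5", "x9"),
    rep("documented-direct", 6))
  p <- build_profile(c("g1", "g2", "g3", "g4", "g5"), reg)
  expect_equal(p$tf, c("A", "B"))            # C regulates no DE gene
  expect_equal(p$n_targets_in_de, c(3L, 2L))
  expect_equal(p$fraction, c(0.6, 0.4))
  expect_equal(attr(p, "n_de_total"), 5)

  # empty regulation table -> empty profile
  p0 <- build_profile(c("g1", "g2"), regulation_table())
  expect_equal(nrow(p0), 0)

  # 25 tied TFs, K = 20: truncation by lexicographic tie-break
  tfs <- sprintf("tf%02d", 1:25)
  reg25 <- regulation_table(tfs, rep("g1", 25),
                            rep("documented-direct", 25))
  p25 <- build_profile("g1", reg25, K = 20)
  expect_equal(nrow(p25), 20)
  expect_equal(p25$tf, sort(tfs)[1:20])

  expect_error(build_profile(character(), reg),
               class = "repcons_input_error")
})

test_that("alignment zero-fills the union axis and normalizes to unit length", {
  mk <- function(tfs, counts, n_de) {
    reg <- regulation_table(rep(tfs, counts),
                            paste0("d", seq_len(sum(counts))),
                            rep("documented-direct", sum(counts)))
    build_profile(paste0("d", seq_len(n_de)), reg)
  }
  # counts (3, 4) on a shared axis -> the 3-4-5 triangle
  p <- mk(c("A", "B"), c(3, 4), 10)
  np <- align_and_normalize(p, p)
  expect_equal(np[[1]]$vector, c(0.6, 0.8))
  expect_equal(np[[1]]$vector, np[[2]]$vector)
  expect_equal(profile_distance(np[[1]], np[[2]]), 0)

  # disjoint TF sets: axis is the union, vectors are orthogonal units
  pa <- mk("A", 2, 4); pb <- mk("B", 3, 4)
  npd <- align_and_normalize(pa, pb)
  expect_equal(npd[[1]]$axis, c("A", "B"))
  expect_equal(npd[[1]]$vector, c(1, 0))
  expect_equal(npd[[2]]$vector, c(0, 1))
  expect_equal(profile_distance(npd[[1]], npd[[2]]), sqrt(2))

  # (0.6, 0.8) vs (0.8, 0.6): sqrt(0.04 + 0.04)
  p34 <- mk(c("A", "B"), c(3, 4), 10)
  p43 <- mk(c("A", "B"), c(4, 3), 10)
  expect_equal(tf_profile_distance(p34, p43), sqrt(0.08))

  # L1 normalization sums to one
  nl1 <- align_and_normalize(p34, p43, norm = "l1")
  expect_equal(sum(nl1[[1]]$vector), 1)

  expect_error(profile_distance(npd[[1]],
                                structure(list(axis = "Z", vector = 1),
                                          class = "normalized_profile")),
               class = "repcons_design_error")
})

test_that("normalized profiles have unit norm and metric-axiom distances", {
  set.seed(77)
  for (i in 1:60) {
    p1 <- random_profile(); p2 <- random_profile(); p3 <- random_profile()
    n12 <- align_and_normalize(p1, p2)
    expect_equal(sqrt(sum(n12[[1]]$vector^2)), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(n12[[2]]$vector^2)), 1, tolerance = 1e-9)

    d12 <- tf_profile_distance(p1, p2)
    d21 <- tf_profile_distance(p2, p1)
    expect_gte(d12, 0)
    expect_equal(d12, d21, tolerance = 1e-12)          # symmetry
    expect_lte(d12, sqrt(2) + 1e-12)                   # nonneg-unit bound
    expect_equal(tf_profile_distance(p1, p1), 0)       # identity

    # triangle inequality on a common axis
    axis <- sort(unique(c(p1$tf, p2$tf, p3$tf)))
    unit <- function(p) {
      v <- stats::setNames(numeric(length(axis)), axis)
      v[p$tf] <- p$fraction
      v / sqrt(sum(v^2))
    }
    v1 <- unit(p1); v2 <- unit(p2); v3 <- unit(p3)
    d <- function(a, b) sqrt(sum((a - b)^2))
    expect_lte(d(v1, v3), d(v1, v2) + d(v2, v3) + 1e-12)
  }
})

test_that("normalization is invariant to rescaling the profile counts", {
  set.seed(12)
  p <- random_profile()
  scaled <- p
  scaled$fraction <- p$fraction * 17.3   # same counts up to a constant
  q <- random_profile()
  expect_equal(tf_profile_distance(p, q), tf_profile_distance(scaled, q),
               tolerance = 1e-12)
})

test_that("conserved TFs are a sorted, idempotent, order-free intersection", {
  mk <- function(tfs) {
    reg <- regulation_table(tfs, paste0("g", seq_along(tfs)),
                            rep("documented-direct", length(tfs)))
    build_profile(paste0("g", 1:5), reg)
  }
  pa <- mk(c("A", "B", "C")); pb <- mk(c("B", "C", "D"))
  expect_equal(conserved_tfs(list(pa, pb)), c("B", "C"))
  expect_equal(conserved_tfs(list(pb, pa)), c("B", "C"))
  expect_equal(conserved_tfs(list(pa, pa, pb, pb)), c("B", "C"))
  expect_equal(conserved_tfs(list(pa)), c("A", "B", "C"))
  expect_equal(conserved_tfs(list(mk("A"), mk("B"))), character())
})

test_that("reference profiles use the ranking head and recover planted TFs", {
  st <- simulate_study(sim_config(n_genes = 1000, n_de = 40, seed = 17),
                       n_pairs = 1, seed = 17)
  ref <- build_reference_profile(st$ranking, st$regulation,
                                 n_ref_genes = 250)
  expect_true(all(st$truth$conserved_tfs %in% ref$tf))

  # n_ref_genes = |ranking| degenerates to a whole-set profile
  whole <- build_reference_profile(st$ranking, st$regulation,
                                   n_ref_genes = length(st$ranking))
  direct <- build_profile(st$ranking, st$regulation, label = "reference")
  expect_equal(as.data.frame(whole), as.data.frame(direct))

  expect_error(build_reference_profile(st$ranking[1:100], st$regulation,
                                       n_ref_genes = 250),
               class = "repcons_input_error")
})
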