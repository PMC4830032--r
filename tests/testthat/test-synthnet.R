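test_that("generator output is schema-valid, seeded and leakage-free", {
  cfg <- synth_config(seed = 3, n_compound = 60L, n_protein = 30L)
  gen <- generate_hetnet(cfg)
  net <- gen$net
  expect_s3_class(net, "hetnet")
  expect_setequal(names(net$adjacency), paste0("A", 1:12))
  expect_true(all(edge_count(net) >= 0))
  # every edge type emitted something at the default densities
  expect_true(all(edge_count(net)[c("A2", "A11", "A12", "A7")] > 0))

  # held-out positives are pre-removed from the binding adjacency
  pos <- gen$truth$positives
  a2 <- adjacency(net, "A2")
  idx <- cbind(match(pos$compound_id, net$registries$compound),
               match(pos$protein_id, net$registries$protein))
  expect_true(all(a2[idx] == 0))
  # negatives are never-linked by construction
  neg <- gen$truth$negatives
  idx_n <- cbind(match(neg$compound_id, net$registries$compound),
                 match(neg$protein_id, net$registries$protein))
  expect_true(all(a2[idx_n] == 0))
  expect_equal(nrow(neg), nrow(pos))

  # same seed: byte-identical serialized edge lists
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_edge_list(net, p1)
  write_edge_list(generate_hetnet(cfg)$net, p2)
  expect_identical(readLines(p1), readLines(p2))
  # different seed: different network
  p3 <- withr::local_tempfile()
  write_edge_list(generate_hetnet(synth_config(seed = 4, n_compound = 60L,
                                               n_protein = 30L))$net, p3)
  expect_false(identical(readLines(p1), readLines(p3)))
})

test_that("symmetric edge types come out symmetric with zero diagonals", {
  net <- generate_hetnet(synth_config(seed = 8, n_compound = 50L,
                                      n_protein = 40L))$net
  for (id in c("A6", "A11", "A12")) {
    m <- adjacency(net, id)
    expect_true(Matrix::isSymmetric(m), label = id)
    expect_true(all(Matrix::diag(m) == 0), label = id)
  }
})

test_that("similarity reaches held-out targets in the fully coherent world", {
  gen <- generate_hetnet(synth_config(seed = 12, n_compound = 60L,
                                      n_protein = 30L, p_in = 1, p_out = 0,
                                      sim_compound = 1, coherence = 1,
                                      holdout_frac = 0.2))
  grp_c <- gen$truth$compound_group
  grp_p <- gen$truth$protein_group
  c1 <- compute_commuting(gen$net, default_catalog()[["C1"]])$matrix
  pos <- gen$truth$positives
  for (k in seq_len(min(25, nrow(pos)))) {
    ci <- pos$compound_id[k]; pi <- pos$protein_id[k]
    # a similar in-group neighbor binding the protein exists unless the
    # compound is alone in its group or every in-group link to it was held out
    nbr <- names(grp_c)[grp_c == grp_c[[ci]] & names(grp_c) != ci]
    binds_p <- adjacency(gen$net, "A2")[match(nbr, gen$net$registries$compound),
                                        match(pi, gen$net$registries$protein)]
    if (sum(binds_p) > 0)
      expect_gte(c1[match(ci, gen$net$registries$compound),
                    match(pi, gen$net$registries$protein)], 1)
  }
})

test_that("activity tables round-trip labels, with controlled noise", {
  gen <- generate_hetnet(synth_config(seed = 5, n_compound = 80L,
                                      n_protein = 40L))
  clean <- generate_activity_table(gen$truth, noise_rate = 0)
  lab <- label_from_activity(clean)
  truth <- rbind(gen$truth$positives[, 1:3], gen$truth$negatives[, 1:3])
  expect_equal(nrow(lab), nrow(truth))
  merged <- merge(lab, truth, by = c("compound_id", "protein_id"))
  expect_equal(merged$label.x, merged$label.y)

  noisy <- generate_activity_table(gen$truth, noise_rate = 0.1)
  n_flip <- attr(noisy, "n_flipped")
  n <- nrow(noisy)
  expect_gt(n_flip, n * 0.1 - 3 * sqrt(n * 0.1 * 0.9))
  expect_lt(n_flip, n * 0.1 + 3 * sqrt(n * 0.1 * 0.9))

  empty <- gen$truth
  empty$positives <- empty$positives[0, ]
  empty$negatives <- empty$negatives[0, ]
  expect_equal(nrow(generate_activity_table(empty)), 0L)
})

test_that("config validation rejects bad probabilities and missing seeds", {
  expect_error(synth_config(p_in = 1.2, seed = 1))
  expect_error(synth_config(n_compound = 50), "seed")
})

test_that("stronger planted signal never degrades downstream ranking (5-seed mean)", {
  auc_for <- function(p_in, seed) {
    gen <- generate_hetnet(synth_config(seed = seed, n_compound = 100L,
                                        n_protein = 60L, p_in = p_in,
                                        p_out = 0.003))
    labels <- rbind(gen$truth$positives, gen$truth$negatives)
    net <- suppressMessages(leakage_guard(gen$net, labels))
    ft <- extract_features(net, default_catalog(), labels, c("PC", "RW"))
    sp <- split_dataset(ft, c(2, 1), seed = seed + 900)
    m <- train_model(sp$train, sp$train$label,
                     model_spec("rf", ntree = 80, mtry_grid = 10L, seed = seed))
    evaluate_model(m, sp$test, sp$test$label)$auc_roc
  }
  means <- vapply(c(0.01, 0.04, 0.10), function(p)
    mean(vapply(1:5, function(s) auc_for(p, s), 0)), 0)
  expect_true(all(diff(means) >= 0))
})

test_that("default-scale feature extraction over the full catalog is fast", {
  gen <- generate_hetnet(synth_config(seed = 2))
  pairs <- rbind(gen$truth$positives, gen$truth$negatives)
  elapsed <- system.time(
    ft <- extract_features(gen$net, default_catalog(), pairs, c("PC", "RW"))
  )["elapsed"]
  expect_length(feature_columns(ft), 102L)
  expect_lt(elapsed, 60)
})
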