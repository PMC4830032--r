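schema <- default_schema()
catalog <- default_catalog(schema)

test_that("commuting matrix counts C1 walk instances on a worked example", {
  net <- tiny_net(tiny_edges(c("A11", "c1", "c2"), c("A2", "c2", "p1"),
                             c("A2", "c2", "p2")))
  pc <- compute_commuting(net, catalog[["C1"]])$matrix
  expect_equal(pc["c1", "p1"], 1)
  expect_equal(pc["c1", "p2"], 1)
  expect_equal(sum(pc["c2", ]), 0)  # c2's only similar neighbor binds nothing
  expect_equal(brute_force_walk_count(net, catalog[["C1"]], "c1", "p1"), 1)
})

test_that("an all-zero adjacency along the path annihilates the product", {
  net <- tiny_net(tiny_edges(c("A11", "c1", "c2")),
                  nodes = list(protein = c("p1", "p2")))
  pc <- compute_commuting(net, catalog[["C1"]])$matrix
  expect_equal(Matrix::nnzero(pc), 0)
  expect_equal(brute_force_walk_count(net, catalog[["C1"]], "c1", "p1"), 0)
})

test_that("shared-target walks (C7) may revisit links, matching the oracle", {
  net <- tiny_net(tiny_edges(c("A2", "c1", "p1"), c("A2", "c2", "p1"),
                             c("A2", "c2", "p2")))
  c7 <- catalog[["C7"]]
  pc <- compute_commuting(net, c7)$matrix
  expect_equal(pc["c1", "p2"], 1)  # c1-p1-c2-p2
  # c1-p1-c1-p1 (link revisited) and c1-p1-c2-p1
  expect_equal(pc["c1", "p1"], 2)
  expect_equal(as.matrix(pc), brute_force_matrix(net, c7), ignore_attr = TRUE)
  expect_equal(brute_force_walk_count(net, c7, "c1", "p1"), 2)
})

test_that("length-1 path count equals the adjacency entry", {
  net <- tiny_net(tiny_edges(c("A2", "c1", "p1")))
  mp <- metapath("binds", "A2", schema)
  expect_equal(brute_force_walk_count(net, mp, "c1", "p1"), 1)
  expect_equal(as.matrix(compute_commuting(net, mp)$matrix),
               as.matrix(adjacency(net, "A2")), ignore_attr = TRUE)
})

test_that("commuting products agree with walk enumeration on random networks", {
  for (seed in 1:6) {
    net <- random_net(seed)
    for (mp in catalog[c("C1", "C4", "C7", "C15", "C18", "C39", "C45")]) {
      expect_equal(as.matrix(compute_commuting(net, mp)$matrix),
                   brute_force_matrix(net, mp), ignore_attr = TRUE,
                   label = sprintf("seed %d, %s", seed, mp$id))
    }
  }
})

test_that("commuting matrices decompose and reverse like matrix products", {
  net <- random_net(7)
  full <- compute_commuting(net, catalog[["C6"]])$matrix  # A11 . A2 . A12
  left <- compute_commuting(net, metapath("l", c("A11", "A2"), schema))$matrix
  right <- compute_commuting(net, metapath("r", "A12", schema))$matrix
  expect_equal(as.matrix(full), as.matrix(left %*% right), ignore_attr = TRUE)

  rev_c6 <- metapath("rev", c("A12", "A2^T", "A11"), schema)
  expect_equal(as.matrix(compute_commuting(net, rev_c6)$matrix),
               t(as.matrix(full)), ignore_attr = TRUE)
})

test_that("removing a link never increases any path count", {
  net <- random_net(8)
  tm <- methods::as(adjacency(net, "A2"), "TsparseMatrix")
  pruned <- remove_links(net, "A2", data.frame(
    source = net$registries$compound[tm@i[1] + 1L],
    target = net$registries$protein[tm@j[1] + 1L]))
  for (mp in catalog[c("C1", "C7", "C19")]) {
    before <- compute_commuting(net, mp)$matrix
    after <- compute_commuting(pruned, mp)$matrix
    expect_true(all(as.matrix(after) <= as.matrix(before)), label = mp$id)
  }
})

test_that("random-walk normalization produces row-stochastic rows, zeros kept", {
  m <- Matrix::sparseMatrix(i = c(1, 1, 3), j = c(1, 2, 2), x = c(3, 1, 5),
                            dims = c(3, 3))
  rw <- rw_normalize(m)
  expect_equal(as.numeric(rw[1, ]), c(0.75, 0.25, 0))
  expect_equal(as.numeric(rw[2, ]), c(0, 0, 0))     # 0/0 -> 0
  expect_equal(as.numeric(rw[3, ]), c(0, 1, 0))     # single nonzero -> 1
  # scaling a PC row by a positive integer leaves RW unchanged
  m2 <- m
  m2[1, ] <- m[1, ] * 7
  expect_equal(as.matrix(rw_normalize(m2)), as.matrix(rw))
  # property on a random commuting matrix
  pc <- compute_commuting(random_net(9), catalog[["C18"]])$matrix
  rs <- Matrix::rowSums(rw_normalize(pc))
  expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
})

test_that("feature extraction yields the documented column counts", {
  pool <- planted_pool(seed = 31, n_compound = 50L, n_protein = 30L)
  pairs <- pool$labels[1:20, ]
  expect_length(feature_columns(
    extract_features(pool$net, catalog, pairs, c("PC", "RW"))), 102L)
  expect_length(feature_columns(
    extract_features(pool$net, catalog, pairs, "PC")), 51L)
  expect_length(feature_columns(
    extract_features(pool$net, similarity_free(catalog, schema), pairs, "PC")),
    29L)
  # deterministic column order: catalog order x (PC, RW)
  ft <- extract_features(pool$net, catalog[c("C2", "C1")], pairs, c("PC", "RW"))
  expect_equal(feature_columns(ft), c("C2_PC", "C2_RW", "C1_PC", "C1_RW"))
  expect_error(extract_features(pool$net, catalog,
                                data.frame(compound_id = "nope",
                                           protein_id = "p0001")),
               "unregistered")
})

test_that("feature values are the commuting-matrix entries for each pair", {
  net <- tiny_net(tiny_edges(c("A11", "c1", "c2"), c("A2", "c2", "p1"),
                             c("A2", "c2", "p2"), c("A2", "c1", "p2")))
  pairs <- data.frame(compound_id = c("c1", "c1"), protein_id = c("p1", "p2"))
  ft <- extract_features(net, catalog["C1"], pairs, c("PC", "RW"))
  expect_equal(ft$C1_PC, c(1, 1))
  expect_equal(ft$C1_RW, c(0.5, 0.5))
  rt <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft, rt)
  expect_equal(read_feature_table(rt)$C1_RW, ft$C1_RW)
})
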