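test_that("packaged default schema declares the expected node and edge types", {
  schema <- default_schema()
  expect_s3_class(schema, "hetnet_schema")
  expect_length(schema$node_types, 9L)
  expect_equal(nrow(schema$edge_specs), 12L)
  expect_equal(schema$edge_specs$id, paste0("A", 1:12))
  expect_equal(schema$edge_specs$id[schema$edge_specs$is_similarity],
               c("A11", "A12"))
  # binding links run compound -> protein
  a2 <- schema$edge_specs[schema$edge_specs$id == "A2", ]
  expect_equal(c(a2$source_type, a2$target_type), c("compound", "protein"))
})

test_that("schema validation rejects bad configs and accepts empty edge lists", {
  dir <- withr::local_tempdir()
  write_yaml_schema <- function(node_types, edge_types) {
    path <- tempfile(tmpdir = dir, fileext = ".yaml")
    yaml::write_yaml(list(name = "t", node_types = node_types,
                          edge_types = edge_types), path)
    path
  }
  empty <- load_schema(write_yaml_schema(c("compound", "protein"), list()))
  expect_equal(nrow(empty$edge_specs), 0L)

  bad <- write_yaml_schema("compound",
    list(list(id = "E1", predicate = "binds", from = "compound", to = "gene")))
  expect_error(load_schema(bad), "E1.*gene")

  dup <- write_yaml_schema(c("compound", "protein"), list(
    list(id = "E1", predicate = "a", from = "compound", to = "protein"),
    list(id = "E1", predicate = "b", from = "compound", to = "protein")))
  expect_error(load_schema(dup), "duplicate edge spec id")
})

test_that("edge-list reading collapses duplicates, symmetrizes, drops self-loops", {
  net <- tiny_net(tiny_edges(c("A2", "c1", "p1"), c("A2", "c1", "p1")))
  expect_equal(unname(edge_count(net, "A2")), 1)

  net <- tiny_net(tiny_edges(c("A11", "c1", "c2")))
  a11 <- adjacency(net, "A11")
  expect_equal(a11[1, 2], 1)
  expect_equal(a11[2, 1], 1)

  expect_warning(net <- tiny_net(tiny_edges(c("A11", "c1", "c1")),
                                 nodes = list(compound = "c1")),
                 "self-loop")
  expect_equal(unname(edge_count(net, "A11")), 0)
})

test_that("edge-list parse errors carry line numbers", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "A2\tc1\tp1", "A99\tc1\tp1"), path)
  expect_error(read_edge_list(path, default_schema()), "A99.*line 3")
  writeLines(c("A2\tc1"), path)
  expect_error(read_edge_list(path, default_schema()), "line 1")
})

test_that("reverse adjacency is the transpose; symmetric specs are direction-free", {
  net <- tiny_net(tiny_edges(c("A2", "c1", "p1"), c("A4", "se1", "c1"),
                             c("A12", "p1", "p2")))
  expect_equal(dim(adjacency(net, "A4", "forward")),
               rev(dim(adjacency(net, "A4", "reverse"))))
  expect_equal(adjacency(net, "A2", "reverse")["p1", "c1"], 1)
  expect_equal(as.matrix(adjacency(net, "A12", "forward")),
               as.matrix(adjacency(net, "A12", "reverse")))
  expect_error(adjacency(net, "A99"), "unknown edge spec")
  # property: forward == t(reverse) for every spec of a random network
  rnet <- random_net(101)
  for (id in paste0("A", 1:12))
    expect_equal(as.matrix(adjacency(rnet, id, "forward")),
                 t(as.matrix(adjacency(rnet, id, "reverse"))),
                 ignore_attr = TRUE)
})

test_that("remove_links deletes pairs copy-on-write and is idempotent", {
  net <- tiny_net(tiny_edges(c("A2", "c1", "p1"), c("A2", "c2", "p1")))
  pruned <- remove_links(net, "A2", data.frame(source = "c1", target = "p1"))
  expect_equal(unname(edge_count(pruned, "A2")), 1)
  expect_equal(adjacency(pruned, "A2")["c2", "p1"], 1)
  expect_equal(unname(edge_count(net, "A2")), 2)  # original untouched
  expect_equal(attr(pruned, "n_removed"), 1)

  expect_message(again <- remove_links(pruned, "A2",
                                       data.frame(source = "c1", target = "p1")),
                 "already absent")
  expect_equal(unname(edge_count(again, "A2")), 1)

  # symmetric spec clears the mirrored entry
  net <- tiny_net(tiny_edges(c("A11", "c1", "c2")))
  pruned <- remove_links(net, "A11", data.frame(source = "c2", target = "c1"))
  expect_equal(unname(edge_count(pruned, "A11")), 0)

  expect_warning(remove_links(net, "A11",
                              data.frame(source = "zz", target = "c1")),
                 "unregistered")
})

test_that("matrix export/import round-trips through MTX plus id sidecar", {
  net <- tiny_net(tiny_edges(c("A2", "c1", "p1"), c("A2", "c2", "p2")))
  path <- withr::local_tempfile(fileext = ".mtx")
  export_matrix(net, "A2", path)
  back <- import_matrix(path)
  expect_equal(as.matrix(back$matrix), as.matrix(adjacency(net, "A2")),
               ignore_attr = TRUE)
  expect_equal(back$row_ids, net$registries$compound)
  expect_equal(back$col_ids, net$registries$protein)

  # empty adjacency still round-trips
  export_matrix(net, "A6", path)
  expect_equal(Matrix::nnzero(import_matrix(path)$matrix), 0)

  # tampered sidecar is rejected
  export_matrix(net, "A2", path)
  ids <- read.table(paste0(path, ".ids.tsv"), header = TRUE, sep = "\t")
  write.table(ids[-2, ], paste0(path, ".ids.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(import_matrix(path), "sidecar")
})

test_that("edge-list writer round-trips a synthetic network byte-identically", {
  gen <- generate_hetnet(synth_config(seed = 5, n_compound = 40L,
                                      n_protein = 25L))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(gen$net, p1)
  back <- read_edge_list(p1, default_schema(), nodes = gen$net$registries)
  write_edge_list(back, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(edge_count(back), edge_count(gen$net))
})
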