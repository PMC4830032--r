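#' Construct a heterogeneous network from node registries and edges
#'
#' Most users build networks with [read_edge_list()] (from a TSV) or
#' [generate_hetnet()] (synthetic); this low-level constructor takes the
#' pieces directly.
#'
#' @param schema a `hetnet_schema` from [load_schema()].
#' @param registries named list (one per node type) of character vectors of
#'   external node identifiers; each vector defines the dense 0-based matrix
#'   indexing for that type.
#' @param edges data.frame with columns `edge`, `source`, `target` (external
#'   ids), one row per observed link.
#' @return A `hetnet`: schema, per-type registries, and one sparse 0/1
#'   adjacency matrix (`Matrix::dgCMatrix`) per edge spec. Same-type specs
#'   (protein interaction, similarity links) are symmetrized and their
#'   diagonal cleared; duplicate rows collapse to a single 1.
#' @export
hetnet <- function(schema, registries, edges = NULL) {
  stopifnot(inherits(schema, "hetnet_schema"))
  for (nt in schema$node_types) {
    if (is.null(registries[[nt]])) registries[[nt]] <- character(0)
    registries[[nt]] <- as.character(registries[[nt]])
    if (anyDuplicated(registries[[nt]]))
      stop("duplicate node id in registry for type '", nt, "'", call. = FALSE)
  }
  net <- structure(list(schema = schema,
                        registries = registries[schema$node_types],
                        adjacency = list()),
                   class = "hetnet")
  es <- schema$edge_specs
  for (i in seq_len(nrow(es))) {
    e <- es[i, ]
    sub <- if (is.null(edges)) NULL else edges[edges$edge == e$id, , drop = FALSE]
    net$adjacency[[e$id]] <- build_adjacency(e, registries, sub)
  }
  net
}

build_adjacency <- function(e, registries, rows) {
  nr <- length(registries[[e$source_type]])
  nc <- length(registries[[e$target_type]])
  dn <- list(registries[[e$source_type]], registries[[e$target_type]])
  if (is.null(rows) || nrow(rows) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(nr, nc), dimnames = dn))
  i <- match(rows$source, registries[[e$source_type]])
  j <- match(rows$target, registries[[e$target_type]])
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(rows$source[is.na(i)], rows$target[is.na(j)]))
    stop("edge spec '", e$id, "': unregistered node id(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  same_type <- e$source_type == e$target_type
  if (same_type) {
    loops <- i == j
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped on same-type edge spec '",
              e$id, "'", call. = FALSE)
      i <- i[!loops]; j <- j[!loops]
    }
    # store symmetric: emit both orientations, dedup via boolean collapse
    ii <- c(i, j); j <- c(j, i); i <- ii
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                            dims = c(nr, nc), dimnames = dn)
  # collapse duplicates (sparseMatrix sums them) back to boolean 0/1
  m@x[] <- 1
  m
}

#' Read a typed edge list into a heterogeneous network
#'
#' The TSV has three columns -- edge spec id, source node id, target node id
#' -- with an optional header and `#` comment lines. Duplicate rows collapse
#' to a single observed link; rows of same-type specs are symmetrized and
#' self-loops are dropped with a warning.
#'
#' @param path path to the edge-list TSV (or a data.frame with columns
#'   `edge`, `source`, `target`).
#' @param schema a `hetnet_schema`; every row's edge id must be declared.
#' @param nodes optional named list of character vectors pre-registering node
#'   ids per type (e.g. isolated nodes that carry no edges).
#' @return A `hetnet`.
#' @export
read_edge_list <- function(path, schema, nodes = NULL) {
  if (is.data.frame(path)) {
    rows <- path
    names(rows)[1:3] <- c("edge", "source", "target")
    rows$line <- seq_len(nrow(rows))
  } else {
    raw <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", raw)
    lineno <- which(keep)
    fields <- strsplit(raw[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 3L))
      stop("malformed edge-list row at line ", lineno[which(nf != 3L)[1L]],
           ": expected 3 tab-separated fields", call. = FALSE)
    rows <- data.frame(edge = vapply(fields, `[[`, "", 1L),
                       source = vapply(fields, `[[`, "", 2L),
                       target = vapply(fields, `[[`, "", 3L),
                       line = lineno, stringsAsFactors = FALSE)
    if (nrow(rows) && rows$edge[1L] %in% c("edge", "edge_type", "edge_spec_id"))
      rows <- rows[-1L, , drop = FALSE]   # optional header
  }
  unknown <- !(rows$edge %in% schema$edge_specs$id)
  if (any(unknown))
    stop("unknown edge spec id '", rows$edge[unknown][1L], "' at line ",
         rows$line[unknown][1L], call. = FALSE)

  registries <- list()
  for (nt in schema$node_types) {
    es <- schema$edge_specs
    src_ids <- rows$source[rows$edge %in% es$id[es$source_type == nt]]
    tgt_ids <- rows$target[rows$edge %in% es$id[es$target_type == nt]]
    registries[[nt]] <- sort(unique(c(as.character(nodes[[nt]]),
                                      src_ids, tgt_ids)))
  }
  hetnet(schema, registries, rows)
}

#' Write a network back to an edge-list TSV
#'
#' Inverse of [read_edge_list()]; same-type specs emit each undirected link
#' once (upper triangle). Rows are sorted, so equal networks serialize to
#' byte-identical files.
#'
#' @param net a `hetnet`.
#' @param path output file.
#' @export
write_edge_list <- function(net, path) {
  out <- lapply(net$schema$edge_specs$id, function(id) {
    e <- edge_spec(net$schema, id)
    m <- net$adjacency[[id]]
    tm <- methods::as(m, "TsparseMatrix")
    i <- tm@i + 1L; j <- tm@j + 1L
    if (e$source_type == e$target_type) {
      keep <- i < j
      i <- i[keep]; j <- j[keep]
    }
    if (!length(i)) return(NULL)
    data.frame(edge = id,
               source = net$registries[[e$source_type]][i],
               target = net$registries[[e$target_type]][j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(edge = character(), source = character(),
                                      target = character())
  out <- out[order(out$edge, out$source, out$target), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.hetnet <- function(x, ...) {
  cat("<hetnet> schema '", x$schema$name, "'\n", sep = "")
  for (nt in x$schema$node_types)
    cat(sprintf("  %-14s %6d nodes\n", nt, length(x$registries[[nt]])))
  for (id in x$schema$edge_specs$id)
    cat(sprintf("  %-4s %8d links\n", id, edge_count(x, id)))
  invisible(x)
}

#' Per-edge-type link counts (nonzeros of each adjacency)
#'
#' For same-type specs the count is of stored nonzeros, i.e. each undirected
#' link counts twice, matching the symmetric matrix representation.
#'
#' @param net a `hetnet`.
#' @param edge_spec_id a single edge spec id, or `NULL` for all.
#' @return Named integer vector of nonzero counts.
#' @export
edge_count <- function(net, edge_spec_id = NULL) {
  ids <- if (is.null(edge_spec_id)) net$schema$edge_specs$id else edge_spec_id
  vapply(ids, function(id) Matrix::nnzero(net$adjacency[[id]]), 0)
}

#' Oriented adjacency matrix of an edge spec
#'
#' The reverse relation of every edge spec is the transpose of its forward
#' adjacency. The returned matrix is a read-only view by contract: callers
#' must not modify it in place.
#'
#' @param net a `hetnet`.
#' @param edge_spec_id edge spec id, e.g. `"A2"`.
#' @param direction `"forward"` (as declared in the schema) or `"reverse"`.
#' @return A sparse 0/1 matrix with rows = oriented source type, columns =
#'   oriented target type.
#' @export
adjacency <- function(net, edge_spec_id, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  edge_spec(net$schema, edge_spec_id)  # validates the id
  m <- net$adjacency[[edge_spec_id]]
  if (direction == "reverse") Matrix::t(m) else m
}

#' Remove links from one edge type (copy-on-write)
#'
#' Used for leakage control: the positively labeled compound-protein links
#' are deleted from the network before topological features are computed, so
#' no feature encodes direct knowledge of the label. The input network is
#' not modified; for same-type specs the mirrored entry is cleared too.
#'
#' @param net a `hetnet`.
#' @param edge_spec_id the edge spec to edit.
#' @param pairs data.frame (or 2-column matrix) of `source`, `target`
#'   external ids. Pairs with unregistered ids are no-ops, with a warning.
#' @return A new `hetnet`; attribute `"n_removed"` carries the number of
#'   links actually deleted (pairs already absent are logged, not errors).
#' @export
remove_links <- function(net, edge_spec_id, pairs) {
  e <- edge_spec(net$schema, edge_spec_id)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("source", "target")
  i <- match(as.character(pairs$source), net$registries[[e$source_type]])
  j <- match(as.character(pairs$target), net$registries[[e$target_type]])
  unreg <- is.na(i) | is.na(j)
  if (any(unreg)) {
    warning(sum(unreg), " pair(s) with unregistered ids ignored by remove_links",
            call. = FALSE)
    i <- i[!unreg]; j <- j[!unreg]
  }
  m <- net$adjacency[[edge_spec_id]]
  present <- m[cbind(i, j)] != 0
  if (any(!present))
    message(sum(!present), " pair(s) already absent from ", edge_spec_id)
  if (any(present)) {
    m[cbind(i[present], j[present])] <- 0
    if (e$source_type == e$target_type)
      m[cbind(j[present], i[present])] <- 0
    m <- Matrix::drop0(m)
  }
  net$adjacency[[edge_spec_id]] <- m
  attr(net, "n_removed") <- sum(present)
  net
}

#' Export / import one typed adjacency via Matrix Market files
#'
#' `export_matrix()` writes the sparse matrix in MatrixMarket coordinate
#' format plus a sidecar `<path>.ids.tsv` mapping matrix rows and columns
#' back to external node ids. `import_matrix()` reads the pair back and
#' validates that the sidecar covers every row and column.
#'
#' @param net a `hetnet`.
#' @param edge_spec_id edge spec to export.
#' @param path output `.mtx` path (sidecar written next to it).
#' @return `export_matrix`: the path, invisibly. `import_matrix`: a list with
#'   `matrix` (sparse), `row_ids`, `col_ids`, `edge_spec_id`.
#' @export
export_matrix <- function(net, edge_spec_id, path) {
  e <- edge_spec(net$schema, edge_spec_id)
  m <- net$adjacency[[edge_spec_id]]
  Matrix::writeMM(m, path)
  ids <- rbind(
    data.frame(axis = "row", index = seq_len(nrow(m)),
               id = net$registries[[e$source_type]]),
    data.frame(axis = "col", index = seq_len(ncol(m)),
               id = net$registries[[e$target_type]])
  )
  ids$edge_spec_id <- edge_spec_id
  utils::write.table(ids, paste0(path, ".ids.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_matrix
#' @param path path to a `.mtx` file previously written by `export_matrix()`.
#' @export
import_matrix <- function(path) {
  m <- methods::as(Matrix::readMM(path), "CsparseMatrix") * 1  # always numeric
  sidecar <- paste0(path, ".ids.tsv")
  if (!file.exists(sidecar))
    stop("missing id-map sidecar: ", sidecar, call. = FALSE)
  ids <- utils::read.table(sidecar, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  rows <- ids[ids$axis == "row", ]
  cols <- ids[ids$axis == "col", ]
  if (nrow(rows) != nrow(m) || !setequal(rows$index, seq_len(nrow(m))))
    stop("id-map sidecar does not cover every matrix row", call. = FALSE)
  if (nrow(cols) != ncol(m) || !setequal(cols$index, seq_len(ncol(m))))
    stop("id-map sidecar does not cover every matrix column", call. = FALSE)
  dimnames(m) <- list(rows$id[order(rows$index)], cols$id[order(cols$index)])
  list(matrix = m,
       row_ids = rows$id[order(rows$index)],
       col_ids = cols$id[order(cols$index)],
       edge_spec_id = unique(ids$edge_spec_id)[1L])
}

node_positions <- function(net, node_type, ids) {
  pos <- match(as.character(ids), net$registries[[node_type]])
  if (anyNA(pos))
    stop("unregistered ", node_type, " id(s): ",
         paste(utils::head(unique(ids[is.na(pos)]), 5), collapse = ", "),
         call. = FALSE)
  pos
}
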