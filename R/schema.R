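#' Load a network schema from a YAML config
#'
#' A schema declares the node types of a heterogeneous (semantic) network and
#' the typed edge specs connecting them. Every edge type is traversable in
#' both directions: the reverse relation is the transpose of the forward
#' adjacency matrix. Edge types flagged `similarity: true` (and any edge type
#' whose two endpoint types coincide) are treated as undirected: their
#' adjacency is stored symmetric with a zero diagonal.
#'
#' The packaged default (`default_schema()`) has 9 node types and 12 edge
#' specs `A1`-`A12`: compound-ChEBI type, compound-protein binding,
#' compound-substructure, side effect-compound, disease-compound,
#' protein-protein interaction, protein-GO annotation, disease-protein,
#' pathway-protein, tissue-protein, plus compound-compound 2D structural
#' similarity (`A11`) and protein-protein sequence similarity (`A12`).
#'
#' @param path path to a YAML schema config. The file must declare
#'   `node_types` (a list of names) and `edge_types` (a list of maps with
#'   `id`, `predicate`, `reverse_predicate`, `from`, `to` and an optional
#'   logical `similarity`).
#' @return An object of class `hetnet_schema`: a list with elements
#'   `name`, `node_types` (character) and `edge_specs` (a data.frame with one
#'   row per edge spec, in declaration order).
#' @export
load_schema <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$node_types) || length(cfg$node_types) == 0L)
    stop("schema config declares no node types", call. = FALSE)
  if (is.null(cfg$edge_types)) cfg$edge_types <- list()
  node_types <- vapply(cfg$node_types, as.character, character(1))
  if (anyDuplicated(node_types))
    stop("duplicate node type in schema: ",
         paste(unique(node_types[duplicated(node_types)]), collapse = ", "),
         call. = FALSE)

  specs <- lapply(cfg$edge_types, function(e) {
    for (f in c("id", "predicate", "from", "to")) {
      if (is.null(e[[f]]))
        stop("edge spec missing field '", f, "'", call. = FALSE)
    }
    data.frame(
      id = as.character(e$id),
      predicate = as.character(e$predicate),
      reverse_predicate = as.character(
        if (is.null(e$reverse_predicate)) e$predicate else e$reverse_predicate),
      source_type = as.character(e$from),
      target_type = as.character(e$to),
      is_similarity = isTRUE(e$similarity),
      stringsAsFactors = FALSE
    )
  })
  edge_specs <- if (length(specs)) do.call(rbind, specs) else
    data.frame(id = character(), predicate = character(),
               reverse_predicate = character(), source_type = character(),
               target_type = character(), is_similarity = logical(),
               stringsAsFactors = FALSE)

  bad_src <- !(edge_specs$source_type %in% node_types)
  bad_tgt <- !(edge_specs$target_type %in% node_types)
  if (any(bad_src | bad_tgt)) {
    off <- edge_specs$id[bad_src | bad_tgt][1L]
    miss <- c(edge_specs$source_type[bad_src], edge_specs$target_type[bad_tgt])[1L]
    stop("edge spec '", off, "' references undeclared node type '", miss, "'",
         call. = FALSE)
  }
  if (anyDuplicated(edge_specs$id))
    stop("duplicate edge spec id: ",
         paste(unique(edge_specs$id[duplicated(edge_specs$id)]), collapse = ", "),
         call. = FALSE)
  # same-type edges are undirected by construction (see symmetrization rules)
  edge_specs$is_same_type <- edge_specs$source_type == edge_specs$target_type

  structure(
    list(name = if (is.null(cfg$name)) "schema" else as.character(cfg$name),
         node_types = node_types,
         edge_specs = edge_specs),
    class = "hetnet_schema"
  )
}

#' @describeIn load_schema Load the packaged 9-node-type / 12-edge-type
#'   default schema.
#' @export
default_schema <- function() {
  load_schema(system.file("extdata", "schema_semantic_network.yaml",
                          package = "metapathDTI", mustWork = TRUE))
}

#' @export
print.hetnet_schema <- function(x, ...) {
  cat("<hetnet_schema> '", x$name, "': ", length(x$node_types),
      " node types, ", nrow(x$edge_specs), " edge specs\n", sep = "")
  cat("node types:", paste(x$node_types, collapse = ", "), "\n")
  if (nrow(x$edge_specs)) {
    for (i in seq_len(nrow(x$edge_specs))) {
      e <- x$edge_specs[i, ]
      cat(sprintf("  %-4s %s --%s--> %s%s\n", e$id, e$source_type,
                  e$predicate, e$target_type,
                  if (e$is_similarity) "  [similarity]" else ""))
    }
  }
  invisible(x)
}

edge_spec <- function(schema, id) {
  i <- match(id, schema$edge_specs$id)
  if (is.na(i)) stop("unknown edge spec id '", id, "'", call. = FALSE)
  schema$edge_specs[i, ]
}

#' Oriented endpoint types of an edge spec
#'
#' @param schema a `hetnet_schema`.
#' @param id edge spec id, e.g. `"A2"`.
#' @param orientation `"forward"` or `"reverse"`.
#' @return Character vector `c(source, target)` of oriented node types.
#' @keywords internal
oriented_types <- function(schema, id, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  e <- edge_spec(schema, id)
  if (orientation == "forward") c(e$source_type, e$target_type)
  else c(e$target_type, e$source_type)
}
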