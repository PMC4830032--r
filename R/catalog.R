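#' Construct a meta-path
#'
#' A meta-path is an ordered sequence of oriented edge-type steps: a
#' composite relation connecting a start node type to an end node type
#' through the heterogeneous network. A step taken in `"reverse"`
#' orientation traverses the edge type against its declared direction
#' (its adjacency is the transpose).
#'
#' @param id label for the meta-path (e.g. `"C15"`); identity for
#'   set-comparisons is always the oriented step sequence, never the id.
#' @param steps either a character vector in compact notation (`"A2"` for a
#'   forward step, `"A2^T"` for a reverse step) or a data.frame with columns
#'   `edge` and `orientation` (`"forward"`/`"reverse"`).
#' @param schema optional `hetnet_schema`; when given, the path is validated
#'   and its `start_type`, `end_type` and human-readable `label` are derived.
#' @return A `metapath` object.
#' @export
metapath <- function(id, steps, schema = NULL) {
  if (is.character(steps)) {
    rev_flag <- grepl("\\^T$", steps)
    steps <- data.frame(edge = sub("\\^T$", "", steps),
                        orientation = ifelse(rev_flag, "reverse", "forward"),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(steps), all(c("edge", "orientation") %in% names(steps)))
  if (!all(steps$orientation %in% c("forward", "reverse")))
    stop("step orientation must be 'forward' or 'reverse'", call. = FALSE)
  mp <- structure(list(id = as.character(id), steps = steps), class = "metapath")
  if (!is.null(schema)) {
    validate_metapath(mp, schema)
    mp$start_type <- oriented_types(schema, steps$edge[1L], steps$orientation[1L])[1L]
    n <- nrow(steps)
    mp$end_type <- oriented_types(schema, steps$edge[n], steps$orientation[n])[2L]
    mp$label <- metapath_label(mp, schema)
  }
  mp
}

#' @export
print.metapath <- function(x, ...) {
  cat("<metapath> ", x$id, " (length ", nrow(x$steps), "): ",
      paste0(x$steps$edge,
             ifelse(x$steps$orientation == "reverse", "^T", ""),
             collapse = " . "), "\n", sep = "")
  if (!is.null(x$label)) cat("  ", x$label, "\n", sep = "")
  invisible(x)
}

#' Length of a meta-path (number of oriented steps)
#' @param x a `metapath`.
#' @export
length.metapath <- function(x) nrow(x$steps)

# canonical identity key: oriented step sequence
metapath_key <- function(mp) {
  paste0(mp$steps$edge,
         ifelse(mp$steps$orientation == "reverse", "^T", ""),
         collapse = ".")
}

#' Validate that a meta-path's oriented steps chain type-compatibly
#'
#' @param mp a `metapath`.
#' @param schema a `hetnet_schema`.
#' @return `TRUE` invisibly; otherwise an error naming the meta-path and the
#'   first incompatible junction.
#' @export
validate_metapath <- function(mp, schema) {
  st <- mp$steps
  if (nrow(st) == 0L)
    stop("meta-path '", mp$id, "' has no steps", call. = FALSE)
  for (k in seq_len(nrow(st))) {
    tk <- oriented_types(schema, st$edge[k], st$orientation[k])
    if (k > 1L && tk[1L] != prev_target)
      stop("meta-path '", mp$id, "': step ", k, " (", st$edge[k], " ",
           st$orientation[k], ") starts at node type '", tk[1L],
           "' but step ", k - 1L, " ends at '", prev_target, "'",
           call. = FALSE)
    prev_target <- tk[2L]
  }
  invisible(TRUE)
}

#' Human-readable arrow label of a meta-path
#'
#' @param mp a `metapath`.
#' @param schema a `hetnet_schema`.
#' @return A string like
#'   `"compound -similar to-> compound -binds to-> protein"`.
#' @export
metapath_label <- function(mp, schema) {
  st <- mp$steps
  first <- oriented_types(schema, st$edge[1L], st$orientation[1L])
  parts <- first[1L]
  for (k in seq_len(nrow(st))) {
    e <- edge_spec(schema, st$edge[k])
    pred <- if (st$orientation[k] == "forward") e$predicate else e$reverse_predicate
    tk <- oriented_types(schema, st$edge[k], st$orientation[k])
    parts <- c(parts, paste0(" -", pred, "-> "), tk[2L])
  }
  paste0(parts, collapse = "")
}

#' Does a meta-path traverse any similarity neighboring link?
#' @param mp a `metapath`.
#' @param schema a `hetnet_schema`.
#' @return Logical scalar.
#' @export
uses_similarity <- function(mp, schema) {
  sim_ids <- schema$edge_specs$id[schema$edge_specs$is_similarity]
  any(mp$steps$edge %in% sim_ids)
}

#' Parse a meta-path catalog config
#'
#' The config is YAML with a `provenance` note and a `metapaths` list; each
#' entry gives an `id`, a `steps` vector in compact notation (`"A11"`,
#' `"A2^T"`, ...) and the expected human-readable `label`. Every entry is
#' validated against the schema and its regenerated label compared (modulo
#' whitespace) to the declared one, guarding the transcription.
#'
#' The packaged default catalog (`default_catalog()`) holds the 51
#' compound-to-protein meta-paths of length 2-4 used for drug-target link
#' prediction: 4 of length 2, 11 of length 3 and 36 of length 4.
#'
#' @param path YAML catalog config.
#' @param schema a `hetnet_schema`.
#' @return A `metapath_catalog`: a list of `metapath` objects plus a
#'   `provenance` attribute.
#' @export
parse_catalog <- function(path, schema) {
  cfg <- yaml::read_yaml(path)
  entries <- cfg$metapaths
  if (is.null(entries)) entries <- list()
  mps <- lapply(entries, function(e) {
    mp <- metapath(e$id, unlist(e$steps), schema)
    if (!is.null(e$label)) {
      norm <- function(s) gsub("\\s+", " ", trimws(s))
      if (norm(e$label) != norm(mp$label))
        stop("catalog entry '", e$id, "': declared label does not match ",
             "the step sequence\n  declared:  ", e$label,
             "\n  derived:   ", mp$label, call. = FALSE)
    }
    mp
  })
  ids <- vapply(mps, function(m) m$id, "")
  if (anyDuplicated(ids))
    stop("duplicate meta-path id in catalog: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  new_catalog(mps, if (is.null(cfg$provenance)) "" else cfg$provenance)
}

new_catalog <- function(mps, provenance = "") {
  names(mps) <- vapply(mps, function(m) m$id, "")
  structure(mps, provenance = provenance, class = "metapath_catalog")
}

#' @describeIn parse_catalog Load the packaged 51-meta-path default catalog.
#' @export
default_catalog <- function(schema = default_schema()) {
  parse_catalog(system.file("extdata", "catalog_slap51.yaml",
                            package = "metapathDTI", mustWork = TRUE),
                schema)
}

#' @export
print.metapath_catalog <- function(x, ...) {
  lens <- vapply(x, function(m) nrow(m$steps), 0L)
  cat("<metapath_catalog> ", length(x), " meta-paths; length histogram: ",
      paste(sprintf("%d:%d", as.integer(names(table(lens))), table(lens)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
`[.metapath_catalog` <- function(x, i) {
  new_catalog(unclass(x)[i], attr(x, "provenance"))
}

#' Filter a catalog down to meta-paths free of similarity links
#'
#' Feature set I of the classification experiments uses only meta-paths that
#' avoid the compound- and protein-similarity neighboring links; on the
#' packaged catalog that leaves 29 of the 51 entries.
#'
#' @param catalog a `metapath_catalog`.
#' @param schema the schema whose `is_similarity` flags define the filter.
#' @return The filtered `metapath_catalog`.
#' @export
similarity_free <- function(catalog, schema = default_schema()) {
  keep <- !vapply(catalog, uses_similarity, TRUE, schema = schema)
  new_catalog(unclass(catalog)[keep],
              paste0(attr(catalog, "provenance"), " [similarity-free subset]"))
}

# -- grammar-preset enumeration ----------------------------------------------

# The "slap51" preset reconstructs the packaged 51-path catalog as a small
# grammar over the default schema. Two forms, total length in [2, max_len]:
#   form 1: [CN] [sim] binds [x] [PN]
#   form 2: [CN] treats caused_by [PN]
# CN: nothing, a compound-X-compound loop (X in {ChEBI type, substructure,
#     side effect, disease}), or binds + binds-back; sim: optional compound
#     similarity; x: nothing, protein interaction or protein similarity;
#     PN: nothing or a protein-Y-protein loop (Y in {GO annotation, pathway,
#     tissue, disease}).
slap51_preset <- function() {
  f <- function(...) {
    v <- c(...)
    data.frame(edge = sub("\\^T$", "", v),
               orientation = ifelse(grepl("\\^T$", v), "reverse", "forward"),
               stringsAsFactors = FALSE)
  }
  list(
    compound_neighborhood = list(f(), f("A1", "A1^T"), f("A3", "A3^T"),
                                 f("A4^T", "A4"), f("A5^T", "A5"),
                                 f("A2", "A2^T")),
    compound_similarity = list(f(), f("A11")),
    binds = f("A2"),
    protein_expansion = list(f(), f("A6"), f("A12")),
    protein_neighborhood = list(f(), f("A7", "A7^T"), f("A9^T", "A9"),
                                f("A10^T", "A10"), f("A8^T", "A8")),
    treats_caused_by = f("A5^T", "A8")
  )
}

#' Enumerate compound-to-protein meta-paths under a grammar preset
#'
#' Exhaustive schema walks of length <= 4 yield far more compound-to-protein
#' meta-paths than the 51 the prediction framework uses; the packaged
#' `"slap51"` preset is a constraint grammar that reproduces exactly that
#' catalog (compound-side neighborhood, optional compound similarity, the
#' binds step, optional protein-side expansion, protein-side neighborhood,
#' plus the treats/caused-by disease route).
#'
#' @param schema a `hetnet_schema`.
#' @param preset preset name; only `"slap51"` is packaged.
#' @param max_len maximum number of steps (paths longer than this are
#'   excluded; the minimum length is 2 because the bare binds link is the
#'   prediction target, not a feature).
#' @return A `metapath_catalog` of deduplicated, validated meta-paths with
#'   generated ids `M1, M2, ...` in canonical (length, step-key) order.
#' @export
enumerate_metapaths <- function(schema, preset = "slap51", max_len = 4L) {
  if (!identical(preset, "slap51"))
    stop("unknown enumeration preset '", preset, "'", call. = FALSE)
  g <- slap51_preset()
  known <- schema$edge_specs$id
  used <- unique(unlist(lapply(
    c(g$compound_neighborhood, g$compound_similarity, g$protein_expansion,
      g$protein_neighborhood, list(g$binds, g$treats_caused_by)),
    function(d) d$edge)))
  if (!all(used %in% known))
    stop("preset references edge id(s) absent from schema: ",
         paste(setdiff(used, known), collapse = ", "), call. = FALSE)

  candidates <- list()
  for (cn in g$compound_neighborhood) {
    # form 1
    for (sim in g$compound_similarity) {
      for (x in g$protein_expansion) {
        for (pn in g$protein_neighborhood) {
          st <- rbind(cn, sim, g$binds, x, pn)
          if (nrow(st) >= 2L && nrow(st) <= max_len)
            candidates[[length(candidates) + 1L]] <- st
        }
      }
    }
    # form 2
    for (pn in g$protein_neighborhood) {
      st <- rbind(cn, g$treats_caused_by, pn)
      if (nrow(st) >= 2L && nrow(st) <= max_len)
        candidates[[length(candidates) + 1L]] <- st
    }
  }
  keys <- vapply(candidates, function(st)
    paste0(st$edge, ifelse(st$orientation == "reverse", "^T", ""),
           collapse = "."), "")
  keep <- !duplicated(keys)
  candidates <- candidates[keep]
  keys <- keys[keep]
  ord <- order(lengths(lapply(candidates, function(st) st$edge)), keys)
  mps <- lapply(seq_along(ord), function(i)
    metapath(paste0("M", i), candidates[[ord[i]]], schema))
  new_catalog(mps, sprintf("enumerated: preset %s, max_len %d", preset, max_len))
}
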