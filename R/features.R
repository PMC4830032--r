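#' Commuting matrix of a meta-path
#'
#' The commuting matrix of a meta-path is the ordered product of the oriented
#' adjacency matrices along its steps (left-to-right in walk order, rows =
#' start type). Entry (i, j) is the exact number of walk instances of the
#' meta-path from node i to node j; walks may revisit nodes and links, which
#' is what a matrix product counts. Everything stays sparse; counts are
#' accumulated in doubles, exact for values below 2^53 (the largest counts on
#' realistic networks are around 10^7).
#'
#' @param net a `hetnet`.
#' @param mp a `metapath` (validated against `net`'s schema).
#' @return A `commuting_matrix`: a list with `metapath_id` and sparse `matrix`
#'   of shape (|start type|, |end type|).
#' @export
compute_commuting <- function(net, mp) {
  validate_metapath(mp, net$schema)
  m <- adjacency(net, mp$steps$edge[1L], mp$steps$orientation[1L])
  for (k in seq_len(nrow(mp$steps))[-1L])
    m <- m %*% adjacency(net, mp$steps$edge[k], mp$steps$orientation[k])
  structure(list(metapath_id = mp$id,
                 matrix = methods::as(m, "CsparseMatrix")),
            class = "commuting_matrix")
}

#' @export
print.commuting_matrix <- function(x, ...) {
  cat("<commuting_matrix> ", x$metapath_id, ": ",
      nrow(x$matrix), " x ", ncol(x$matrix), ", ",
      Matrix::nnzero(x$matrix), " nonzeros, max ",
      if (Matrix::nnzero(x$matrix)) max(x$matrix@x) else 0, "\n", sep = "")
  invisible(x)
}

#' Brute-force walk counting (test oracle)
#'
#' Counts walk instances of a meta-path between two named nodes by explicit
#' recursive traversal, one walk at a time. This is the independent oracle
#' for the matrix-product semantics of [compute_commuting()]; its cost grows
#' exponentially with path length, so use it only on small networks.
#'
#' @param net a `hetnet`.
#' @param mp a `metapath`.
#' @param source_id,target_id external node ids of the start/end nodes.
#' @return Integer walk count.
#' @export
brute_force_walk_count <- function(net, mp, source_id, target_id) {
  validate_metapath(mp, net$schema)
  types1 <- oriented_types(net$schema, mp$steps$edge[1L], mp$steps$orientation[1L])
  n <- nrow(mp$steps)
  typesN <- oriented_types(net$schema, mp$steps$edge[n], mp$steps$orientation[n])
  src <- node_positions(net, types1[1L], source_id)
  tgt <- node_positions(net, typesN[2L], target_id)

  mats <- lapply(seq_len(n), function(k)
    adjacency(net, mp$steps$edge[k], mp$steps$orientation[k]))
  count_from <- function(node, k) {
    nbrs <- which(mats[[k]][node, ] != 0)
    if (k == n) return(sum(nbrs == tgt))
    total <- 0L
    for (v in nbrs) total <- total + count_from(v, k + 1L)
    total
  }
  count_from(src, 1L)
}

#' Random-walk normalization of a commuting matrix
#'
#' The random-walk (RW) measure divides each path count by its compound's
#' row-wise total, `PC[i,j] / PC[i,.]`, giving the probability mass of
#' reaching protein j from compound i along the meta-path. All-zero rows stay
#' all-zero (0/0 is taken as 0: an isolated compound has no walk to
#' normalize).
#'
#' @param cm a `commuting_matrix` (or a sparse matrix of path counts).
#' @return A sparse matrix with values in `[0, 1]`; every nonzero row sums
#'   to 1.
#' @export
rw_normalize <- function(cm) {
  m <- if (inherits(cm, "commuting_matrix")) cm$matrix else cm
  rs <- Matrix::rowSums(m)
  scale <- ifelse(rs > 0, 1 / rs, 0)
  out <- methods::as(Matrix::Diagonal(x = scale) %*% m, "CsparseMatrix")
  dimnames(out) <- dimnames(m)
  out
}

# normalized path count: PC[i,j] / (PC[i,.] + PC[.,j]); optional measure
npc_normalize <- function(cm) {
  m <- if (inherits(cm, "commuting_matrix")) cm$matrix else cm
  tm <- methods::as(m, "TsparseMatrix")
  if (!length(tm@x)) return(methods::as(m, "CsparseMatrix"))
  denom <- Matrix::rowSums(m)[tm@i + 1L] + Matrix::colSums(m)[tm@j + 1L]
  methods::as(Matrix::sparseMatrix(i = tm@i + 1L, j = tm@j + 1L,
                                   x = tm@x / denom, dims = dim(m)),
              "CsparseMatrix")
}

#' Extract per-pair topological features
#'
#' Computes one commuting matrix per catalog meta-path (once, not per pair)
#' and reads out the requested measures for a list of compound-protein
#' pairs. Columns are named `<metapath_id>_<measure>` in deterministic order
#' (catalog order x measure order). With the full packaged catalog this
#' yields 51 columns for `"PC"` alone, 29 for path counts on the
#' similarity-free subset, and 102 for `c("PC", "RW")`.
#'
#' Leakage control is the caller's responsibility: remove positively labeled
#' links (see [leakage_guard()]) before calling.
#'
#' @param net a `hetnet`.
#' @param catalog a `metapath_catalog` of compound-to-protein meta-paths.
#' @param pairs data.frame with columns `compound_id`, `protein_id` (extra
#'   columns such as `label` are carried through untouched).
#' @param measures subset of `c("PC", "RW", "NPC", "SRW")`; `NPC` and `SRW`
#'   are optional extensions, disabled by default.
#' @return A `feature_table`: a data.frame with the pair columns followed by
#'   one numeric column per (meta-path, measure).
#' @export
extract_features <- function(net, catalog, pairs, measures = c("PC", "RW")) {
  measures <- match.arg(measures, c("PC", "RW", "NPC", "SRW"),
                        several.ok = TRUE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("compound_id", "protein_id") %in% names(pairs)))
  ci <- node_positions(net, "compound", pairs$compound_id)
  pj <- node_positions(net, "protein", pairs$protein_id)
  idx <- cbind(ci, pj)

  cols <- list()
  for (mp in catalog) {
    cm <- compute_commuting(net, mp)
    for (meas in measures) {
      m <- switch(meas,
        PC = cm$matrix,
        RW = rw_normalize(cm),
        NPC = npc_normalize(cm),
        SRW = {
          rev_mp <- metapath(paste0(mp$id, "_rev"),
                             data.frame(edge = rev(mp$steps$edge),
                                        orientation = ifelse(
                                          rev(mp$steps$orientation) == "forward",
                                          "reverse", "forward")))
          Matrix::t(rw_normalize(compute_commuting(net, rev_mp))) +
            rw_normalize(cm)
        })
      cols[[paste0(mp$id, "_", meas)]] <- as.numeric(m[idx])
    }
  }
  ft <- cbind(pairs, as.data.frame(cols, optional = TRUE))
  class(ft) <- c("feature_table", "data.frame")
  ft
}

#' Names of the feature columns of a feature table
#' @param ft a `feature_table`.
#' @return Character vector of `<metapath_id>_<measure>` column names.
#' @export
feature_columns <- function(ft) {
  grep("_(PC|RW|NPC|SRW)$", names(ft), value = TRUE)
}

#' Read/write a feature table as TSV
#' @param ft a `feature_table`.
#' @param path file path.
#' @export
write_feature_table <- function(ft, path) {
  utils::write.table(ft, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ft <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(compound_id = "character",
                                         protein_id = "character"))
  class(ft) <- c("feature_table", "data.frame")
  ft
}
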