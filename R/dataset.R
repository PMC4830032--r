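#' Label compound-protein pairs from bioactivity evidence
#'
#' Applies the bioassay labeling rules: a pair is negatively labeled when its
#' experimental bioactivity value exceeds `negative_threshold_uM` (default
#' 10 uM), and positively labeled when the assay outcome is `"active"` and
#' the reported value is below `positive_threshold_uM` (default 1 uM).
#' Records meeting neither rule are dropped. If different records assign both
#' labels to the same pair, the pair is dropped entirely and the conflict
#' counted (conservative: no majority vote).
#'
#' @param records data.frame with columns `compound_id`, `protein_id`,
#'   `activity_uM` (positive real, `NA` allowed) and optionally `outcome`
#'   (`"active"`, `"inactive"`, `"unspecified"`).
#' @param negative_threshold_uM,positive_threshold_uM activity cutoffs in uM;
#'   the positive threshold must not exceed the negative one.
#' @return data.frame of labeled pairs: `compound_id`, `protein_id`, `label`
#'   (`"positive"`/`"negative"`), `source` tag; attribute `"n_conflicts"`
#'   counts dropped conflicting pairs.
#' @export
label_from_activity <- function(records, negative_threshold_uM = 10,
                                positive_threshold_uM = 1) {
  stopifnot(negative_threshold_uM > 0, positive_threshold_uM > 0,
            positive_threshold_uM <= negative_threshold_uM)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (is.null(records$outcome)) records$outcome <- "unspecified"
  records$outcome[is.na(records$outcome)] <- "unspecified"
  if (any(!is.na(records$activity_uM) & records$activity_uM <= 0))
    stop("non-positive activity value in records", call. = FALSE)

  neg <- !is.na(records$activity_uM) &
    records$activity_uM > negative_threshold_uM
  pos <- records$outcome == "active" &
    !is.na(records$activity_uM) &
    records$activity_uM < positive_threshold_uM

  lab <- rbind(
    data.frame(compound_id = records$compound_id[pos],
               protein_id = records$protein_id[pos],
               label = "positive", stringsAsFactors = FALSE),
    data.frame(compound_id = records$compound_id[neg],
               protein_id = records$protein_id[neg],
               label = "negative", stringsAsFactors = FALSE)
  )
  lab <- unique(lab)
  key <- paste(lab$compound_id, lab$protein_id, sep = "\r")
  conflicted <- key %in% key[duplicated(key)]
  n_conflicts <- length(unique(key[conflicted]))
  if (n_conflicts > 0)
    warning(n_conflicts, " pair(s) labeled both positive and negative; dropped",
            call. = FALSE)
  lab <- lab[!conflicted, , drop = FALSE]
  lab$source <- "activity"
  rownames(lab) <- NULL
  attr(lab, "n_conflicts") <- n_conflicts
  lab
}

#' Stratified random train/test split of labeled pairs
#'
#' Splits positives and negatives independently at the requested ratio (the
#' train share gets `floor(n_label * ratio)` pairs per label), so e.g. 5,387
#' positives and 26,682 negatives at 2:1 give 3,591/17,788 training and
#' 1,796/8,894 test pairs. The permutation is driven entirely by `seed`.
#'
#' @param pairs data.frame of labeled pairs (`compound_id`, `protein_id`,
#'   `label`).
#' @param ratio train:test ratio as a length-2 numeric, default `c(2, 1)`.
#' @param seed integer seed; mandatory for reproducibility.
#' @param stratified split per label (default) or globally.
#' @return A `split_dataset`: list with `train`, `test` (data.frames), `seed`,
#'   `ratio`.
#' @export
split_dataset <- function(pairs, ratio = c(2, 1), seed, stratified = TRUE) {
  stopifnot(length(ratio) == 2, all(ratio > 0), !missing(seed))
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  frac <- ratio[1] / sum(ratio)
  groups <- if (stratified) split(seq_len(nrow(pairs)), pairs$label)
            else list(all = seq_len(nrow(pairs)))
  if (stratified &&
      (!all(c("positive", "negative") %in% names(groups)) ||
       any(lengths(groups) == 0L)))
    stop("stratified split requires at least one pair per label", call. = FALSE)
  set.seed(as.integer(seed))
  train_idx <- unlist(lapply(groups, function(ix) {
    ix <- ix[sample.int(length(ix))]
    ix[seq_len(floor(length(ix) * frac))]
  }), use.names = FALSE)
  structure(list(train = pairs[sort(train_idx), , drop = FALSE],
                 test = pairs[sort(setdiff(seq_len(nrow(pairs)), train_idx)), ,
                              drop = FALSE],
                 seed = as.integer(seed), ratio = ratio),
            class = "split_dataset")
}

#' @export
print.split_dataset <- function(x, ...) {
  tab <- function(d) paste(names(table(d$label)), table(d$label),
                           sep = ":", collapse = ", ")
  cat("<split_dataset> ratio ", paste(x$ratio, collapse = ":"),
      ", seed ", x$seed, "\n  train: ", nrow(x$train), " (", tab(x$train),
      ")\n  test:  ", nrow(x$test), " (", tab(x$test), ")\n", sep = "")
  invisible(x)
}

#' Leakage control: remove positively labeled links from the network
#'
#' Deletes every positively labeled compound-protein pair from the binding
#' edge type before feature computation, so the topological features carry
#' no direct knowledge of the prediction target. Negatives are asserted to be
#' unobserved links: a "negative" pair found present in the binding adjacency
#' is a data-consistency error.
#'
#' @param net a `hetnet`.
#' @param labeled_pairs data.frame with `compound_id`, `protein_id`, `label`.
#' @param binds_edge id of the compound-protein binding edge spec
#'   (default `"A2"`).
#' @return The guarded `hetnet` (input unmodified).
#' @export
leakage_guard <- function(net, labeled_pairs, binds_edge = "A2") {
  lp <- as.data.frame(labeled_pairs, stringsAsFactors = FALSE)
  negs <- lp[lp$label == "negative", , drop = FALSE]
  if (nrow(negs)) {
    ci <- match(negs$compound_id, net$registries$compound)
    pj <- match(negs$protein_id, net$registries$protein)
    ok <- !is.na(ci) & !is.na(pj)
    present <- logical(nrow(negs))
    present[ok] <- net$adjacency[[binds_edge]][cbind(ci[ok], pj[ok])] != 0
    if (any(present))
      stop("negatively labeled pair(s) present in ", binds_edge, ": ",
           paste(utils::head(paste(negs$compound_id[present],
                                   negs$protein_id[present], sep = "-"), 5),
                 collapse = ", "), call. = FALSE)
  }
  pos <- lp[lp$label == "positive", c("compound_id", "protein_id"), drop = FALSE]
  if (nrow(pos) == 0L) return(net)
  remove_links(net, binds_edge, pos)
}

#' Split labeled pairs by network era (evolving-network evaluation)
#'
#' Trains on pairs whose links exist in the current network snapshot and
#' tests on pairs discovered after the network was built; there is no random
#' element. Callers still apply [leakage_guard()] with the training positives
#' before feature extraction.
#'
#' @param labeled_pairs data.frame with `compound_id`, `protein_id`, `label`
#'   and an `era` column tagging each pair `"in_network"` or
#'   `"post_network"`.
#' @return A `split_dataset` with `seed = NA` (deterministic partition).
#' @export
evolving_split <- function(labeled_pairs) {
  lp <- as.data.frame(labeled_pairs, stringsAsFactors = FALSE)
  if (is.null(lp$era) || anyNA(lp$era))
    stop("evolving_split requires an 'era' tag on every pair", call. = FALSE)
  if (!all(lp$era %in% c("in_network", "post_network")))
    stop("era must be 'in_network' or 'post_network'", call. = FALSE)
  test <- lp[lp$era == "post_network", , drop = FALSE]
  if (nrow(test) == 0L)
    warning("no post-network pairs: evolving test set is empty", call. = FALSE)
  structure(list(train = lp[lp$era == "in_network", , drop = FALSE],
                 test = test, seed = NA_integer_, ratio = NA),
            class = "split_dataset")
}

#' Read labeled pairs / activity records from TSV
#'
#' `read_pairs()` expects columns `compound_id`, `protein_id`, `label` (and
#' optionally `era`); `read_activity()` expects `compound_id`, `protein_id`,
#' `activity_uM` and optionally `outcome`.
#'
#' @param path TSV file with a header.
#' @return data.frame.
#' @export
read_pairs <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    colClasses = c(compound_id = "character",
                                   protein_id = "character"))
}

#' @rdname read_pairs
#' @export
read_activity <- function(path) read_pairs(path)
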