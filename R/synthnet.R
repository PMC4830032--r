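#' Configuration for the synthetic semantic-network generator
#'
#' The generator emulates the structure of the real drug-target semantic
#' network (9 node types, 12 edge types) at test scale, with a planted
#' latent block-model signal: compounds and proteins are assigned to
#' `n_groups` latent groups, binding links appear with probability `p_in`
#' inside a matched compound-protein group and `p_out` across groups, and
#' similarity / annotation edges prefer their group (controlled by
#' `coherence`), so similarity- and shared-target-style meta-paths become
#' genuinely informative.
#'
#' When `p_in == p_out` the generator switches to a null world: every edge
#' probability collapses to its group-agnostic average and negatives are
#' sampled from all never-linked pairs, so no channel -- binding, similarity
#' or annotation -- carries group signal and downstream classifiers should
#' sit at chance.
#'
#' @param n_compound,n_protein primary node counts (defaults 200/100: full
#'   51-meta-path feature extraction stays well under a minute).
#' @param n_chebi,n_substructure,n_side_effect,n_disease,n_go,n_pathway,n_tissue
#'   peripheral node counts.
#' @param n_groups latent block count (default 4).
#' @param p_in,p_out binding probability within / across matched groups
#'   (defaults 0.10 / 0.003: sparse binding, as in real compound-target
#'   matrices, keeps shared-target paths from drowning out the similarity
#'   channel).
#' @param sim_compound,sim_protein within-group similarity-link probability
#'   for the compound and protein similarity edge types (defaults 0.35 and
#'   0.15: compound analog series are similarity-dense, making the
#'   compound-similarity link the dominant planted channel).
#' @param coherence probability that a similarity or annotation link respects
#'   the group structure; cross-group probability is scaled by
#'   `1 - coherence` (default 0.95).
#' @param ppi_in,ppi_out protein-interaction probabilities within/across
#'   groups (defaults 0.10 / 0.01).
#' @param annot_in,annot_out node-annotation probabilities within/across
#'   groups (defaults 0.25 / 0.02).
#' @param holdout_frac fraction of true binding links held out as labeled
#'   positives and removed from the emitted network (default 0.3).
#' @param seed mandatory integer seed; every stage derives its own stream
#'   from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_compound = 200L, n_protein = 100L, n_chebi = 12L,
                         n_substructure = 25L, n_side_effect = 15L,
                         n_disease = 12L, n_go = 30L, n_pathway = 8L,
                         n_tissue = 6L, n_groups = 4L,
                         p_in = 0.10, p_out = 0.003,
                         sim_compound = 0.35, sim_protein = 0.15,
                         coherence = 0.95, ppi_in = 0.10, ppi_out = 0.01,
                         annot_in = 0.25, annot_out = 0.02,
                         holdout_frac = 0.3, seed) {
  if (missing(seed)) stop("synth_config requires a seed", call. = FALSE)
  probs <- c(p_in, p_out, sim_compound, sim_protein, coherence,
             ppi_in, ppi_out, annot_in, annot_out, holdout_frac)
  stopifnot(all(probs >= 0), all(probs <= 1), n_groups >= 1,
            n_compound >= 1, n_protein >= 1)
  structure(mget(names(formals())), class = "synth_config")
}

#' Generate a synthetic heterogeneous network with planted signal
#'
#' Emits edges for all 12 edge types of the default schema, holds out a
#' fraction of the true binding links as labeled positives (pre-removed from
#' the network, mirroring the leakage-control protocol) and samples an
#' equal-size set of never-linked cross-group pairs as labeled negatives.
#'
#' @param config a [synth_config()].
#' @return List with `net` (a `hetnet`) and `truth` (a `synth_truth`:
#'   group assignments, held-out positive pairs, sampled negative pairs, the
#'   config).
#' @export
generate_hetnet <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  schema <- default_schema()
  cfg <- config
  g <- cfg$n_groups
  null_mode <- isTRUE(all.equal(cfg$p_in, cfg$p_out))

  ids <- list(
    compound = sprintf("c%04d", seq_len(cfg$n_compound)),
    protein = sprintf("p%04d", seq_len(cfg$n_protein)),
    chebi_type = sprintf("ch%03d", seq_len(cfg$n_chebi)),
    substructure = sprintf("s%03d", seq_len(cfg$n_substructure)),
    side_effect = sprintf("se%03d", seq_len(cfg$n_side_effect)),
    disease = sprintf("d%03d", seq_len(cfg$n_disease)),
    go_annotation = sprintf("go%03d", seq_len(cfg$n_go)),
    pathway = sprintf("pw%03d", seq_len(cfg$n_pathway)),
    tissue = sprintf("t%03d", seq_len(cfg$n_tissue))
  )
  set.seed(derive_seed(cfg$seed, 1L))
  grp <- lapply(ids, function(v) sample.int(g, length(v), replace = TRUE))

  # group-dependent Bernoulli draw over a full bipartite index grid
  draw_bipartite <- function(ga, gb, prob_in, prob_out, stage) {
    same <- outer(ga, gb, "==")
    pmat <- ifelse(same, prob_in, prob_out)
    if (null_mode) pmat[] <- mean(c(prob_in, rep(prob_out, g - 1)))
    set.seed(derive_seed(cfg$seed, stage))
    which(matrix(stats::runif(length(pmat)), nrow(pmat)) < pmat, arr.ind = TRUE)
  }
  # same for an undirected same-type edge set (upper triangle only)
  draw_same_type <- function(ga, prob_in, prob_out, stage) {
    hits <- draw_bipartite(ga, ga, prob_in, prob_out, stage)
    hits[hits[, 1] < hits[, 2], , drop = FALSE]
  }
  edges <- function(edge, from_ids, to_ids, hits) {
    if (nrow(hits) == 0L)
      return(data.frame(edge = character(), source = character(),
                        target = character(), stringsAsFactors = FALSE))
    data.frame(edge = edge, source = from_ids[hits[, 1]],
               target = to_ids[hits[, 2]], stringsAsFactors = FALSE)
  }
  sim_cross <- function(p) p * (1 - cfg$coherence)

  # binding links (the prediction target)
  binds <- draw_bipartite(grp$compound, grp$protein, cfg$p_in, cfg$p_out, 2L)
  set.seed(derive_seed(cfg$seed, 3L))
  n_hold <- floor(cfg$holdout_frac * nrow(binds))
  hold <- sample.int(nrow(binds), n_hold)
  kept <- binds[setdiff(seq_len(nrow(binds)), hold), , drop = FALSE]
  positives <- data.frame(
    compound_id = ids$compound[binds[hold, 1]],
    protein_id = ids$protein[binds[hold, 2]],
    label = "positive", stringsAsFactors = FALSE)

  # negatives: never-linked pairs; cross-group only when signal is planted
  linked <- binds[, 1] + (binds[, 2] - 1L) * cfg$n_compound
  same <- outer(grp$compound, grp$protein, "==")
  candidate <- setdiff(
    if (null_mode) seq_len(cfg$n_compound * cfg$n_protein) else which(!same),
    linked)
  set.seed(derive_seed(cfg$seed, 4L))
  if (length(candidate) < n_hold)
    stop("not enough never-linked pairs to sample negatives", call. = FALSE)
  negdraw <- sample(candidate, n_hold)
  negatives <- data.frame(
    compound_id = ids$compound[(negdraw - 1L) %% cfg$n_compound + 1L],
    protein_id = ids$protein[(negdraw - 1L) %/% cfg$n_compound + 1L],
    label = "negative", stringsAsFactors = FALSE)

  all_edges <- rbind(
    edges("A2", ids$compound, ids$protein, kept),
    edges("A11", ids$compound, ids$compound,
          draw_same_type(grp$compound, cfg$sim_compound,
                         sim_cross(cfg$sim_compound), 5L)),
    edges("A12", ids$protein, ids$protein,
          draw_same_type(grp$protein, cfg$sim_protein,
                         sim_cross(cfg$sim_protein), 6L)),
    edges("A6", ids$protein, ids$protein,
          draw_same_type(grp$protein, cfg$ppi_in, cfg$ppi_out, 7L)),
    edges("A1", ids$compound, ids$chebi_type,
          draw_bipartite(grp$compound, grp$chebi_type, cfg$annot_in,
                         cfg$annot_out, 8L)),
    edges("A3", ids$compound, ids$substructure,
          draw_bipartite(grp$compound, grp$substructure, cfg$annot_in,
                         cfg$annot_out, 9L)),
    edges("A4", ids$side_effect, ids$compound,
          draw_bipartite(grp$side_effect, grp$compound, cfg$annot_in,
                         cfg$annot_out, 10L)),
    edges("A5", ids$disease, ids$compound,
          draw_bipartite(grp$disease, grp$compound, cfg$annot_in,
                         cfg$annot_out, 11L)),
    edges("A7", ids$protein, ids$go_annotation,
          draw_bipartite(grp$protein, grp$go_annotation, cfg$annot_in,
                         cfg$annot_out, 12L)),
    edges("A8", ids$disease, ids$protein,
          draw_bipartite(grp$disease, grp$protein, cfg$annot_in,
                         cfg$annot_out, 13L)),
    edges("A9", ids$pathway, ids$protein,
          draw_bipartite(grp$pathway, grp$protein, cfg$annot_in,
                         cfg$annot_out, 14L)),
    edges("A10", ids$tissue, ids$protein,
          draw_bipartite(grp$tissue, grp$protein, cfg$annot_in,
                         cfg$annot_out, 15L))
  )
  net <- hetnet(schema, ids, all_edges)
  truth <- structure(list(compound_group = stats::setNames(grp$compound,
                                                           ids$compound),
                          protein_group = stats::setNames(grp$protein,
                                                          ids$protein),
                          positives = positives, negatives = negatives,
                          null_mode = null_mode, config = cfg),
                     class = "synth_truth")
  list(net = net, truth = truth)
}

#' Emit bioactivity records for the synthetic truth
#'
#' Held-out positives become `"active"` assay records with sub-micromolar
#' activity values; sampled negatives become `"inactive"` records above the
#' 10 uM cutoff. A fraction `noise_rate` of records is flipped across the
#' labeling thresholds, emulating assay noise.
#'
#' @param truth a `synth_truth` from [generate_hetnet()].
#' @param noise_rate flip probability in `[0, 0.5)`.
#' @return data.frame of activity records (`compound_id`, `protein_id`,
#'   `activity_uM`, `outcome`) with attribute `"n_flipped"`.
#' @export
generate_activity_table <- function(truth, noise_rate = 0) {
  stopifnot(inherits(truth, "synth_truth"), noise_rate >= 0, noise_rate < 0.5)
  pos <- truth$positives
  neg <- truth$negatives
  if (nrow(pos) + nrow(neg) == 0L)
    return(data.frame(compound_id = character(), protein_id = character(),
                      activity_uM = numeric(), outcome = character()))
  set.seed(derive_seed(truth$config$seed, 20L))
  flip <- stats::runif(nrow(pos) + nrow(neg)) < noise_rate
  fp <- flip[seq_len(nrow(pos))]
  fn <- flip[nrow(pos) + seq_len(nrow(neg))]
  rec <- rbind(
    data.frame(compound_id = pos$compound_id, protein_id = pos$protein_id,
               activity_uM = ifelse(fp, stats::runif(nrow(pos), 11, 100),
                                    stats::runif(nrow(pos), 0.01, 0.9)),
               outcome = ifelse(fp, "inactive", "active"),
               stringsAsFactors = FALSE),
    data.frame(compound_id = neg$compound_id, protein_id = neg$protein_id,
               activity_uM = ifelse(fn, stats::runif(nrow(neg), 0.01, 0.9),
                                    stats::runif(nrow(neg), 11, 100)),
               outcome = ifelse(fn, "active", "inactive"),
               stringsAsFactors = FALSE)
  )
  attr(rec, "n_flipped") <- sum(flip)
  rec
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("<synth_truth> ", length(x$compound_group), " compounds / ",
      length(x$protein_group), " proteins in ", x$config$n_groups,
      " groups; ", nrow(x$positives), " held-out positives, ",
      nrow(x$negatives), " sampled negatives",
      if (x$null_mode) " [null mode]" else "", "\n", sep = "")
  invisible(x)
}
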