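# Shared fixtures: tiny hand-built networks and a random-network generator
# for oracle-equivalence property tests. Everything is built in code.

tiny_edges <- function(...) {
  rows <- list(...)
  data.frame(edge = vapply(rows, `[[`, "", 1L),
             source = vapply(rows, `[[`, "", 2L),
             target = vapply(rows, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}

# network over the default schema from explicit edge triples; all node ids
# appearing anywhere can be pre-registered via `nodes`
tiny_net <- function(edges, nodes = NULL) {
  read_edge_list(edges, default_schema(), nodes = nodes)
}

# seeded random network: n nodes per type, iid Bernoulli(density) edges for
# every edge spec (same-type specs symmetrized/self-loop-free by read rules)
random_net <- function(seed, n = 12L, density = 0.12) {
  set.seed(seed)
  schema <- default_schema()
  prefix <- c(compound = "c", protein = "p", chebi_type = "ch",
              substructure = "s", side_effect = "se", disease = "d",
              go_annotation = "go", pathway = "pw", tissue = "t")
  ids <- lapply(schema$node_types, function(nt)
    sprintf("%s%02d", prefix[[nt]], seq_len(n)))
  names(ids) <- schema$node_types
  rows <- lapply(seq_len(nrow(schema$edge_specs)), function(k) {
    e <- schema$edge_specs[k, ]
    hits <- which(matrix(runif(n * n), n) < density, arr.ind = TRUE)
    if (e$source_type == e$target_type)
      hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    if (nrow(hits) == 0L) return(NULL)
    data.frame(edge = e$id, source = ids[[e$source_type]][hits[, 1]],
               target = ids[[e$target_type]][hits[, 2]],
               stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  hetnet(schema, ids, rows)
}

# independent walk-counting oracle: enumerates every walk one at a time via
# adjacency lists (no matrix products); returns the full count matrix
brute_force_matrix <- function(net, mp) {
  k_max <- nrow(mp$steps)
  nbrs <- lapply(seq_len(k_max), function(k) {
    m <- adjacency(net, mp$steps$edge[k], mp$steps$orientation[k])
    lapply(seq_len(nrow(m)), function(i) which(m[i, ] != 0))
  })
  n_src <- length(nbrs[[1L]])
  m_last <- adjacency(net, mp$steps$edge[k_max], mp$steps$orientation[k_max])
  n_tgt <- ncol(m_last)
  out <- matrix(0, n_src, n_tgt)
  for (src in seq_len(n_src)) {
    counts <- numeric(n_tgt)
    walk <- function(node, k) {
      if (k > k_max) {
        counts[node] <<- counts[node] + 1
        return(invisible())
      }
      for (v in nbrs[[k]][[node]]) walk(v, k + 1L)
    }
    walk(src, 1L)
    out[src, ] <- counts
  }
  out
}

# brute-force Mann-Whitney AUC: all positive/negative score pairs, ties 1/2
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# direct BEDROC formula evaluation from 1-based active ranks
bedroc_formula <- function(ranks, n, N, alpha) {
  Ra <- n / N
  rie <- sum(exp(-alpha * ranks / N)) /
    (n * (1 / N) * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
}

# labeled pool with planted signal used by model tests (small, fast)
planted_pool <- function(seed = 42, n_compound = 150L, n_protein = 80L) {
  gen <- generate_hetnet(synth_config(seed = seed, n_compound = n_compound,
                                      n_protein = n_protein))
  labels <- rbind(gen$truth$positives, gen$truth$negatives)
  net <- suppressMessages(leakage_guard(gen$net, labels))
  list(net = net, labels = labels, truth = gen$truth)
}
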