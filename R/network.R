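#' Markov clustering and term enrichment of interaction networks
#'
#' @name network_module
NULL

edges_to_adjacency <- function(graph, nodes = NULL) {
  if (is.matrix(graph)) {
    if (nrow(graph) != ncol(graph) || is.null(rownames(graph))) {
      stop_apmsq("adjacency matrix must be square with node names")
    }
    if (any(diag(graph) != 0)) stop_apmsq("input graph must not contain self-loops")
    if (any(graph < 0)) stop_apmsq("edge weights must be positive")
    return(graph)
  }
  req <- c("node_a", "node_b", "weight")
  if (!is.data.frame(graph) || !all(req %in% names(graph))) {
    stop_apmsq("graph must be an adjacency matrix or an edge data frame (node_a, node_b, weight)")
  }
  if (any(graph$node_a == graph$node_b)) stop_apmsq("input graph must not contain self-loops")
  if (any(graph$weight <= 0)) stop_apmsq("edge weights must be positive")
  all_nodes <- sort(unique(c(graph$node_a, graph$node_b, nodes)))
  A <- matrix(0, length(all_nodes), length(all_nodes),
              dimnames = list(all_nodes, all_nodes))
  for (i in seq_len(nrow(graph))) {
    a <- graph$node_a[i]; b <- graph$node_b[i]
    A[a, b] <- A[a, b] + graph$weight[i]
    A[b, a] <- A[b, a] + graph$weight[i]
  }
  A
}

normalize_columns <- function(M) {
  cs <- colSums(M)
  zero <- cs == 0
  if (any(zero)) {
    # a column emptied by pruning restarts as a self-loop
    M[cbind(which(zero), which(zero))] <- 1
    cs <- colSums(M)
  }
  sweep(M, 2, cs, "/")
}

#' Markov clustering (MCL) of a weighted graph
#'
#' Standard MCL on the column-stochastic transition matrix of the graph:
#' self-loops are added (weight = maximum incident edge weight, so the
#' random walk is aperiodic), columns are normalized, then expansion
#' (matrix power) and inflation (elementwise power followed by
#' renormalization) alternate, with entries below `prune_below` set to
#' zero, until the maximum absolute column change drops below `tol`.
#' Clusters are read off the attractor structure of the limit matrix:
#' attractors (nodes with positive return probability) that reach each
#' other form one attractor system, and every other node joins the system
#' of the attractor that attracts it most strongly (ties broken by
#' lexicographically smallest attractor id). The result is a partition of
#' the node set.
#'
#' @param graph edge data frame (`node_a`, `node_b`, `weight`) or a named
#'   symmetric adjacency matrix without self-loops.
#' @param inflation inflation exponent (> 1 sharpens cluster structure;
#'   default 2).
#' @param expansion expansion power (default 2).
#' @param prune_below entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param tol convergence tolerance on the max column change (default 1e-6).
#' @param max_iter iteration cap (default 100).
#' @param nodes optional nodes to include even if isolated.
#' @param self_loop self-loop weight rule: `"max"` (maximum incident
#'   weight, the default) or a positive number.
#' @return List of character vectors (clusters), each node in exactly one;
#'   clusters ordered by decreasing size then first member, members sorted.
#' @export
mcl_cluster <- function(graph, inflation = 2, expansion = 2,
                        prune_below = 1e-5, tol = 1e-6, max_iter = 100,
                        nodes = NULL, self_loop = "max") {
  if (!is.numeric(inflation) || inflation <= 0) stop_apmsq("inflation must be positive")
  A <- edges_to_adjacency(graph, nodes)
  n <- nrow(A)
  if (n == 0) stop_apmsq("graph has no nodes")
  ids <- rownames(A)
  loop <- if (identical(self_loop, "max")) {
    w <- apply(A, 1, max)
    ifelse(w > 0, w, 1)
  } else {
    if (!is.numeric(self_loop) || self_loop <= 0) stop_apmsq("self_loop must be 'max' or a positive number")
    rep(self_loop, n)
  }
  diag(A) <- loop
  M <- normalize_columns(A)
  for (iter in seq_len(max_iter)) {
    Mexp <- M
    if (expansion > 1) for (e in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    Minf <- Mexp ^ inflation
    Minf[Minf < prune_below] <- 0
    Minf <- normalize_columns(Minf)
    if (max(abs(Minf - M)) < tol) { M <- Minf; break }
    M <- Minf
  }
  interpret_mcl(M, ids)
}

interpret_mcl <- function(M, ids) {
  eps <- 1e-9
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0) attractors <- seq_along(ids)
  # attractor systems: attractors reaching one another share a cluster
  sys <- seq_along(attractors)
  repeat {
    changed <- FALSE
    for (i in seq_along(attractors)) for (j in seq_along(attractors)) {
      if (sys[i] != sys[j] &&
          (M[attractors[i], attractors[j]] > eps || M[attractors[j], attractors[i]] > eps)) {
        new <- min(sys[i], sys[j]); sys[sys == sys[i] | sys == sys[j]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sys_ids <- unique(sys)
  assignment <- integer(length(ids))
  for (j in seq_along(ids)) {
    pull <- M[attractors, j]
    if (j %in% attractors) {
      assignment[j] <- sys[match(j, attractors)]
    } else if (max(pull) > eps) {
      best <- attractors[pull == max(pull)]
      best <- best[order(ids[best])][1]
      assignment[j] <- sys[match(best, attractors)]
    } else {
      assignment[j] <- 0L  # unattracted: singleton
    }
  }
  clusters <- lapply(sys_ids, function(s) sort(ids[assignment == s]))
  singles <- lapply(which(assignment == 0L), function(j) ids[j])
  clusters <- c(clusters, singles)
  clusters <- clusters[lengths(clusters) > 0]
  ord <- order(-lengths(clusters), vapply(clusters, `[`, "", 1L), method = "radix")
  clusters[ord]
}

#' Hypergeometric term enrichment for a cluster
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between a cluster and each annotation term, within a stated
#' universe; equivalent to a one-sided Fisher exact test on the 2x2 table.
#' Terms with zero overlap are reported, not skipped. q-values are
#' Benjamini-Hochberg adjusted across terms.
#'
#' @param cluster character vector of member ids, a subset of `universe`.
#' @param annotations named list, term id -> member-id vector (e.g. from
#'   [read_gmt()]); members outside the universe are ignored.
#' @param universe character vector of all ids under consideration
#'   (conventionally the interactome result, not the whole annotation
#'   file - the choice changes p-values).
#' @return Data frame: `term_id`, `term_size`, `overlap`, `universe_size`,
#'   `cluster_size`, `p_value`, `q_value`.
#' @export
term_enrichment <- function(cluster, annotations, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_apmsq("empty universe")
  if (!all(cluster %in% universe)) stop_apmsq("cluster must be a subset of the universe")
  cluster <- unique(cluster)
  N <- length(universe)
  k <- length(cluster)
  term_in_universe <- lapply(annotations, function(ids) intersect(unique(ids), universe))
  m <- lengths(term_in_universe)
  x <- vapply(term_in_universe, function(ids) length(intersect(ids, cluster)), 1L)
  p <- stats::phyper(x - 1, m = m, n = N - m, k = k, lower.tail = FALSE)
  p <- pmin(pmax(p, 0), 1)
  data.frame(term_id = names(annotations) %||% as.character(seq_along(annotations)),
             term_size = unname(m), overlap = unname(x),
             universe_size = N, cluster_size = k,
             p_value = unname(p), q_value = unname(bh_adjust(p)),
             row.names = NULL, stringsAsFactors = FALSE)
}
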