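# Network querying as MAP inference in a conditional random field.
#
# The target network G' is treated as a label set: every query node v_i
# receives a label y_i in V' or the explicit GAP label, and a labeling Y
# has probability
#
#   Pr(Y | G) = 1/Z(G) * prod_i f_N(y_i) * prod_(i,j) in E f_E(y_i, y_j)
#
# with node potential f_N(y_i) = S(v_i, y_i) (sequence similarity) and
# edge potential f_E(y_i, y_j) = (S(v_i,y_i) + S(v_j,y_j))/2 * W(y_i, y_j),
# where W rewards label pairs that are close in the target.  Z(G) is never
# computed: MAP inference is invariant to it, so all scoring happens on
# unnormalised log-potentials.

.gap <- "<gap>"

#' The reserved gap label
#'
#' Label meaning "unmatched".  Node identifiers must not equal this string.
#' @return the gap label string.
#' @export
gap_label <- function() .gap

#' Querying parameters
#'
#' @param top_k candidate labels kept per query node (by similarity).
#' @param gap_score potential of the GAP label; a query node prefers a gap
#'   over any candidate scoring (after edge terms) below this.
#' @param dmax maximum target distance at which two labels still count as
#'   compatible across a query edge.
#' @param decay per-hop decay of the edge compatibility: labels at target
#'   distance d get `decay^(d-1)`, in (0, 1].
#' @param floor_eps strictly positive floor replacing zero potentials so
#'   log-space scores stay finite; must be below `gap_score`.
#' @param bp_max_iters sweep cap for loopy belief propagation.
#' @param bp_damping message damping in [0, 1) for loopy graphs.
#' @param seed integer seed recorded with results.
#' @return a list of class `query_params`.
#' @export
query_params <- function(top_k = 10, gap_score = 0.01, dmax = 2,
                         decay = 0.5, floor_eps = 1e-6,
                         bp_max_iters = 100, bp_damping = 0.5, seed = 1) {
  stopifnot(top_k >= 1, dmax >= 1, decay > 0, decay <= 1,
            floor_eps > 0, floor_eps < gap_score,
            bp_max_iters >= 1, bp_damping >= 0, bp_damping < 1)
  structure(list(top_k = as.integer(top_k), gap_score = gap_score,
                 dmax = as.integer(dmax), decay = decay,
                 floor_eps = floor_eps,
                 bp_max_iters = as.integer(bp_max_iters),
                 bp_damping = bp_damping, seed = as.integer(seed)),
            class = "query_params")
}

#' Node feature potential
#'
#' `f_N(y_i) = S(v_i, y_i)` floored at `floor_eps`; the GAP label has
#' constant potential `gap_score`.
#'
#' @param sim a `node_sim`.
#' @param i query node identifier.
#' @param y label (target node or [gap_label()]).
#' @param p a `query_params`.
#' @return the potential (positive scalar).
#' @export
node_feature <- function(sim, i, y, p = query_params()) {
  if (identical(y, .gap)) return(p$gap_score)
  max(sim_score(sim, i, y), p$floor_eps)
}

#' Edge compatibility score W
#'
#' How structurally compatible two target labels are across a query edge:
#' `decay^(d-1)` for target distance `1 <= d <= dmax` (so adjacent labels
#' score 1), `floor_eps` for identical or unreachable/far labels (the
#' identical-label penalty discourages adjacent query nodes collapsing onto
#' one target), and a neutral 1 whenever either label is GAP.
#'
#' @param target the target `ppi_net`.
#' @param y_i,y_j labels.
#' @param p a `query_params`.
#' @return the W score.
#' @export
edge_compat <- function(target, y_i, y_j, p = query_params()) {
  if (identical(y_i, .gap) || identical(y_j, .gap)) return(1)
  if (identical(y_i, y_j)) return(p$floor_eps)
  d <- igraph::distances(as_igraph(target), v = y_i, to = y_j,
                         mode = "all")[1, 1]
  if (is.finite(d) && d >= 1 && d <= p$dmax) p$decay^(d - 1) else p$floor_eps
}

#' Edge feature potential
#'
#' `f_E(y_i, y_j) = (S(v_i, y_i) + S(v_j, y_j)) / 2 * W(y_i, y_j)`,
#' floored at `floor_eps`; a GAP label contributes `gap_score` to the
#' similarity average.
#'
#' @param sim a `node_sim`.
#' @param i,j endpoint query nodes of the edge.
#' @param y_i,y_j their labels.
#' @param target the target `ppi_net`.
#' @param p a `query_params`.
#' @return the potential (positive scalar).
#' @export
edge_feature <- function(sim, i, j, y_i, y_j, target, p = query_params()) {
  s_i <- if (identical(y_i, .gap)) p$gap_score else sim_score(sim, i, y_i)
  s_j <- if (identical(y_j, .gap)) p$gap_score else sim_score(sim, j, y_j)
  max((s_i + s_j) / 2 * edge_compat(target, y_i, y_j, p), p$floor_eps)
}

#' Build the CRF model for a query
#'
#' Assembles label domains and log-potentials.  The label domain of each
#' query node is its `top_k` target nodes by similarity score (only
#' strictly positive scores; ties broken lexicographically) plus the GAP
#' label.  The normalisation factor Z(G) is deliberately never computed.
#'
#' @param query,target `ppi_net` objects.
#' @param sim a `node_sim` from `query` nodes to `target` nodes.
#' @param p a `query_params`.
#' @return a list of class `crf_model` with the query node order, per-node
#'   label domains and log node potentials, and per-query-edge log edge
#'   potential matrices.
#' @export
build_crf <- function(query, target, sim, p = query_params()) {
  if (num_nodes(query) == 0) stop("empty query network")
  nodes <- query$nodes
  tr <- Matrix::summary(sim$mat)
  tr <- tr[tr$x > 0, , drop = FALSE]
  rn <- rownames(sim$mat); cn <- colnames(sim$mat)
  by_row <- split(seq_len(nrow(tr)), factor(rn[tr$i], levels = nodes))

  domains <- vector("list", length(nodes))
  node_logpot <- vector("list", length(nodes))
  scores <- vector("list", length(nodes))          # raw S for f_E averages
  for (k in seq_along(nodes)) {
    rows <- by_row[[k]]
    cand <- character(0); sc <- numeric(0)
    if (length(rows)) {
      cand <- cn[tr$j[rows]]; sc <- tr$x[rows]
      ord <- order(-sc, cand, method = "radix")
      keep <- head(ord, p$top_k)
      cand <- cand[keep]; sc <- sc[keep]
    }
    domains[[k]] <- c(cand, .gap)
    scores[[k]] <- c(sc, p$gap_score)
    node_logpot[[k]] <- log(c(pmax(sc, p$floor_eps), p$gap_score))
  }
  names(domains) <- names(node_logpot) <- names(scores) <- nodes

  # target distances among all candidate labels, capped past dmax
  cand_union <- sort(unique(unlist(lapply(domains, function(d)
    d[d != .gap]))), method = "radix")
  if (length(cand_union)) {
    dm <- igraph::distances(as_igraph(target), v = cand_union,
                            to = cand_union, mode = "all")
  } else {
    dm <- matrix(numeric(), 0, 0)
  }

  edge_index <- matrix(match(query$edges, nodes), ncol = 2)
  edge_logpot <- vector("list", nrow(edge_index))
  lfloor <- log(p$floor_eps)
  for (e in seq_len(nrow(edge_index))) {
    a <- edge_index[e, 1]; b <- edge_index[e, 2]
    da <- domains[[a]]; db <- domains[[b]]
    na_ <- length(da); nb_ <- length(db)
    # similarity average (gap contributes gap_score)
    S <- (matrix(scores[[a]], na_, nb_) +
            matrix(scores[[b]], na_, nb_, byrow = TRUE)) / 2
    # W matrix: candidates by target distance, gap rows/cols neutral
    W <- matrix(1, na_, nb_)
    ca <- da[-na_]; cb <- db[-nb_]
    if (length(ca) && length(cb)) {
      d <- dm[ca, cb, drop = FALSE]
      w <- p$decay^(d - 1)
      w[!is.finite(d) | d < 1 | d > p$dmax] <- p$floor_eps
      w[outer(ca, cb, "==")] <- p$floor_eps
      W[seq_along(ca), seq_along(cb)] <- w
    }
    lp <- log(pmax(S * W, p$floor_eps))
    lp[lp < lfloor] <- lfloor
    edge_logpot[[e]] <- lp
  }

  structure(list(nodes = nodes, domains = domains,
                 node_logpot = node_logpot,
                 edge_index = edge_index, edge_logpot = edge_logpot,
                 forest = igraph::is_forest(as_igraph(query)),
                 params = p, query = query, target = target),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat("<crf_model> ", length(x$nodes), " query nodes, ",
      nrow(x$edge_index), " query edges, ",
      if (x$forest) "forest (exact DP)" else "loopy (max-product BP)",
      "\n", sep = "")
  invisible(x)
}

#' Log-score of a labeling
#'
#' Sum of log node and edge potentials; differs from `log Pr(Y|G)` only by
#' the constant `log Z(G)`, so it orders labelings identically.
#'
#' @param model a `crf_model`.
#' @param y named character vector assigning each query node a label from
#'   its domain (the gap label counts as assigned).
#' @return the log-potential sum (scalar).
#' @export
labeling_score <- function(model, y) {
  y <- y[model$nodes]
  if (anyNA(y)) stop("labeling must assign every query node")
  total <- 0
  for (k in seq_along(model$nodes)) {
    pos <- match(y[[k]], model$domains[[k]])
    if (is.na(pos)) {
      stop("label '", y[[k]], "' outside the domain of node ",
           model$nodes[k])
    }
    total <- total + model$node_logpot[[k]][pos]
  }
  ei <- model$edge_index
  for (e in seq_len(nrow(ei))) {
    pa <- match(y[[ei[e, 1]]], model$domains[[ei[e, 1]]])
    pb <- match(y[[ei[e, 2]]], model$domains[[ei[e, 2]]])
    total <- total + model$edge_logpot[[e]][pa, pb]
  }
  total
}

# deterministic decode: among tied maxima prefer the lexicographically
# smallest real label; gap only when it strictly dominates or ties nothing
pick_label <- function(vals, labels) {
  mx <- max(vals)
  cand <- labels[vals == mx]
  real <- cand[cand != .gap]
  if (length(real)) sort(real, method = "radix")[1] else .gap
}

#' MAP inference
#'
#' Returns a labeling maximising [labeling_score()].  Forest-shaped queries
#' are solved exactly by max-product dynamic programming (root each tree,
#' upward max-messages, downward argmax decoding).  Loopy queries use
#' damped asynchronous max-product belief propagation in a fixed node
#' order, decoded from per-node max-marginals; the forest result is exact,
#' the loopy one is the standard CRF MAP approximation.  All tie-breaks are
#' lexicographic on the label, with GAP last.
#'
#' @param model a `crf_model`.
#' @param p parameters (defaults to those the model was built with).
#' @return named character labeling with attributes `score` (its
#'   log-score), `method`, and for BP `iterations` and `converged`.
#' @export
map_infer <- function(model, p = model$params) {
  y <- if (model$forest) infer_forest(model) else infer_loopy(model, p)
  attr(y, "score") <- labeling_score(model, y)
  y
}

infer_forest <- function(model) {
  n <- length(model$nodes)
  ei <- model$edge_index
  nbr <- vector("list", n)                      # list of c(other, edge id)
  for (e in seq_len(nrow(ei))) {
    a <- ei[e, 1]; b <- ei[e, 2]
    nbr[[a]] <- c(nbr[[a]], list(c(b, e)))
    nbr[[b]] <- c(nbr[[b]], list(c(a, e)))
  }
  y <- character(n)
  up <- vector("list", n)                       # message child -> parent
  visited <- logical(n)
  for (root in seq_len(n)) {
    if (visited[root]) next
    # BFS order from root (roots are lexicographically first in their tree)
    order_ <- integer(0); parent <- integer(n); pedge <- integer(n)
    queue <- root; visited[root] <- TRUE; parent[root] <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; order_ <- c(order_, v)
      for (nb in nbr[[v]]) {
        w <- nb[1]
        if (!visited[w]) {
          visited[w] <- TRUE; parent[w] <- v; pedge[w] <- nb[2]
          queue <- c(queue, w)
        }
      }
    }
    # upward pass: leaves to root
    for (v in rev(order_)) {
      if (parent[v] == 0L) next
      sc <- model$node_logpot[[v]]
      for (nb in nbr[[v]]) if (nb[1] != parent[v]) sc <- sc + up[[nb[1]]]
      M <- model$edge_logpot[[pedge[v]]]
      up[[v]] <- if (ei[pedge[v], 1] == v) {
        apply(M + sc, 2, max)                   # v is the row side
      } else {
        apply(M + rep(sc, each = nrow(M)), 1, max)
      }
    }
    # downward decode
    for (v in order_) {
      sc <- model$node_logpot[[v]]
      for (nb in nbr[[v]]) if (nb[1] != parent[v]) sc <- sc + up[[nb[1]]]
      if (parent[v] != 0L) {
        M <- model$edge_logpot[[pedge[v]]]
        pp <- match(y[parent[v]], model$domains[[parent[v]]])
        sc <- sc + if (ei[pedge[v], 1] == v) M[, pp] else M[pp, ]
      }
      y[v] <- pick_label(sc, model$domains[[v]])
    }
  }
  y <- setNames(y, model$nodes)
  attr(y, "method") <- "forest-dp"
  y
}

infer_loopy <- function(model, p) {
  res <- bp_max_sum(length(model$nodes),
                    model$edge_index[, 1] - 1L, model$edge_index[, 2] - 1L,
                    model$node_logpot, model$edge_logpot,
                    p$bp_max_iters, p$bp_damping, 1e-8)
  y <- vapply(seq_along(model$nodes), function(k)
    pick_label(res$beliefs[[k]], model$domains[[k]]), "")
  y <- icm_refine(model, y)
  y <- setNames(y, model$nodes)
  attr(y, "method") <- "loopy-bp"
  attr(y, "iterations") <- res$iterations
  attr(y, "converged") <- res$converged
  y
}

# Iterated-conditional-modes cleanup after loopy decoding: node-wise
# sweeps (re-optimise each label given its neighbours), then edge-wise
# sweeps (re-optimise both endpoints of each query edge jointly, which
# escapes the two-node traps single moves cannot).  Every move strictly
# improves labeling_score, so the refinement terminates, is deterministic,
# and is a no-op when BP already decoded a local optimum.
icm_refine <- function(model, y, max_sweeps = 25) {
  n <- length(model$nodes)
  ei <- model$edge_index
  inc <- vector("list", n)               # per node: (edge id, other node)
  for (e in seq_len(nrow(ei))) {
    a <- ei[e, 1]; b <- ei[e, 2]
    inc[[a]] <- c(inc[[a]], list(c(e, b)))
    inc[[b]] <- c(inc[[b]], list(c(e, a)))
  }
  pos <- vapply(seq_len(n), function(k) match(y[k], model$domains[[k]]), 0L)
  # conditional score of node v over its domain, optionally leaving out
  # one incident edge (whose contribution the caller adds jointly)
  cond_score <- function(v, skip_edge = 0L) {
    sc <- model$node_logpot[[v]]
    for (nb in inc[[v]]) {
      e <- nb[1]; w <- nb[2]
      if (e == skip_edge) next
      M <- model$edge_logpot[[e]]
      sc <- sc + if (ei[e, 1] == v) M[, pos[w]] else M[pos[w], ]
    }
    sc
  }
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (v in seq_len(n)) {
      sc <- cond_score(v)
      best <- pick_label(sc, model$domains[[v]])
      bi <- match(best, model$domains[[v]])
      # move only on a strict score improvement to guarantee termination
      if (bi != pos[v] && sc[bi] > sc[pos[v]]) {
        pos[v] <- bi; changed <- TRUE
      }
    }
    for (e in seq_len(nrow(ei))) {
      a <- ei[e, 1]; b <- ei[e, 2]
      joint <- outer(cond_score(a, e), cond_score(b, e), "+") +
        model$edge_logpot[[e]]
      mx <- max(joint)
      if (mx > joint[pos[a], pos[b]] + 1e-12) {
        best <- which(joint == mx, arr.ind = TRUE)[1, ]
        pos[a] <- best[[1]]; pos[b] <- best[[2]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  vapply(seq_len(n), function(k) model$domains[[k]][pos[k]], "")
}

#' Query a network in a target network (CNetQ)
#'
#' Builds the CRF for the query and returns the MAP labeling as a node
#' mapping; GAP-labelled nodes are omitted.  The result may be many-to-one
#' (several query nodes sharing one target); use
#' [extract_one_to_one()] or [net_align()] for injective results.
#'
#' @param query,target `ppi_net` objects.
#' @param sim a `node_sim` from query to target nodes.
#' @param p a `query_params`.
#' @return a `node_map` with attributes `score`, `labeling` and (for loopy
#'   queries) `iterations`.
#' @examples
#' net <- network(cbind(c("a", "b", "c"), c("b", "c", "a")))
#' s <- node_similarity(net, net,
#'                      data.frame(u = net$nodes, v = net$nodes, s = 1))
#' net_query(net, net, s)
#' @export
net_query <- function(query, target, sim, p = query_params()) {
  model <- build_crf(query, target, sim, p)
  y <- map_infer(model, p)
  keep <- y != .gap
  m <- node_mapping(model$nodes[keep], unname(y[keep]),
                    from = query$name, to = target$name)
  attr(m, "score") <- attr(y, "score")
  attr(m, "labeling") <- y
  attr(m, "iterations") <- attr(y, "iterations")
  m
}
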