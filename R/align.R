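# One-to-one network alignment by iterative bi-directional mapping.
#
# A single querying pass is asymmetric (querying X in Y differs from Y in
# X) and may be many-to-one.  The aligner therefore queries in both
# directions each round, fixes the reciprocal (common) pairs by clamping
# their similarity, and repeats until no new reciprocal pair appears.
# Only accumulated fixed pairs are returned: they are one-to-one and
# bidirectionally consistent by construction.

#' Alignment parameters
#'
#' @param query_params a [query_params()] list shared by both querying
#'   directions.
#' @param max_rounds hard iteration cap guarding against oscillation; the
#'   natural stopping rule is "no new reciprocal pairs".
#' @param boost potential given to fixed pairs, must exceed every stored
#'   similarity so clamped evidence dominates; `NULL` means
#'   `1 + max(similarity)` computed at run time.
#' @return a list of class `align_params`.
#' @export
align_params <- function(query_params = crfalign::query_params(),
                         max_rounds = 20, boost = NULL) {
  stopifnot(max_rounds >= 1)
  structure(list(query_params = query_params,
                 max_rounds = as.integer(max_rounds), boost = boost),
            class = "align_params")
}

#' Keep only one-to-one pairs of a mapping
#'
#' Removes every pair whose target node is hit by two or more query nodes,
#' leaving an injective mapping.  This is the published post-processing of
#' many-to-one querying results.
#'
#' @param m a `node_map`.
#' @return an injective `node_map`.
#' @export
extract_one_to_one <- function(m) {
  hits <- table(m$target)
  keep <- m$target %in% names(hits)[hits == 1]
  node_mapping(m$query[keep], m$target[keep],
               from = attr(m, "from"), to = attr(m, "to"))
}

#' Reciprocal pairs of two opposite-direction mappings
#'
#' `(u, v)` is common when the forward pass maps `u` to `v` and the
#' backward pass maps `v` back to `u`; such mutual-best pairs are
#' necessarily one-to-one.
#'
#' @param fwd mapping from network A to network B.
#' @param bwd mapping from network B to network A.
#' @return a `node_map` in the forward direction.
#' @export
common_pairs <- function(fwd, bwd) {
  if (!identical(attr(fwd, "from"), attr(bwd, "to")) ||
      !identical(attr(fwd, "to"), attr(bwd, "from"))) {
    stop("mappings are not in opposite directions")
  }
  back <- mapping_lookup(bwd)
  keep <- fwd$target %in% names(back) &
    back[fwd$target] == fwd$query
  node_mapping(fwd$query[keep], fwd$target[keep],
               from = attr(fwd, "from"), to = attr(fwd, "to"))
}

#' Clamp fixed pairs into a similarity
#'
#' For each fixed pair `(u, v)` the row of `u` and the column of `v` are
#' zeroed and `S(u, v)` is set to `boost`, so subsequent querying treats
#' the pair as certain and removes both nodes from all other candidate
#' domains.
#'
#' @param sim a `node_sim`.
#' @param fixed a one-to-one `node_map` (or data frame of query/target
#'   columns) of pairs to clamp.
#' @param boost the clamped score; must exceed all stored scores.
#' @return the updated `node_sim`.
#' @export
fix_and_update <- function(sim, fixed, boost) {
  if (nrow(fixed) == 0) return(sim)
  if (anyDuplicated(fixed$query) || anyDuplicated(fixed$target)) {
    stop("fixed pairs must be one-to-one")
  }
  tr <- Matrix::summary(sim$mat)
  ri <- match(fixed$query, rownames(sim$mat))
  cj <- match(fixed$target, colnames(sim$mat))
  if (anyNA(ri) || anyNA(cj)) stop("fixed pair names unknown node")
  keep <- !(tr$i %in% ri) & !(tr$j %in% cj)
  i <- c(tr$i[keep], ri); j <- c(tr$j[keep], cj)
  x <- c(tr$x[keep], rep(boost, length(ri)))
  structure(list(left = sim$left, right = sim$right,
                 mat = Matrix::sparseMatrix(i = i, j = j, x = x,
                                            dims = dim(sim$mat),
                                            dimnames = dimnames(sim$mat))),
            class = "node_sim")
}

iterate_align <- function(G, Gp, sim, p, query_fn) {
  boost <- p$boost
  if (is.null(boost)) boost <- 1 + max(c(0, sim$mat@x))
  fixed <- node_mapping(from = G$name, to = Gp$name)
  S <- sim
  trace <- data.frame(round = integer(), fwd_size = integer(),
                      bwd_size = integer(), new_fixed = integer())
  for (round in seq_len(p$max_rounds)) {
    fwd <- query_fn(G, Gp, S)
    bwd <- query_fn(Gp, G, sim_transpose(S))
    common <- common_pairs(fwd, bwd)
    new <- !(common$query %in% fixed$query)
    trace <- rbind(trace, data.frame(round = round, fwd_size = nrow(fwd),
                                     bwd_size = nrow(bwd),
                                     new_fixed = sum(new)))
    if (!any(new)) break
    fixed <- node_mapping(c(fixed$query, common$query[new]),
                          c(fixed$target, common$target[new]),
                          from = G$name, to = Gp$name)
    S <- fix_and_update(S, node_mapping(common$query[new],
                                        common$target[new],
                                        from = G$name, to = Gp$name),
                        boost)
    if (round == p$max_rounds) {
      warning("alignment stopped at max_rounds = ", p$max_rounds,
              " with new pairs still appearing")
    }
  }
  list(mapping = fixed, trace = trace)
}

#' Align two networks one-to-one (CNetA)
#'
#' Iterative bi-directional mapping: each round runs [net_query()] in both
#' directions, fixes the reciprocal pairs via [fix_and_update()], and
#' repeats until no new reciprocal pair appears (or `max_rounds`).  The
#' returned mapping is the accumulated fixed set — injective in both
#' directions and symmetric under swapping the two networks.
#'
#' @param G,Gp `ppi_net` objects.
#' @param sim a `node_sim` from `G` nodes to `Gp` nodes.
#' @param p an [align_params()] list.
#' @return a list of class `align_result`: `mapping` (one-to-one
#'   `node_map`) and `trace` (per-round sizes and newly fixed counts).
#' @export
net_align <- function(G, Gp, sim, p = align_params()) {
  qp <- p$query_params
  res <- iterate_align(G, Gp, sim, p,
                       function(a, b, s) net_query(a, b, s, qp))
  structure(res, class = "align_result")
}

#' @export
print.align_result <- function(x, ...) {
  cat("<align_result> ", nrow(x$mapping), " fixed pairs in ",
      nrow(x$trace), " round(s)\n", sep = "")
  print(x$trace, row.names = FALSE)
  invisible(x)
}

#' Best-hit querying baseline (BLASTQ)
#'
#' Each query node maps to its unique highest-similarity target; a node
#' whose best score is tied between several targets is left unmatched (its
#' best hits are indistinguishable by similarity alone), and
#' [extract_one_to_one()] then removes residual many-to-one collisions.
#' This purely biological baseline ignores all network structure.
#'
#' @param G,Gp `ppi_net` objects.
#' @param sim a `node_sim` from `G` to `Gp` nodes.
#' @return an injective `node_map`.
#' @export
best_hit_query <- function(G, Gp, sim) {
  tr <- Matrix::summary(sim$mat)
  tr <- tr[tr$x > 0, , drop = FALSE]
  q <- character(0); t <- character(0)
  if (nrow(tr) > 0) {
    rn <- rownames(sim$mat); cn <- colnames(sim$mat)
    for (grp in split(seq_len(nrow(tr)), tr$i)) {
      mx <- max(tr$x[grp])
      best <- grp[tr$x[grp] == mx]
      if (length(best) == 1) {
        q <- c(q, rn[tr$i[best]]); t <- c(t, cn[tr$j[best]])
      }
    }
  }
  keep <- q %in% G$nodes & t %in% Gp$nodes
  extract_one_to_one(node_mapping(q[keep], t[keep],
                                  from = G$name, to = Gp$name))
}

#' Best-hit alignment baseline (BLASTA)
#'
#' [best_hit_query()] combined with the same iterative bi-directional
#' mapping strategy as [net_align()].
#'
#' @param G,Gp `ppi_net` objects.
#' @param sim a `node_sim` from `G` to `Gp` nodes.
#' @param p an [align_params()] list (`query_params` is ignored).
#' @return a list of class `align_result` (see [net_align()]).
#' @export
best_hit_align <- function(G, Gp, sim, p = align_params()) {
  structure(iterate_align(G, Gp, sim, p, best_hit_query),
            class = "align_result")
}
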