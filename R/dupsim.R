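# Gene-duplication network evolution simulator.
#
# A duplicated network G' grows from a base network G by repeatedly
# copying a node together with its interaction pattern and thinning the
# edges of both copies, then losing a small random fraction of all edges.
# Because duplications never touch adjacent or already-duplicated nodes,
# successive events are independent, and the construction yields a known
# true alignment: every G' node has an origin in G, and the correct fate
# of a duplicate is alignment to gap.

#' Simulation parameters
#'
#' @param N maximum number of duplication events.
#' @param p1 fraction of the duplicate's edges lost (redundancy pressure
#'   on the new copy).
#' @param p2 fraction of the original's edges lost; must satisfy
#'   `p1 >= p2`.  The intended regime is `p1 >= p2 >> p3`.
#' @param p3 fraction of all edges lost at random at the end (background
#'   noise).
#' @param seed integer RNG seed; the whole simulation is deterministic
#'   given the parameters.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(N = 100, p1 = 0.2, p2 = 0.1, p3 = 0.005, seed = 1) {
  stopifnot(N >= 0, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, p3 >= 0, p3 <= 1)
  if (p1 < p2) stop("duplication model requires p1 >= p2")
  if (p3 > p2) warning("expected ordering p1 >= p2 >> p3 violated (p3 > p2)")
  structure(list(N = as.integer(N), p1 = p1, p2 = p2, p3 = p3,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Evolve a duplicated network from a base network
#'
#' Implements the duplication event model: (1) start with the duplicated
#' set D, adjacent set A empty and remaining set R = V; (2) pick v
#' uniformly from R and add v' carrying v's interaction pattern (v' is not
#' linked to v: the copy inherits interactions, heterodimerisation is not
#' modelled); (3) remove `round(p1 * deg(v'))` of v's copy's edges and
#' `round(p2 * deg(v))` of v's edges, uniformly without replacement;
#' (4) move v to D, its neighbours to A, and drop both from R; (5) repeat
#' until N events or R is empty; (6) finally remove `round(p3 * |E'|)`
#' edges uniformly from the whole network.  Duplicates are named
#' `<base>__dup`.
#'
#' @param G the base `ppi_net`.
#' @param p a [sim_params()] list.
#' @return a list of class `dup_sim`: `network` (the evolved `ppi_net`)
#'   and `truth` (a `true_alignment`: `origin` named vector G' -> G,
#'   `duplicated` = D, `adjacent` = A, `remaining` = final R, and
#'   `removed` edge-removal tallies).
#' @export
duplicate_network <- function(G, p = sim_params()) {
  if (num_nodes(G) == 0) stop("empty base network")
  set.seed(p$seed)
  adj <- lapply(setNames(G$nodes, G$nodes), function(v) character(0))
  for (e in seq_len(nrow(G$edges))) {
    u <- G$edges[e, 1]; v <- G$edges[e, 2]
    adj[[u]] <- c(adj[[u]], v); adj[[v]] <- c(adj[[v]], u)
  }
  drop_edge <- function(a, b) {
    adj[[a]] <<- setdiff(adj[[a]], b); adj[[b]] <<- setdiff(adj[[b]], a)
  }
  D <- character(0); A <- character(0); R <- G$nodes
  n <- 0L; rem1 <- 0L; rem2 <- 0L
  origin <- setNames(G$nodes, G$nodes)
  while (n < p$N && length(R) > 0) {
    v <- R[sample.int(length(R), 1)]
    nb <- adj[[v]]
    vd <- paste0(v, "__dup")
    adj[[vd]] <- nb
    for (w in nb) adj[[w]] <- c(adj[[w]], vd)
    origin[vd] <- v
    k1 <- round(p$p1 * length(nb))
    if (k1 > 0) {
      lost <- adj[[vd]][sample.int(length(adj[[vd]]), k1)]
      for (w in lost) drop_edge(vd, w)
      rem1 <- rem1 + k1
    }
    k2 <- round(p$p2 * length(adj[[v]]))
    if (k2 > 0) {
      lost <- adj[[v]][sample.int(length(adj[[v]]), k2)]
      for (w in lost) drop_edge(v, w)
      rem2 <- rem2 + k2
    }
    n <- n + 1L
    D <- c(D, v)
    A <- union(A, nb)
    R <- setdiff(R, c(v, nb))
  }
  # collect the current edge set, then background loss
  em <- do.call(rbind, lapply(names(adj), function(u) {
    nb <- adj[[u]][adj[[u]] > u]
    if (length(nb)) cbind(u, nb) else NULL
  }))
  n_edges <- NROW(em)
  k3 <- round(p$p3 * n_edges)
  if (k3 > 0) {
    em <- em[-sample.int(n_edges, k3), , drop = FALSE]
  }
  Gp <- network(em, nodes = names(adj), name = paste0(G$name, "_dup"))
  truth <- structure(list(origin = origin[Gp$nodes],
                          duplicated = sort(D, method = "radix"),
                          adjacent = sort(A, method = "radix"),
                          remaining = sort(R, method = "radix"),
                          removed = c(p1 = rem1, p2 = rem2, p3 = k3)),
                     class = "true_alignment")
  structure(list(network = Gp, truth = truth, base = G, params = p),
            class = "dup_sim")
}

#' @export
print.dup_sim <- function(x, ...) {
  cat("<dup_sim> ", num_nodes(x$base), " -> ", num_nodes(x$network),
      " nodes (", length(x$truth$duplicated), " duplications), ",
      num_edges(x$network), " edges\n", sep = "")
  invisible(x)
}

#' The duplicate node of a base node
#' @param truth a `true_alignment`.
#' @param v base node identifier(s).
#' @return the duplicate identifiers (`NA` where `v` was not duplicated).
#' @export
duplicate_of <- function(truth, v) {
  dups <- names(truth$origin)[names(truth$origin) != truth$origin]
  setNames(dups[match(v, truth$origin[dups])], v)
}

#' Synthetic similarity for a simulated pair
#'
#' Duplicates carry their original's sequence, so similarity rows are
#' copied: `S(u, w) = 1` whenever `origin(w) = u`.  A duplicated base node
#' thus has two perfect hits — itself and its duplicate — which is the
#' deliberate ambiguity sequence-only methods cannot resolve.  Optional
#' uniform background noise entries emulate spurious weak hits.
#'
#' @param G,Gp base and duplicated `ppi_net` objects.
#' @param truth the `true_alignment` from [duplicate_network()].
#' @param background score of noise entries.
#' @param noise_pairs number of random extra entries.
#' @param seed RNG seed for the noise.
#' @return a `node_sim` from `G` to `Gp`.
#' @export
synth_similarity <- function(G, Gp, truth, background = 0,
                             noise_pairs = 0, seed = 1) {
  pairs <- data.frame(u = unname(truth$origin), v = names(truth$origin),
                      s = 1, stringsAsFactors = FALSE)
  if (noise_pairs > 0 && background > 0) {
    set.seed(seed)
    pairs <- rbind(pairs,
                   data.frame(u = G$nodes[sample.int(num_nodes(G),
                                                     noise_pairs,
                                                     replace = TRUE)],
                              v = Gp$nodes[sample.int(num_nodes(Gp),
                                                      noise_pairs,
                                                      replace = TRUE)],
                              s = background, stringsAsFactors = FALSE))
  }
  node_similarity(G, Gp, pairs)
}

#' Duplication-aware alignment accuracy
#'
#' A duplicated base node v is correctly aligned only when v is mapped to
#' its own image in the duplicated network AND its duplicate is matched by
#' no base node (the duplicate's correct fate is gap).
#' `accuracy_dup` scores only the duplicated nodes; `accuracy_all` scores
#' every base node (non-duplicated nodes are correct when mapped to
#' themselves).
#'
#' @param m a `node_map` from the base to the duplicated network.
#' @param truth the `true_alignment`.
#' @return fraction correct in [0, 1] (`accuracy_dup` returns 1 when no
#'   node was duplicated).
#' @export
accuracy_dup <- function(m, truth) {
  D <- truth$duplicated
  if (length(D) == 0) return(1)
  look <- mapping_lookup(m)
  dups <- duplicate_of(truth, D)
  correct <- !is.na(look[D]) & look[D] == D & !(dups %in% m$target)
  mean(correct)
}

#' @rdname accuracy_dup
#' @param G the base `ppi_net` (defines the node universe).
#' @export
accuracy_all <- function(m, truth, G) {
  look <- mapping_lookup(m)
  D <- truth$duplicated
  ok <- !is.na(look[G$nodes]) & look[G$nodes] == G$nodes
  if (length(D)) {
    dups <- duplicate_of(truth, D)
    ok[match(D, G$nodes)] <- ok[match(D, G$nodes)] & !(dups %in% m$target)
  }
  mean(ok)
}

#' Benchmark alignment methods on simulated duplication instances
#'
#' For each `(p1, p2)` setting and replicate: simulate a duplicated
#' network, build the origin-based similarity, run each method, and score
#' matching pairs, edge correctness, largest common connected subgraph and
#' the two accuracies against the known truth.  Fully seeded: replicate r
#' of setting s uses seed `seed + 97 * s + r`.
#'
#' @param G the base `ppi_net`.
#' @param settings data frame (or 2-column matrix) of `p1`, `p2` values.
#' @param reps replicates per setting.
#' @param N,p3 remaining simulation parameters, shared by all settings.
#' @param methods subset of `"cnetq"`, `"cneta"`, `"blastq"`, `"blasta"`.
#'   The querying methods are reported after one-to-one extraction.
#' @param seed base seed.
#' @param query_params CRF parameters for the CNet methods.
#' @param max_rounds iteration cap for the aligners.
#' @return a list of class `benchmark_result`: `runs` (one row per
#'   setting x replicate x method) and `summary` (per-method means), plus
#'   the run metadata.
#' @export
run_benchmark <- function(G, settings = data.frame(p1 = 0.2, p2 = 0.1),
                          reps = 10, N = 100, p3 = 0.005,
                          methods = c("cnetq", "cneta", "blastq", "blasta"),
                          seed = 1,
                          query_params = crfalign::query_params(),
                          max_rounds = 20) {
  known <- c("cnetq", "cneta", "blastq", "blasta")
  if (!all(methods %in% known)) {
    stop("unknown method(s): ", paste(setdiff(methods, known),
                                      collapse = ", "))
  }
  settings <- as.data.frame(settings)
  names(settings)[1:2] <- c("p1", "p2")
  ap <- align_params(query_params = query_params, max_rounds = max_rounds)
  runs <- list()
  for (s in seq_len(nrow(settings))) {
    for (r in seq_len(reps)) {
      run_seed <- seed + 97L * s + r
      sm <- duplicate_network(G, sim_params(N = N, p1 = settings$p1[s],
                                            p2 = settings$p2[s], p3 = p3,
                                            seed = run_seed))
      Gp <- sm$network
      S <- synth_similarity(G, Gp, sm$truth)
      for (method in methods) {
        m <- switch(method,
          cnetq = extract_one_to_one(net_query(G, Gp, S, query_params)),
          cneta = net_align(G, Gp, S, ap)$mapping,
          blastq = best_hit_query(G, Gp, S),
          blasta = best_hit_align(G, Gp, S, ap)$mapping)
        lc <- lccs(G, Gp, m)
        runs[[length(runs) + 1]] <- data.frame(
          p1 = settings$p1[s], p2 = settings$p2[s], rep = r,
          seed = run_seed, method = method,
          mp = mp(m), ec = edge_correctness(G, Gp, m),
          lccs_nodes = lc[["nodes"]], lccs_edges = lc[["edges"]],
          acc_dup = accuracy_dup(m, sm$truth),
          acc_all = accuracy_all(m, sm$truth, G),
          stringsAsFactors = FALSE)
      }
    }
  }
  runs <- do.call(rbind, runs)
  num <- c("mp", "ec", "lccs_nodes", "lccs_edges", "acc_dup", "acc_all")
  summary <- aggregate(runs[num], by = list(method = runs$method), mean)
  summary <- summary[match(intersect(known, methods), summary$method), ]
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary,
                 metadata = list(N = N, p3 = p3, reps = reps,
                                 settings = settings, seed = seed)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  md <- x$metadata
  cat("<benchmark_result> ", nrow(md$settings), " setting(s) x ",
      md$reps, " replicate(s), N = ", md$N, ", p3 = ", md$p3, "\n",
      sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
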