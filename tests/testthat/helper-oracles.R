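# Shared fixtures and independent oracles.  Oracles deliberately avoid the
# package's own code paths: exhaustive enumeration for MAP inference and
# one-to-one assignment, Floyd-Warshall for distances, hand-rolled BFS for
# connected components.

net_from_text <- function(txt, name = "net") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(txt, path)
  read_network(path, name = name)
}

# Erdos-Renyi style random network with letter-ish labels
rand_net <- function(n, p_edge = 0.3, seed = 1, name = "rand",
                     connected = FALSE) {
  set.seed(seed)
  repeat {
    ids <- sprintf("n%02d", seq_len(n))
    pairs <- t(combn(ids, 2))
    keep <- runif(nrow(pairs)) < p_edge
    net <- network(pairs[keep, , drop = FALSE], nodes = ids, name = name)
    if (!connected) return(net)
    if (igraph::is_connected(as_igraph(net))) return(net)
  }
}

identity_sim <- function(net, score = 1) {
  node_similarity(net, net,
                  data.frame(u = net$nodes, v = net$nodes, s = score))
}

# exhaustive MAP: enumerate every labeling in the model's domains
enumerate_best <- function(model) {
  grids <- expand.grid(model$domains, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  best <- -Inf; best_y <- NULL
  for (r in seq_len(nrow(grids))) {
    y <- setNames(as.character(grids[r, ]), model$nodes)
    sc <- labeling_score(model, y)
    if (sc > best) { best <- sc; best_y <- y }
  }
  list(score = best, labeling = best_y)
}

# Floyd-Warshall all-pairs hop distances
fw_distances <- function(net) {
  n <- length(net$nodes)
  d <- matrix(Inf, n, n, dimnames = list(net$nodes, net$nodes))
  diag(d) <- 0
  for (e in seq_len(nrow(net$edges))) {
    i <- match(net$edges[e, 1], net$nodes)
    j <- match(net$edges[e, 2], net$nodes)
    d[i, j] <- d[j, i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# brute-force LCCS: explicit pair graph + hand BFS components
brute_lccs <- function(G, Gp, m) {
  np <- nrow(m)
  if (np == 0) return(c(nodes = 0L, edges = 0L))
  ekey <- function(net) paste(net$edges[, 1], net$edges[, 2], sep = "|")
  keyG <- ekey(G); keyGp <- ekey(Gp)
  adj <- matrix(FALSE, np, np)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i >= j) next
    u1 <- m$query[i]; u2 <- m$query[j]
    v1 <- m$target[i]; v2 <- m$target[j]
    eG <- paste(min(u1, u2), max(u1, u2), sep = "|") %in% keyG
    eGp <- paste(min(v1, v2), max(v1, v2), sep = "|") %in% keyGp
    if (eG && eGp) adj[i, j] <- adj[j, i] <- TRUE
  }
  seen <- logical(np); best <- c(nodes = 0L, edges = 0L)
  for (s in seq_len(np)) {
    if (seen[s]) next
    comp <- s; queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ])) if (!seen[w]) {
        seen[w] <- TRUE; comp <- c(comp, w); queue <- c(queue, w)
      }
    }
    cand <- c(nodes = length(comp),
              edges = sum(adj[comp, comp, drop = FALSE]) / 2)
    if (cand["nodes"] > best["nodes"] ||
        (cand["nodes"] == best["nodes"] && cand["edges"] > best["edges"])) {
      best <- cand
    }
  }
  setNames(as.integer(best), c("nodes", "edges"))
}

# random CRF querying instance: small query forest/graph, random target,
# random sparse similarity
rand_instance <- function(seed, n_query = 5, n_target = 8, forest = TRUE,
                          cand = 4) {
  set.seed(seed)
  nq <- sample(2:n_query, 1)
  q_ids <- sprintf("q%d", seq_len(nq))
  if (forest) {
    # random forest: each node links to an earlier node with prob 0.8
    edges <- NULL
    for (k in 2:nq) {
      if (runif(1) < 0.8) {
        edges <- rbind(edges, c(q_ids[sample(k - 1, 1)], q_ids[k]))
      }
    }
    query <- network(edges, nodes = q_ids, name = "q")
  } else {
    pairs <- t(combn(q_ids, 2))
    keep <- runif(nrow(pairs)) < 0.7
    query <- network(pairs[keep, , drop = FALSE], nodes = q_ids,
                     name = "q")
  }
  target <- rand_net(n_target, 0.35, seed = seed + 2000, name = "t")
  entries <- do.call(rbind, lapply(q_ids, function(u) {
    k <- sample(0:cand, 1)
    if (k == 0) return(NULL)
    data.frame(u = u, v = sample(target$nodes, k),
               s = round(runif(k, 0.05, 1), 3))
  }))
  sim <- node_similarity(query, target, entries)
  list(query = query, target = target, sim = sim)
}

# all permutations of a character vector (oracle for exhaustive
# one-to-one assignment search)
combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

pa_net <- function(n, m = 3, seed = 1, name = "pa") {
  set.seed(seed)
  g <- igraph::sample_pa(n, m = m, directed = FALSE)
  network(matrix(as.character(igraph::as_edgelist(g)), ncol = 2),
          nodes = as.character(seq_len(n)), name = name)
}
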