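# Data model and file I/O for undirected networks, sparse node
# similarities and node mappings.  Node identifiers are case-sensitive
# opaque strings; edges are unordered pairs without self-loops or
# multiplicity.  All writers emit deterministically sorted output so
# repeated runs are byte-identical.

#' Construct an undirected network
#'
#' Builds a simple undirected graph from an edge table and (optionally)
#' extra isolated nodes.  Self-loops and duplicate edges are dropped with a
#' warning; real PPI exports routinely contain both, and the matching model
#' assumes simple graphs.
#'
#' @param edges two-column character matrix or data frame of endpoint pairs
#'   (may be `NULL` for an edgeless network).
#' @param nodes character vector of additional node identifiers to register
#'   even if they touch no edge.
#' @param name label used in printing and in similarity/mapping direction
#'   checks.
#' @return An object of class `ppi_net` with components `name`, `nodes`
#'   (sorted character vector) and `edges` (two-column character matrix,
#'   each row sorted, rows sorted).
#' @examples
#' net <- network(cbind(c("a", "b", "c"), c("b", "c", "a")), name = "triangle")
#' num_nodes(net)
#' @export
network <- function(edges = NULL, nodes = character(), name = "network") {
  if (is.null(edges) || NROW(edges) == 0) {
    em <- matrix(character(), ncol = 2)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    loops <- em[, 1] == em[, 2]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      em <- em[!loops, , drop = FALSE]
    }
    # canonical order within each edge, then dedupe
    u <- pmin(em[, 1], em[, 2])
    v <- pmax(em[, 1], em[, 2])
    key <- paste(u, v, sep = "\r")
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sum(dup), " duplicate edge(s) dropped")
    }
    ord <- order(u[!dup], v[!dup], method = "radix")
    em <- cbind(u[!dup], v[!dup])[ord, , drop = FALSE]
  }
  dimnames(em) <- NULL
  all_nodes <- sort(unique(c(as.character(nodes), as.vector(em))),
                    method = "radix")
  structure(list(name = name, nodes = all_nodes, edges = em),
            class = "ppi_net")
}

#' @export
print.ppi_net <- function(x, ...) {
  cat("<ppi_net> ", x$name, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param net a `ppi_net`.
#' @return integer count.
#' @export
num_nodes <- function(net) length(net$nodes)

#' @rdname num_nodes
#' @export
num_edges <- function(net) nrow(net$edges)

#' Convert a network to an igraph object
#'
#' @param net a `ppi_net`.
#' @return an undirected `igraph` graph whose vertex names are the node
#'   identifiers (isolated nodes included).
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges) > 0) {
    g <- igraph::add_edges(g, t(matrix(match(net$edges, net$nodes),
                                       ncol = 2)))
  }
  g
}

#' Read a network from an edge-list file
#'
#' The canonical dialect: one edge per line, two (or more) whitespace
#' separated tokens of which the first two are the endpoints, `#` starts a
#' comment line, blank lines are ignored.  Self-loops and repeated edges
#' are dropped with a warning.
#'
#' @param path file path.
#' @param name network label (defaults to the file name).
#' @return a `ppi_net`.
#' @export
read_network <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  ntok <- lengths(toks)
  if (any(ntok < 2)) {
    stop("malformed network line ", idx[which(ntok < 2)[1]],
         " in ", path, ": expected at least 2 tokens")
  }
  em <- cbind(vapply(toks, `[`, "", 1L), vapply(toks, `[`, "", 2L))
  network(em, name = name)
}

#' Write a network to an edge-list file
#'
#' Inverse of [read_network()]: tab-separated endpoint pairs in sorted
#' order, plus isolated nodes as comment lines so the node set round-trips.
#'
#' @param net a `ppi_net`.
#' @param path output file path.
#' @export
write_network <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  iso <- setdiff(net$nodes, as.vector(net$edges))
  if (length(iso)) {
    writeLines(paste0("#node\t", iso), con)
  }
  if (nrow(net$edges) > 0) {
    writeLines(paste(net$edges[, 1], net$edges[, 2], sep = "\t"), con)
  }
  invisible(path)
}

# read_network drops "#node" lines as comments; recover isolated nodes here
# so write/read round-trips exactly.
read_network_full <- function(path, name = basename(path)) {
  net <- read_network(path, name = name)
  lines <- readLines(path, warn = FALSE)
  iso <- sub("^#node\t", "", lines[startsWith(lines, "#node\t")])
  net$nodes <- sort(unique(c(net$nodes, iso)), method = "radix")
  net
}

#' Truncated single-source shortest-path distances
#'
#' Unweighted breadth-first-search distances from `source`, truncated at
#' `dmax` hops.  Used by the edge-compatibility potential and by the edge
#' accumulated coverage curve.
#'
#' @param net a `ppi_net`.
#' @param source a node identifier in `net`.
#' @param dmax positive integer hop limit.
#' @return named integer vector of distances `<= dmax` (the source maps
#'   to 0).
#' @export
bounded_distances <- function(net, source, dmax) {
  if (!source %in% net$nodes) stop("unknown source node: ", source)
  stopifnot(dmax >= 1)
  d <- igraph::distances(as_igraph(net), v = source, mode = "all")[1, ]
  d <- d[is.finite(d) & d <= dmax]
  setNames(as.integer(d), names(d))[order(names(d), method = "radix")]
}

# ---------------------------------------------------------------------------
# Sparse node similarity

#' Construct a sparse node-similarity object
#'
#' Holds non-negative similarity scores `S(u, v)` between the nodes of two
#' networks, with 0 for absent pairs.
#'
#' @param left,right `ppi_net` objects (or character node vectors) for the
#'   row and column node sets.
#' @param pairs optional data frame / matrix with columns (u, v, score);
#'   repeated (u, v) entries are merged by maximum.
#' @param left_name,right_name labels when `left`/`right` are plain vectors.
#' @return an object of class `node_sim`: labels `left`, `right` and a
#'   `dgCMatrix` `mat` with sorted dimnames.
#' @export
node_similarity <- function(left, right, pairs = NULL,
                            left_name = "left", right_name = "right") {
  lnodes <- if (inherits(left, "ppi_net")) left$nodes else
    sort(unique(as.character(left)), method = "radix")
  rnodes <- if (inherits(right, "ppi_net")) right$nodes else
    sort(unique(as.character(right)), method = "radix")
  lname <- if (inherits(left, "ppi_net")) left$name else left_name
  rname <- if (inherits(right, "ppi_net")) right$name else right_name
  if (is.null(pairs) || NROW(pairs) == 0) {
    mat <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(length(lnodes), length(rnodes)),
                                dimnames = list(lnodes, rnodes))
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    u <- as.character(pairs[[1]]); v <- as.character(pairs[[2]])
    s <- as.numeric(pairs[[3]])
    if (anyNA(s)) stop("non-numeric similarity score")
    if (any(s < 0)) stop("negative similarity score")
    i <- match(u, lnodes); j <- match(v, rnodes)
    bad <- is.na(i) | is.na(j)
    if (any(bad)) {
      warning(sum(bad), " similarity entr(y/ies) dropped: unknown node(s)")
      i <- i[!bad]; j <- j[!bad]; s <- s[!bad]
    }
    # merge duplicates by max (best-hit semantics)
    if (length(i)) {
      key <- paste(i, j)
      mx <- tapply(s, key, max)
      ij <- do.call(rbind, strsplit(names(mx), " "))
      i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2]); s <- as.numeric(mx)
    }
    mat <- Matrix::sparseMatrix(i = i, j = j, x = s,
                                dims = c(length(lnodes), length(rnodes)),
                                dimnames = list(lnodes, rnodes))
  }
  structure(list(left = lname, right = rname, mat = mat),
            class = "node_sim")
}

#' @export
print.node_sim <- function(x, ...) {
  cat("<node_sim> ", x$left, " x ", x$right, ": ",
      nrow(x$mat), " x ", ncol(x$mat), " nodes, ",
      length(x$mat@x), " stored scores\n", sep = "")
  invisible(x)
}

#' Read a node-similarity file
#'
#' Format: one `u v score` triplet per line (whitespace separated), `#`
#' comments allowed.  Entries naming unknown nodes are dropped with a
#' warning; repeated pairs keep the maximum score.
#'
#' @param path file path.
#' @param left,right the two `ppi_net` objects the scores connect.
#' @return a `node_sim`.
#' @export
read_similarity <- function(path, left, right) {
  if (!file.exists(path)) stop("similarity file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  ntok <- lengths(toks)
  if (any(ntok < 3)) {
    stop("malformed similarity line ", idx[which(ntok < 3)[1]],
         " in ", path, ": expected 'u v score'")
  }
  sc <- suppressWarnings(as.numeric(vapply(toks, `[`, "", 3L)))
  if (anyNA(sc)) {
    stop("non-numeric score on similarity line ", idx[which(is.na(sc))[1]],
         " in ", path)
  }
  if (any(sc < 0)) {
    stop("negative score on similarity line ", idx[which(sc < 0)[1]],
         " in ", path)
  }
  node_similarity(left, right,
                  data.frame(u = vapply(toks, `[`, "", 1L),
                             v = vapply(toks, `[`, "", 2L),
                             s = sc, stringsAsFactors = FALSE))
}

#' Write a node-similarity file
#' @param sim a `node_sim`.
#' @param path output file path.
#' @export
write_similarity <- function(sim, path) {
  tr <- sim_entries(sim)
  tr <- tr[order(tr$u, tr$v, method = "radix"), , drop = FALSE]
  writeLines(paste(tr$u, tr$v, format(tr$score, scientific = FALSE,
                                      trim = TRUE)),
             path)
  invisible(path)
}

#' Stored similarity entries as a triplet data frame
#' @param sim a `node_sim`.
#' @return data frame with columns `u`, `v`, `score` (only stored,
#'   typically non-zero, entries).
#' @export
sim_entries <- function(sim) {
  tr <- Matrix::summary(sim$mat)
  data.frame(u = rownames(sim$mat)[tr$i], v = colnames(sim$mat)[tr$j],
             score = tr$x, stringsAsFactors = FALSE)
}

#' Transpose a node similarity
#' @param sim a `node_sim`.
#' @return the `node_sim` with rows and columns (and direction) swapped.
#' @export
sim_transpose <- function(sim) {
  structure(list(left = sim$right, right = sim$left,
                 mat = Matrix::t(sim$mat)),
            class = "node_sim")
}

#' Look up similarity scores
#' @param sim a `node_sim`.
#' @param u,v node identifiers (vectorised, recycled).
#' @return numeric scores (0 for absent pairs).
#' @export
sim_score <- function(sim, u, v) {
  i <- match(u, rownames(sim$mat)); j <- match(v, colnames(sim$mat))
  if (anyNA(i) || anyNA(j)) stop("unknown node in similarity lookup")
  as.numeric(sim$mat[cbind(i, j)])
}

# ---------------------------------------------------------------------------
# Node mappings

#' Construct a node mapping
#'
#' A partial function from query nodes to target nodes.  Querying may map
#' several query nodes to one target (many-to-one); alignment results are
#' additionally injective.
#'
#' @param query,target character vectors of equal length (the pairs).
#' @param from,to labels of the two networks (direction of the mapping).
#' @return an object of class `node_map`: a data frame with columns
#'   `query` and `target`, pairs sorted by query node, with attributes
#'   `from` and `to`.
#' @export
node_mapping <- function(query = character(), target = character(),
                         from = "left", to = "right") {
  query <- as.character(query); target <- as.character(target)
  stopifnot(length(query) == length(target))
  if (anyDuplicated(query)) {
    stop("duplicate query node in mapping: ",
         query[duplicated(query)][1])
  }
  ord <- order(query, method = "radix")
  structure(data.frame(query = query[ord], target = target[ord],
                       stringsAsFactors = FALSE),
            from = from, to = to,
            class = c("node_map", "data.frame"))
}

#' @export
print.node_map <- function(x, ...) {
  cat("<node_map> ", attr(x, "from"), " -> ", attr(x, "to"), ": ",
      nrow(x), " pairs", if (is_one_to_one(x)) " (one-to-one)", "\n",
      sep = "")
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Is a mapping one-to-one?
#' @param m a `node_map`.
#' @return `TRUE` when no target node is hit twice.
#' @export
is_one_to_one <- function(m) !anyDuplicated(m$target)

#' Look up a mapping as a named vector
#' @param m a `node_map`.
#' @return named character vector `target` indexed by `query`.
#' @export
mapping_lookup <- function(m) setNames(m$target, m$query)

#' Read / write a mapping file
#'
#' Two tab-separated columns, one `query<TAB>target` pair per line, sorted
#' by query node.  Reading validates the partial-function invariant
#' (duplicate query node is an error); pairs naming unknown nodes are
#' dropped with a warning.
#'
#' @param path file path.
#' @param left,right `ppi_net` objects giving the two node sets.
#' @return a `node_map`.
#' @export
read_mapping <- function(path, left, right) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    return(node_mapping(from = left$name, to = right$name))
  }
  toks <- strsplit(lines, "\t|\\s+")
  if (any(lengths(toks) < 2)) stop("malformed mapping line")
  u <- vapply(toks, `[`, "", 1L); v <- vapply(toks, `[`, "", 2L)
  bad <- !(u %in% left$nodes) | !(v %in% right$nodes)
  if (any(bad)) {
    warning(sum(bad), " mapping pair(s) dropped: unknown node(s)")
    u <- u[!bad]; v <- v[!bad]
  }
  node_mapping(u, v, from = left$name, to = right$name)
}

#' @rdname read_mapping
#' @param m a `node_map` to write.
#' @export
write_mapping <- function(m, path) {
  writeLines(paste(m$query, m$target, sep = "\t"), path)
  invisible(path)
}
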