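# Structural and biological evaluation measures for a network alignment.
#
# Structural: matching pairs (MP), edge correctness (EC), edge accumulated
# coverage (EAC(k): EC relaxed to target distance <= k), largest common
# connected subgraph (LCCS).  Biological: shared GO terms (SGO(k)), GO
# coverage at term depth >= 3, hit pathways (HP), pathway average coverage
# (PAC), and known ortholog pairs (OP).

#' Number of matching pairs
#' @param m a `node_map`.
#' @return integer pair count.
#' @export
mp <- function(m) nrow(m)

# conserved query edges: both endpoints matched and image edge present
conserved_edges <- function(G, Gp, m) {
  look <- mapping_lookup(m)
  E <- G$edges
  both <- E[, 1] %in% names(look) & E[, 2] %in% names(look)
  ekey <- paste(Gp$edges[, 1], Gp$edges[, 2], sep = "\r")
  iu <- look[E[both, 1]]; iv <- look[E[both, 2]]
  cons <- paste(pmin(iu, iv), pmax(iu, iv), sep = "\r") %in% ekey &
    iu != iv
  list(both = which(both), conserved = which(both)[cons])
}

ec_denominator <- function(G, Gp, n_matched, denom_mode) {
  switch(denom_mode,
         matched = n_matched,
         all = num_edges(G),
         stop("unknown denominator mode: ", denom_mode))
}

#' Edge correctness (EC)
#'
#' Percentage of query edges conserved under the mapping: both endpoints
#' matched and the image pair is an edge of the target.  The default
#' denominator counts only query edges with both endpoints matched (fair
#' to partial mappings); `denom_mode = "all"` divides by the full edge
#' count of the query network instead (the convention of complete-matching
#' aligners, which take the smaller network as the query).
#'
#' @param G,Gp `ppi_net` objects.
#' @param m a `node_map` from `G` to `Gp`.
#' @param denom_mode `"matched"` or `"all"`.
#' @return percentage in [0, 100] (0 when the denominator is 0).
#' @export
edge_correctness <- function(G, Gp, m, denom_mode = "matched") {
  ce <- conserved_edges(G, Gp, m)
  den <- ec_denominator(G, Gp, length(ce$both), denom_mode)
  if (den == 0) 0 else 100 * length(ce$conserved) / den
}

#' Edge accumulated coverage curve EAC(k)
#'
#' EC relaxed by distance: a query edge counts at level k when both
#' endpoint images lie within distance k in the target (and are distinct).
#' `EAC(1)` equals [edge_correctness()] under the same denominator.
#'
#' @param G,Gp `ppi_net` objects.
#' @param m a `node_map`.
#' @param kmax maximum distance level.
#' @param denom_mode as in [edge_correctness()].
#' @return named numeric vector `EAC(1) .. EAC(kmax)` (percent).
#' @export
eac_curve <- function(G, Gp, m, kmax = 5, denom_mode = "matched") {
  stopifnot(kmax >= 1)
  look <- mapping_lookup(m)
  E <- G$edges
  both <- E[, 1] %in% names(look) & E[, 2] %in% names(look)
  den <- ec_denominator(G, Gp, sum(both), denom_mode)
  out <- setNames(numeric(kmax), paste0("k", seq_len(kmax)))
  if (den == 0 || !any(both)) return(out)
  imgs <- sort(unique(look[c(E[both, 1], E[both, 2])]), method = "radix")
  dm <- igraph::distances(as_igraph(Gp), v = imgs, to = imgs, mode = "all")
  d <- dm[cbind(match(look[E[both, 1]], imgs),
                match(look[E[both, 2]], imgs))]
  for (k in seq_len(kmax)) {
    out[k] <- 100 * sum(is.finite(d) & d >= 1 & d <= k) / den
  }
  out
}

#' Largest common connected subgraph (LCCS)
#'
#' Builds the conserved graph whose vertices are the matched pairs and
#' whose edges are the query edges conserved in both networks, and returns
#' the node and edge counts of its largest connected component (ties:
#' larger edge count, then the component containing the lexicographically
#' smallest query node).
#'
#' @param G,Gp `ppi_net` objects.
#' @param m a `node_map`.
#' @return named integer vector `c(nodes, edges)`; `(1, 0)` when pairs
#'   exist but no edge is conserved, `(0, 0)` for an empty mapping.
#' @export
lccs <- function(G, Gp, m) {
  if (nrow(m) == 0) return(c(nodes = 0L, edges = 0L))
  ce <- conserved_edges(G, Gp, m)
  g <- igraph::make_empty_graph(n = nrow(m), directed = FALSE)
  if (length(ce$conserved)) {
    E <- G$edges[ce$conserved, , drop = FALSE]
    g <- igraph::add_edges(g, t(matrix(match(E, m$query), ncol = 2)))
  }
  comp <- igraph::components(g)
  best <- c(nodes = 0L, edges = 0L); best_anchor <- ""
  for (ci in seq_len(comp$no)) {
    vs <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(g, vs)
    cand <- c(nodes = length(vs), edges = igraph::ecount(sub))
    anchor <- min(m$query[vs])
    if (cand["nodes"] > best["nodes"] ||
        (cand["nodes"] == best["nodes"] && cand["edges"] > best["edges"]) ||
        (all(cand == best) && (best_anchor == "" || anchor < best_anchor))) {
      best <- cand; best_anchor <- anchor
    }
  }
  setNames(as.integer(best), c("nodes", "edges"))
}

# ---------------------------------------------------------------------------
# Biological measures

#' Read a GO annotation table
#'
#' TSV with columns node, GO term id, domain (MF/BP/CC) and term depth;
#' depth is consumed as a precomputed column (ontology parsing is out of
#' scope here).
#'
#' @param path file path.
#' @return data frame with columns `node`, `term`, `domain`, `depth`.
#' @export
read_annotations <- function(path) {
  ann <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("node", "term", "domain", "depth"),
                    stringsAsFactors = FALSE, comment.char = "#")
  if (!all(ann$domain %in% c("MF", "BP", "CC"))) {
    stop("GO domain must be one of MF, BP, CC")
  }
  if (any(ann$depth < 0)) stop("negative GO term depth")
  ann
}

#' Read a pathway membership table
#'
#' TSV with columns pathway id, side (`A` = first network, `B` = second)
#' and node; only pathways defined on both sides are retained (others are
#' dropped with a warning).
#'
#' @param path file path.
#' @return data frame with columns `pathway`, `side`, `node`.
#' @export
read_pathways <- function(path) {
  pdb <- read.table(path, header = FALSE, sep = "\t",
                    col.names = c("pathway", "side", "node"),
                    stringsAsFactors = FALSE, comment.char = "#")
  if (!all(pdb$side %in% c("A", "B"))) stop("pathway side must be A or B")
  ok <- vapply(split(pdb$side, pdb$pathway),
               function(s) all(c("A", "B") %in% s), TRUE)
  bad <- names(ok)[!ok]
  if (length(bad)) {
    warning(length(bad), " pathway(s) not defined on both sides dropped")
    pdb <- pdb[!pdb$pathway %in% bad, , drop = FALSE]
  }
  pdb
}

#' Read a cross-network ortholog pair list
#' @param path TSV file with two columns (node in first network, node in
#'   second network).
#' @return data frame with columns `a`, `b`.
#' @export
read_orthologs <- function(path) {
  read.table(path, header = FALSE, sep = "\t", col.names = c("a", "b"),
             stringsAsFactors = FALSE, comment.char = "#")
}

shared_terms <- function(m, ann) {
  terms <- split(ann$term, ann$node)
  vapply(seq_len(nrow(m)), function(i) {
    length(intersect(terms[[m$query[i]]], terms[[m$target[i]]]))
  }, 0L)
}

#' Shared-GO-term curve SGO(k)
#'
#' Percentage of matched pairs sharing at least k GO terms (all domains
#' pooled), for k = 1..kmax.
#'
#' @param m a `node_map`.
#' @param ann annotation table (see [read_annotations()]) covering nodes of
#'   both networks.
#' @param kmax maximum shared-term count.
#' @return named numeric vector (percent), non-increasing in k.
#' @export
sgo_curve <- function(m, ann, kmax = 5) {
  stopifnot(kmax >= 1)
  out <- setNames(numeric(kmax), paste0("k", seq_len(kmax)))
  if (nrow(m) == 0) return(out)
  sh <- shared_terms(m, ann)
  for (k in seq_len(kmax)) out[k] <- 100 * mean(sh >= k)
  out
}

#' GO coverage at depth >= min_depth
#'
#' Among matched pairs in which both nodes carry at least one term of the
#' given domain at depth >= `min_depth`, the percentage sharing at least
#' one such term.
#'
#' @param m a `node_map`.
#' @param ann annotation table.
#' @param domain one of `"MF"`, `"BP"`, `"CC"`.
#' @param min_depth minimum term depth.
#' @return percentage (0 with a warning when no pair is eligible).
#' @export
go_coverage <- function(m, ann, domain, min_depth = 3) {
  stopifnot(domain %in% c("MF", "BP", "CC"))
  deep <- ann[ann$domain == domain & ann$depth >= min_depth, , drop = FALSE]
  terms <- split(deep$term, deep$node)
  has <- function(v) v %in% names(terms)
  elig <- has(m$query) & has(m$target)
  if (!any(elig)) {
    warning("no matched pair eligible for GO coverage in domain ", domain)
    return(0)
  }
  share <- vapply(which(elig), function(i) {
    length(intersect(terms[[m$query[i]]], terms[[m$target[i]]])) > 0
  }, TRUE)
  100 * mean(share)
}

#' Pathway hit statistics (HP, PAC)
#'
#' A pathway is hit when at least one matched pair lies inside it on both
#' sides; its coverage is `100 * 2 * pairs / (|P_A| + |P_B|)`.  HP is the
#' number of hit pathways and PAC the mean coverage over them (0 when no
#' pathway is hit).
#'
#' @param m a `node_map`.
#' @param pdb pathway table (see [read_pathways()]).
#' @return named vector `c(hp, pac)`.
#' @export
pathway_stats <- function(m, pdb) {
  cov <- numeric(0)
  for (pw in unique(pdb$pathway)) {
    pa <- pdb$node[pdb$pathway == pw & pdb$side == "A"]
    pb <- pdb$node[pdb$pathway == pw & pdb$side == "B"]
    inside <- sum(m$query %in% pa & m$target %in% pb)
    if (inside > 0) {
      cov <- c(cov, 100 * 2 * inside / (length(pa) + length(pb)))
    }
  }
  c(hp = length(cov), pac = if (length(cov)) mean(cov) else 0)
}

#' Known ortholog pairs recovered (OP)
#'
#' Number of matched pairs present in a cross-network ortholog list;
#' direction is respected.
#'
#' @param m a `node_map`.
#' @param orth ortholog table (see [read_orthologs()]).
#' @return integer count.
#' @export
ortholog_pairs <- function(m, orth) {
  sum(paste(m$query, m$target, sep = "\r") %in%
        paste(orth$a, orth$b, sep = "\r"))
}

#' Evaluate an alignment
#'
#' Computes every measure whose inputs are provided; the rest are `NULL`.
#'
#' @param G,Gp `ppi_net` objects.
#' @param m a `node_map` from `G` to `Gp`.
#' @param truth optional `true_alignment` (adds the two accuracies).
#' @param annotations optional annotation table (adds SGO and GO coverage).
#' @param pathways optional pathway table (adds HP and PAC).
#' @param orthologs optional ortholog table (adds OP).
#' @param kmax curve length for EAC and SGO.
#' @param denom_mode EC/EAC denominator mode.
#' @return a list of class `evaluation_report`.
#' @export
evaluate_alignment <- function(G, Gp, m, truth = NULL, annotations = NULL,
                               pathways = NULL, orthologs = NULL,
                               kmax = 5, denom_mode = "matched") {
  lc <- lccs(G, Gp, m)
  rep_ <- list(mp = mp(m),
               ec = edge_correctness(G, Gp, m, denom_mode),
               eac = eac_curve(G, Gp, m, kmax, denom_mode),
               lccs_nodes = lc[["nodes"]], lccs_edges = lc[["edges"]],
               sgo = NULL, go_coverage = NULL, hp = NULL, pac = NULL,
               op = NULL, acc_dup = NULL, acc_all = NULL)
  if (!is.null(annotations)) {
    rep_$sgo <- sgo_curve(m, annotations, kmax)
    rep_$go_coverage <- vapply(c(MF = "MF", BP = "BP", CC = "CC"),
                               function(d)
                                 suppressWarnings(
                                   go_coverage(m, annotations, d)),
                               0)
  }
  if (!is.null(pathways)) {
    ps <- pathway_stats(m, pathways)
    rep_$hp <- unname(ps["hp"]); rep_$pac <- unname(ps["pac"])
  }
  if (!is.null(orthologs)) rep_$op <- ortholog_pairs(m, orthologs)
  if (!is.null(truth)) {
    rep_$acc_dup <- accuracy_dup(m, truth)
    rep_$acc_all <- accuracy_all(m, truth, G)
  }
  structure(rep_, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (nm in names(x)) {
    if (is.null(x[[nm]])) next
    cat("  ", nm, ": ", paste(signif(x[[nm]], 5), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Write / read an evaluation report as TSV
#'
#' Key-value lines; curve entries are flattened as `eac.1`, `sgo.2`, ...
#' The reader reconstructs the numeric fields, so a report round-trips.
#'
#' @param report an `evaluation_report`.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  lines <- character(0)
  for (nm in names(report)) {
    val <- report[[nm]]
    if (is.null(val)) next
    if (length(val) > 1) {
      lines <- c(lines, paste0(nm, ".", seq_along(val), "\t",
                               format(unname(val), digits = 10,
                                      scientific = FALSE, trim = TRUE)))
    } else {
      lines <- c(lines, paste0(nm, "\t", format(unname(val), digits = 10,
                                                scientific = FALSE,
                                                trim = TRUE)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_report
#' @return `read_report` returns the report as an `evaluation_report`.
#' @export
read_report <- function(path) {
  kv <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("key", "value"),
                   stringsAsFactors = FALSE)
  out <- list()
  base_keys <- sub("\\.[0-9]+$", "", kv$key)
  for (bk in unique(base_keys)) {
    vals <- kv$value[base_keys == bk]
    v <- as.numeric(vals)
    if (length(v) > 1) names(v) <- paste0("k", seq_along(v))
    out[[bk]] <- v
  }
  structure(out, class = "evaluation_report")
}
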