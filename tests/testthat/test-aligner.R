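# Iterative bi-directional one-to-one alignment and best-hit baselines.

test_that("one-to-one extraction removes every collision", {
  m <- node_mapping(c("a", "b", "c"), c("x", "x", "y"))
  expect_equal(mapping_lookup(extract_one_to_one(m)), c(c = "y"))
  inj <- node_mapping(c("a", "b"), c("x", "y"))
  expect_equal(extract_one_to_one(inj), inj)
  all_col <- node_mapping(c("a", "b", "c"), c("x", "x", "x"))
  expect_equal(nrow(extract_one_to_one(all_col)), 0)
})

test_that("common pairs are the mutual-best intersections", {
  fwd <- node_mapping(c("a", "b"), c("x", "y"), from = "A", to = "B")
  bwd <- node_mapping(c("x", "y"), c("a", "z"), from = "B", to = "A")
  expect_equal(mapping_lookup(common_pairs(fwd, bwd)), c(a = "x"))
  none <- node_mapping("y", "q", from = "B", to = "A")
  expect_equal(nrow(common_pairs(fwd, none)), 0)
  full <- node_mapping(c("x", "y"), c("a", "b"), from = "B", to = "A")
  expect_equal(nrow(common_pairs(fwd, full)), 2)
  expect_true(is_one_to_one(common_pairs(fwd, full)))
  expect_error(common_pairs(fwd, fwd), "opposite")
})

test_that("fixing a pair clamps its row and column", {
  A <- net_from_text("a b", name = "A"); B <- net_from_text("x y", name = "B")
  s <- node_similarity(A, B, data.frame(u = c("a", "a", "b"),
                                        v = c("x", "y", "x"),
                                        s = c(0.5, 0.4, 0.3)))
  s2 <- fix_and_update(s, node_mapping("a", "x", from = "A", to = "B"),
                       boost = 2)
  expect_equal(sim_score(s2, "a", "x"), 2)
  expect_equal(sim_score(s2, "a", "y"), 0)
  expect_equal(sim_score(s2, "b", "x"), 0)
  expect_equal(fix_and_update(s, node_mapping(from = "A", to = "B"), 2), s)
  expect_error(fix_and_update(s, data.frame(query = c("a", "b"),
                                            target = c("x", "x")), 2),
               "one-to-one")
})

test_that("querying a fully clamped similarity returns the clamp", {
  net <- rand_net(8, 0.35, seed = 5, name = "A", connected = TRUE)
  # isomorphic copy with renamed nodes: the clamped matching is
  # structure-consistent, so querying must reproduce it exactly
  ren <- setNames(sub("^n", "m", net$nodes), net$nodes)
  netB <- network(cbind(ren[net$edges[, 1]], ren[net$edges[, 2]]),
                  nodes = unname(ren), name = "B")
  perm <- node_mapping(net$nodes, unname(ren[net$nodes]),
                       from = "A", to = "B")
  s <- fix_and_update(node_similarity(net, netB), perm, boost = 2)
  m <- net_query(net, netB, s)
  expect_equal(mapping_lookup(m), mapping_lookup(perm))
})

test_that("self-alignment with identity similarity is the identity", {
  tri <- net_from_text("a b\nb c\nc a", name = "tri")
  res <- net_align(tri, tri, identity_sim(tri))
  expect_equal(mapping_lookup(res$mapping), c(a = "a", b = "b", c = "c"))
  expect_equal(res$trace$new_fixed[1], 3)

  s0 <- node_similarity(tri, tri)
  res0 <- net_align(tri, tri, s0)
  expect_equal(nrow(res0$mapping), 0)
  expect_equal(res0$trace$new_fixed, 0)
})

test_that("aligning isomorphic paths under weak noise finds the isomorphism", {
  A <- net_from_text("a1 a2\na2 a3\na3 a4", name = "A")
  B <- net_from_text("b1 b2\nb2 b3\nb3 b4", name = "B")
  iso <- paste0("b", 1:4)
  set.seed(42)
  entries <- data.frame(u = paste0("a", 1:4), v = iso, s = 1)
  noise <- expand.grid(u = A$nodes, v = B$nodes,
                       stringsAsFactors = FALSE)
  noise$s <- round(runif(nrow(noise), 0, 0.2), 3)
  s <- node_similarity(A, B, rbind(entries, noise))
  res <- net_align(A, B, s)
  expect_equal(mapping_lookup(res$mapping),
               setNames(iso, paste0("a", 1:4)))

  # brute-force oracle: the best one-to-one assignment by CRF score
  model <- build_crf(A, B, s, query_params())
  best <- -Inf; best_m <- NULL
  for (perm in combinat_perms(B$nodes)) {
    y <- setNames(perm, A$nodes)
    sc <- labeling_score(model, y)
    if (sc > best) { best <- sc; best_m <- y }
  }
  expect_equal(mapping_lookup(res$mapping), best_m)
})

test_that("alignment output is injective in both directions", {
  for (seed in 1:6) {
    G <- rand_net(10, 0.3, seed = seed, name = "G")
    Gp <- rand_net(9, 0.3, seed = seed + 50, name = "Gp")
    set.seed(seed + 100)
    entries <- data.frame(u = sample(G$nodes, 20, replace = TRUE),
                          v = sample(Gp$nodes, 20, replace = TRUE),
                          s = round(runif(20), 3))
    s <- node_similarity(G, Gp, entries)
    res <- net_align(G, Gp, s)
    expect_false(anyDuplicated(res$mapping$query) > 0)
    expect_false(anyDuplicated(res$mapping$target) > 0)
    expect_true(all(res$trace$new_fixed >= 0))
    expect_equal(res$trace$new_fixed[nrow(res$trace)], 0)
    expect_lte(nrow(res$trace), min(num_nodes(G), num_nodes(Gp)) + 1)
  }
})

test_that("alignment is symmetric under swapping the networks", {
  for (seed in 1:5) {
    G <- rand_net(8, 0.35, seed = seed, name = "G")
    Gp <- rand_net(8, 0.35, seed = seed + 30, name = "Gp")
    set.seed(seed + 60)
    entries <- data.frame(u = sample(G$nodes, 16, replace = TRUE),
                          v = sample(Gp$nodes, 16, replace = TRUE),
                          s = round(runif(16), 3))
    s <- node_similarity(G, Gp, entries)
    ab <- net_align(G, Gp, s)$mapping
    ba <- net_align(Gp, G, sim_transpose(s))$mapping
    tr <- setNames(ba$query, ba$target)
    expect_equal(mapping_lookup(ab), tr[order(names(tr), method = "radix")],
                 info = paste("seed", seed))
  }
})

test_that("fixed pairs persist across rounds", {
  # construct a two-round alignment: an ambiguous pair resolves only
  # after the unambiguous ones are clamped
  G <- net_from_text("a b\nb c", name = "G")
  Gp <- net_from_text("x y\ny z", name = "Gp")
  s <- node_similarity(G, Gp,
                       data.frame(u = c("a", "b", "c", "c"),
                                  v = c("x", "y", "z", "x"),
                                  s = c(1, 1, 0.5, 0.5)))
  res <- net_align(G, Gp, s)
  expect_equal(mapping_lookup(res$mapping), c(a = "x", b = "y", c = "z"))
  # every pair fixed at round r is still present at the end
  expect_true(all(cumsum(res$trace$new_fixed) <= nrow(res$mapping)))
})

test_that("best-hit query maps unique maxima and drops ambiguity", {
  G <- net_from_text("a b\nb c", name = "G")
  Gp <- net_from_text("x y\ny z", name = "Gp")
  s <- node_similarity(G, Gp,
                       data.frame(u = c("a", "a", "b"),
                                  v = c("x", "y", "y"),
                                  s = c(0.9, 0.2, 0.8)))
  expect_equal(mapping_lookup(best_hit_query(G, Gp, s)),
               c(a = "x", b = "y"))
  # all-zero row: unmatched
  expect_false("c" %in% best_hit_query(G, Gp, s)$query)
  # tied best hits are indistinguishable: node left unmatched
  tie <- node_similarity(G, Gp, data.frame(u = "a", v = c("x", "y"),
                                           s = 0.7))
  expect_equal(nrow(best_hit_query(G, Gp, tie)), 0)
  # two query nodes sharing one best hit: both dropped
  share <- node_similarity(G, Gp, data.frame(u = c("a", "b"), v = "x",
                                             s = c(0.9, 0.8)))
  expect_equal(nrow(best_hit_query(G, Gp, share)), 0)
})

test_that("best-hit alignment mirrors the iterative loop", {
  G <- net_from_text("a b\nb c", name = "G")
  Gp <- net_from_text("x y\ny z", name = "Gp")
  # symmetric unambiguous similarity: same result as one-shot best hit
  s <- node_similarity(G, Gp, data.frame(u = c("a", "b", "c"),
                                         v = c("x", "y", "z"),
                                         s = c(0.9, 0.8, 0.7)))
  res <- best_hit_align(G, Gp, s)
  expect_equal(res$mapping, best_hit_query(G, Gp, s))

  # two query nodes with identical rows stay unresolved in every round
  dup <- node_similarity(G, Gp,
                         data.frame(u = c("a", "b", "a", "b", "c"),
                                    v = c("x", "x", "y", "y", "z"),
                                    s = c(0.9, 0.9, 0.9, 0.9, 0.5)))
  resd <- best_hit_align(G, Gp, dup)
  expect_equal(mapping_lookup(resd$mapping), c(c = "z"))

  expect_equal(nrow(best_hit_align(G, Gp,
                                   node_similarity(G, Gp))$mapping), 0)
})
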