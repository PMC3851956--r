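# CRF model construction and MAP inference, validated against exhaustive
# enumeration.

two_nets <- function() {
  list(q = net_from_text("a b", name = "q"),
       t = net_from_text("x y\ny z", name = "t"))
}

test_that("node feature is the floored similarity, gap a constant", {
  nn <- two_nets()
  p <- query_params()
  s <- node_similarity(nn$q, nn$t, data.frame(u = "a", v = "x", s = 0.8))
  expect_equal(node_feature(s, "a", "x", p), 0.8)
  expect_equal(node_feature(s, "a", gap_label(), p), p$gap_score)
  expect_equal(node_feature(s, "b", "x", p), p$floor_eps)
})

test_that("edge compatibility decays with target distance", {
  t <- net_from_text("x y\ny z", name = "t")
  p <- query_params(decay = 0.5, dmax = 2)
  expect_equal(edge_compat(t, "x", "y", p), 1)
  expect_equal(edge_compat(t, "x", "z", p), 0.5)
  expect_equal(edge_compat(t, "x", "x", p), p$floor_eps)
  expect_equal(edge_compat(t, gap_label(), "x", p), 1)
  lonely <- network(cbind("x", "y"), nodes = "far", name = "t2")
  expect_equal(edge_compat(lonely, "x", "far", p), p$floor_eps)
})

test_that("edge feature averages similarities and multiplies W", {
  nn <- two_nets()
  p <- query_params()
  s <- node_similarity(nn$q, nn$t,
                       data.frame(u = c("a", "b"), v = c("x", "y"),
                                  s = c(0.8, 0.6)))
  expect_equal(edge_feature(s, "a", "b", "x", "y", nn$t, p), 0.7)
  expect_equal(edge_feature(s, "a", "b", gap_label(), gap_label(), nn$t, p),
               p$gap_score)
  # unreachable labels floor out even at perfect similarity
  t2 <- network(cbind("x", "w"), nodes = "y", name = "t2")
  s2 <- node_similarity(nn$q, t2, data.frame(u = c("a", "b"),
                                             v = c("x", "y"), s = 1))
  expect_equal(edge_feature(s2, "a", "b", "x", "y", t2, p), p$floor_eps)
})

test_that("label domains keep top_k positive candidates plus gap", {
  nn <- two_nets()
  s <- node_similarity(nn$q, nn$t,
                       data.frame(u = c("a", "a", "a"),
                                  v = c("x", "y", "z"),
                                  s = c(0.9, 0.5, 0.2)))
  model <- build_crf(nn$q, nn$t, s, query_params(top_k = 2))
  expect_equal(model$domains[["a"]], c("x", "y", gap_label()))
  # no positive score: gap-only domain
  expect_equal(model$domains[["b"]], gap_label())
  # equal scores break ties lexicographically
  s2 <- node_similarity(nn$q, nn$t,
                        data.frame(u = c("a", "a"), v = c("y", "x"),
                                   s = c(0.9, 0.9)))
  m2 <- build_crf(nn$q, nn$t, s2, query_params(top_k = 1))
  expect_equal(m2$domains[["a"]], c("x", gap_label()))
  expect_error(build_crf(network(name = "empty"), nn$t, s), "empty query")
})

test_that("labeling score is the sum of log factors", {
  nn <- two_nets()
  p <- query_params()
  s <- node_similarity(nn$q, nn$t,
                       data.frame(u = c("a", "b"), v = c("x", "y"),
                                  s = c(0.8, 0.6)))
  model <- build_crf(nn$q, nn$t, s, p)
  y <- c(a = "x", b = "y")
  # direct product of the three factors, computed by hand
  expect_equal(labeling_score(model, y), log(0.8 * 0.6 * 0.7))
  expect_error(labeling_score(model, c(a = "z", b = "y")), "outside")

  # single-node model: one factor
  q1 <- network(nodes = "a", name = "q1")
  m1 <- build_crf(q1, nn$t, node_similarity(q1, nn$t,
                                            data.frame("a", "x", 0.8)), p)
  expect_equal(labeling_score(m1, c(a = "x")), log(0.8))

  # score differences are independent of any global constant (Z cancels)
  y2 <- c(a = "x", b = gap_label())
  d0 <- labeling_score(model, y) - labeling_score(model, y2)
  shifted <- model
  shifted$node_logpot <- lapply(model$node_logpot, `+`, log(7))
  shifted$edge_logpot <- lapply(model$edge_logpot, `+`, log(7))
  d1 <- labeling_score(shifted, y) - labeling_score(shifted, y2)
  expect_equal(d0, d1)
})

test_that("a constant potential multiplier never changes the MAP labeling", {
  for (seed in 1:20) {
    inst <- rand_instance(seed, forest = FALSE)
    model <- build_crf(inst$query, inst$target, inst$sim, query_params())
    y0 <- map_infer(model)
    scaled <- model
    scaled$node_logpot <- lapply(model$node_logpot, `+`, log(13))
    scaled$edge_logpot <- lapply(model$edge_logpot, `+`, log(13))
    y1 <- map_infer(scaled)
    expect_equal(as.character(y0), as.character(y1),
                 info = paste("seed", seed))
  }
})

test_that("forest MAP inference matches exhaustive enumeration", {
  # one-node query: argmax of the node potential
  t <- net_from_text("x y\ny z", name = "t")
  q1 <- network(nodes = "a", name = "q1")
  s1 <- node_similarity(q1, t, data.frame(u = c("a", "a"), v = c("x", "y"),
                                          s = c(0.3, 0.6)))
  y <- map_infer(build_crf(q1, t, s1, query_params()))
  expect_equal(unname(y["a"]), "y")

  # random small forests against the brute-force oracle
  for (seed in 1:60) {
    inst <- rand_instance(seed, forest = TRUE)
    model <- build_crf(inst$query, inst$target, inst$sim, query_params())
    expect_true(model$forest)
    y <- map_infer(model)
    oracle <- enumerate_best(model)
    expect_equal(attr(y, "score"), oracle$score,
                 info = paste("seed", seed))
  }
})

test_that("loopy BP matches enumeration in the strong-signal regime", {
  checked <- 0
  for (seed in 1:40) {
    inst <- rand_instance(seed, n_query = 4, forest = FALSE)
    model <- build_crf(inst$query, inst$target, inst$sim, query_params())
    if (model$forest) next
    y <- map_infer(model)
    oracle <- enumerate_best(model)
    # equality required when the optimum is clearly separated
    grids <- expand.grid(model$domains, stringsAsFactors = FALSE)
    scores <- apply(grids, 1, function(r)
      labeling_score(model, setNames(as.character(r), model$nodes)))
    top2 <- sort(scores, decreasing = TRUE)[1:2]
    strong <- is.na(top2[2]) ||
      (top2[1] - top2[2]) > 0.01 * abs(oracle$score)
    if (strong) {
      checked <- checked + 1
      expect_equal(attr(y, "score"), oracle$score,
                   info = paste("seed", seed))
    }
  }
  expect_gt(checked, 10)
})

test_that("raising a MAP label's similarity never evicts it", {
  for (seed in 1:25) {
    inst <- rand_instance(seed, forest = TRUE)
    model <- build_crf(inst$query, inst$target, inst$sim, query_params())
    y <- map_infer(model)
    hit <- which(y != gap_label())
    if (length(hit) == 0) next
    v <- names(y)[hit[1]]; lab <- y[[hit[1]]]
    sim2 <- inst$sim
    sim2$mat[v, lab] <- sim2$mat[v, lab] + 0.5
    y2 <- map_infer(build_crf(inst$query, inst$target, sim2,
                              query_params()))
    expect_equal(unname(y2[v]), lab, info = paste("seed", seed))
  }
})

test_that("net_query maps the query into the target deterministically", {
  tri <- net_from_text("a b\nb c\nc a", name = "tri")
  s <- identity_sim(tri)
  m <- net_query(tri, tri, s)
  expect_equal(mapping_lookup(m), c(a = "a", b = "b", c = "c"))
  # repeated runs are identical
  expect_identical(m, net_query(tri, tri, s))

  # all-zero similarity: everything gaps
  s0 <- node_similarity(tri, tri)
  expect_equal(nrow(net_query(tri, tri, s0)), 0)

  # two disconnected query nodes sharing one perfect hit: many-to-one
  q <- network(nodes = c("a", "b"), name = "q")
  t <- network(nodes = "x", name = "t")
  s2 <- node_similarity(q, t, data.frame(u = c("a", "b"), v = "x", s = 1))
  m2 <- net_query(q, t, s2)
  expect_equal(mapping_lookup(m2), c(a = "x", b = "x"))
  expect_false(is_one_to_one(m2))
})
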