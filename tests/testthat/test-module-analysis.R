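module_test_net <- function() {
  edges <- cbind(
    c("L1", "L1", "L2", "a", "b", "c", "L3"),
    c("a",  "b",  "b",  "b", "c", "d", "d")
  )
  kinds <- c("coexpression", "coexpression", "coexpression",
             "subpathway", "subpathway", "subpathway", "coexpression")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::V(g)$type <- ifelse(grepl("^L", igraph::V(g)$name), "lncrna", "pcg")
  igraph::V(g)$is_seed <- igraph::V(g)$name %in% c("a", "d")
  igraph::E(g)$kind <- kinds
  igraph::E(g)$r <- NA_real_
  class(g) <- c("hetero_network", class(g))
  g
}

test_that("module extraction takes co-expression first neighbours with set-union semantics", {
  net <- module_test_net()
  mod <- extract_module(net, c("L1", "L2"), seeds = c("a", "d"))
  expect_setequal(mod$pcgs, c("a", "b"))      # shared neighbour b counted once
  expect_equal(mod$known_disease_pcgs, "a")
  expect_setequal(mod$lncrnas, c("L1", "L2"))
  # order-invariance and idempotence
  mod2 <- extract_module(net, c("L2", "L1"), seeds = c("a", "d"))
  expect_equal(mod$pcgs, mod2$pcgs)
  expect_error(extract_module(net, "L9"), "L9")
  # "all" mode follows subpathway edges too
  mod_all <- extract_module(net, "L2", neighbor_kind = "all")
  expect_setequal(mod_all$pcgs, "b")
})

test_that("module degree test compares module vs complement and guards full cover", {
  net <- module_test_net()
  all_nodes <- igraph::V(net)$name
  expect_error(module_degree_test(net, all_nodes), "complement")
  dt <- module_degree_test(net, c("b", "d"))
  expect_equal(dt$avg_in, mean(igraph::degree(net)[c("b", "d")]))
  expect_gt(dt$p, 0)
})

test_that("a hub module is significantly denser than the periphery", {
  # star-of-stars: hubs dominate every leaf degree
  g <- igraph::make_tree(40, children = 3, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", 1:40)
  hubs <- sprintf("n%02d", 1:8)
  dt <- module_degree_test(g, hubs)
  expect_lt(dt$p, 0.01)
  expect_gt(dt$avg_in, dt$avg_out)
})

test_that("module degree p approximates a brute-force exact rank-sum", {
  set.seed(22)
  for (i in 1:5) {
    g <- random_small_graph(12)
    mod <- sample(igraph::V(g)$name, 5)
    got <- module_degree_test(g, mod)$p
    deg <- igraph::degree(g)
    want <- oracle_ranksum_greater(deg[mod], deg[setdiff(names(deg), mod)])
    # normal approximation with tie correction vs exact enumeration
    expect_lt(abs(got - want), 0.05)
  }
})

test_that("a randomly sampled module yields calibrated degree p-values", {
  set.seed(23)
  g <- random_small_graph(20, p_extra = 0.2)
  ps <- replicate(100, module_degree_test(g, sample(igraph::V(g)$name, 8))$p)
  # uniform-ish: mean near 0.5, substantial spread across both tails
  expect_gt(mean(ps > 0.5), 0.25)
  expect_gt(mean(ps < 0.5), 0.25)
})

test_that("biclustering recovers planted anti-correlated blocks exactly", {
  set.seed(24)
  base <- rnorm(10)
  m <- rbind(
    do.call(rbind, lapply(1:4, function(i) base + rnorm(10, sd = 0.05))),
    do.call(rbind, lapply(1:4, function(i) -base + rnorm(10, sd = 0.05)))
  )
  rownames(m) <- sprintf("f%d", 1:8)
  colnames(m) <- sprintf("s%d", 1:10)
  sm <- bicluster(expr_tbl(m), rownames(m), n_submodules = 2)
  lab <- sm$assignments$submodule
  expect_length(unique(lab[1:4]), 1)
  expect_length(unique(lab[5:8]), 1)
  expect_false(lab[1] == lab[5])
  # single submodule: one label; too many submodules: error
  expect_equal(unique(bicluster(expr_tbl(m), rownames(m), 1)$assignments$submodule), 1L)
  expect_error(bicluster(expr_tbl(m), rownames(m), 9), "exceeds")
})

test_that("cluster assignments ignore row order and affine rescaling of a row", {
  set.seed(25)
  m <- matrix(rnorm(60), 6, 10, dimnames = list(sprintf("f%d", 1:6), sprintf("s%d", 1:10)))
  e1 <- expr_tbl(m)
  sm1 <- bicluster(e1, rownames(m), 2)
  sm2 <- bicluster(e1[sample(6), ], rownames(m), 2)
  expect_equal(sm1$assignments[order(sm1$assignments$feature_id), ],
               sm2$assignments[order(sm2$assignments$feature_id), ])
  m3 <- m; m3[2, ] <- 3 * m3[2, ] + 7   # correlation distance is affine-invariant
  sm3 <- bicluster(expr_tbl(m3), rownames(m), 2)
  expect_equal(sm1$assignments, sm3$assignments)
})

test_that("two clear phenotype blocks split at the top of the sample tree", {
  set.seed(26)
  # 20 features shifted by +/-1 between two groups of four, iid noise
  shift <- rep(c(-1, 1), each = 4)
  m <- t(sapply(1:20, function(i) 8 + sample(c(-1, 1), 1) * shift + rnorm(8, sd = 0.3)))
  rownames(m) <- sprintf("f%02d", 1:20)
  colnames(m) <- c(paste0("ctrl_", 1:4), paste0("case_", 1:4))
  sm <- bicluster(expr_tbl(m), rownames(m), n_submodules = 2)
  top2 <- cutree(sm$sample_tree, k = 2)
  expect_length(unique(top2[1:4]), 1)
  expect_length(unique(top2[5:8]), 1)
  expect_false(top2[1] == top2[5])
})

test_that("module samples sit closer within phenotype than between", {
  # with 4 + 4 samples and coherent module covariation a single sample can
  # defect across the top dendrogram branch, so assert the distance structure
  # rather than an exact 2-cut
  ratios <- sapply(1:5, function(s) {
    d <- synth_dataset(synth_config(rng_seed = s))
    x <- expr_matrix(log2_transform(d$expression))
    feats <- c(d$truth$planted_risk_lncrnas,
               unique(d$truth$planted_coexpr_edges$gene_id))
    z <- t(scale(t(x[feats, ])))
    dm <- as.matrix(dist(t(z)))
    grp <- d$phenotype$group[match(colnames(dm), d$phenotype$sample)]
    same <- outer(grp, grp, "==") & upper.tri(dm)
    diff <- outer(grp, grp, "!=") & upper.tri(dm)
    mean(dm[diff]) / mean(dm[same])
  })
  expect_true(all(ratios > 1))
})
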