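# Key-module extraction around selected lncRNAs, module-vs-rest degree test,
# and bidirectional hierarchical clustering into submodules.

#' Extract the key module around selected lncRNAs
#'
#' The module is the selected lncRNAs plus their first neighbours in the
#' network — by default only neighbours joined through co-expression edges
#' (`neighbor_kind = "coexpression"`); `"all"` also follows subpathway edges.
#' All network edges among module nodes are induced.
#'
#' @param net a `hetero_network`
#' @param selected_lncrnas lncRNA IDs present in the network
#' @param seeds seed gene IDs (to flag known disease genes in the module)
#' @param neighbor_kind which edge kinds define neighbourhood
#' @return a `key_module`: list with `lncrnas`, `pcgs`, `known_disease_pcgs`,
#'   `induced_edges` tibble, and the degree-test fields from
#'   [module_degree_test()]
#' @export
extract_module <- function(net, selected_lncrnas, seeds = character(),
                           neighbor_kind = c("coexpression", "all")) {
  neighbor_kind <- match.arg(neighbor_kind)
  nodes <- igraph::V(net)$name
  absent <- setdiff(selected_lncrnas, nodes)
  if (length(absent) > 0) abort(sprintf("lncRNA not in network: %s", absent[1]))
  selected_lncrnas <- sort(unique(selected_lncrnas))
  g <- net
  if (neighbor_kind == "coexpression") {
    g <- igraph::subgraph_from_edges(net, igraph::E(net)[igraph::E(net)$kind == "coexpression"],
                                     delete.vertices = FALSE)
  }
  nb <- unique(unlist(purrr::map(selected_lncrnas,
                                 ~ igraph::neighbors(g, .x)$name)))
  type <- setNames(igraph::V(net)$type, nodes)
  pcgs <- sort(intersect(nb, names(type)[type == "pcg"]))
  members <- c(selected_lncrnas, pcgs)
  sg <- igraph::induced_subgraph(net, members)
  el <- igraph::as_edgelist(sg)
  induced <- tibble(from = el[, 1], to = el[, 2],
                    kind = igraph::E(sg)$kind)
  dt <- module_degree_test(net, members)
  structure(list(
    lncrnas = selected_lncrnas,
    pcgs = pcgs,
    known_disease_pcgs = sort(intersect(pcgs, seeds)),
    induced_edges = induced,
    avg_degree_module = dt$avg_in,
    avg_degree_rest = dt$avg_out,
    p_degree = dt$p
  ), class = "key_module")
}

#' Test whether module nodes have higher network degree than the rest
#'
#' One-sided Mann-Whitney U test (module degrees greater than non-module
#' degrees); a Welch t-test is available via `method = "t"`.
#'
#' @param net the network whose degrees are compared
#' @param module_nodes node IDs forming the module
#' @param method `"wilcox"` (default) or `"t"`
#' @return list (avg_in, avg_out, p)
#' @export
module_degree_test <- function(net, module_nodes, method = c("wilcox", "t")) {
  method <- match.arg(method)
  deg <- igraph::degree(net)
  stopifnot(all(module_nodes %in% names(deg)))
  din <- deg[module_nodes]
  dout <- deg[setdiff(names(deg), module_nodes)]
  if (length(dout) == 0) abort("module covers the whole network; no complement to test")
  p <- if (method == "wilcox") {
    wilcox.test(din, dout, alternative = "greater", exact = FALSE)$p.value
  } else {
    stats::t.test(din, dout, alternative = "greater")$p.value
  }
  list(avg_in = mean(din), avg_out = mean(dout), p = p)
}

#' Bidirectional hierarchical clustering of module expression
#'
#' Features are clustered with average linkage on correlation distance
#' (1 - Pearson) and the tree is cut into exactly `n_submodules` groups;
#' samples are clustered with average linkage on Euclidean distance of
#' z-scored rows.
#'
#' @param expr log2-scale expression tibble containing the module features
#' @param features module feature IDs (lncRNAs and genes)
#' @param n_submodules number of submodules to cut (default 4)
#' @return a `submodule_set`: list with `assignments` tibble
#'   (feature_id, submodule), `feature_order`, `sample_order`, and the two
#'   hclust trees
#' @export
bicluster <- function(expr, features, n_submodules = 4L) {
  x <- expr_matrix(expr)
  missing <- setdiff(features, rownames(x))
  if (length(missing) > 0) abort(sprintf("module feature absent from expression: %s", missing[1]))
  x <- x[features, , drop = FALSE]
  if (n_submodules > nrow(x)) abort("n_submodules exceeds the number of module features")
  df <- as.dist(1 - cor(t(x)))
  hf <- hclust(df, method = "average")
  labels <- cutree(hf, k = n_submodules)
  z <- t(scale(t(x)))
  z[!is.finite(z)] <- 0
  hs <- hclust(dist(t(z)), method = "average")
  structure(list(
    assignments = tibble(feature_id = names(labels),
                         submodule = as.integer(labels)),
    feature_order = hf$labels[hf$order],
    sample_order = hs$labels[hs$order],
    feature_tree = hf,
    sample_tree = hs
  ), class = "submodule_set")
}
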