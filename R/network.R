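# Heterogeneous lncRNA-gene network: co-expression edge calling, assembly on
# top of the fused subpathway network, randomization test of average degrees,
# and a log-log power-law fit of the degree distribution.

#' Call lncRNA-gene co-expression pairs
#'
#' Pearson correlation over all samples between every DE lncRNA and every DE
#' protein-coding gene; pairs with `r > r_threshold` (signed by default, the
#' literal reading of the calling rule; `use_abs = TRUE` thresholds |r|) are
#' kept. Zero-variance features are skipped with a warning.
#'
#' @param expr log2-scale expression tibble containing all listed features
#' @param de_pcgs,de_lncrnas DE gene / lncRNA IDs
#' @param r_threshold correlation threshold in (0, 1), default 0.8
#' @param use_abs threshold the absolute correlation instead of the signed one
#' @return tibble (lncrna_id, gene_id, r), sorted
#' @export
coexpression_pairs <- function(expr, de_pcgs, de_lncrnas, r_threshold = 0.8,
                               use_abs = FALSE) {
  check_fraction(r_threshold, "r_threshold", open = TRUE)
  x <- expr_matrix(expr)
  missing <- setdiff(c(de_pcgs, de_lncrnas), rownames(x))
  if (length(missing) > 0) {
    abort(sprintf("features absent from expression: %s ...", missing[1]))
  }
  if (ncol(x) < 3) abort("need >= 3 samples for correlation")
  sds <- apply(x[c(de_lncrnas, de_pcgs), , drop = FALSE], 1, sd)
  zv <- names(sds)[sds == 0]
  if (length(zv) > 0) {
    warn(sprintf("skipping %d zero-variance feature(s)", length(zv)))
    de_pcgs <- setdiff(de_pcgs, zv)
    de_lncrnas <- setdiff(de_lncrnas, zv)
  }
  if (length(de_pcgs) == 0 || length(de_lncrnas) == 0) {
    return(tibble(lncrna_id = character(), gene_id = character(), r = numeric()))
  }
  r <- cor(t(x[de_lncrnas, , drop = FALSE]), t(x[de_pcgs, , drop = FALSE]))
  keep <- if (use_abs) abs(r) > r_threshold else r > r_threshold
  idx <- which(keep, arr.ind = TRUE)
  tibble(
    lncrna_id = rownames(r)[idx[, 1]],
    gene_id = colnames(r)[idx[, 2]],
    r = r[idx]
  ) |> arrange(.data$lncrna_id, .data$gene_id)
}

#' Assemble the heterogeneous lncRNA-gene network
#'
#' Starts from the fused subpathway network (gene nodes, subpathway edges) and
#' adds each lncRNA with at least one co-expression partner already present in
#' the network, together with those co-expression edges. lncRNAs whose
#' partners are all absent are not added; no lncRNA-lncRNA or gene-gene
#' co-expression edges are created.
#'
#' @param fused a `fused_network` from [fuse_subpathways()]
#' @param pairs tibble (lncrna_id, gene_id, r) from [coexpression_pairs()]
#' @param seeds known disease gene IDs used to flag seed nodes
#' @return a `hetero_network` igraph with vertex attributes `type`
#'   (`pcg`/`lncrna`) and `is_seed`, and edge attributes `kind`
#'   (`subpathway`/`coexpression`) and `r`
#' @export
assemble_chlpn <- function(fused, pairs, seeds = character()) {
  g <- fused
  class(g) <- setdiff(class(g), "fused_network")
  igraph::E(g)$kind <- "subpathway"
  igraph::E(g)$r <- NA_real_
  in_net <- pairs$gene_id %in% igraph::V(g)$name
  pairs <- pairs[in_net, , drop = FALSE]
  if (nrow(pairs) > 0) {
    lncs <- sort(unique(pairs$lncrna_id))
    g <- igraph::add_vertices(g, length(lncs), name = lncs, type = "lncrna")
    eidx <- rbind(match(pairs$lncrna_id, igraph::V(g)$name),
                  match(pairs$gene_id, igraph::V(g)$name))
    g <- igraph::add_edges(g, as.vector(eidx), kind = "coexpression", r = pairs$r)
  }
  igraph::V(g)$is_seed <- igraph::V(g)$name %in% seeds
  class(g) <- c("hetero_network", class(g))
  g
}

#' Randomization test of average network degrees
#'
#' Rebuilds the heterogeneous network `n_iter` times from random "DE" sets of
#' the observed sizes (the fused subpathway side is held fixed; only the
#' co-expression edges are re-derived) and compares the observed average
#' degree of gene and lncRNA nodes with the null distributions. The empirical
#' p-value is the fraction of iterations whose average degree is at least the
#' observed one; a raw p of 0 is additionally reported floored at
#' `1/(n_iter+1)`.
#'
#' @param expr log2-scale expression tibble (all candidate features)
#' @param fused the fixed fused subpathway network
#' @param de_pcgs,de_lncrnas the observed DE sets
#' @param seeds seed gene IDs (only used to flag nodes)
#' @param n_iter number of randomizations (default 1000)
#' @param r_threshold co-expression threshold
#' @param seed RNG seed
#' @return list with `observed` (avg_degree_pcg, avg_degree_lncrna), `null`
#'   tibble, `p_pcg`, `p_lnc`, raw exceed counts and floored p-values
#' @export
randomization_degree_test <- function(expr, fused, de_pcgs, de_lncrnas,
                                      seeds = character(), n_iter = 1000,
                                      r_threshold = 0.8, seed = 1L) {
  biot <- expr$biotype
  all_pcg <- expr$feature_id[biot == "pcg"]
  all_lnc <- expr$feature_id[biot == "lncrna"]
  if (length(de_pcgs) > length(all_pcg) || length(de_lncrnas) > length(all_lnc)) {
    abort("requested DE set sizes exceed available features")
  }
  avg_degrees <- function(pcgs, lncs) {
    pr <- coexpression_pairs(expr, pcgs, lncs, r_threshold = r_threshold)
    net <- assemble_chlpn(fused, pr)
    deg <- igraph::degree(net)
    type <- igraph::V(net)$type
    c(pcg = mean(deg[type == "pcg"]),
      lnc = if (any(type == "lncrna")) mean(deg[type == "lncrna"]) else 0)
  }
  obs <- avg_degrees(de_pcgs, de_lncrnas)
  null <- withr::with_seed(seed, {
    purrr::map(seq_len(n_iter), function(i) {
      avg_degrees(sample(all_pcg, length(de_pcgs)), sample(all_lnc, length(de_lncrnas)))
    })
  })
  null <- tibble(avg_degree_pcg = purrr::map_dbl(null, "pcg"),
                 avg_degree_lncrna = purrr::map_dbl(null, "lnc"))
  m_pcg <- sum(null$avg_degree_pcg >= obs[["pcg"]])
  m_lnc <- sum(null$avg_degree_lncrna >= obs[["lnc"]])
  list(
    observed = c(avg_degree_pcg = obs[["pcg"]], avg_degree_lncrna = obs[["lnc"]]),
    null = null,
    p_pcg = m_pcg / n_iter,
    p_lnc = m_lnc / n_iter,
    exceed_pcg = m_pcg, exceed_lnc = m_lnc, n_iter = n_iter,
    p_pcg_floored = max(m_pcg / n_iter, 1 / (n_iter + 1)),
    p_lnc_floored = max(m_lnc / n_iter, 1 / (n_iter + 1))
  )
}

#' Power-law fit of a degree distribution
#'
#' Least-squares line on (log10 degree, log10 frequency) over degrees >= 1.
#'
#' @param net an igraph, or a numeric vector of node degrees
#' @return list (slope, r_squared, fit data tibble) of class `powerlaw_fit`
#' @export
powerlaw_fit <- function(net) {
  deg <- if (igraph::is_igraph(net)) igraph::degree(net) else net
  deg <- deg[deg >= 1]
  tab <- table(deg)
  if (length(tab) < 3) abort("need >= 3 distinct degree values for a power-law fit")
  df <- tibble(degree = as.numeric(names(tab)), frequency = as.numeric(tab))
  fit <- lm(log10(frequency) ~ log10(degree), data = df)
  structure(list(
    slope = unname(coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    data = df
  ), class = "powerlaw_fit")
}
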