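# k-clique subpathway mining, hypergeometric enrichment, and fusion of
# significant subpathways into a single gene network.

#' Mine k-clique subpathways from one pathway graph
#'
#' A k-clique subpathway is a maximal gene set whose pairwise shortest-path
#' distances within the pathway are all at most `k`: the maximal cliques of
#' the distance-k closure graph (edge iff finite distance <= k; distances are
#' per connected component, so no cross-component sets arise). Sets smaller
#' than `min_size` are discarded.
#'
#' @param pw undirected igraph with gene-ID vertex names
#' @param k distance threshold (>= 1; the study uses k = 4)
#' @param min_size minimum subpathway size (default 3)
#' @return tibble (members list-column, size, induced_edges list-column of
#'   two-column matrices of the pathway's edges among members)
#' @export
mine_k_clique_subpathways <- function(pw, k = 4, min_size = 3L) {
  stopifnot(k >= 1)
  n <- igraph::vcount(pw)
  if (n == 0) {
    return(tibble(members = list(), size = integer(), induced_edges = list()))
  }
  d <- igraph::distances(pw)
  adj <- d <= k & d > 0
  cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  cls <- igraph::max_cliques(cg, min = min_size)
  members <- purrr::map(cls, ~ sort(names(.x)))
  members <- unique(members)
  induced <- purrr::map(members, function(mm) {
    sg <- igraph::induced_subgraph(pw, mm)
    el <- igraph::as_edgelist(sg)
    if (nrow(el) == 0) return(el)
    # canonical order: smaller endpoint first, rows sorted
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el[order(el[, 1], el[, 2]), , drop = FALSE]
  })
  ord <- order(purrr::map_chr(members, paste, collapse = ";"))
  tibble(
    members = members[ord],
    size = lengths(members[ord]),
    induced_edges = induced[ord]
  )
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of drawing at least the observed overlap with the DE set when
#' `|hit|` genes are drawn without replacement from the background.
#'
#' @param hit_genes gene set being tested (must lie in `background`)
#' @param de_genes differentially expressed gene set
#' @param background sampling frame (e.g. the union of all pathway genes)
#' @return p-value in `[0, 1]`
#' @export
hypergeometric_enrichment <- function(hit_genes, de_genes, background) {
  if (length(background) == 0) abort("empty background")
  if (!all(hit_genes %in% background)) abort("hit genes must be a subset of the background")
  de_in_bg <- intersect(de_genes, background)
  ov <- length(intersect(hit_genes, de_in_bg))
  phyper(ov - 1, length(de_in_bg), length(background) - length(de_in_bg),
         length(hit_genes), lower.tail = FALSE)
}

#' Mine and enrich subpathways across a pathway collection
#'
#' @param pathways a `pathway_collection` (list with named `graphs`)
#' @param de_genes DE gene IDs used for enrichment
#' @param k distance threshold for [mine_k_clique_subpathways()]
#' @param min_size minimum subpathway size
#' @param background enrichment background; default is the union of all genes
#'   in the collection
#' @return tibble (pathway_id, subpathway_id, members, size, de_overlap,
#'   p_hyper, induced_edges)
#' @export
find_subpathways <- function(pathways, de_genes, k = 4, min_size = 3L,
                             background = NULL) {
  graphs <- pathways$graphs
  if (is.null(background)) {
    background <- unique(unlist(purrr::map(graphs, ~ igraph::V(.x)$name)))
  }
  de_genes <- intersect(unique(de_genes), background)
  hits <- purrr::imap(graphs, function(g, pid) {
    h <- mine_k_clique_subpathways(g, k = k, min_size = min_size)
    if (nrow(h) == 0) return(NULL)
    h$pathway_id <- pid
    h
  })
  hits <- bind_rows(hits)
  if (nrow(hits) == 0) {
    return(tibble(pathway_id = character(), subpathway_id = character(),
                  members = list(), size = integer(), de_overlap = integer(),
                  p_hyper = numeric(), induced_edges = list()))
  }
  hits <- hits |>
    group_by(.data$pathway_id) |>
    mutate(subpathway_id = sprintf("%s_sp%02d", .data$pathway_id, dplyr::row_number())) |>
    ungroup()
  hits$de_overlap <- purrr::map_int(hits$members, ~ length(intersect(.x, de_genes)))
  hits$p_hyper <- purrr::map_dbl(hits$members, hypergeometric_enrichment,
                                 de_genes = de_genes, background = background)
  select(hits, "pathway_id", "subpathway_id", "members", "size",
         "de_overlap", "p_hyper", "induced_edges")
}

#' Keep subpathways significant at `alpha`
#'
#' @param hits tibble from [find_subpathways()]
#' @param alpha significance level (default 0.05)
#' @return filtered tibble
#' @export
select_significant <- function(hits, alpha = 0.05) {
  filter(hits, .data$p_hyper < alpha)
}

#' Fuse subpathways into one network by shared genes
#'
#' Nodes are the union of member genes; edges are the union of the
#' subpathways' induced edge sets (no new edges are invented between
#' subpathways — components connect only through shared genes). Each edge
#' records the subpathways that contributed it.
#'
#' @param hits tibble of subpathways with `subpathway_id`, `members`,
#'   `induced_edges`
#' @return a `fused_network` igraph with edge attribute `provenance`
#' @export
fuse_subpathways <- function(hits) {
  if (nrow(hits) == 0) abort("no subpathways to fuse")
  edges <- purrr::map2(hits$induced_edges, hits$subpathway_id, function(el, id) {
    if (is.null(el) || nrow(el) == 0) return(NULL)
    # canonical endpoint order so duplicates collapse regardless of orientation
    tibble(from = pmin(el[, 1], el[, 2]), to = pmax(el[, 1], el[, 2]),
           subpathway_id = id)
  }) |> bind_rows()
  nodes <- sort(unique(unlist(hits$members)))
  if (nrow(edges) > 0) {
    edges <- edges |>
      group_by(.data$from, .data$to) |>
      summarise(provenance = paste(sort(unique(.data$subpathway_id)), collapse = ";"),
                .groups = "drop")
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = tibble(name = nodes))
  igraph::V(g)$type <- "pcg"
  class(g) <- c("fused_network", class(g))
  g
}
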