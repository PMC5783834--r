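# broom-style tidiers for the package's result objects.

#' Tidy a heterogeneous network into an edge tibble
#'
#' @param x a `hetero_network`
#' @param ... unused
#' @return tibble (from, to, kind, r)
#' @export
tidy.hetero_network <- function(x, ...) {
  el <- igraph::as_edgelist(x)
  tibble(from = el[, 1], to = el[, 2],
         kind = igraph::E(x)$kind,
         r = igraph::E(x)$r)
}

#' One-row summary of a heterogeneous network
#'
#' @param x a `hetero_network`
#' @param ... unused
#' @return tibble with node/edge counts by type and kind
#' @export
glance.hetero_network <- function(x, ...) {
  type <- igraph::V(x)$type
  kind <- igraph::E(x)$kind
  tibble(
    n_nodes = igraph::vcount(x),
    n_pcg = sum(type == "pcg"),
    n_lncrna = sum(type == "lncrna"),
    n_edges = igraph::ecount(x),
    n_subpathway_edges = sum(kind == "subpathway"),
    n_coexpression_edges = sum(kind == "coexpression"),
    n_seeds = sum(igraph::V(x)$is_seed %||% FALSE)
  )
}

#' Tidy an RWR result into the per-lncRNA ranking table
#'
#' @param x an `rwr_result`
#' @param ... unused
#' @return tibble (lncrna_id, score, rank, m, n_perm, p_emp)
#' @export
tidy.rwr_result <- function(x, ...) {
  x$lncrna
}

#' One-row summary of an RWR run
#'
#' @param x an `rwr_result`
#' @param alpha threshold used to count significant lncRNAs
#' @param ... unused
#' @export
glance.rwr_result <- function(x, alpha = 0.05, ...) {
  tibble(
    n_lncrna = nrow(x$lncrna),
    n_significant = sum(x$lncrna$p_emp < alpha),
    n_iter = x$n_iter,
    r = x$r,
    epsilon = x$epsilon,
    n_perm = x$n_perm,
    n_seeds = length(x$seeds)
  )
}

#' Tidy a key module into its node table
#'
#' @param x a `key_module`
#' @param ... unused
#' @return tibble (id, role)
#' @export
tidy.key_module <- function(x, ...) {
  bind_rows(
    tibble(id = x$lncrnas, role = "lncrna"),
    tibble(id = x$pcgs,
           role = ifelse(x$pcgs %in% x$known_disease_pcgs, "known_disease_pcg", "pcg"))
  )
}

#' One-row summary of a key module
#' @param x a `key_module`
#' @param ... unused
#' @export
glance.key_module <- function(x, ...) {
  tibble(
    n_lncrna = length(x$lncrnas),
    n_pcg = length(x$pcgs),
    n_known_disease_pcg = length(x$known_disease_pcgs),
    n_edges = nrow(x$induced_edges),
    avg_degree_module = x$avg_degree_module,
    avg_degree_rest = x$avg_degree_rest,
    p_degree = x$p_degree
  )
}

#' Tidy a power-law fit into its degree-frequency table
#' @param x a `powerlaw_fit`
#' @param ... unused
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  x$data
}

#' One-row summary of a power-law fit
#' @param x a `powerlaw_fit`
#' @param ... unused
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(slope = x$slope, r_squared = x$r_squared,
         n_degrees = nrow(x$data))
}

#' Tidy a submodule set into its assignment table
#' @param x a `submodule_set`
#' @param ... unused
#' @export
tidy.submodule_set <- function(x, ...) {
  x$assignments
}
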