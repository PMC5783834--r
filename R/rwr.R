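# Random walk with restart from disease seed genes, with empirical lncRNA
# significance from a degree-preserving seed permutation null.

#' Column-normalized adjacency operator of a network
#'
#' Each column of the adjacency matrix is divided by the node's degree so
#' every column sums to one; an isolated node gets a unit self-loop column to
#' keep the operator column-stochastic.
#'
#' @param net an igraph
#' @return sparse column-stochastic matrix with node names as dimnames
#' @export
column_normalize <- function(net) {
  if (igraph::vcount(net) == 0) abort("empty network")
  a <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  cs <- Matrix::colSums(a)
  iso <- cs == 0
  if (any(iso)) {
    ii <- which(iso)
    a <- a + Matrix::sparseMatrix(i = ii, j = ii, x = 1, dims = dim(a),
                                  dimnames = dimnames(a))
    cs[iso] <- 1
  }
  w <- a %*% Matrix::Diagonal(x = 1 / cs)
  dimnames(w) <- list(igraph::V(net)$name, igraph::V(net)$name)
  w
}

# Normalized restart vector: equal mass on every seed.
restart_vector <- function(w, seeds) {
  nodes <- rownames(w)
  if (length(seeds) == 0) abort("at least one seed node is required")
  if (!all(seeds %in% nodes)) {
    abort(sprintf("seed not in network: %s", setdiff(seeds, nodes)[1]))
  }
  p0 <- numeric(length(nodes))
  names(p0) <- nodes
  p0[seeds] <- 1 / length(seeds)
  p0
}

#' Iterative random walk with restart
#'
#' Iterates `p_{t+1} = (1 - r) W p_t + r p_0` from the normalized seed vector
#' until the L1 change falls below `epsilon`. With a column-stochastic `W` and
#' normalized `p_0` the iterate remains a probability vector, and the L1
#' residual contracts by at least `(1 - r)` per step.
#'
#' @param w column-stochastic operator from [column_normalize()]
#' @param seeds seed node IDs (equal initial mass)
#' @param r restart probability in (0, 1); default 0.7, the usual choice in
#'   network-propagation gene prioritization
#' @param epsilon L1 convergence threshold (default 1e-10)
#' @param max_iter iteration cap
#' @return list (p_steady named vector, n_iter, residual)
#' @export
rwr_iterate <- function(w, seeds, r = 0.7, epsilon = 1e-10, max_iter = 10000L) {
  check_fraction(r, "r", open = TRUE)
  stopifnot(epsilon > 0)
  p0 <- restart_vector(w, seeds)
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - r) * (w %*% p)) + r * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < epsilon) {
      names(p) <- rownames(w)
      return(list(p_steady = p, n_iter = it, residual = delta))
    }
  }
  abort(sprintf("random walk did not converge in %d iterations (last change %.3e)",
                max_iter, delta))
}

#' Exact steady state of the random walk with restart
#'
#' Direct dense solve of `(I - (1 - r) W) p = r p_0`; intended as an
#' independent check of [rwr_iterate()] on networks small enough to solve
#' densely.
#'
#' @inheritParams rwr_iterate
#' @return named steady-state probability vector
#' @export
rwr_exact <- function(w, seeds, r = 0.7) {
  check_fraction(r, "r", open = TRUE)
  n <- nrow(w)
  if (n > 5000) abort("network too large for a dense solve (> 5000 nodes)")
  p0 <- restart_vector(w, seeds)
  a <- diag(n) - (1 - r) * as.matrix(w)
  p <- solve(a, r * p0)
  setNames(as.numeric(p), rownames(w))
}

# Degree-preserving sample of pseudo-seeds: for each seed, draw an unused
# candidate of equal degree, widening the tolerance (10% of degree, then
# doubling) when a bin has no eligible candidate left.
sample_degree_matched <- function(cand_deg, seed_deg) {
  chosen <- character(0)
  widened <- FALSE
  for (d in sort(seed_deg, decreasing = TRUE)) {
    avail <- setdiff(names(cand_deg), chosen)
    tol <- 0
    repeat {
      ok <- avail[abs(cand_deg[avail] - d) <= tol]
      if (length(ok) > 0) break
      widened <- TRUE
      tol <- if (tol == 0) max(1, ceiling(0.1 * d)) else tol * 2
      if (tol > max(cand_deg) + d) abort("no eligible degree-matched candidates")
    }
    chosen <- c(chosen, if (length(ok) == 1) ok else sample(ok, 1))
  }
  attr(chosen, "widened") <- widened
  chosen
}

#' RWR lncRNA prioritization with degree-preserving permutation significance
#'
#' Runs the walk from the real seeds, then `n_perm` times from pseudo-seed
#' sets sampled without replacement from the non-seed protein-coding nodes
#' with the same degree distribution as the real seeds (exact degree bins,
#' widened when empty). For lncRNA i, `m_i` counts permutations whose score
#' strictly exceeds the real score, and `p_emp = m_i / n_perm`.
#'
#' @param net a `hetero_network` with vertex `type` attributes
#' @param seeds seed gene IDs present in the network
#' @param n_perm number of permutations (default 5000)
#' @param r,epsilon,max_iter walk parameters, see [rwr_iterate()]
#' @param seed RNG seed for the permutation draws
#' @param p_floor if `TRUE`, report zero p-values as `1/(n_perm+1)` instead of 0
#' @return an `rwr_result`: list with `lncrna` tibble (lncrna_id, score,
#'   rank, m, n_perm, p_emp), full `p_steady`, `n_iter`, and the walk
#'   parameters
#' @export
permutation_significance <- function(net, seeds, n_perm = 5000, r = 0.7,
                                     epsilon = 1e-10, max_iter = 10000L,
                                     seed = 1L, p_floor = FALSE) {
  w <- column_normalize(net)
  type <- setNames(igraph::V(net)$type, igraph::V(net)$name)
  seeds <- intersect(seeds, rownames(w))
  if (length(seeds) == 0) abort("no seeds present in the network")
  real <- rwr_iterate(w, seeds, r = r, epsilon = epsilon, max_iter = max_iter)
  lnc <- names(type)[type == "lncrna"]
  real_scores <- real$p_steady[lnc]

  deg <- igraph::degree(net)
  cand <- deg[type == "pcg" & !(names(type) %in% seeds)]
  if (length(cand) < length(seeds)) abort("not enough non-seed gene nodes to permute")
  m <- integer(length(lnc))
  any_widened <- FALSE
  withr::with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pseudo <- sample_degree_matched(cand, deg[seeds])
      any_widened <- any_widened || isTRUE(attr(pseudo, "widened"))
      perm <- rwr_iterate(w, pseudo, r = r, epsilon = epsilon, max_iter = max_iter)
      m <- m + (perm$p_steady[lnc] > real_scores)
    }
  })
  if (any_widened) {
    warn("some degree bins had no exact-degree candidates; tolerance was widened")
  }
  p_emp <- m / n_perm
  if (p_floor) p_emp <- pmax(p_emp, 1 / (n_perm + 1))
  res <- tibble(lncrna_id = lnc, score = unname(real_scores),
                m = unname(m), n_perm = n_perm, p_emp = unname(p_emp)) |>
    arrange(dplyr::desc(.data$score), .data$lncrna_id) |>
    mutate(rank = dplyr::row_number(), .after = "score")
  structure(list(
    lncrna = res, p_steady = real$p_steady, n_iter = real$n_iter,
    r = r, epsilon = epsilon, n_perm = n_perm, seeds = seeds, seed = seed
  ), class = "rwr_result")
}

#' Select significant, top-ranked lncRNAs
#'
#' The selection is the intersection of the significant set
#' (`p_emp < alpha`) with the top `top_n` score ranks; score ties are broken
#' by ID for determinism.
#'
#' @param res an `rwr_result`
#' @param alpha empirical p-value threshold (default 0.05)
#' @param top_n rank cut-off (default 20)
#' @return character vector of selected lncRNA IDs, in rank order
#' @export
rank_and_select <- function(res, alpha = 0.05, top_n = 20) {
  tab <- res$lncrna
  tab$lncrna_id[tab$p_emp < alpha & tab$rank <= top_n]
}

#' Compare scores of significant vs non-significant lncRNAs
#'
#' One-sided Wilcoxon rank-sum test that significant lncRNAs score higher.
#'
#' @param res an `rwr_result`
#' @param alpha significance threshold defining the two groups
#' @return list (p_value, n_significant, n_other)
#' @export
score_separation_test <- function(res, alpha = 0.05) {
  tab <- res$lncrna
  sig <- tab$score[tab$p_emp < alpha]
  oth <- tab$score[tab$p_emp >= alpha]
  if (length(sig) == 0 || length(oth) == 0) {
    return(list(p_value = NA_real_, n_significant = length(sig), n_other = length(oth)))
  }
  # exact rank-sum p when sample sizes permit and there are no ties
  wt <- suppressWarnings(wilcox.test(sig, oth, alternative = "greater"))
  list(p_value = wt$p.value, n_significant = length(sig), n_other = length(oth))
}
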