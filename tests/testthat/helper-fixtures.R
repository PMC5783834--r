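# Shared fixture builders and independent brute-force oracles.

# Small expression tibble from a matrix, on the log2 scale.
expr_tbl <- function(m, biotype = NULL, log2 = TRUE) {
  out <- dplyr::bind_cols(
    tibble::tibble(feature_id = rownames(m)),
    if (!is.null(biotype)) tibble::tibble(biotype = biotype),
    tibble::as_tibble(m)
  )
  attr(out, "log2") <- log2
  out
}

# Minimal probe match table built from a compact spec:
# hits is a data frame (probe, gene, biotype, perfect).
probe_table <- function(hits, probe_len = 25L) {
  tx <- unique(hits[, c("gene", "biotype")])
  aln <- tibble::tibble(
    qseqid = hits$probe,
    sseqid = paste0("TX_", hits$gene),
    pident = ifelse(hits$perfect, 100, 96),
    length = probe_len,
    mismatch = ifelse(hits$perfect, 0L, 1L),
    gapopen = 0L, qstart = 1L, qend = probe_len,
    sstart = 1L, send = probe_len, evalue = 1e-10, bitscore = 50
  )
  structure(list(
    alignments = aln,
    biotypes = tibble::tibble(transcript_id = paste0("TX_", tx$gene),
                              gene_id = tx$gene, biotype = tx$biotype),
    probe_lengths = tibble::tibble(probe_id = unique(hits$probe), probe_len = probe_len)
  ), class = "probe_match_table")
}

# A clean probe table: n perfect probes for each of the given genes.
clean_probe_table <- function(genes, biotypes, n_probes = 3L) {
  hits <- data.frame(
    probe = sprintf("p_%s_%d", rep(genes, each = n_probes), seq_len(n_probes)),
    gene = rep(genes, each = n_probes),
    biotype = rep(biotypes, each = n_probes),
    perfect = TRUE
  )
  probe_table(hits)
}

# Random connected undirected igraph with vertex names a, b, c, ...
random_small_graph <- function(n, p_extra = 0.3) {
  nodes <- letters[seq_len(n)]
  ord <- sample(nodes)
  el <- cbind(ord[-1], ord[vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- extra[stats::runif(nrow(extra)) < p_extra, , drop = FALSE]
  if (nrow(pick) > 0) {
    g <- igraph::add_edges(g, as.vector(t(cbind(nodes[pick[, 1]], nodes[pick[, 2]]))))
  }
  igraph::simplify(g)
}

# Brute-force oracle: all maximal vertex subsets of size >= min_size whose
# pairwise shortest-path distances are <= k. Enumerates every one of the 2^n
# subsets as a bitmask (vectorized over subsets; independent of any clique
# algorithm).
oracle_k_clique <- function(g, k, min_size = 3L) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  stopifnot(n <= 20)
  d <- igraph::distances(g)
  bit <- bitwShiftL(1L, 0:(n - 1))
  # closure neighbourhood masks (within distance k), including self
  nbr <- vapply(seq_len(n), function(v) {
    sum(bit[d[v, ] <= k & d[v, ] > 0]) + bit[v]
  }, numeric(1))
  s <- seq_len(2^n - 1)
  valid <- rep(TRUE, length(s))     # every member sees the whole subset
  extend <- rep(FALSE, length(s))   # some outside vertex sees the whole subset
  for (v in seq_len(n)) {
    member <- bitwAnd(s, bit[v]) > 0
    sees_all <- bitwAnd(s, nbr[v]) == s
    valid <- valid & (!member | sees_all)
    extend <- extend | (!member & sees_all)
  }
  sizes <- rowSums(outer(s, bit, function(a, b) bitwAnd(a, b) > 0))
  keep <- which(valid & !extend & sizes >= min_size)
  lapply(keep, function(code) sort(nodes[bitwAnd(code, bit) > 0]))
}

# Exhaustive hypergeometric oracle: enumerate all draws of |hit| from the
# background and count those with overlap >= observed.
oracle_hypergeom <- function(hit_genes, de_genes, background) {
  ov <- length(intersect(hit_genes, de_genes))
  draws <- utils::combn(background, length(hit_genes))
  mean(apply(draws, 2, function(s) length(intersect(s, de_genes)) >= ov))
}

# Exact one-sided rank-sum p-value by enumerating all group assignments.
oracle_ranksum_greater <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  obs <- sum(rank(all_v)[seq_len(n)])
  splits <- utils::combn(length(all_v), n)
  stats <- apply(splits, 2, function(idx) sum(rank(all_v)[idx]))
  mean(stats >= obs)
}
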