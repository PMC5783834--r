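# Synthetic two-phenotype microarray study generator.
#
# Emulates the statistical structure the downstream analysis assumes: two
# groups of n samples on the log2 scale, planted fold changes, planted
# lncRNA-gene co-expression through shared latent factors, overlapping pathway
# graphs seeded with differentially expressed and disease genes, probe-to-
# transcript alignment records with known filter-rule violations, and miRNA
# interaction tables with planted ceRNA pairs.

#' Configuration for the synthetic study generator
#'
#' Defaults are the study conditions used throughout the package: a 4 vs 4
#' two-group microarray design, a planted log2 fold change of 2, residual
#' noise of 1 on the log2 scale, planted differential expression in one in
#' eight genes, and planted lncRNA-gene co-expression modules whose pairs
#' target an overall Pearson correlation of 0.95, well above the 0.8
#' co-expression calling threshold at eight samples.
#'
#' @param n_pcg number of protein-coding genes (PCGs)
#' @param n_lncrna number of lncRNAs
#' @param n_samples_per_group samples per phenotype group (study design = 4)
#' @param n_pathways number of pathway graphs
#' @param pathway_size_range length-2 integer range of pathway sizes (min >= 5)
#' @param frac_shared_genes fraction of a pathway's genes shared with the
#'   previous pathway of its overlap group, in `[0,1]`
#' @param frac_pathway_planted fraction of a pathway's fresh slots drawn from
#'   the planted DE/seed gene pool while it lasts; the remainder are
#'   background genes, so enriched pathways carry background dilution as real
#'   pathways do
#' @param n_seed_genes number of known disease (seed) PCGs
#' @param n_planted_risk_lncrna number of planted risk lncRNAs (must not
#'   exceed `n_de_lncrna`)
#' @param n_planted_modules number of planted co-expression modules; risk
#'   lncRNAs are split across modules and each module's lncRNAs and partner
#'   genes share one latent factor, mimicking a co-regulated disease block
#' @param n_de_pcg,n_de_lncrna numbers of planted differentially expressed
#'   PCGs and lncRNAs
#' @param n_coexpr_partners planted co-expressed partner genes per module
#'   (every lncRNA of the module correlates with all of them; partners are
#'   seed genes, so planted risk lncRNAs sit next to disease genes)
#' @param de_log2fc planted case-minus-control difference in log2 units
#' @param noise_sd residual standard deviation on the log2 scale (> 0)
#' @param coexpr_rho target overall Pearson correlation of a planted
#'   lncRNA-gene pair, in (0,1) and above the 0.8 calling threshold
#' @param n_probes_per_transcript perfect probes per clean transcript (>= 3)
#' @param probe_noise_sd per-probe log2 noise around the feature value
#' @param n_imperfect_probes,n_cross_biotype_probes,n_multi_target_probes
#'   numbers of injected probe-level violations of filter rules 1-3
#' @param n_low_probe_features number of injected features with only two
#'   perfect probes (rule-4 violations)
#' @param n_mirna number of decoy miRNAs in the interaction tables
#' @param rng_seed integer seed; all generator randomness derives from it
#' @return a `synth_config` list, validated
#' @export
synth_config <- function(n_pcg = 800, n_lncrna = 100, n_samples_per_group = 4,
                         n_pathways = 30, pathway_size_range = c(12L, 24L),
                         frac_shared_genes = 0.1, frac_pathway_planted = 0.75,
                         n_seed_genes = 20,
                         n_planted_risk_lncrna = 6, n_planted_modules = 2,
                         n_de_pcg = 100,
                         n_de_lncrna = 20, n_coexpr_partners = 9,
                         de_log2fc = 2, noise_sd = 1, coexpr_rho = 0.95,
                         n_probes_per_transcript = 4, probe_noise_sd = 0.05,
                         n_imperfect_probes = 5, n_cross_biotype_probes = 5,
                         n_multi_target_probes = 4, n_low_probe_features = 3,
                         n_mirna = 40, rng_seed = 1L) {
  cfg <- list(
    n_pcg = check_count(n_pcg, "n_pcg"),
    n_lncrna = check_count(n_lncrna, "n_lncrna"),
    n_samples_per_group = check_count(n_samples_per_group, "n_samples_per_group", min = 2L),
    n_pathways = check_count(n_pathways, "n_pathways"),
    pathway_size_range = c(check_count(pathway_size_range[1], "pathway_size_range", min = 5L),
                           check_count(pathway_size_range[2], "pathway_size_range", min = 5L)),
    frac_shared_genes = check_fraction(frac_shared_genes, "frac_shared_genes"),
    frac_pathway_planted = check_fraction(frac_pathway_planted, "frac_pathway_planted"),
    n_seed_genes = check_count(n_seed_genes, "n_seed_genes"),
    n_planted_risk_lncrna = check_count(n_planted_risk_lncrna, "n_planted_risk_lncrna", min = 0L),
    n_planted_modules = check_count(n_planted_modules, "n_planted_modules", min = 0L),
    n_de_pcg = check_count(n_de_pcg, "n_de_pcg", min = 0L),
    n_de_lncrna = check_count(n_de_lncrna, "n_de_lncrna", min = 0L),
    n_coexpr_partners = check_count(n_coexpr_partners, "n_coexpr_partners"),
    de_log2fc = as.numeric(de_log2fc),
    noise_sd = check_fraction(noise_sd, "noise_sd", lo = 0, hi = Inf, open = TRUE),
    coexpr_rho = check_fraction(coexpr_rho, "coexpr_rho", open = TRUE),
    n_probes_per_transcript = check_count(n_probes_per_transcript, "n_probes_per_transcript", min = 3L),
    probe_noise_sd = check_fraction(probe_noise_sd, "probe_noise_sd", lo = 0, hi = Inf),
    n_imperfect_probes = check_count(n_imperfect_probes, "n_imperfect_probes", min = 0L),
    n_cross_biotype_probes = check_count(n_cross_biotype_probes, "n_cross_biotype_probes", min = 0L),
    n_multi_target_probes = check_count(n_multi_target_probes, "n_multi_target_probes", min = 0L),
    n_low_probe_features = check_count(n_low_probe_features, "n_low_probe_features", min = 0L),
    n_mirna = check_count(n_mirna, "n_mirna", min = 0L),
    rng_seed = check_count(rng_seed, "rng_seed", min = 0L)
  )
  if (cfg$pathway_size_range[1] > cfg$pathway_size_range[2]) {
    abort("config field 'pathway_size_range' must be non-decreasing")
  }
  if (cfg$pathway_size_range[2] > cfg$n_pcg) {
    abort("config field 'pathway_size_range' exceeds n_pcg: pathways cannot be filled")
  }
  if (cfg$n_de_pcg > cfg$n_pcg) abort("config field 'n_de_pcg' exceeds n_pcg")
  if (cfg$n_de_lncrna > cfg$n_lncrna) abort("config field 'n_de_lncrna' exceeds n_lncrna")
  if (cfg$n_planted_risk_lncrna > cfg$n_de_lncrna) {
    abort("config field 'n_planted_risk_lncrna' exceeds n_de_lncrna")
  }
  if (cfg$n_seed_genes > cfg$n_pcg) abort("config field 'n_seed_genes' exceeds n_pcg")
  if (cfg$n_planted_risk_lncrna > 0 && cfg$n_planted_modules == 0) {
    abort("config field 'n_planted_modules' must be positive when risk lncRNAs are planted")
  }
  if (cfg$n_planted_modules > max(cfg$n_planted_risk_lncrna, 1L)) {
    abort("config field 'n_planted_modules' exceeds n_planted_risk_lncrna")
  }
  n_partner <- cfg$n_planted_modules * cfg$n_coexpr_partners
  if (n_partner > cfg$n_seed_genes) {
    abort("config field 'n_seed_genes' too small for n_planted_modules * n_coexpr_partners")
  }
  if (n_partner > cfg$n_de_pcg) {
    abort("config field 'n_de_pcg' too small for n_planted_modules * n_coexpr_partners")
  }
  structure(cfg, class = "synth_config")
}

# Within-group latent-factor correlation needed so that the OVERALL two-group
# Pearson correlation of a planted pair equals rho. With group half-difference
# d = de_log2fc/2 and residual sd sigma, overall covariance is
# rho_w*sigma^2 + d^2 over variance sigma^2 + d^2; solve for rho_w and clip
# at 0 when the shared group effect alone already exceeds the target.
within_group_rho <- function(rho, de_log2fc, noise_sd) {
  d2 <- (de_log2fc / 2)^2
  s2 <- noise_sd^2
  rw <- (rho * (s2 + d2) - d2) / s2
  if (rw < 0) {
    inform("planted group effect alone exceeds coexpr_rho; using independent residuals")
    rw <- 0
  }
  min(rw, 1)
}

#' Generate the synthetic expression matrix and ground truth
#'
#' Non-planted rows are i.i.d. Gaussian noise around a per-row baseline drawn
#' once from N(8, 1) on the log2 scale; planted DE rows differ between groups
#' by `de_log2fc` log2 units; each planted risk lncRNA shares a latent factor
#' with its partner genes so the pair's overall Pearson correlation targets
#' `coexpr_rho`. Values are returned on the raw (linear) intensity scale, as a
#' scanner would deliver them; apply [log2_transform()] before analysis.
#'
#' @param cfg a [synth_config()]
#' @return list with `expression` (tibble: feature_id, biotype, one column per
#'   sample; raw scale), `phenotype` (tibble: sample, group) and `truth`
#'   (`synth_truth` list of planted ID sets and pair tables)
#' @export
synth_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(derive_seed(cfg$rng_seed, 0L), synth_expression_impl(cfg))
}

synth_expression_impl <- function(cfg) {
  pcg_ids <- sprintf("PCG%04d", seq_len(cfg$n_pcg))
  lnc_ids <- sprintf("LNC%03d", seq_len(cfg$n_lncrna))
  n_per <- cfg$n_samples_per_group
  samples <- c(sprintf("ctrl_%d", seq_len(n_per)), sprintf("case_%d", seq_len(n_per)))
  group <- rep(c("control", "case"), each = n_per)

  de_pcgs <- sort(sample(pcg_ids, cfg$n_de_pcg))
  de_lncs <- sort(sample(lnc_ids, cfg$n_de_lncrna))
  risk_lncs <- de_lncs[seq_len(cfg$n_planted_risk_lncrna)]

  # planted co-expression modules: risk lncRNAs split across modules, each
  # module backed by a disjoint group of seed partner genes (all DE)
  n_mod <- if (cfg$n_planted_risk_lncrna > 0) cfg$n_planted_modules else 0L
  n_partner <- n_mod * cfg$n_coexpr_partners
  partner_pool <- sample(de_pcgs, n_partner)
  mod_genes <- if (n_mod > 0) {
    split(partner_pool, rep(seq_len(n_mod), each = cfg$n_coexpr_partners))
  } else list()
  mod_of_lnc <- if (n_mod > 0) {
    sort(rep_len(seq_len(n_mod), length(risk_lncs)))
  } else integer(0)
  extra_seeds <- sample(setdiff(pcg_ids, de_pcgs), cfg$n_seed_genes - n_partner)
  seed_genes <- sort(c(partner_pool, extra_seeds))

  feat <- c(pcg_ids, lnc_ids)
  biotype <- rep(c("pcg", "lncrna"), c(cfg$n_pcg, cfg$n_lncrna))
  n_feat <- length(feat)
  n_samp <- length(samples)

  mu <- rnorm(n_feat, mean = 8, sd = 1)
  de_set <- c(de_pcgs, de_lncs)
  sign_de <- setNames(sample(c(-1, 1), length(de_set), replace = TRUE), de_set)
  # a module's lncRNAs and partner genes share the DE direction so a
  # positive planted correlation is attainable
  for (j in seq_len(n_mod)) {
    s <- sample(c(-1, 1), 1)
    sign_de[risk_lncs[mod_of_lnc == j]] <- s
    sign_de[mod_genes[[j]]] <- s
  }

  delta <- matrix(0, n_feat, n_samp, dimnames = list(feat, samples))
  half <- cfg$de_log2fc / 2
  shift <- rep(c(-half, half), each = n_per)
  for (f in de_set) delta[f, ] <- sign_de[[f]] * shift

  rw <- within_group_rho(cfg$coexpr_rho, cfg$de_log2fc, cfg$noise_sd)
  eps <- matrix(rnorm(n_feat * n_samp), n_feat, n_samp, dimnames = list(feat, samples))
  resid <- eps
  grp_idx <- rep(seq_len(2), each = n_per)
  for (j in seq_len(n_mod)) {
    members <- c(risk_lncs[mod_of_lnc == j], mod_genes[[j]])
    f_lat <- rnorm(n_samp)
    # centre the factor within each group so shared covariation cannot move
    # the realized fold change of a whole module at once, and rescale to
    # unit per-sample variance
    f_lat <- (f_lat - ave(f_lat, grp_idx)) / sqrt(1 - 1 / n_per)
    resid[members, ] <- sqrt(rw) * matrix(f_lat, length(members), n_samp, byrow = TRUE) +
      sqrt(1 - rw) * eps[members, , drop = FALSE]
  }
  x_log2 <- mu + delta + cfg$noise_sd * resid

  coexpr_edges <- purrr::map2(risk_lncs, mod_of_lnc, function(l, j) {
    tibble(lncrna_id = l, gene_id = mod_genes[[j]])
  }) |> bind_rows()
  if (nrow(coexpr_edges) == 0) {
    coexpr_edges <- tibble(lncrna_id = character(), gene_id = character())
  }
  # one planted ceRNA pair per risk lncRNA, with a distinct module gene
  cerna_gene <- purrr::imap_chr(mod_of_lnc, function(j, i) {
    within <- sum(mod_of_lnc[seq_len(i)] == j)
    mod_genes[[j]][(within - 1) %% length(mod_genes[[j]]) + 1]
  })
  cerna_pairs <- tibble(
    lncrna_id = risk_lncs,
    gene_id = cerna_gene,
    mirna_id = sprintf("mmu-miR-P%02d", seq_along(risk_lncs))
  )

  truth <- structure(list(
    planted_de_pcgs = de_pcgs,
    planted_de_lncrnas = de_lncs,
    planted_risk_lncrnas = risk_lncs,
    seed_genes = seed_genes,
    planted_coexpr_edges = coexpr_edges,
    planted_cerna_pairs = cerna_pairs,
    de_signs = sign_de
  ), class = "synth_truth")

  expression <- bind_cols(
    tibble(feature_id = feat, biotype = biotype),
    as_tibble(2^x_log2)
  )
  attr(expression, "log2") <- FALSE
  list(
    expression = expression,
    phenotype = tibble(sample = samples, group = group),
    truth = truth
  )
}

#' Generate overlapping connected pathway graphs
#'
#' Pathways are random connected labelled graphs (random spanning tree plus
#' extra edges). Planted DE PCGs and seed genes fill pathways first so that
#' subpathway enrichment of the planted signal can succeed; pathways within an
#' overlap group share `frac_shared_genes` of their members with the previous
#' pathway of the group.
#'
#' @param cfg a [synth_config()]
#' @param truth the `synth_truth` from [synth_expression()]
#' @return a `pathway_collection`: list with `graphs` (named list of igraph)
#'   and `manifest` (tibble: pathway_id, n_nodes, n_edges)
#' @export
synth_pathways <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  withr::with_seed(derive_seed(cfg$rng_seed, 1L), synth_pathways_impl(cfg, truth))
}

synth_pathways_impl <- function(cfg, truth) {
  pcg_ids <- sprintf("PCG%04d", seq_len(cfg$n_pcg))
  hot <- unique(c(
    truth$planted_cerna_pairs$gene_id,
    truth$planted_coexpr_edges$gene_id,
    truth$seed_genes,
    truth$planted_de_pcgs
  ))
  cold <- sample(setdiff(pcg_ids, hot))

  sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                  cfg$n_pathways, replace = TRUE)
  overlap_group <- ceiling(seq_len(cfg$n_pathways) / 3)

  graphs <- vector("list", cfg$n_pathways)
  members_prev <- NULL
  group_prev <- 0L
  for (i in seq_len(cfg$n_pathways)) {
    s <- sizes[i]
    nodes <- character(0)
    if (overlap_group[i] == group_prev && cfg$frac_shared_genes > 0) {
      n_ov <- round(cfg$frac_shared_genes * s)
      n_ov <- min(n_ov, length(members_prev))
      if (n_ov > 0) nodes <- sample(members_prev, n_ov)
    }
    n_fresh <- s - length(nodes)
    # planted (DE/seed) genes fill a fixed share of fresh slots while they
    # last; the rest are background genes
    n_hot <- min(round(cfg$frac_pathway_planted * n_fresh), length(hot))
    take <- c(head(hot, n_hot), head(cold, n_fresh - n_hot))
    hot <- hot[-seq_len(n_hot)]
    if (n_fresh - n_hot > 0) cold <- cold[-seq_len(min(n_fresh - n_hot, length(cold)))]
    if (length(take) < n_fresh) {
      # gene pool exhausted: reuse genes not already in this pathway
      extra <- sample(setdiff(pcg_ids, c(nodes, take)), n_fresh - length(take))
      take <- c(take, extra)
    }
    nodes <- c(nodes, take)
    graphs[[i]] <- random_connected_graph(nodes, n_extra = round(0.4 * s))
    members_prev <- nodes
    group_prev <- overlap_group[i]
  }
  ids <- sprintf("path%02d", seq_len(cfg$n_pathways))
  names(graphs) <- ids
  structure(list(
    graphs = graphs,
    manifest = tibble(
      pathway_id = ids,
      n_nodes = purrr::map_int(graphs, igraph::vcount),
      n_edges = purrr::map_int(graphs, igraph::ecount)
    )
  ), class = "pathway_collection")
}

# Random connected labelled graph: random spanning tree + extra random edges.
random_connected_graph <- function(nodes, n_extra = 0) {
  n <- length(nodes)
  ord <- sample(nodes)
  el <- cbind(ord[-1], ord[vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1))])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (n_extra > 0) {
    for (k in seq_len(n_extra)) {
      pair <- sample(nodes, 2)
      if (!igraph::are_adjacent(g, pair[1], pair[2])) {
        g <- igraph::add_edges(g, pair)
      }
    }
  }
  igraph::simplify(g)
}

#' Generate probe-to-transcript alignment records with known violations
#'
#' Clean features get `n_probes_per_transcript` perfect full-length hits each.
#' Violations of each filter rule are injected in known numbers: probes with
#' only imperfect alignments (rule 1), probes hitting both a lncRNA and a PCG
#' transcript (rule 2), probes hitting two distinct genes of one biotype
#' (rule 3), and extra features with only two perfect probes (rule 4).
#'
#' @param cfg a [synth_config()]
#' @return a `probe_match_table`: list with `alignments` (BLAST outfmt-6
#'   tibble), `biotypes` (transcript_id, gene_id, biotype), `probe_lengths`
#'   (probe_id, probe_len) and `violations` (rule, kind, id)
#' @export
synth_probe_alignments <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(derive_seed(cfg$rng_seed, 2L), synth_probe_alignments_impl(cfg))
}

perfect_hit <- function(probe, transcript, probe_len = 25L) {
  sstart <- sample.int(500L, length(probe), replace = TRUE)
  tibble(
    qseqid = probe, sseqid = transcript, pident = 100, length = probe_len,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = probe_len,
    sstart = sstart, send = sstart + probe_len - 1L,
    evalue = 1e-10, bitscore = 50
  )
}

synth_probe_alignments_impl <- function(cfg) {
  pcg_ids <- sprintf("PCG%04d", seq_len(cfg$n_pcg))
  lnc_ids <- sprintf("LNC%03d", seq_len(cfg$n_lncrna))
  genes <- c(pcg_ids, lnc_ids)
  biotype <- rep(c("pcg", "lncrna"), c(cfg$n_pcg, cfg$n_lncrna))
  tx <- paste0("TX_", genes)
  biotypes <- tibble(transcript_id = tx, gene_id = genes, biotype = biotype)

  npp <- cfg$n_probes_per_transcript
  clean_probes <- sprintf("probe_%s_%02d", rep(genes, each = npp), rep(seq_len(npp), length(genes)))
  aln <- perfect_hit(clean_probes, rep(tx, each = npp))
  violations <- list()

  # rule 1: probes whose only alignments are imperfect (identity or length)
  if (cfg$n_imperfect_probes > 0) {
    p1 <- sprintf("probe_bad1_%02d", seq_len(cfg$n_imperfect_probes))
    h <- perfect_hit(p1, sample(tx, length(p1), replace = TRUE))
    odd <- seq_along(p1) %% 2 == 1
    h$pident[odd] <- 96
    h$mismatch[odd] <- 1L
    h$length[!odd] <- 24L
    h$qend[!odd] <- 24L
    aln <- bind_rows(aln, h)
    violations$r1 <- tibble(rule = 1L, kind = "probe", id = p1)
  }
  # rule 2: probes perfectly matching a lncRNA and a PCG transcript
  if (cfg$n_cross_biotype_probes > 0) {
    p2 <- sprintf("probe_bad2_%02d", seq_len(cfg$n_cross_biotype_probes))
    aln <- bind_rows(
      aln,
      perfect_hit(p2, paste0("TX_", sample(pcg_ids, length(p2)))),
      perfect_hit(p2, paste0("TX_", sample(lnc_ids, length(p2), replace = TRUE)))
    )
    violations$r2 <- tibble(rule = 2L, kind = "probe", id = p2)
  }
  # rule 3: probes perfectly matching two distinct genes of the same biotype
  if (cfg$n_multi_target_probes > 0) {
    p3 <- sprintf("probe_bad3_%02d", seq_len(cfg$n_multi_target_probes))
    half <- seq_along(p3) %% 2 == 1
    tgt1 <- tgt2 <- character(length(p3))
    g <- sample(pcg_ids, 2 * sum(half)); tgt1[half] <- g[seq_len(sum(half))]
    tgt2[half] <- g[-seq_len(sum(half))]
    g <- sample(lnc_ids, 2 * sum(!half)); tgt1[!half] <- g[seq_len(sum(!half))]
    tgt2[!half] <- g[-seq_len(sum(!half))]
    aln <- bind_rows(aln, perfect_hit(p3, paste0("TX_", tgt1)), perfect_hit(p3, paste0("TX_", tgt2)))
    violations$r3 <- tibble(rule = 3L, kind = "probe", id = p3)
  }
  # rule 4: extra features with only two perfect probes
  if (cfg$n_low_probe_features > 0) {
    g4 <- sprintf("PCGV%02d", seq_len(cfg$n_low_probe_features))
    tx4 <- paste0("TX_", g4)
    biotypes <- bind_rows(biotypes, tibble(transcript_id = tx4, gene_id = g4, biotype = "pcg"))
    p4 <- sprintf("probe_%s_%02d", rep(g4, each = 2), rep(1:2, length(g4)))
    aln <- bind_rows(aln, perfect_hit(p4, rep(tx4, each = 2)))
    violations$r4 <- tibble(rule = 4L, kind = "feature", id = g4)
  }

  probe_ids <- unique(aln$qseqid)
  structure(list(
    alignments = aln,
    biotypes = biotypes,
    probe_lengths = tibble(probe_id = probe_ids, probe_len = 25L),
    violations = bind_rows(violations)
  ), class = "probe_match_table")
}

#' Expand feature-level expression to probe-level measurements
#'
#' Each surviving probe measures its feature's intensity with multiplicative
#' log-normal probe noise; probes injected as rule violations (and rule-4
#' features absent from the feature matrix) get baseline noise rows.
#'
#' @param expr raw-scale expression tibble from [synth_expression()]
#' @param probes a `probe_match_table` from [synth_probe_alignments()]
#' @param cfg the [synth_config()]
#' @return probe-level raw-scale tibble (probe_id, one column per sample)
#' @export
synth_probe_expression <- function(expr, probes, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(derive_seed(cfg$rng_seed, 4L), {
    sc <- expr_sample_cols(expr)
    m <- log2(expr_matrix(expr))
    map <- probes$alignments |>
      left_join(probes$biotypes, by = c(sseqid = "transcript_id")) |>
      distinct(.data$qseqid, .data$gene_id)
    probe_ids <- unique(map$qseqid)
    first_gene <- map$gene_id[match(probe_ids, map$qseqid)]
    out <- matrix(0, length(probe_ids), length(sc), dimnames = list(probe_ids, sc))
    known <- first_gene %in% rownames(m)
    out[known, ] <- m[first_gene[known], , drop = FALSE]
    out[!known, ] <- rnorm(sum(!known), 8, 1)  # violation features: baseline rows
    out <- out + matrix(rnorm(length(out), 0, cfg$probe_noise_sd), nrow(out))
    res <- bind_cols(tibble(probe_id = probe_ids), as_tibble(2^out))
    attr(res, "log2") <- FALSE
    res
  })
}

#' Generate miRNA interaction tables with planted ceRNA pairs
#'
#' The lncRNA-side table carries miRanda-style alignment scores and free
#' energies spanning both sides of the score >= 160 / energy <= -20 kcal/mol
#' cut-offs; the gene-side table is database-styled (no scores). Each planted
#' ceRNA pair shares one dedicated miRNA whose lncRNA-side record passes the
#' cut-offs; decoy miRNAs are split between the two tables so they create no
#' unplanned shared-miRNA pairs.
#'
#' @param cfg a [synth_config()]
#' @param truth the `synth_truth` from [synth_expression()]
#' @return list with `lncrna` and `gene` interaction tibbles
#'   (source_id, mirna_id, alignment_score, free_energy)
#' @export
synth_mirna_tables <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  withr::with_seed(derive_seed(cfg$rng_seed, 3L), synth_mirna_tables_impl(cfg, truth))
}

synth_mirna_tables_impl <- function(cfg, truth) {
  lnc_ids <- sprintf("LNC%03d", seq_len(cfg$n_lncrna))
  pcg_ids <- sprintf("PCG%04d", seq_len(cfg$n_pcg))
  pairs <- truth$planted_cerna_pairs

  lnc_tab <- tibble(
    source_id = pairs$lncrna_id,
    mirna_id = pairs$mirna_id,
    alignment_score = round(runif(nrow(pairs), 160, 180), 1),
    free_energy = round(runif(nrow(pairs), -35, -21), 2)
  )
  gene_tab <- tibble(
    source_id = pairs$gene_id,
    mirna_id = pairs$mirna_id,
    alignment_score = NA_real_,
    free_energy = NA_real_
  )

  # decoy miRNA pools are disjoint between the two tables
  n_half <- cfg$n_mirna %/% 2
  mir_lnc <- sprintf("mmu-miR-L%03d", seq_len(n_half))
  mir_gene <- sprintf("mmu-miR-G%03d", seq_len(cfg$n_mirna - n_half))
  if (n_half > 0) {
    dec <- tibble(
      source_id = sample(lnc_ids, 3 * n_half, replace = TRUE),
      mirna_id = rep(mir_lnc, 3),
      alignment_score = round(runif(3 * n_half, 120, 185), 1),
      free_energy = round(runif(3 * n_half, -35, -10), 2)
    )
    lnc_tab <- bind_rows(lnc_tab, dec)
  }
  if (length(mir_gene) > 0) {
    gene_tab <- bind_rows(gene_tab, tibble(
      source_id = sample(pcg_ids, 3 * length(mir_gene), replace = TRUE),
      mirna_id = rep(mir_gene, 3),
      alignment_score = NA_real_,
      free_energy = NA_real_
    ))
  }
  # literature-style fixture records on one non-planted lncRNA: one passing
  # site and partial-threshold failures, attached to a lncRNA-side-only miRNA
  fix_lnc <- setdiff(lnc_ids, pairs$lncrna_id)[1]
  lnc_tab <- bind_rows(lnc_tab, tibble(
    source_id = fix_lnc,
    mirna_id = "mmu-miR-328",
    alignment_score = c(162, 156, 150, 164),
    free_energy = c(-32.22, -27.51, -19.13, -24.11)
  ))
  list(lncrna = arrange(lnc_tab, .data$source_id, .data$mirna_id),
       gene = arrange(gene_tab, .data$source_id, .data$mirna_id))
}

#' Generate a complete synthetic study
#'
#' Runs every generator with seeds derived from `cfg$rng_seed`; identical
#' configurations give identical output.
#'
#' @param cfg a [synth_config()]
#' @return list with `expression`, `phenotype`, `truth`, `pathways`, `probes`,
#'   `probe_expression`, `mirna`, and the `config`
#' @export
synth_dataset <- function(cfg = synth_config()) {
  ex <- synth_expression(cfg)
  pw <- synth_pathways(cfg, ex$truth)
  pr <- synth_probe_alignments(cfg)
  pe <- synth_probe_expression(ex$expression, pr, cfg)
  mi <- synth_mirna_tables(cfg, ex$truth)
  list(expression = ex$expression, phenotype = ex$phenotype, truth = ex$truth,
       pathways = pw, probes = pr, probe_expression = pe, mirna = mi,
       config = cfg)
}
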