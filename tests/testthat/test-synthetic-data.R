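test_that("configuration invariants are enforced with the field named", {
  expect_error(synth_config(n_planted_risk_lncrna = 30, n_de_lncrna = 20),
               "n_planted_risk_lncrna")
  expect_error(synth_config(n_seed_genes = 900, n_pcg = 800), "n_seed_genes")
  expect_error(synth_config(pathway_size_range = c(3, 10)), "pathway_size_range")
  expect_error(synth_config(coexpr_rho = 1.2), "coexpr_rho")
  expect_error(synth_config(noise_sd = 0), "noise_sd")
  expect_error(synth_config(n_probes_per_transcript = 2), "n_probes_per_transcript")
})

test_that("expression matrix has the configured dimensions", {
  cfg <- synth_config(n_pcg = 100, n_lncrna = 20, n_samples_per_group = 4,
                      n_de_pcg = 30, n_de_lncrna = 8, n_planted_risk_lncrna = 2,
                      n_planted_modules = 1, n_coexpr_partners = 5,
                      n_seed_genes = 10, rng_seed = 1)
  ex <- synth_expression(cfg)
  expect_equal(nrow(ex$expression), 120)
  expect_length(expr_sample_cols(ex$expression), 8)
  expect_equal(nrow(ex$phenotype), 8)
})

test_that("generation is byte-identical for identical configurations", {
  cfg <- synth_config(rng_seed = 7)
  a <- synth_dataset(cfg)
  b <- synth_dataset(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$probes$alignments, b$probes$alignments)
  expect_identical(a$mirna, b$mirna)
  expect_identical(
    purrr::map(a$pathways$graphs, igraph::as_edgelist),
    purrr::map(b$pathways$graphs, igraph::as_edgelist)
  )
  c <- synth_dataset(synth_config(rng_seed = 8))
  expect_false(identical(a$expression, c$expression))
})

test_that("truth IDs exist in the generated tables and satisfy invariants", {
  d <- synth_dataset(synth_config(rng_seed = 3))
  truth <- d$truth
  ids <- d$expression$feature_id
  expect_true(all(truth$planted_de_pcgs %in% ids))
  expect_true(all(truth$planted_de_lncrnas %in% ids))
  expect_true(all(truth$seed_genes %in% ids))
  expect_true(all(truth$planted_risk_lncrnas %in% truth$planted_de_lncrnas))
  # every planted co-expression edge joins a risk lncRNA to a seed gene
  expect_true(all(truth$planted_coexpr_edges$gene_id %in% truth$seed_genes))
  expect_true(all(truth$planted_cerna_pairs$lncrna_id %in% truth$planted_risk_lncrnas))
  expect_true(all(truth$planted_cerna_pairs$mirna_id %in% d$mirna$lncrna$mirna_id))
  expect_true(all(truth$planted_cerna_pairs$gene_id %in% d$mirna$gene$source_id))
})

test_that("planted fold changes land near the configured effect", {
  # realized group-mean difference of a planted row has sd noise_sd * sqrt(2/4);
  # the 3 * noise_sd / sqrt(4) envelope is ~2.1 sd, so a few percent of rows
  # fall outside by chance — assert the envelope for >= 95% of rows and the
  # grand mean tightly
  diffs <- unlist(lapply(1:25, function(s) {
    cfg <- synth_config(n_pcg = 60, n_lncrna = 10, n_de_pcg = 20, n_de_lncrna = 4,
                        n_planted_risk_lncrna = 2, n_planted_modules = 1,
                        n_coexpr_partners = 4, n_seed_genes = 6, rng_seed = s)
    ex <- synth_expression(cfg)
    x <- log2(expr_matrix(ex$expression))
    grp <- ex$phenotype$group
    lfc <- rowMeans(x[, grp == "case"]) - rowMeans(x[, grp == "control"])
    abs(lfc[ex$truth$planted_de_pcgs])
  }))
  bound <- 3 * 1 / sqrt(4)
  expect_gt(mean(abs(diffs - 2) <= bound), 0.95)
  se <- sqrt(2 / 4) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 2), 3 * se)
})

test_that("the latent-factor construction hits the target pair correlation", {
  # many columns so the sample correlation concentrates near the target
  cfg <- synth_config(n_pcg = 40, n_lncrna = 6, n_samples_per_group = 250,
                      n_de_pcg = 12, n_de_lncrna = 4, n_planted_risk_lncrna = 2,
                      n_planted_modules = 1, n_coexpr_partners = 5,
                      n_seed_genes = 6, coexpr_rho = 0.9, rng_seed = 11)
  ex <- synth_expression(cfg)
  x <- log2(expr_matrix(ex$expression))
  edges <- ex$truth$planted_coexpr_edges
  r <- purrr::map2_dbl(edges$lncrna_id, edges$gene_id, ~ cor(x[.x, ], x[.y, ]))
  expect_true(all(r >= 0.85 & r <= 0.95))
})

test_that("pathway graphs are connected, sized in range, and overlap as configured", {
  cfg <- synth_config(rng_seed = 5)
  ex <- synth_expression(cfg)
  pw <- synth_pathways(cfg, ex$truth)
  expect_length(pw$graphs, cfg$n_pathways)
  for (g in pw$graphs) {
    expect_true(igraph::is_connected(g))
    expect_gte(igraph::vcount(g), cfg$pathway_size_range[1])
    expect_lte(igraph::vcount(g), cfg$pathway_size_range[2])
  }
  # zero sharing gives pairwise-disjoint pathways
  cfg0 <- synth_config(frac_shared_genes = 0, n_pathways = 10, rng_seed = 5)
  pw0 <- synth_pathways(cfg0, synth_expression(cfg0)$truth)
  members <- purrr::map(pw0$graphs, ~ igraph::V(.x)$name)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_length(intersect(members[[i]], members[[j]]), 0)
  }
})

test_that("a pathway shares exactly the configured fraction with its predecessor", {
  cfg <- synth_config(n_pcg = 100, n_lncrna = 10, n_pathways = 2,
                      pathway_size_range = c(10, 10), frac_shared_genes = 0.3,
                      n_de_pcg = 20, n_de_lncrna = 4, n_planted_risk_lncrna = 2,
                      n_planted_modules = 1, n_coexpr_partners = 4,
                      n_seed_genes = 6, rng_seed = 9)
  pw <- synth_pathways(cfg, synth_expression(cfg)$truth)
  members <- purrr::map(pw$graphs, ~ igraph::V(.x)$name)
  expect_length(intersect(members[[1]], members[[2]]), 3)
})

test_that("probe alignment violations are injected in known counts", {
  cfg <- synth_config(rng_seed = 2)
  pr <- synth_probe_alignments(cfg)
  v <- pr$violations
  expect_equal(sum(v$rule == 1), cfg$n_imperfect_probes)
  expect_equal(sum(v$rule == 2), cfg$n_cross_biotype_probes)
  expect_equal(sum(v$rule == 3), cfg$n_multi_target_probes)
  expect_equal(sum(v$rule == 4), cfg$n_low_probe_features)
  expect_true(all(pr$alignments$sseqid %in% pr$biotypes$transcript_id))
})

test_that("miRNA tables span both sides of the binding cut-offs", {
  d <- synth_dataset(synth_config(rng_seed = 4))
  lnc <- d$mirna$lncrna
  kept <- filter_bindings(lnc)
  expect_gt(nrow(kept), 0)
  expect_lt(nrow(kept), nrow(lnc))
  # every planted pair's miRNA record passes the filters
  planted <- d$truth$planted_cerna_pairs
  for (i in seq_len(nrow(planted))) {
    expect_true(any(kept$source_id == planted$lncrna_id[i] &
                      kept$mirna_id == planted$mirna_id[i]))
  }
})
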