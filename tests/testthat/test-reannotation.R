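test_that("perfect-match calls follow the strict full-length definition", {
  rec <- tibble::tibble(pident = c(100, 96, 100, 100),
                        length = c(25, 25, 24, 25),
                        mismatch = c(0, 1, 0, 0),
                        gapopen = c(0, 0, 0, 1))
  expect_equal(is_perfect_match(rec, 25L), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(is_perfect_match(rec[1, ], NA), "probe length")
})

test_that("a clean table passes untouched with zero removal counts", {
  tab <- clean_probe_table(c("G1", "G2", "L1"), c("pcg", "pcg", "lncrna"))
  ann <- filter_probes(tab)
  expect_setequal(ann$features_kept$gene_id, c("G1", "G2", "L1"))
  expect_equal(ann$report$probes_removed, rep(0L, 4))
  expect_equal(ann$report$features_removed[4], 0L)
})

test_that("each filter rule removes exactly its constructed violations", {
  tab <- clean_probe_table(c("G1", "G2", "L1", "L2"), c("pcg", "pcg", "lncrna", "lncrna"))
  extra <- probe_table(data.frame(
    probe   = c("bad_imp", "bad_x", "bad_x", "bad_m", "bad_m", "p_G3_1", "p_G3_2"),
    gene    = c("G1",      "G1",    "L1",    "G1",    "G2",    "G3",     "G3"),
    biotype = c("pcg",     "pcg",   "lncrna","pcg",   "pcg",   "pcg",    "pcg"),
    perfect = c(FALSE,     TRUE,    TRUE,    TRUE,    TRUE,    TRUE,     TRUE)
  ))
  tab$alignments <- dplyr::bind_rows(tab$alignments, extra$alignments)
  tab$biotypes <- dplyr::distinct(dplyr::bind_rows(tab$biotypes, extra$biotypes))
  tab$probe_lengths <- dplyr::distinct(dplyr::bind_rows(tab$probe_lengths, extra$probe_lengths))
  ann <- filter_probes(tab)
  expect_equal(ann$report$probes_removed, c(1L, 1L, 1L, 2L))
  expect_equal(ann$report$features_removed[4], 1L)  # G3 has only 2 probes
  expect_false("G3" %in% ann$features_kept$gene_id)
  expect_setequal(ann$features_kept$gene_id, c("G1", "G2", "L1", "L2"))
})

test_that("rule order matters: a cross-biotype probe can starve a feature below three probes", {
  # G1 has exactly 3 perfect probes but one of them also hits a lncRNA:
  # rule 2 removes it first, then rule 4 drops G1 entirely. Applying the
  # probe-count rule before the cross-biotype rule would keep G1.
  hits <- data.frame(
    probe   = c("p1", "p2", "p3", "p3", "q1", "q2", "q3"),
    gene    = c("G1", "G1", "G1", "L1", "L1", "L1", "L1"),
    biotype = c("pcg", "pcg", "pcg", "lncrna", "lncrna", "lncrna", "lncrna"),
    perfect = TRUE
  )
  ann <- filter_probes(probe_table(hits))
  expect_false("G1" %in% ann$features_kept$gene_id)
  expect_true("L1" %in% ann$features_kept$gene_id)
})

test_that("probes hitting two isoforms of one gene are kept", {
  tab <- clean_probe_table("G1", "pcg")
  iso <- tibble::tibble(
    qseqid = "p_G1_1", sseqid = "TX2_G1", pident = 100, length = 25L,
    mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 25L, sstart = 1L,
    send = 25L, evalue = 1e-10, bitscore = 50
  )
  tab$alignments <- dplyr::bind_rows(tab$alignments, iso)
  tab$biotypes <- dplyr::bind_rows(tab$biotypes,
    tibble::tibble(transcript_id = "TX2_G1", gene_id = "G1", biotype = "pcg"))
  ann <- filter_probes(tab)
  expect_equal(ann$report$probes_removed[3], 0L)
  expect_true("G1" %in% ann$features_kept$gene_id)
})

test_that("filtering is idempotent", {
  cfg <- synth_config(rng_seed = 6)
  tab <- synth_probe_alignments(cfg)
  ann1 <- filter_probes(tab)
  kept_aln <- tab$alignments[tab$alignments$qseqid %in% ann1$annotation$probe_id, ]
  tab2 <- tab
  tab2$alignments <- kept_aln
  ann2 <- filter_probes(tab2)
  expect_equal(ann2$annotation, ann1$annotation)
  expect_equal(ann2$report$probes_removed, rep(0L, 4))
})

test_that("synthetic violations are removed exactly, by rule", {
  cfg <- synth_config(rng_seed = 12)
  tab <- synth_probe_alignments(cfg)
  ann <- filter_probes(tab)
  v <- tab$violations
  expect_equal(ann$report$probes_removed[1], sum(v$rule == 1))
  expect_equal(ann$report$probes_removed[2], sum(v$rule == 2))
  expect_equal(ann$report$probes_removed[3], sum(v$rule == 3))
  expect_equal(ann$report$features_removed[4], sum(v$rule == 4))
  expect_length(intersect(v$id[v$kind == "probe"], ann$annotation$probe_id), 0)
  expect_length(intersect(v$id[v$kind == "feature"], ann$features_kept$gene_id), 0)
  # all clean features survive
  n_clean <- cfg$n_pcg + cfg$n_lncrna
  expect_equal(nrow(ann$features_kept), n_clean)
})

test_that("collapse takes the per-sample median and ignores probe order", {
  ann <- filter_probes(clean_probe_table("G1", "pcg"))
  pe <- expr_tbl(matrix(c(4, 6, 8, 1, 2, 9), nrow = 3,
                        dimnames = list(c("p_G1_1", "p_G1_2", "p_G1_3"), c("s1", "s2"))))
  names(pe)[1] <- "probe_id"
  out <- collapse_to_features(pe, ann)
  expect_equal(out$s1, 6)
  expect_equal(out$s2, 2)
  out2 <- collapse_to_features(pe[c(3, 1, 2), ], ann)
  expect_equal(out2, out)
  expect_error(collapse_to_features(dplyr::mutate(pe, probe_id = paste0("x", probe_id)), ann),
               "no overlap")
})
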