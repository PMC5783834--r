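# Probe re-annotation: map microarray probes to lncRNA/PCG features from
# probe-to-transcript alignment records via four sequential filter rules.

#' Is an alignment record a perfect full-length match?
#'
#' Perfect means 100% identity, zero mismatches, zero gap opens, and an
#' alignment length equal to the probe length — the strictest reading of an
#' exact probe-transcript match.
#'
#' @param record one-or-more-row data frame with BLAST outfmt-6 columns
#'   `pident`, `length`, `mismatch`, `gapopen`
#' @param probe_len probe length(s) in nucleotides (recycled)
#' @return logical vector, one element per record row
#' @export
is_perfect_match <- function(record, probe_len) {
  if (missing(probe_len) || any(is.na(probe_len))) {
    abort("probe length is required to call a perfect match")
  }
  record$pident == 100 & record$mismatch == 0 & record$gapopen == 0 &
    record$length == probe_len
}

#' Filter probe alignments by the four re-annotation rules
#'
#' Rules are applied in order: (1) keep only perfect full-length matches;
#' (2) drop probes matching both a lncRNA and a PCG; (3) drop probes matching
#' multiple distinct genes of one biotype (isoforms of a single gene are
#' kept); (4) keep only features with at least `min_probes` surviving probes.
#'
#' @param table a `probe_match_table` (list with `alignments`, `biotypes`,
#'   `probe_lengths`) as produced by [synth_probe_alignments()] or
#'   [read_probe_match_table()]
#' @param min_probes minimum surviving probes per kept feature (default 3)
#' @return a `probe_annotation`: list with `annotation` (probe_id, gene_id,
#'   biotype), `features_kept` (gene_id, biotype, n_probes) and `report`
#'   (rule, probes_removed, features_removed)
#' @export
filter_probes <- function(table, min_probes = 3L) {
  aln <- table$alignments
  if (is.null(aln) || nrow(aln) == 0) abort("empty probe match table")
  missing_tx <- setdiff(aln$sseqid, table$biotypes$transcript_id)
  if (length(missing_tx) > 0) {
    abort(sprintf("transcripts missing from biotype map: %s", missing_tx[1]))
  }
  rec <- aln |>
    left_join(table$probe_lengths, by = c(qseqid = "probe_id")) |>
    left_join(table$biotypes, by = c(sseqid = "transcript_id"))

  # rule 1: perfect full-length matches only
  keep1 <- rec[is_perfect_match(rec, rec$probe_len), ]
  n_r1 <- dplyr::n_distinct(rec$qseqid) - dplyr::n_distinct(keep1$qseqid)
  if (nrow(keep1) == 0) {
    warn("no perfect probe matches; annotation is empty")
    return(empty_annotation(n_r1))
  }

  # per-probe gene/biotype profile after rule 1
  prof <- keep1 |>
    distinct(.data$qseqid, .data$gene_id, .data$biotype) |>
    group_by(.data$qseqid) |>
    summarise(n_biotypes = dplyr::n_distinct(.data$biotype),
              n_genes = dplyr::n_distinct(.data$gene_id),
              gene_id = .data$gene_id[1], biotype = .data$biotype[1],
              .groups = "drop")

  # rule 2: probes matching both biotypes
  cross <- prof$qseqid[prof$n_biotypes > 1]
  prof2 <- prof[prof$n_biotypes == 1, ]
  # rule 3: probes matching multiple distinct genes of one biotype
  multi <- prof2$qseqid[prof2$n_genes > 1]
  prof3 <- prof2[prof2$n_genes == 1, ]

  # rule 4: features with fewer than min_probes surviving probes
  feat <- prof3 |>
    group_by(.data$gene_id, .data$biotype) |>
    summarise(n_probes = dplyr::n(), .groups = "drop")
  dropped_feat <- feat$gene_id[feat$n_probes < min_probes]
  kept_feat <- feat[feat$n_probes >= min_probes, ]
  ann <- prof3 |>
    filter(.data$gene_id %in% kept_feat$gene_id) |>
    select("qseqid", "gene_id", "biotype") |>
    rename(probe_id = "qseqid") |>
    arrange(.data$probe_id)

  report <- tibble(
    rule = 1:4,
    probes_removed = c(n_r1, length(cross), length(multi),
                       sum(prof3$gene_id %in% dropped_feat)),
    features_removed = c(NA_integer_, NA_integer_, NA_integer_, length(dropped_feat))
  )
  structure(list(annotation = ann, features_kept = arrange(kept_feat, .data$gene_id),
                 report = report),
            class = "probe_annotation")
}

empty_annotation <- function(n_r1 = 0L) {
  structure(list(
    annotation = tibble(probe_id = character(), gene_id = character(), biotype = character()),
    features_kept = tibble(gene_id = character(), biotype = character(), n_probes = integer()),
    report = tibble(rule = 1:4, probes_removed = c(n_r1, 0L, 0L, 0L),
                    features_removed = c(NA_integer_, NA_integer_, NA_integer_, 0L))
  ), class = "probe_annotation")
}

#' Collapse probe-level expression to feature level
#'
#' Each kept feature's value in a sample is the median of its probes' values —
#' a robust summary; probe row order does not matter.
#'
#' @param expr_probe probe-level expression tibble (probe_id + sample columns)
#' @param ann a `probe_annotation` from [filter_probes()]
#' @return feature-level expression tibble (feature_id, biotype, samples);
#'   the log2 flag of the input is carried over
#' @export
collapse_to_features <- function(expr_probe, ann) {
  map <- ann$annotation
  common <- intersect(expr_probe$probe_id, map$probe_id)
  if (length(common) == 0) abort("no overlap between probe expression and annotation")
  m <- expr_matrix(expr_probe)[common, , drop = FALSE]
  gene <- map$gene_id[match(common, map$probe_id)]
  med <- apply(m, 2, function(col) tapply(col, gene, median))
  if (is.null(dim(med))) med <- matrix(med, nrow = 1, dimnames = list(unique(gene), colnames(m)))
  genes <- rownames(med)
  out <- bind_cols(
    tibble(feature_id = genes,
           biotype = ann$features_kept$biotype[match(genes, ann$features_kept$gene_id)]),
    as_tibble(med)
  )
  attr(out, "log2") <- isTRUE(attr(expr_probe, "log2"))
  out
}
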