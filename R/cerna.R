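# Competing endogenous RNA calling: shared-miRNA lncRNA-gene pairs with
# miRanda-style score/energy filters and a co-expression requirement.

#' Filter miRNA-binding records by alignment score and free energy
#'
#' Keeps records with `alignment_score >= min_score` and
#' `free_energy <= max_energy` (kcal/mol). Records without scores (e.g.
#' gene-side interactions imported from a database dump) pass unfiltered.
#'
#' @param table interaction tibble (source_id, mirna_id, alignment_score,
#'   free_energy)
#' @param min_score minimum miRanda alignment score (default 160)
#' @param max_energy maximum free energy in kcal/mol (default -20)
#' @return filtered tibble
#' @export
filter_bindings <- function(table, min_score = 160, max_energy = -20) {
  unscored <- is.na(table$alignment_score) & is.na(table$free_energy)
  keep <- unscored |
    (!is.na(table$alignment_score) & !is.na(table$free_energy) &
       table$alignment_score >= min_score & table$free_energy <= max_energy)
  table[keep, , drop = FALSE]
}

#' Call candidate ceRNA pairs via shared miRNAs
#'
#' Every (lncRNA, gene) pair sharing at least one miRNA between the two
#' filtered tables is emitted with its shared-miRNA set and the Pearson
#' correlation of the pair's expression; `passes` requires `r > r_threshold`.
#' miRNA IDs are matched case-insensitively.
#'
#' @param lnc_table filtered lncRNA-miRNA interaction tibble
#' @param gene_table filtered gene-miRNA interaction tibble
#' @param expr log2-scale expression tibble for the correlation
#' @param r_threshold co-expression threshold (default 0.8)
#' @return tibble (lncrna_id, gene_id, n_shared, shared_mirnas, r, passes),
#'   sorted by (lncrna_id, gene_id)
#' @export
shared_mirna_pairs <- function(lnc_table, gene_table, expr, r_threshold = 0.8) {
  lt <- lnc_table |> distinct(lncrna_id = .data$source_id,
                              mirna = tolower(.data$mirna_id))
  gt <- gene_table |> distinct(gene_id = .data$source_id,
                               mirna = tolower(.data$mirna_id))
  pairs <- inner_join(lt, gt, by = "mirna", relationship = "many-to-many") |>
    group_by(.data$lncrna_id, .data$gene_id) |>
    summarise(n_shared = dplyr::n(),
              shared_mirnas = paste(sort(.data$mirna), collapse = ";"),
              .groups = "drop")
  if (nrow(pairs) == 0) {
    return(tibble(lncrna_id = character(), gene_id = character(),
                  n_shared = integer(), shared_mirnas = character(),
                  r = numeric(), passes = logical()))
  }
  x <- expr_matrix(expr)
  r <- purrr::map2_dbl(pairs$lncrna_id, pairs$gene_id, function(l, g) {
    if (!(l %in% rownames(x)) || !(g %in% rownames(x))) return(NA_real_)
    cor(x[l, ], x[g, ])
  })
  if (anyNA(r)) warn("some pair members are absent from expression; r undefined for them")
  pairs |>
    mutate(r = r, passes = !is.na(r) & r > r_threshold) |>
    arrange(.data$lncrna_id, .data$gene_id)
}

#' Rank features by mean expression in case samples
#'
#' @param expr log2-scale expression tibble
#' @param phenotype tibble (sample, group)
#' @param ids features to rank (default: all in `expr`)
#' @return tibble (feature_id, mean_case_log2, mean_case_linear, rank),
#'   ranked by decreasing mean case expression, ties broken by ID
#' @export
expression_rank_report <- function(expr, phenotype, ids = NULL) {
  x <- expr_matrix(expr)
  ids <- ids %||% rownames(x)
  missing <- setdiff(ids, rownames(x))
  if (length(missing) > 0) abort(sprintf("feature absent from expression: %s", missing[1]))
  case_samples <- phenotype$sample[phenotype$group == "case"]
  m <- rowMeans(x[ids, case_samples, drop = FALSE])
  tibble(feature_id = ids, mean_case_log2 = unname(m),
         mean_case_linear = 2^unname(m)) |>
    arrange(dplyr::desc(.data$mean_case_log2), .data$feature_id) |>
    mutate(rank = dplyr::row_number())
}

#' Linear-scale expression ratio between two ranked features
#'
#' @param report tibble from [expression_rank_report()]
#' @param id_a,id_b feature IDs
#' @return the ratio of mean case expression of `id_a` over `id_b` on the
#'   linear scale, `2^(log2 mean difference)`
#' @export
expression_ratio <- function(report, id_a, id_b) {
  a <- report$mean_case_log2[report$feature_id == id_a]
  b <- report$mean_case_log2[report$feature_id == id_b]
  if (length(a) != 1 || length(b) != 1) abort("both features must appear in the report")
  2^(a - b)
}
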