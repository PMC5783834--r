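# Plain-text readers and writers for the pipeline's file contracts
# (TSV for tables, GML for pathway graphs, JSON for reports).

#' Read / write an expression TSV
#'
#' Layout: one identifier column (`feature_id` or `probe_id`), an optional
#' `biotype` column, then one numeric column per sample.
#'
#' @param path file path
#' @param log2 whether the stored values are log2-transformed
#' @return expression tibble with the log2 flag set accordingly
#' @export
read_expression_tsv <- function(path, log2 = FALSE) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  attr(out, "log2") <- log2
  out
}

#' @rdname read_expression_tsv
#' @param expr expression tibble
#' @export
write_expression_tsv <- function(expr, path) {
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Read / write a phenotype TSV (sample, group)
#' @param path file path
#' @export
read_phenotype_tsv <- function(path) {
  readr::read_tsv(path, col_types = "cc")
}

#' @rdname read_phenotype_tsv
#' @param phenotype tibble (sample, group)
#' @export
write_phenotype_tsv <- function(phenotype, path) {
  readr::write_tsv(phenotype, path)
  invisible(path)
}

#' Read a seed-gene list (one ID per line)
#' @param path file path
#' @return character vector
#' @export
read_seed_genes <- function(path) {
  readr::read_lines(path) |> trimws() |> purrr::keep(nzchar)
}

#' @rdname read_seed_genes
#' @param seeds character vector of gene IDs
#' @export
write_seed_genes <- function(seeds, path) {
  readr::write_lines(seeds, path)
  invisible(path)
}

#' Read probe alignment inputs into a `probe_match_table`
#'
#' @param alignment_path BLAST outfmt-6 TSV (qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore), no header
#' @param biotype_path TSV (transcript_id, gene_id, biotype)
#' @param probe_length_path TSV (probe_id, probe_len)
#' @return a `probe_match_table` list
#' @export
read_probe_match_table <- function(alignment_path, biotype_path, probe_length_path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  aln <- readr::read_tsv(alignment_path, col_names = cols,
                         col_types = "ccdiiiiiiidd")
  structure(list(
    alignments = aln,
    biotypes = readr::read_tsv(biotype_path, col_types = "ccc"),
    probe_lengths = readr::read_tsv(probe_length_path, col_types = "ci")
  ), class = "probe_match_table")
}

#' Read / write a miRNA interaction TSV
#' @param path file path
#' @export
read_mirna_table <- function(path) {
  readr::read_tsv(path, col_types = "ccdd")
}

#' @rdname read_mirna_table
#' @param table interaction tibble
#' @export
write_mirna_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Read a directory of pathway GML files into a `pathway_collection`
#'
#' Expects a `manifest.tsv` (pathway_id, file) next to the GML files; vertex
#' names are restored from the GML `name` (or `label`) attribute.
#'
#' @param dir directory containing `manifest.tsv` and GML files
#' @return a `pathway_collection`
#' @export
read_pathway_dir <- function(dir) {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"), col_types = "cc")
  graphs <- purrr::map(manifest$file, function(f) {
    g <- igraph::read_graph(file.path(dir, f), format = "gml")
    if (!("name" %in% igraph::vertex_attr_names(g)) &&
        "label" %in% igraph::vertex_attr_names(g)) {
      igraph::V(g)$name <- igraph::V(g)$label
    }
    g
  })
  names(graphs) <- manifest$pathway_id
  structure(list(
    graphs = graphs,
    manifest = tibble(pathway_id = manifest$pathway_id,
                      n_nodes = purrr::map_int(graphs, igraph::vcount),
                      n_edges = purrr::map_int(graphs, igraph::ecount))
  ), class = "pathway_collection")
}

#' Write a `pathway_collection` as GML files plus a manifest
#' @param pathways a `pathway_collection`
#' @param dir output directory (created if needed)
#' @export
write_pathway_dir <- function(pathways, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(names(pathways$graphs), ".gml")
  purrr::walk2(pathways$graphs, files, function(g, f) {
    igraph::write_graph(g, file.path(dir, f), format = "gml")
  })
  readr::write_tsv(tibble(pathway_id = names(pathways$graphs), file = files),
                   file.path(dir, "manifest.tsv"))
  invisible(dir)
}

#' Write a complete synthetic dataset to plain-text files
#'
#' Writes the expression, phenotype, probe alignment (BLAST outfmt-6),
#' biotype, probe-length, miRNA, seed-gene and pathway files plus the ground
#' truth as JSON under `dir`.
#'
#' @param data result of [synth_dataset()]
#' @param dir output directory
#' @export
write_synth_dataset <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(data$expression, file.path(dir, "expression.tsv"))
  write_expression_tsv(data$probe_expression, file.path(dir, "probe_expression.tsv"))
  write_phenotype_tsv(data$phenotype, file.path(dir, "phenotype.tsv"))
  readr::write_tsv(data$probes$alignments, file.path(dir, "probe_alignments.tsv"),
                   col_names = FALSE)
  readr::write_tsv(data$probes$biotypes, file.path(dir, "transcript_biotypes.tsv"))
  readr::write_tsv(data$probes$probe_lengths, file.path(dir, "probe_lengths.tsv"))
  write_mirna_table(data$mirna$lncrna, file.path(dir, "mirna_lncrna.tsv"))
  write_mirna_table(data$mirna$gene, file.path(dir, "mirna_gene.tsv"))
  write_seed_genes(data$truth$seed_genes, file.path(dir, "seed_genes.txt"))
  write_pathway_dir(data$pathways, file.path(dir, "pathways"))
  truth <- data$truth
  truth$de_signs <- NULL
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = FALSE)
  invisible(dir)
}

#' Write a heterogeneous network as edge-list and node TSVs
#' @param net a `hetero_network`
#' @param edge_path,node_path output TSV paths
#' @export
write_network_tsv <- function(net, edge_path, node_path) {
  readr::write_tsv(tidy(net), edge_path)
  deg <- igraph::degree(net)
  readr::write_tsv(tibble(
    id = igraph::V(net)$name,
    type = igraph::V(net)$type,
    is_seed = igraph::V(net)$is_seed %||% FALSE,
    degree = unname(deg)
  ), node_path)
  invisible(edge_path)
}
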