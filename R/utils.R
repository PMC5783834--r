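# Internal helpers shared across modules.

# Columns of an expression tibble that identify features rather than samples.
.id_cols <- c("feature_id", "probe_id", "gene_id", "biotype")

#' Sample (measurement) columns of an expression tibble
#' @param expr expression tibble
#' @return character vector of sample column names
#' @keywords internal
expr_sample_cols <- function(expr) {
  setdiff(names(expr), .id_cols)
}

#' Convert an expression tibble to a numeric matrix
#'
#' Rows are features (named by the first identifier column present), columns
#' are samples.
#'
#' @param expr expression tibble with an identifier column (`feature_id` or
#'   `probe_id`) followed by one numeric column per sample
#' @return numeric matrix with feature rownames
#' @export
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr))
  idc <- intersect(c("feature_id", "probe_id"), names(expr))[1]
  if (is.na(idc)) abort("expression table needs a 'feature_id' or 'probe_id' column")
  sc <- expr_sample_cols(expr)
  m <- as.matrix(expr[, sc, drop = FALSE])
  rownames(m) <- expr[[idc]]
  storage.mode(m) <- "double"
  m
}

# Rebuild an expression tibble from a matrix, carrying over id/biotype columns
# of a template where rownames match.
expr_from_matrix <- function(m, template = NULL) {
  idc <- "feature_id"
  out <- tibble(feature_id = rownames(m))
  if (!is.null(template) && "biotype" %in% names(template)) {
    idt <- intersect(c("feature_id", "probe_id"), names(template))[1]
    out$biotype <- template$biotype[match(rownames(m), template[[idt]])]
  }
  bind_cols(out, as_tibble(m))
}

# Validate a scalar config field, erroring with the field name.
check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("config field '%s' must be a single integer >= %d", field, min))
  }
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1, open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) {
    abort(sprintf("config field '%s' must be in %s%g, %g%s",
                  field, if (open) "(" else "[", lo, hi, if (open) ")" else "]"))
  }
  as.numeric(x)
}

# Derive a stream-specific 32-bit seed from a base seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
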