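# Differential expression: fold change plus a SAM-style moderated statistic
# with permutation significance, combined as a union call.

#' Log2-transform a raw-scale expression table
#'
#' @param expr expression tibble on the raw (linear) scale
#' @param offset constant added before taking logs (default 0); required if
#'   any value is non-positive
#' @return the same tibble with log2 values and the log2 flag set
#' @export
log2_transform <- function(expr, offset = 0) {
  if (isTRUE(attr(expr, "log2"))) abort("expression is already log2-transformed")
  sc <- expr_sample_cols(expr)
  vals <- as.matrix(expr[, sc]) + offset
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("non-positive or non-finite values; supply a positive offset")
  }
  expr[, sc] <- as_tibble(log2(vals))
  attr(expr, "log2") <- TRUE
  expr
}

#' SAM-style moderated difference statistic
#'
#' `d = (mean(case) - mean(ctrl)) / (s + s0)` where `s` is the pooled standard
#' error of the mean difference and `s0` a small positive constant that damps
#' features with tiny variance.
#'
#' @param x_case,x_ctrl numeric vectors, each of length >= 2
#' @param s0 variance-damping constant (>= 0)
#' @return the statistic `d` (signed infinity with a warning if both the
#'   pooled error and `s0` are zero while the means differ)
#' @export
sam_statistic <- function(x_case, x_ctrl, s0 = 0) {
  stopifnot(length(x_case) >= 2, length(x_ctrl) >= 2)
  n1 <- length(x_case); n2 <- length(x_ctrl)
  sp2 <- ((n1 - 1) * stats::var(x_case) + (n2 - 1) * stats::var(x_ctrl)) / (n1 + n2 - 2)
  s <- sqrt(sp2 * (1 / n1 + 1 / n2))
  num <- mean(x_case) - mean(x_ctrl)
  if (s + s0 == 0) {
    if (num == 0) return(0)
    warn("zero variance with s0 = 0; returning signed infinity")
    return(sign(num) * Inf)
  }
  num / (s + s0)
}

# All d statistics for a binary split, vectorized over matrix rows.
# case_idx indexes the columns treated as cases.
sam_stat_matrix <- function(x, case_idx, s0) {
  n1 <- length(case_idx)
  n2 <- ncol(x) - n1
  xc <- x[, case_idx, drop = FALSE]
  xk <- x[, -case_idx, drop = FALSE]
  m1 <- rowMeans(xc); m2 <- rowMeans(xk)
  v1 <- rowSums((xc - m1)^2) / (n1 - 1)
  v2 <- rowSums((xk - m2)^2) / (n2 - 1)
  s <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
  (m1 - m2) / (s + s0)
}

#' SAM permutation test with union differential-expression call
#'
#' Computes per-feature log2 fold changes (case mean minus control mean) and
#' SAM statistics, then permutes the sample labels jointly across features to
#' obtain empirical p-values. When the number of distinct label splits is at
#' most `B` (70 for a 4 vs 4 design) all splits are enumerated and p-values
#' are permutation-count exact; otherwise `B` random splits are drawn and the
#' add-one convention `p = (1 + m) / (B + 1)` is used. [call_de()] flags are
#' attached.
#'
#' @param expr log2-scale expression tibble (feature_id, biotype, samples)
#' @param phenotype tibble (sample, group) with groups `control` and `case`
#' @param s0 damping constant; default is the median of the per-feature
#'   pooled standard errors
#' @param B maximum number of permutations (default 1000)
#' @param seed RNG seed for the sampled-permutation path
#' @param fc_threshold,p_threshold thresholds passed to [call_de()]
#' @return tibble (feature_id, biotype, log2_fold_change, d_stat, p_perm,
#'   is_de_fc, is_de_p, is_de) with attributes `s0`, `n_perm`, `exhaustive`
#' @export
sam_de <- function(expr, phenotype, s0 = NULL, B = 1000, seed = 1L,
                   fc_threshold = 2, p_threshold = 0.05) {
  stopifnot(B >= 1)
  if (!isTRUE(attr(expr, "log2"))) {
    warn("expression not flagged log2-transformed; statistics assume log2 scale")
  }
  x <- expr_matrix(expr)
  grp <- phenotype$group[match(colnames(x), phenotype$sample)]
  if (anyNA(grp)) abort("phenotype table does not cover all samples")
  case_idx <- which(grp == "case")
  ctrl_idx <- which(grp == "control")
  if (length(case_idx) < 2 || length(ctrl_idx) < 2) abort("need >= 2 samples per group")

  m1 <- rowMeans(x[, case_idx, drop = FALSE])
  m2 <- rowMeans(x[, ctrl_idx, drop = FALSE])
  lfc <- m1 - m2
  if (is.null(s0)) {
    n1 <- length(case_idx); n2 <- length(ctrl_idx)
    v1 <- rowSums((x[, case_idx] - m1)^2) / (n1 - 1)
    v2 <- rowSums((x[, ctrl_idx] - m2)^2) / (n2 - 1)
    se <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2) * (1 / n1 + 1 / n2))
    s0 <- median(se)
  }
  d_obs <- sam_stat_matrix(x, case_idx, s0)

  n <- ncol(x)
  n_case <- length(case_idx)
  n_splits <- choose(n, n_case)
  exhaustive <- n_splits <= B
  if (exhaustive) {
    splits <- combn(n, n_case)
    exceed <- integer(nrow(x))
    for (j in seq_len(ncol(splits))) {
      exceed <- exceed + (abs(sam_stat_matrix(x, splits[, j], s0)) >= abs(d_obs) - 1e-12)
    }
    p <- exceed / n_splits
    n_perm <- n_splits
  } else {
    exceed <- integer(nrow(x))
    withr::with_seed(seed, {
      for (b in seq_len(B)) {
        idx <- sample.int(n, n_case)
        exceed <- exceed + (abs(sam_stat_matrix(x, idx, s0)) >= abs(d_obs) - 1e-12)
      }
    })
    p <- (1 + exceed) / (B + 1)
    n_perm <- B
  }

  res <- tibble(
    feature_id = rownames(x),
    biotype = if ("biotype" %in% names(expr)) expr$biotype else NA_character_,
    log2_fold_change = unname(lfc),
    d_stat = unname(d_obs),
    p_perm = unname(p)
  )
  res <- call_de(res, fc_threshold = fc_threshold, p_threshold = p_threshold)
  attr(res, "s0") <- s0
  attr(res, "n_perm") <- n_perm
  attr(res, "exhaustive") <- exhaustive
  res
}

#' Flag differentially expressed features
#'
#' A feature is DE if its linear fold change exceeds `fc_threshold` in either
#' direction (|log2 FC| > log2(fc_threshold)) OR its permutation p-value is
#' below `p_threshold` — the union of the two criteria.
#'
#' @param res tibble with `log2_fold_change` and `p_perm`
#' @param fc_threshold linear fold-change threshold (default 2)
#' @param p_threshold p-value threshold (default 0.05)
#' @return `res` with logical columns `is_de_fc`, `is_de_p`, `is_de`
#' @export
call_de <- function(res, fc_threshold = 2, p_threshold = 0.05) {
  res$is_de_fc <- abs(res$log2_fold_change) > log2(fc_threshold)
  res$is_de_p <- res$p_perm < p_threshold
  res$is_de <- res$is_de_fc | res$is_de_p
  res
}
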