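# Rank-based single-sample cell-type signature scores and a linear
# trend-across-age test per cell type and sex.

#' Single-sample signature scores
#'
#' For each sample, all genes are ranked ascending (ties averaged) and
#' mapped to normalized ranks `(rank - 1) / G`. A signature's score is the
#' mean normalized rank of its member genes minus 0.5, so a random
#' signature scores ~0, an up-shifted signature scores positive, and the
#' score is invariant to any monotone per-sample transformation of
#' expression. Signatures with fewer than `min_genes` members present in the
#' matrix are skipped with a warning.
#'
#' @param expr Expression matrix (any scale; `tpm` typical). Rows genes,
#'   columns samples.
#' @param signatures Named list of gene vectors (see [read_gmt()]).
#' @param min_genes Minimum matched genes per signature (default 3).
#' @return Matrix of cell types x samples.
#' @export
signature_scores <- function(expr, signatures, min_genes = 3L) {
  stopifnot(is.matrix(expr), length(signatures) > 0L)
  g <- nrow(expr)
  matched <- lapply(signatures, function(s) intersect(toupper(s), rownames(expr)))
  usable <- vapply(matched, length, 1L) >= min_genes
  if (!all(usable))
    warning("signature(s) skipped (fewer than ", min_genes, " matched genes): ",
            paste(names(signatures)[!usable], collapse = ", "))
  if (!any(usable)) stop("no usable signatures")
  matched <- matched[usable]
  nr <- apply(expr, 2L, function(x) (rank(x, ties.method = "average") - 1) / g)
  rownames(nr) <- rownames(expr)
  out <- t(vapply(matched, function(s) colMeans(nr[s, , drop = FALSE]) - 0.5,
                  numeric(ncol(expr))))
  dimnames(out) <- list(names(matched), colnames(expr))
  out
}

#' Linear trend-across-age test
#'
#' Post-ANOVA linear contrast across the ordered age groups, run per sex
#' and cell type: contrast coefficients are the centered, equally spaced
#' indices of the usable groups; the statistic is
#' `t = sum(c_j * mean_j) / sqrt(MSE_within * sum(c_j^2 / n_j))` on
#' `N - k` degrees of freedom, with a two-sided p-value. Groups with fewer
#' than 2 samples are dropped; a sex with fewer than 3 usable groups is
#' skipped.
#'
#' @param scores Cell types x samples matrix (see [signature_scores()]).
#' @param samples Sample table.
#' @param tissue Tissue (default "vat").
#' @param alpha Significance threshold (default 0.05).
#' @return data.frame: cell_type, sex, direction (up/down), t, df, p,
#'   significant.
#' @export
trend_test <- function(scores, samples, tissue = "vat", alpha = 0.05) {
  stopifnot(is.matrix(scores))
  samples <- validate_sample_table(samples)
  sub <- samples[samples$tissue == tissue & samples$sample_id %in% colnames(scores), ,
                 drop = FALSE]
  rows <- list()
  for (sx in intersect(c("male", "female"), unique(sub$sex))) {
    ss <- sub[sub$sex == sx, , drop = FALSE]
    tab <- table(ss$age_group)
    usable <- names(tab)[tab >= 2L]
    usable <- usable[order(match(usable, age_groups()))]
    if (length(usable) < 3L) {
      warning("fewer than 3 usable age groups for ", sx, "; trend test skipped")
      next
    }
    cc <- seq_along(usable) - mean(seq_along(usable))
    n_j <- as.numeric(tab[usable])
    ids_by_grp <- lapply(usable, function(g) ss$sample_id[ss$age_group == g])
    n_tot <- sum(n_j)
    df <- n_tot - length(usable)
    for (ct in rownames(scores)) {
      means <- vapply(ids_by_grp, function(ids) mean(scores[ct, ids]), numeric(1L))
      sse <- sum(vapply(ids_by_grp, function(ids) {
        v <- scores[ct, ids]
        sum((v - mean(v))^2)
      }, numeric(1L)))
      mse <- sse / df
      est <- sum(cc * means)
      se <- sqrt(mse * sum(cc^2 / n_j))
      t <- if (se > 0) est / se else 0
      p <- if (se > 0) 2 * stats::pt(-abs(t), df = df) else 1
      rows[[paste(ct, sx)]] <- data.frame(
        cell_type = ct, sex = sx,
        direction = if (est >= 0) "up" else "down",
        t = t, df = df, p = p, significant = p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
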