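# Empirical-Bayes moderated two-group differential expression of each age
# group against the common 20-29 reference, run per sex, with BH-FDR and a
# linear fold-change gate; SASP panel extraction.

#' Differential-expression configuration
#'
#' @param fdr_threshold BH-FDR cutoff (default 0.05).
#' @param fc_threshold Linear fold-change cutoff, applied in either
#'   direction, i.e. significance needs `|log2 FC| >= log2(fc_threshold)`
#'   (default 2.0).
#' @param reference_group Common reference age group (default "20-29").
#' @return List of class `de_config`.
#' @export
de_config <- function(fdr_threshold = 0.05, fc_threshold = 2.0,
                      reference_group = "20-29") {
  stopifnot(fdr_threshold > 0, fc_threshold > 0)
  if (!reference_group %in% age_groups())
    stop("reference_group must be one of: ", paste(age_groups(), collapse = ", "))
  structure(list(fdr_threshold = fdr_threshold, fc_threshold = fc_threshold,
                 reference_group = reference_group),
            class = "de_config")
}

#' Invert the trigamma function
#'
#' Solves `trigamma(y) = x` for y > 0 by monotone root-finding (trigamma is
#' strictly decreasing from +Inf to 0 on (0, Inf)).
#'
#' @param x Positive value(s).
#' @return y such that `trigamma(y) = x`, elementwise.
#' @export
trigamma_inverse <- function(x) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NA_real_)
    if (xi > 1e7) return(1 / sqrt(xi))      # trigamma(y) ~ 1/y^2 as y -> 0
    if (xi < 1e-8) return(1 / xi)           # trigamma(y) ~ 1/y as y -> Inf
    lo <- 0.1 * min(1 / xi, 1 / sqrt(xi))
    hi <- 10 * max(1 / xi, 1 / sqrt(xi))
    stats::uniroot(function(y) trigamma(y) - xi, lower = lo, upper = hi,
                   tol = 1e-12 * max(1, 1 / xi))$root
  }, numeric(1L))
}

#' Fit the empirical-Bayes variance prior
#'
#' Matches the first two moments of `log(s2)` to the scaled log-F
#' distribution implied by the hierarchical model: per-gene sample variances
#' `s2 ~ s0^2 * F(d, d0)`. The excess spread of `log(s2)` beyond the
#' chi-square contribution `trigamma(d/2)` determines the prior degrees of
#' freedom `d0` (via trigamma inversion); when no excess spread is present
#' the prior is degenerate (`d0 = Inf`) and every posterior variance equals
#' `s0^2`.
#'
#' @param s2 Per-gene residual (pooled) variances; zeros are excluded from
#'   the moment fit.
#' @param df Residual degrees of freedom, a scalar or one value per gene.
#' @return List of class `moderation_fit` with elements `d0` (prior df,
#'   possibly Inf), `s02` (prior variance), and `posterior_var` (per-gene
#'   posterior variances `(d0*s02 + d*s2)/(d0 + d)`).
#' @export
fit_moderation <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  stopifnot(length(df) == length(s2))
  use <- is.finite(s2) & s2 > 0 & df >= 1
  if (sum(use) == 0L) stop("all residual variances are zero: degenerate data")
  if (sum(use) < 10L)
    warning("moment fit based on fewer than 10 positive variances")
  z <- log(s2[use])
  dfu <- df[use]
  e <- z - digamma(dfu / 2) + log(dfu / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dfu / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread: degenerate prior, all true variances equal; the
    # pooled mean variance is the maximum-likelihood scale
    d0 <- Inf
    s02 <- mean(s2[use])
  }
  post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + df * s2) / (d0 + df)
  structure(list(d0 = d0, s02 = s02, posterior_var = post),
            class = "moderation_fit")
}

#' Moderated two-sample t-statistics
#'
#' Shrinks per-gene pooled variances toward a prior and forms
#' `t = (mean2 - mean1) / sqrt(postvar * (1/n1 + 1/n2))` on
#' `d0 + n1 + n2 - 2` degrees of freedom. With `d0 = 0` this is exactly the
#' ordinary pooled two-sample t-test.
#'
#' @param x1,x2 Numeric matrices (genes x samples) for the two groups, same
#'   genes in the same order.
#' @param d0,s02 Prior degrees of freedom and prior variance; if `NULL`,
#'   fitted from the data with [fit_moderation()].
#' @return data.frame with per-gene `diff` (group2 - group1 mean), `s2`
#'   (pooled variance), `post_var`, `t`, `df_total`, `p` (two-sided).
#' @export
moderated_t <- function(x1, x2, d0 = NULL, s02 = NULL) {
  stopifnot(nrow(x1) == nrow(x2), ncol(x1) >= 2L, ncol(x2) >= 2L)
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  d <- n1 + n2 - 2L
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  s2 <- ss / d
  if (is.null(d0) || is.null(s02)) {
    fit <- fit_moderation(s2, d)
    d0 <- fit$d0; s02 <- fit$s02
    post <- fit$posterior_var
  } else {
    post <- if (is.infinite(d0)) rep(s02, length(s2)) else
      (d0 * s02 + d * s2) / (d0 + d)
  }
  diff <- m2 - m1
  se <- sqrt(post * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, diff / se, 0)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t), df = df_total)
  p[se == 0] <- 1
  data.frame(diff = diff, s2 = s2, post_var = post, t = t,
             df_total = rep(df_total, length(t)), p = p,
             row.names = rownames(x1))
}

#' Moderated differential expression against the youngest reference
#'
#' For one sex, tests each non-reference age group against the common
#' reference group on the log10-CPM scale, with empirical-Bayes variance
#' moderation fitted per contrast, BH-FDR within each contrast, and a
#' significance flag requiring both `fdr < fdr_threshold` and linear fold
#' change `>= fc_threshold` in either direction. The log2 fold change is the
#' log10-scale group-mean difference rescaled by `log2(10)`.
#'
#' @param expr Expression matrix on the `log10_cpm` scale.
#' @param samples Sample table (see [read_sample_table()]).
#' @param sex `"male"` or `"female"`.
#' @param cfg A [de_config()].
#' @param tissue Tissue to test within (default `"vat"`).
#' @return data.frame with columns gene, sex, contrast, log2_fc, mod_t, p,
#'   fdr, significant.
#' @export
moderated_test <- function(expr, samples, sex, cfg = de_config(), tissue = "vat") {
  stop_unless_scale(expr, "log10_cpm")
  samples <- validate_sample_table(samples)
  sex <- match.arg(sex, c("male", "female"))
  sub <- samples[samples$sex == sex & samples$tissue == tissue &
                   samples$sample_id %in% colnames(expr), , drop = FALSE]
  if (nrow(sub) == 0L) stop("no ", sex, " ", tissue, " samples found in expr")
  ref <- cfg$reference_group
  ref_ids <- sub$sample_id[sub$age_group == ref]
  if (length(ref_ids) < 2L)
    stop("reference group ", ref, " needs at least 2 samples (", sex, ")")
  x_ref <- expr[, ref_ids, drop = FALSE]
  out <- list()
  for (grp in setdiff(levels(sub$age_group), ref)) {
    ids <- sub$sample_id[sub$age_group == grp]
    if (length(ids) == 0L) next
    if (length(ids) < 2L) {
      warning("contrast ", grp, " vs ", ref, " (", sex,
              ") skipped: fewer than 2 samples")
      next
    }
    mt <- moderated_t(x_ref, expr[, ids, drop = FALSE])
    log2_fc <- mt$diff * log2(10)
    fdr <- stats::p.adjust(mt$p, method = "BH")
    out[[grp]] <- data.frame(
      gene = rownames(expr),
      sex = sex,
      contrast = paste0(grp, "_vs_", ref),
      log2_fc = log2_fc,
      mod_t = mt$t,
      p = mt$p,
      fdr = fdr,
      significant = fdr < cfg$fdr_threshold &
        abs(log2_fc) >= log2(cfg$fc_threshold),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) stop("no testable contrasts for sex ", sex)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Union of differentially expressed genes across contrasts
#'
#' Genes significant in at least one contrast, de-duplicated and sorted.
#'
#' @param results One or more `moderated_test` result tables (rbind-able).
#' @return Sorted character vector.
#' @export
deg_union <- function(results) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  sort(unique(results$gene[results$significant]))
}

#' SASP panel profile
#'
#' Extracts fold change and FDR for every gene of a senescence-associated
#' secretory phenotype panel that is present in the tested data, whether or
#' not it reached significance; the star flag marks genes with FDR < 0.05 in
#' at least one contrast. Panel genes absent from the data are omitted with
#' a warning.
#'
#' @param results A `moderated_test` result table (one or both sexes).
#' @param sasp_genes Character vector of SASP gene symbols.
#' @param star_fdr FDR cutoff for the star flag (default 0.05).
#' @return data.frame of gene x contrast rows with a per-gene `star` column.
#' @export
sasp_profile <- function(results, sasp_genes, star_fdr = 0.05) {
  if (length(sasp_genes) == 0L) stop("sasp_genes must be non-empty")
  sasp_genes <- unique(toupper(sasp_genes))
  present <- intersect(sasp_genes, unique(results$gene))
  absent <- setdiff(sasp_genes, present)
  if (length(absent) > 0L)
    warning("SASP gene(s) absent from data omitted: ",
            paste(absent, collapse = ", "))
  sub <- results[results$gene %in% present,
                 c("gene", "sex", "contrast", "log2_fc", "fdr"), drop = FALSE]
  starred <- tapply(sub$fdr < star_fdr, sub$gene, any)
  sub$star <- unname(starred[sub$gene])
  sub <- sub[order(sub$gene, sub$sex, sub$contrast), , drop = FALSE]
  rownames(sub) <- NULL
  sub
}
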