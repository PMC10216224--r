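# Expression scales: log10-CPM (differential expression), TMM-scaled CPM
# (trajectory comparison), TPM (connectome expression thresholds).

expr_scale <- function(x) attr(x, "expr_scale")

set_expr_scale <- function(x, scale) {
  attr(x, "expr_scale") <- scale
  class(x) <- unique(c("viscage_expr", class(x)))
  x
}

#' @export
`[.viscage_expr` <- function(x, ...) {
  sc <- attr(x, "expr_scale")
  out <- NextMethod()
  if (is.matrix(out)) {
    attr(out, "expr_scale") <- sc
    class(out) <- class(x)
  }
  out
}

stop_unless_scale <- function(x, scale, arg = deparse(substitute(x))) {
  s <- expr_scale(x)
  if (is.null(s) || s != scale)
    stop(sprintf("'%s' must be an expression matrix on the '%s' scale (got '%s')",
                 arg, scale, if (is.null(s)) "unset" else s))
  invisible(x)
}

#' Log10 counts-per-million
#'
#' Depth-normalizes each sample to counts per million and applies
#' `log10(CPM + 1)`. The pseudo-count of 1 maps zero counts to exactly zero
#' and preserves within-sample ordering.
#'
#' @param counts Validated count matrix (genes x samples).
#' @return Matrix of the same shape with `expr_scale` attribute
#'   `"log10_cpm"`.
#' @export
log10_cpm <- function(counts) {
  counts <- validate_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  out <- log10(sweep(counts, 2L, lib, "/") * 1e6 + 1)
  set_expr_scale(out, "log10_cpm")
}

#' Counts-per-million (optionally TMM-scaled)
#'
#' @param counts Validated count matrix.
#' @param factors Optional per-sample scaling factors (e.g. from
#'   [tmm_factors()]); effective library size is `libsize * factor`.
#' @return CPM matrix with `expr_scale` `"tmm_cpm"` when factors are given,
#'   else `"cpm"`.
#' @export
tmm_cpm <- function(counts, factors = NULL) {
  counts <- validate_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(factors)) {
    out <- sweep(counts, 2L, lib, "/") * 1e6
    return(set_expr_scale(out, "cpm"))
  }
  if (length(factors) != ncol(counts))
    stop("need one scaling factor per sample")
  out <- sweep(counts, 2L, lib * factors, "/") * 1e6
  set_expr_scale(out, "tmm_cpm")
}

#' TMM between-sample scaling factors
#'
#' Trimmed mean of M-values. The reference sample is the one whose
#' upper-quartile of nonzero CPM is closest to the mean upper-quartile
#' across samples. For each sample, per-gene M (log2 CPM ratio vs the
#' reference) and A (mean log2 CPM) are computed over genes nonzero in both
#' samples; the top and bottom `trim_m` of M and `trim_a` of A are trimmed;
#' the factor is 2 to the precision-weighted mean of the surviving M values,
#' with weights the inverse asymptotic binomial variance. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param counts Validated count matrix with >= 2 samples, each with at
#'   least one nonzero gene.
#' @param trim_m,trim_a Two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05).
#' @param min_genes If fewer than this many genes survive trimming for a
#'   sample, its factor falls back to 1 with a warning.
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05, min_genes = 10L) {
  counts <- validate_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  nz_ok <- colSums(counts > 0) >= 1L
  if (!all(nz_ok)) stop("every sample needs at least one nonzero gene")
  cpm <- sweep(counts, 2L, lib, "/") * 1e6
  uq <- apply(cpm, 2L, function(x) stats::quantile(x[x > 0], 0.75, names = FALSE))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    .tmm_pair_factor(counts[, k], counts[, ref], lib[k], lib[ref],
                     trim_m, trim_a, min_genes,
                     sample_id = colnames(counts)[k])
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One sample vs the reference; the factor before geometric-mean rescaling.
.tmm_pair_factor <- function(y, yr, n, nr, trim_m, trim_a, min_genes, sample_id) {
  keep <- y > 0 & yr > 0
  y <- y[keep]; yr <- yr[keep]
  if (length(y) == 0L) {
    warning("no genes shared with the reference for sample ", sample_id,
            "; factor set to 1")
    return(1)
  }
  p <- y / n
  pr <- yr / nr
  M <- log2(p / pr)
  A <- 0.5 * (log2(p) + log2(pr))
  w <- 1 / ((n - y) / (n * y) + (nr - yr) / (nr * yr))
  ng <- length(M)
  lo_m <- floor(ng * trim_m) + 1
  hi_m <- ng + 1 - lo_m
  lo_a <- floor(ng * trim_a) + 1
  hi_a <- ng + 1 - lo_a
  rm_ <- rank(M, ties.method = "first")
  ra_ <- rank(A, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (sum(keep2) < min_genes) {
    warning("fewer than ", min_genes, " genes survive TMM trimming for sample ",
            sample_id, "; factor set to 1")
    return(1)
  }
  2^(sum(w[keep2] * M[keep2]) / sum(w[keep2]))
}

#' Transcripts-per-million from counts and gene lengths
#'
#' Standard TPM: counts are divided by gene length (rate of reads per base),
#' then each sample column is scaled to sum to one million.
#'
#' @param counts Validated count matrix.
#' @param gene_lengths Named numeric vector of positive lengths (bases)
#'   covering every gene in `counts`.
#' @return Matrix with `expr_scale` `"tpm"`; every column sums to 1e6.
#' @export
tpm_like <- function(counts, gene_lengths) {
  counts <- validate_counts(counts)
  if (is.null(names(gene_lengths)))
    stop("gene_lengths must be named by gene symbol")
  names(gene_lengths) <- toupper(names(gene_lengths))
  miss <- setdiff(rownames(counts), names(gene_lengths))
  if (length(miss) > 0L)
    stop("missing gene length(s): ", paste(utils::head(miss, 5L), collapse = ", "))
  len <- gene_lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0))
    stop("gene lengths must be positive and finite")
  rate <- counts / len
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("sample(s) with no reads after length normalization: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  out <- sweep(rate, 2L, tot, "/") * 1e6
  set_expr_scale(out, "tpm")
}
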