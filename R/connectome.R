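# Source-tissue -> target-tissue ligand-receptor connectome from TPM
# expression thresholds, secretome annotation, gradient-cluster membership,
# an interaction table, and blood-secretion curation.

#' Connectome configuration
#'
#' @param tpm_threshold Minimum TPM for a gene to count as expressed in a
#'   sample (default 25, inclusive).
#' @param sample_fraction Minimum fraction of samples at or above the TPM
#'   threshold (default 0.25, inclusive).
#' @param require_blood_secretion If `TRUE` (default), ligands must be
#'   annotated `secreted_blood`; if `FALSE`, any secreted class qualifies.
#' @return List of class `connectome_config`.
#' @export
connectome_config <- function(tpm_threshold = 25, sample_fraction = 0.25,
                              require_blood_secretion = TRUE) {
  stopifnot(tpm_threshold > 0, sample_fraction > 0, sample_fraction <= 1)
  structure(list(tpm_threshold = tpm_threshold,
                 sample_fraction = sample_fraction,
                 require_blood_secretion = require_blood_secretion),
            class = "connectome_config")
}

#' Expression filter on a TPM matrix
#'
#' Genes whose TPM is at or above `tpm_threshold` in at least
#' `sample_fraction` of samples (both bounds inclusive).
#'
#' @param expr Expression matrix on the `tpm` scale.
#' @param cfg A [connectome_config()].
#' @return Character vector of passing genes.
#' @export
expressed_filter <- function(expr, cfg = connectome_config()) {
  stop_unless_scale(expr, "tpm")
  frac <- rowMeans(expr >= cfg$tpm_threshold)
  rownames(expr)[frac >= cfg$sample_fraction]
}

# Secretion class lookup with the not_secreted default for unknown genes.
.secretion_class <- function(genes, annot) {
  cls <- stats::setNames(annot$secretion_class, annot$gene)
  out <- cls[genes]
  out[is.na(out)] <- "not_secreted"
  stats::setNames(out, genes)
}

#' Per-ligand filter report
#'
#' Evaluates each of the four ligand criteria separately for every ligand
#' appearing in the interaction table: expressed in the source tissue,
#' secreted (to blood when required), member of a gradient cluster, and
#' having at least one interaction partner expressed in the target tissue.
#' Useful for auditing why a candidate was excluded.
#'
#' @param source_expr,target_expr TPM matrices for the source and target
#'   tissues.
#' @param clusters A `cluster_set` with gradients detected.
#' @param annot Secretome annotation (see [read_annotation()]).
#' @param interactions Ligand-receptor table (see [read_interactions()]).
#' @param cfg A [connectome_config()].
#' @return data.frame: ligand, expressed, secreted, in_gradient_cluster,
#'   has_expressed_receptor, passes.
#' @export
ligand_filter_report <- function(source_expr, target_expr, clusters, annot,
                                 interactions, cfg = connectome_config()) {
  stop_unless_scale(source_expr, "tpm")
  stop_unless_scale(target_expr, "tpm")
  if (nrow(interactions) == 0L) stop("empty interaction table")
  src_ok <- expressed_filter(source_expr, cfg)
  tgt_ok <- expressed_filter(target_expr, cfg)
  grad <- gradient_members(clusters)
  ligands <- sort(unique(interactions$ligand))
  cls <- .secretion_class(ligands, annot)
  secreted <- if (cfg$require_blood_secretion) cls == "secreted_blood" else
    cls %in% c("secreted_blood", "secreted_other")
  has_rec <- vapply(ligands, function(lg) {
    any(interactions$receptor[interactions$ligand == lg] %in% tgt_ok)
  }, logical(1L))
  out <- data.frame(
    ligand = ligands,
    expressed = ligands %in% src_ok,
    secreted = unname(secreted),
    in_gradient_cluster = ligands %in% names(grad),
    has_expressed_receptor = unname(has_rec),
    stringsAsFactors = FALSE)
  out$passes <- out$expressed & out$secreted & out$in_gradient_cluster &
    out$has_expressed_receptor
  out
}

# Expression summaries used on both sides of an edge.
.expr_summary <- function(expr, gene, cfg) {
  v <- expr[gene, ]
  c(frac = mean(v >= cfg$tpm_threshold), median = stats::median(v))
}

#' Build the ligand-receptor connectome
#'
#' A ligand qualifies when it passes the source-tissue expression filter, is
#' secreted (to blood when `require_blood_secretion`), belongs to a gradient
#' cluster, and has at least one interaction partner passing the
#' target-tissue expression filter. A receptor qualifies when it passes the
#' target-tissue expression filter and is listed as a partner of a
#' qualifying ligand. One edge is emitted per qualifying (ligand, receptor)
#' pair, carrying the ligand's cluster and direction and expression
#' summaries in both tissues. Every emitted edge is re-validated against the
#' raw inputs before return.
#'
#' @inheritParams ligand_filter_report
#' @return data.frame of connectome edges: ligand, receptor,
#'   ligand_cluster, ligand_direction, ligand_frac_expressed,
#'   ligand_median_tpm, receptor_frac_expressed, receptor_median_tpm.
#' @export
build_connectome <- function(source_expr, target_expr, clusters, annot,
                             interactions, cfg = connectome_config()) {
  report <- ligand_filter_report(source_expr, target_expr, clusters, annot,
                                 interactions, cfg)
  tgt_ok <- expressed_filter(target_expr, cfg)
  grad <- gradient_members(clusters)
  passing <- report$ligand[report$passes]
  edges <- interactions[interactions$ligand %in% passing &
                          interactions$receptor %in% tgt_ok, , drop = FALSE]
  edges <- unique(edges)
  if (nrow(edges) == 0L) {
    warning("no ligand-receptor pairs pass all connectome filters")
    return(data.frame(ligand = character(), receptor = character(),
                      ligand_cluster = character(), ligand_direction = character(),
                      ligand_frac_expressed = numeric(), ligand_median_tpm = numeric(),
                      receptor_frac_expressed = numeric(),
                      receptor_median_tpm = numeric()))
  }
  assignment <- clusters$assignment
  lsum <- t(vapply(edges$ligand, .expr_summary, numeric(2L), expr = source_expr,
                   cfg = cfg))
  rsum <- t(vapply(edges$receptor, .expr_summary, numeric(2L), expr = target_expr,
                   cfg = cfg))
  out <- data.frame(
    ligand = edges$ligand,
    receptor = edges$receptor,
    ligand_cluster = unname(assignment[edges$ligand]),
    ligand_direction = unname(grad[edges$ligand]),
    ligand_frac_expressed = lsum[, "frac"],
    ligand_median_tpm = lsum[, "median"],
    receptor_frac_expressed = rsum[, "frac"],
    receptor_median_tpm = rsum[, "median"],
    stringsAsFactors = FALSE)
  out <- out[order(out$ligand, out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  # self-audit: each emitted edge must re-validate against the raw inputs
  for (i in seq_len(nrow(out))) {
    lg <- out$ligand[i]; rc <- out$receptor[i]
    stopifnot(
      mean(source_expr[lg, ] >= cfg$tpm_threshold) >= cfg$sample_fraction,
      mean(target_expr[rc, ] >= cfg$tpm_threshold) >= cfg$sample_fraction,
      lg %in% names(grad),
      any(interactions$ligand == lg & interactions$receptor == rc))
    cls <- .secretion_class(lg, annot)
    stopifnot(if (cfg$require_blood_secretion) cls == "secreted_blood" else
      cls != "not_secreted")
  }
  out
}

#' Enrichment of connectome genes
#'
#' Over-representation analysis (see [ora()]) of the union of connectome
#' ligands and receptors.
#'
#' @param edges Connectome edge table from [build_connectome()].
#' @param sets Named list of gene sets.
#' @param universe Background gene vector.
#' @param alpha FDR threshold (default 0.05).
#' @return [ora()] result table.
#' @export
connectome_enrichment <- function(edges, sets, universe, alpha = 0.05) {
  if (nrow(edges) == 0L) stop("connectome has no edges")
  genes <- union(edges$ligand, edges$receptor)
  ora(genes, sets, universe, alpha = alpha)
}
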