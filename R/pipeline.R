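# End-to-end convenience wrapper: normalize -> differential expression ->
# trajectory clustering -> connectome, on a simulated or user-supplied study.

#' Run the full analysis pipeline
#'
#' Convenience wrapper chaining the pipeline stages on a simulated study (or
#' any list with the same elements): log10-CPM + moderated differential
#' expression per sex against the youngest reference, union-DEG trajectory
#' clustering with gradient detection and AUC ratios on TMM-scaled CPM,
#' SASP profiling, TPM-threshold ligand-receptor connectome construction,
#' and cell-type signature scoring with the trend-across-age test.
#'
#' @param sim A `viscage_sim` (see [simulate_study()]) or a list with
#'   elements `vat_counts`, `liver_counts`, `samples`, `gene_lengths`,
#'   `annotation`, `interactions`, `sasp_genes`, `signatures`.
#' @param de_cfg A [de_config()].
#' @param conn_cfg A [connectome_config()].
#' @param k Number of k-means clusters (default 11).
#' @param kmeans_seed Seed for the clustering restarts (default 7).
#' @param rho_min Gradient (monotonicity) threshold (default 0.9).
#' @return List: `de` (combined male+female result table), `degs`
#'   (union-DEG vector), `clusters` (`cluster_set` with gradients),
#'   `trajectories` (z-scored mean-trajectory matrix), `profiles` (AUC
#'   table), `sasp` (SASP profile), `connectome` (edge table), `scores`
#'   (signature scores), `trends` (trend-test table).
#' @export
run_pipeline <- function(sim, de_cfg = de_config(),
                         conn_cfg = connectome_config(),
                         k = 11L, kmeans_seed = 7L, rho_min = 0.9) {
  log_expr <- log10_cpm(sim$vat_counts)
  de <- rbind(
    moderated_test(log_expr, sim$samples, sex = "male", cfg = de_cfg),
    moderated_test(log_expr, sim$samples, sex = "female", cfg = de_cfg))
  degs <- deg_union(de)
  if (length(degs) < k)
    stop("fewer union DEGs (", length(degs), ") than clusters (", k, ")")

  tmm <- tmm_factors(sim$vat_counts)
  expr_tmm <- tmm_cpm(sim$vat_counts, tmm)
  traj <- mean_trajectories(expr_tmm, sim$samples, degs)
  clusters <- kmeans_cluster(traj, k = k, seed = kmeans_seed)
  clusters <- detect_gradients(clusters, rho_min = rho_min)
  profiles <- auc_ratio(expr_tmm, sim$samples, clusters)

  sasp <- sasp_profile(de, sim$sasp_genes)

  vat_tpm <- tpm_like(sim$vat_counts, sim$gene_lengths)
  liver_tpm <- tpm_like(sim$liver_counts, sim$gene_lengths)
  connectome <- build_connectome(vat_tpm, liver_tpm, clusters, sim$annotation,
                                 sim$interactions, conn_cfg)

  scores <- signature_scores(vat_tpm, sim$signatures)
  trends <- trend_test(scores, sim$samples)

  list(de = de, degs = degs, clusters = clusters, trajectories = traj,
       profiles = profiles, sasp = sasp, connectome = connectome,
       scores = scores, trends = trends)
}

#' Write pipeline outputs to a directory
#'
#' Deterministic TSV outputs for every pipeline product, so that two runs
#' with the same seeds are byte-identical on disk.
#'
#' @param result List from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(result$de, file.path(dir, "de.tsv"))
  writeLines(result$degs, file.path(dir, "degs.txt"))
  assign_df <- data.frame(gene = names(result$clusters$assignment),
                          cluster = unname(result$clusters$assignment),
                          stringsAsFactors = FALSE)
  write_table(assign_df, file.path(dir, "clusters.tsv"))
  write_table(result$clusters$centroids, file.path(dir, "centroids.tsv"))
  write_table(result$clusters$gradient, file.path(dir, "gradients.tsv"))
  write_table(result$profiles, file.path(dir, "profiles.tsv"))
  write_table(result$sasp, file.path(dir, "sasp_profile.tsv"))
  write_table(result$connectome, file.path(dir, "connectome.tsv"))
  write_table(result$scores, file.path(dir, "signature_scores.tsv"))
  write_table(result$trends, file.path(dir, "trends.tsv"))
  invisible(dir)
}
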