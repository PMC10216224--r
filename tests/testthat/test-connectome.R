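# Ligand-receptor connectome construction from TPM thresholds, secretome
# annotation, gradient-cluster membership and interaction wiring.

test_that("expressed_filter applies inclusive bounds on both thresholds", {
  m <- rbind(
    EXACT = c(25, 25, 10, 10),   # exactly 25 TPM in exactly 25% -> passes
    LOW   = rep(24.9, 4),        # never reaches the threshold -> fails
    ONE   = c(30, 1, 1, 1),      # 1 of 4 = 0.25 -> passes
    HIGH  = rep(100, 4))
  colnames(m) <- sprintf("S%d", 1:4)
  got <- expressed_filter(as_tpm(m), connectome_config(25, 0.5))
  expect_setequal(got, c("HIGH", "EXACT"))
  got2 <- expressed_filter(as_tpm(m), connectome_config(25, 0.25))
  expect_setequal(got2, c("HIGH", "EXACT", "ONE"))
  expect_error(expressed_filter(m), "tpm")
})

test_that("build_connectome recovers exactly the planted wiring", {
  sim <- small_sim(19)
  res <- run_pipeline(sim)
  truth <- sim$truth$connectome_edges
  got <- res$connectome
  expect_identical(nrow(got), nrow(truth))
  expect_setequal(paste(got$ligand, got$receptor),
                  paste(truth$ligand, truth$receptor))
  # directions carried from the gradient clusters are consistent with truth
  gt <- sim$truth$gene_table
  for (i in seq_len(nrow(got))) {
    tpl <- gt$template[gt$gene == got$ligand[i]]
    expect_identical(got$ligand_direction[i],
                     if (grepl("^inc", tpl)) "increasing" else "decreasing")
  }
})

test_that("each decoy fails exactly its planted filter", {
  sim <- small_sim(19)
  res <- run_pipeline(sim)
  vat_tpm <- tpm_like(sim$vat_counts, sim$gene_lengths)
  liver_tpm <- tpm_like(sim$liver_counts, sim$gene_lengths)
  rep_tab <- ligand_filter_report(vat_tpm, liver_tpm, res$clusters,
                                  sim$annotation, sim$interactions)
  checks <- c(low_tpm = "expressed", not_secreted = "secreted",
              secreted_other = "secreted",
              non_gradient_cluster = "in_gradient_cluster",
              silent_receptor = "has_expressed_receptor")
  crit <- c("expressed", "secreted", "in_gradient_cluster",
            "has_expressed_receptor")
  for (reason in names(checks)) {
    row <- rep_tab[rep_tab$ligand == sim$truth$decoys[[reason]], ]
    expect_false(row$passes)
    failed <- crit[!unlist(row[crit])]
    expect_identical(failed, unname(checks[reason]))
  }
  # true ligands pass everything
  lig <- sim$truth$connectome_edges$ligand
  expect_true(all(rep_tab$passes[rep_tab$ligand %in% lig]))
})

test_that("relaxing blood-secretion admits the secreted_other decoy only", {
  sim <- small_sim(19)
  res <- run_pipeline(sim)
  vat_tpm <- tpm_like(sim$vat_counts, sim$gene_lengths)
  liver_tpm <- tpm_like(sim$liver_counts, sim$gene_lengths)
  relaxed <- connectome_config(require_blood_secretion = FALSE)
  edges <- build_connectome(vat_tpm, liver_tpm, res$clusters, sim$annotation,
                            sim$interactions, relaxed)
  extra <- setdiff(unique(edges$ligand), sim$truth$connectome_edges$ligand)
  expect_identical(extra, unname(sim$truth$decoys["secreted_other"]))
})

test_that("raising thresholds never adds an edge (monotonicity)", {
  sim <- small_sim(23)
  res <- run_pipeline(sim)
  vat_tpm <- tpm_like(sim$vat_counts, sim$gene_lengths)
  liver_tpm <- tpm_like(sim$liver_counts, sim$gene_lengths)
  grid_t <- c(5, 25, 100, 500, 1500)
  grid_f <- c(0.05, 0.25, 0.5, 0.75, 1)
  edge_sets <- matrix(vector("list", 25), 5, 5)
  for (i in seq_along(grid_t)) for (j in seq_along(grid_f)) {
    e <- suppressWarnings(build_connectome(
      vat_tpm, liver_tpm, res$clusters, sim$annotation, sim$interactions,
      connectome_config(grid_t[i], grid_f[j])))
    edge_sets[[i, j]] <- paste(e$ligand, e$receptor)
  }
  for (i in 1:5) for (j in 1:5) {
    if (i < 5) expect_true(all(edge_sets[[i + 1, j]] %in% edge_sets[[i, j]]))
    if (j < 5) expect_true(all(edge_sets[[i, j + 1]] %in% edge_sets[[i, j]]))
  }
})

test_that("two qualifying receptors give two edges; degenerate inputs handled", {
  tpm_src <- as_tpm(matrix(100, 2, 4, dimnames = list(c("LIG", "OTHER"),
                                                      sprintf("S%d", 1:4))))
  tpm_tgt <- as_tpm(matrix(c(100, 100, 100, 100, 100, 100, 100, 100, 0, 0, 0, 0),
                           3, 4, byrow = TRUE,
                           dimnames = list(c("R1", "R2", "R3"),
                                           sprintf("T%d", 1:4))))
  cl <- structure(list(assignment = c(LIG = "A"),
                       centroids = rbind(A = 6:1), sizes = c(A = 1), k = 1,
                       gradient = data.frame(cluster = "A", rho = -1,
                                             gradient = TRUE,
                                             direction = "decreasing")),
                  class = "cluster_set")
  annot <- data.frame(gene = "LIG", secretion_class = "secreted_blood")
  inter <- data.frame(ligand = rep("LIG", 3), receptor = c("R1", "R2", "R3"))
  edges <- build_connectome(tpm_src, tpm_tgt, cl, annot, inter)
  expect_identical(nrow(edges), 2L)
  expect_setequal(edges$receptor, c("R1", "R2"))
  expect_error(build_connectome(tpm_src, tpm_tgt, cl, annot,
                                inter[0, ]), "empty interaction")
  silent <- inter[3, ]
  expect_warning(none <- build_connectome(tpm_src, tpm_tgt, cl, annot, silent),
                 "no ligand-receptor")
  expect_identical(nrow(none), 0L)
})

test_that("connectome enrichment flags the planted pathway", {
  universe <- sprintf("G%03d", 1:1000)
  lig <- universe[1:12]; rec <- universe[13:24]
  edges <- data.frame(ligand = lig, receptor = rec)
  sets <- list(hit = c(universe[1:7], universe[900:922]),
               miss = universe[500:529])
  out <- connectome_enrichment(edges, sets, universe)
  expect_identical(out$set[1], "hit")
  expect_equal(out$p[out$set == "hit"],
               hyper_brute(7, 30, 24, 1000), tolerance = 1e-12)
  expect_false(out$reportable[out$set == "miss"])
})
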