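# Negative binomial simulator with planted ground truth: trajectory
# templates, a SASP panel, cell-type mixing trends, secreted-ligand /
# liver-receptor wiring and single-filter decoys. Emulates the two-tissue
# (visceral fat + liver), two-sex, six-age-group GTEx-style design so that
# every pipeline stage is testable without downloads.

#' Planted trajectory shape templates
#'
#' Eleven age-trajectory shapes on a common [0, 1] scale over the six age
#' groups: four monotone (three decreasing with distinct kinetics, one
#' increasing) and seven non-monotone (peaks, troughs, a zigzag). A gene
#' following template T with effect amplitude a has group-j log2 shift
#' `a * (T[j] - T[1])`, so the youngest group is always the baseline.
#'
#' @return 11 x 6 matrix with rownames naming the shapes and a logical
#'   `monotone` attribute flagging the four monotone templates.
#' @export
trajectory_templates <- function() {
  tpl <- rbind(
    dec_linear = c(1, 0.8, 0.6, 0.4, 0.2, 0),
    dec_early  = c(1, 0.45, 0.2, 0.1, 0.05, 0),
    dec_late   = c(1, 0.95, 0.9, 0.8, 0.55, 0),
    inc_linear = c(0, 0.2, 0.4, 0.6, 0.8, 1),
    peak_2     = c(0, 1, 0.5, 0.2, 0.1, 0),
    peak_3     = c(0, 0.5, 1, 0.5, 0.2, 0),
    peak_4     = c(0, 0.2, 0.5, 1, 0.5, 0),
    peak_5     = c(0, 0.1, 0.3, 0.5, 1, 0.2),
    trough_2   = c(1, 0, 0.3, 0.6, 0.8, 1),
    trough_4   = c(1, 0.7, 0.4, 0, 0.5, 1),
    zigzag     = c(0, 1, 0, 1, 0, 1))
  colnames(tpl) <- age_groups()
  attr(tpl, "monotone") <- stats::setNames(
    rownames(tpl) %in% c("dec_linear", "dec_early", "dec_late", "inc_linear"),
    rownames(tpl))
  tpl
}

#' Simulation configuration
#'
#' Defaults mirror the study design the package targets: a 241-male /
#' 114-female visceral-fat cohort and a 161-male / 65-female liver cohort
#' across six age decades (small youngest and oldest bins, largest at
#' 50-59), negative binomial counts with dispersion 0.1, 8-12M library
#' sizes, 2-log2-unit (4-fold) planted effects, and a one-group delayed
#' female onset echoing the later appearance of female DEGs.
#'
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param genes_total Total number of genes (default 6000).
#' @param vat_samples,liver_samples Named lists (male, female) of per-age
#'   group sample counts, in [age_groups()] order.
#' @param nb_dispersion Negative binomial dispersion phi, so
#'   `var = mu + phi * mu^2` (default 0.1).
#' @param library_size_range Uniform range of per-sample library sizes.
#' @param genes_per_template Planted genes per trajectory template
#'   (default 40).
#' @param effect_amplitude Maximum |log2 fold change| of a template gene vs
#'   the youngest group (default 2, i.e. 4-fold).
#' @param female_delay Female trajectory onset delay in age-group steps
#'   (default 1).
#' @param sasp_size SASP panel size, drawn from the increasing template
#'   (default 20).
#' @param n_ligands,n_receptors Planted qualifying ligands wired to
#'   expressed liver receptors (defaults 6 and 8).
#' @param n_decoys Number of decoy ligands, each violating exactly one
#'   connectome filter; fixed at 5 (one per filter violation).
#' @param cell_type_slopes Named log2-per-age-step slopes of the planted
#'   cell-type mixing trends driving the marker genes.
#' @param markers_per_type Marker genes per cell type (default 15).
#' @param background_edges Random background edges in the gene-gene network
#'   (default 300).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       genes_total = 6000L,
                       vat_samples = list(male = c(14L, 18L, 32L, 93L, 75L, 9L),
                                          female = c(11L, 10L, 25L, 31L, 34L, 3L)),
                       liver_samples = list(male = c(4L, 14L, 24L, 60L, 56L, 3L),
                                            female = c(3L, 3L, 11L, 23L, 23L, 2L)),
                       nb_dispersion = 0.1,
                       library_size_range = c(8e6, 12e6),
                       genes_per_template = 40L,
                       effect_amplitude = 2,
                       female_delay = 1L,
                       sasp_size = 20L,
                       n_ligands = 6L,
                       n_receptors = 8L,
                       n_decoys = 5L,
                       cell_type_slopes = c(adipocyte = -0.3, preadipocyte = -0.25,
                                            fibroblast = 0.3, tcell = 0.2),
                       markers_per_type = 15L,
                       background_edges = 300L) {
  stopifnot(genes_total > 0, nb_dispersion > 0, genes_per_template > 0,
            effect_amplitude >= 0, sasp_size > 0, n_ligands > 0,
            n_receptors >= n_ligands, markers_per_type >= 3,
            length(library_size_range) == 2L,
            all(library_size_range > 0))
  if (n_decoys != 5L)
    stop("n_decoys is fixed at 5: one decoy per connectome filter violation")
  for (tab in c(vat_samples, liver_samples))
    stopifnot(length(tab) == 6L, all(tab >= 1L))
  tpl <- trajectory_templates()
  n_template_genes <- nrow(tpl) * genes_per_template
  n_roles <- n_receptors + 1L + length(cell_type_slopes) * markers_per_type
  if (genes_total < n_template_genes + n_roles + 100L)
    stop("genes_total too small for the planted design")
  if (sasp_size + 10L > genes_per_template)
    stop("sasp_size must leave room in the increasing template")
  structure(list(seed = seed, genes_total = genes_total,
                 vat_samples = vat_samples, liver_samples = liver_samples,
                 nb_dispersion = nb_dispersion,
                 library_size_range = library_size_range,
                 genes_per_template = genes_per_template,
                 effect_amplitude = effect_amplitude,
                 female_delay = female_delay, sasp_size = sasp_size,
                 n_ligands = n_ligands, n_receptors = n_receptors,
                 n_decoys = n_decoys, cell_type_slopes = cell_type_slopes,
                 markers_per_type = markers_per_type,
                 background_edges = background_edges),
            class = "sim_config")
}

# Rescale the expected CPM of the genes in `targets` (named by gene, values
# in TPM) so their expected TPM is exactly the target given the other
# genes' length-normalized rates. Closed form: with S_rest the rate sum of
# untouched genes and T the summed targets, each pinned gene needs rate
# r_g = t_g * S_rest / (1e6 - T).
.pin_expected_tpm <- function(q, lengths, targets) {
  stopifnot(sum(targets) < 1e6)
  adj <- names(targets)
  rest <- setdiff(names(q), adj)
  s_rest <- sum(q[rest] / lengths[rest])
  r <- targets * s_rest / (1e6 - sum(targets))
  q[adj] <- r * lengths[adj]
  q
}

# sample table for one tissue from a (male, female) list of per-group counts
.build_samples <- function(counts_by_sex, tissue) {
  rows <- list()
  for (sx in c("male", "female")) {
    for (j in seq_along(age_groups())) {
      n <- counts_by_sex[[sx]][j]
      if (n == 0L) next
      grp <- age_groups()[j]
      ids <- sprintf("%s_%s_%s_%02d", toupper(tissue),
                     toupper(substr(sx, 1L, 1L)), gsub("-", "", grp), seq_len(n))
      rows[[paste(sx, grp)]] <- data.frame(
        sample_id = ids, sex = sx, age_group = grp, tissue = tissue,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# NB count matrix for one tissue: q is expected CPM per gene, delta is a
# list (male, female) of genes x 6 log2-shift matrices.
.simulate_counts <- function(q, delta, samples, lib_range, dispersion) {
  n_s <- nrow(samples)
  lib <- stats::runif(n_s, lib_range[1L], lib_range[2L])
  grp_idx <- match(as.character(samples$age_group), age_groups())
  mat <- matrix(0, nrow = length(q), ncol = n_s,
                dimnames = list(names(q), samples$sample_id))
  for (s in seq_len(n_s)) {
    d <- delta[[samples$sex[s]]][, grp_idx[s]]
    mu <- q * 2^d / 1e6 * lib[s]
    mat[, s] <- stats::rnbinom(length(q), mu = mu, size = 1 / dispersion)
  }
  storage.mode(mat) <- "integer"
  mat
}

#' Simulate the full planted study
#'
#' Generates every input the pipeline consumes, with ground truth: visceral
#' fat and liver count matrices, sample metadata, gene lengths, secretome
#' annotation, ligand-receptor interactions, a gene-gene network edge list,
#' a SASP panel, cell-type signature sets, and the planted-truth tables.
#'
#' Baseline expected CPM is log-normal. Template genes shift their group
#' means along their trajectory template scaled to the configured amplitude,
#' with the female onset delayed by `female_delay` age groups. Counts are
#' negative binomial with `var = mu + phi mu^2`. The liver matrix expresses
#' the planted receptors constitutively above the connectome TPM threshold
#' and the decoy-target receptor below it. Cell-type marker genes follow the
#' planted mixing-trend slopes. Ligand decoys each violate exactly one
#' connectome filter: below-threshold expression, not secreted, secreted
#' but not to blood, non-gradient cluster, or a target-silent receptor.
#'
#' @param cfg A [sim_config()].
#' @return List of class `viscage_sim` with elements `vat_counts`,
#'   `liver_counts`, `samples`, `gene_lengths`, `annotation`,
#'   `interactions`, `edge_list`, `sasp_genes`, `signatures`, `truth`
#'   (list: gene_table, connectome_edges, decoys, cell_type_slopes,
#'   monotone_templates), and `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tpl <- trajectory_templates()
  monotone <- attr(tpl, "monotone")
  n_tpl <- nrow(tpl)
  gpt <- cfg$genes_per_template
  genes <- sprintf("G%05d", seq_len(cfg$genes_total))

  gene_table <- data.frame(gene = genes, template = NA_character_,
                           role = "background", decoy_reason = NA_character_,
                           cell_type = NA_character_, stringsAsFactors = FALSE)
  tpl_genes <- split(genes[seq_len(n_tpl * gpt)],
                     rep(rownames(tpl), each = gpt))
  for (tn in rownames(tpl))
    gene_table$template[match(tpl_genes[[tn]], genes)] <- tn

  nxt <- n_tpl * gpt  # cursor into the background block
  take_background <- function(n) {
    out <- genes[nxt + seq_len(n)]
    nxt <<- nxt + n
    out
  }

  # roles: ligands spread round-robin over the 4 monotone templates
  mono_names <- names(monotone)[monotone]
  lig_tpl <- rep(mono_names, length.out = cfg$n_ligands)
  used <- stats::setNames(rep(0L, n_tpl), rownames(tpl))
  take_tpl_gene <- function(tn) {
    used[tn] <<- used[tn] + 1L
    tpl_genes[[tn]][used[tn]]
  }
  ligands <- vapply(lig_tpl, take_tpl_gene, character(1L))
  decoy_reason <- c("low_tpm", "not_secreted", "secreted_other",
                    "non_gradient_cluster", "silent_receptor")
  decoy_tpl <- c("dec_linear", "dec_early", "dec_late", "peak_3", "inc_linear")
  decoys <- vapply(decoy_tpl, take_tpl_gene, character(1L))
  names(decoys) <- decoy_reason
  receptors <- take_background(cfg$n_receptors)
  silent_receptor <- take_background(1L)
  markers <- lapply(cfg$cell_type_slopes, function(s)
    take_background(cfg$markers_per_type))
  # SASP panel from the increasing template, past the reserved role genes
  sasp_genes <- tpl_genes[["inc_linear"]][10L + seq_len(cfg$sasp_size)]

  gene_table$role[match(ligands, genes)] <- "ligand"
  gene_table$role[match(decoys, genes)] <- "decoy"
  gene_table$decoy_reason[match(decoys, genes)] <- decoy_reason
  gene_table$role[match(receptors, genes)] <- "receptor"
  gene_table$role[match(silent_receptor, genes)] <- "receptor_silent"
  for (ct in names(markers)) {
    gene_table$role[match(markers[[ct]], genes)] <- "marker"
    gene_table$cell_type[match(markers[[ct]], genes)] <- ct
  }
  gene_table$role[match(sasp_genes, genes)] <- "sasp"

  gene_lengths <- stats::setNames(
    round(stats::rlnorm(cfg$genes_total, meanlog = log(2000), sdlog = 0.4)),
    genes)

  # baseline expected CPM: log-normal background, boosted planted genes
  log2q <- stats::rnorm(cfg$genes_total, mean = 3, sd = 2)
  planted <- !is.na(gene_table$template)
  log2q[planted] <- pmax(stats::rnorm(sum(planted), mean = 5, sd = 1), 2)
  for (ct in names(markers))
    log2q[match(markers[[ct]], genes)] <-
      pmax(stats::rnorm(length(markers[[ct]]), mean = 5, sd = 1), 2)
  q_vat <- 2^log2q
  q_vat <- q_vat / sum(q_vat) * 1e6
  names(q_vat) <- genes
  # pin role genes to target expected TPM: qualifying ligands and the
  # filter-decoys far above the 25-TPM threshold, the low-TPM decoy far below
  vat_targets <- c(stats::setNames(rep(1000, length(ligands)), ligands),
                   stats::setNames(c(5, 1000, 1000, 1000, 1000), unname(decoys)))
  q_vat <- .pin_expected_tpm(q_vat, gene_lengths, vat_targets)

  # liver baseline: independent background, receptors constitutively high,
  # the decoy-target receptor silent
  log2q_liv <- stats::rnorm(cfg$genes_total, mean = 3, sd = 2)
  q_liv <- 2^log2q_liv
  q_liv <- q_liv / sum(q_liv) * 1e6
  names(q_liv) <- genes
  liv_targets <- c(stats::setNames(rep(1000, length(receptors)), receptors),
                   stats::setNames(1, silent_receptor))
  q_liv <- .pin_expected_tpm(q_liv, gene_lengths, liv_targets)

  # per-sex log2 shift matrices (genes x 6)
  shift_for <- function(delay) {
    d <- matrix(0, cfg$genes_total, 6L, dimnames = list(genes, age_groups()))
    jj <- pmax(seq_len(6L) - 1L - delay, 0L) + 1L  # delayed template index
    for (tn in rownames(tpl)) {
      rows <- match(tpl_genes[[tn]], genes)
      d[rows, ] <- matrix(cfg$effect_amplitude * (tpl[tn, jj] - tpl[tn, 1L]),
                          nrow = length(rows), ncol = 6L, byrow = TRUE)
    }
    for (ct in names(markers)) {
      rows <- match(markers[[ct]], genes)
      d[rows, ] <- matrix(cfg$cell_type_slopes[[ct]] * (jj - 1L),
                          nrow = length(rows), ncol = 6L, byrow = TRUE)
    }
    d
  }
  delta_vat <- list(male = shift_for(0L), female = shift_for(cfg$female_delay))
  delta_liv <- list(male = matrix(0, cfg$genes_total, 6L),
                    female = matrix(0, cfg$genes_total, 6L))

  vat_samples <- .build_samples(cfg$vat_samples, "vat")
  liver_samples <- .build_samples(cfg$liver_samples, "liver")
  vat_counts <- .simulate_counts(q_vat, delta_vat, vat_samples,
                                 cfg$library_size_range, cfg$nb_dispersion)
  liver_counts <- .simulate_counts(q_liv, delta_liv, liver_samples,
                                   cfg$library_size_range, cfg$nb_dispersion)

  # annotation: planted classes plus secreted background noise (kept off the
  # interaction table so no decoy-by-accident arises)
  annot <- data.frame(gene = c(ligands, decoys),
                      secretion_class = c(rep("secreted_blood", length(ligands)),
                                          "secreted_blood", "not_secreted",
                                          "secreted_other", "secreted_blood",
                                          "secreted_blood"),
                      stringsAsFactors = FALSE)
  noise_secreted <- take_background(60L)
  annot <- rbind(annot, data.frame(
    gene = noise_secreted,
    secretion_class = rep(c("secreted_other", "secreted_blood"), c(40L, 20L)),
    stringsAsFactors = FALSE))

  # interactions: planted wiring (each ligand one receptor; the first two
  # ligands gain a second receptor so all receptors are used), decoy wiring,
  # and inert background pairs
  planted_edges <- data.frame(ligand = ligands,
                              receptor = receptors[seq_len(cfg$n_ligands)],
                              stringsAsFactors = FALSE)
  extra <- cfg$n_receptors - cfg$n_ligands
  if (extra > 0L)
    planted_edges <- rbind(planted_edges, data.frame(
      ligand = ligands[seq_len(extra)],
      receptor = receptors[cfg$n_ligands + seq_len(extra)],
      stringsAsFactors = FALSE))
  decoy_edges <- data.frame(
    ligand = unname(decoys),
    receptor = c(receptors[seq_len(4L)], silent_receptor),
    stringsAsFactors = FALSE)
  bg_pair_genes <- take_background(40L)
  bg_edges <- data.frame(ligand = bg_pair_genes[seq_len(20L)],
                         receptor = bg_pair_genes[20L + seq_len(20L)],
                         stringsAsFactors = FALSE)
  interactions <- rbind(planted_edges, decoy_edges, bg_edges)
  rownames(interactions) <- NULL

  # gene-gene network: a chain plus random extra edges within each template,
  # random weak background edges
  edge_rows <- list()
  for (tn in rownames(tpl)) {
    g <- tpl_genes[[tn]]
    chain <- data.frame(gene_a = g[-length(g)], gene_b = g[-1L],
                        weight = stats::runif(length(g) - 1L, 0.5, 1),
                        stringsAsFactors = FALSE)
    ii <- sample.int(length(g), 20L, replace = TRUE)
    jj2 <- sample.int(length(g), 20L, replace = TRUE)
    ok <- ii != jj2
    extra_e <- data.frame(gene_a = g[ii[ok]], gene_b = g[jj2[ok]],
                          weight = stats::runif(sum(ok), 0.5, 1),
                          stringsAsFactors = FALSE)
    edge_rows[[tn]] <- rbind(chain, extra_e)
  }
  bi <- sample.int(cfg$genes_total, cfg$background_edges, replace = TRUE)
  bj <- sample.int(cfg$genes_total, cfg$background_edges, replace = TRUE)
  okb <- bi != bj
  edge_rows[["background"]] <- data.frame(
    gene_a = genes[bi[okb]], gene_b = genes[bj[okb]],
    weight = stats::runif(sum(okb), 0.1, 0.5), stringsAsFactors = FALSE)
  edge_list <- do.call(rbind, edge_rows)
  key <- ifelse(edge_list$gene_a < edge_list$gene_b,
                paste(edge_list$gene_a, edge_list$gene_b),
                paste(edge_list$gene_b, edge_list$gene_a))
  edge_list <- edge_list[!duplicated(key), , drop = FALSE]
  rownames(edge_list) <- NULL

  signatures <- lapply(markers, identity)

  truth <- list(gene_table = gene_table,
                connectome_edges = planted_edges[order(planted_edges$ligand,
                                                       planted_edges$receptor), ],
                decoys = decoys,
                cell_type_slopes = cfg$cell_type_slopes,
                monotone_templates = mono_names)
  rownames(truth$connectome_edges) <- NULL

  structure(list(vat_counts = vat_counts, liver_counts = liver_counts,
                 samples = rbind(vat_samples, liver_samples),
                 gene_lengths = gene_lengths, annotation = annot,
                 interactions = interactions, edge_list = edge_list,
                 sasp_genes = sasp_genes, signatures = signatures,
                 truth = truth, config = cfg),
            class = "viscage_sim")
}

#' Two-group negative binomial simulation
#'
#' A minimal planted differential-expression benchmark: `n_genes` genes,
#' two groups of `n_per_group` samples, the first `n_de` genes shifted by
#' `log2_fc` log2 units in group 2, NB counts with the given dispersion.
#' Used for error-control and power calibration of the moderated test.
#'
#' @param n_genes,n_per_group,n_de,log2_fc,dispersion,seed Scalars.
#' @param lib_range Library size range (default 8-12M).
#' @return List: `counts`, `group` (factor of 1/2), `de_genes`.
#' @export
simulate_two_group <- function(n_genes = 5000L, n_per_group = 10L, n_de = 0L,
                               log2_fc = 2, dispersion = 0.1, seed = 1L,
                               lib_range = c(8e6, 12e6)) {
  stopifnot(n_de <= n_genes)
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  log2q <- pmax(stats::rnorm(n_genes, mean = 5, sd = 1.5), 1)
  q <- 2^log2q
  q <- q / sum(q) * 1e6
  n_s <- 2L * n_per_group
  lib <- stats::runif(n_s, lib_range[1L], lib_range[2L])
  group <- rep(c(1L, 2L), each = n_per_group)
  shift <- ifelse(seq_len(n_genes) <= n_de, log2_fc, 0)
  counts <- vapply(seq_len(n_s), function(s) {
    mu <- q * 2^(shift * (group[s] == 2L)) / 1e6 * lib[s]
    stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }, numeric(n_genes))
  dimnames(counts) <- list(genes, sprintf("S%03d", seq_len(n_s)))
  list(counts = counts, group = factor(group),
       de_genes = genes[seq_len(n_de)])
}

#' Write all simulated inputs to a directory
#'
#' Emits every file the pipeline reads: count TSVs, sample table, gene
#' lengths, annotation, interactions, network edge list, SASP gene list,
#' signature GMT, and the ground-truth gene table. Writing is
#' deterministic: the same simulation writes byte-identical files.
#'
#' @param sim A `viscage_sim` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  stopifnot(inherits(sim, "viscage_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_table(sim$vat_counts, file.path(dir, "vat_counts.tsv"))
  write_table(sim$liver_counts, file.path(dir, "liver_counts.tsv"))
  write_table(sim$samples, file.path(dir, "samples.tsv"))
  write_table(data.frame(gene = names(sim$gene_lengths),
                         length = as.integer(sim$gene_lengths)),
              file.path(dir, "gene_lengths.tsv"))
  write_table(sim$annotation, file.path(dir, "annotation.tsv"))
  write_table(sim$interactions, file.path(dir, "interactions.tsv"))
  write_table(sim$edge_list, file.path(dir, "network_edges.tsv"))
  writeLines(sim$sasp_genes, file.path(dir, "sasp_genes.txt"))
  gmt <- vapply(names(sim$signatures), function(nm)
    paste(c(nm, "planted", sim$signatures[[nm]]), collapse = "\t"),
    character(1L))
  writeLines(unname(gmt), file.path(dir, "signatures.gmt"))
  write_table(sim$truth$gene_table, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
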