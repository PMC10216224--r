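# K-means clustering of union-DEG mean age trajectories, gradient (monotone)
# cluster detection, and per-sex (0,1)-normalized trajectory AUC ratios.

#' Row z-score (population sd)
#'
#' Centers and scales each row by its mean and population (n-denominator)
#' standard deviation.
#'
#' @param x Numeric matrix.
#' @return Matrix of z-scored rows; constant rows yield NaN.
#' @keywords internal
row_zscore <- function(x) {
  m <- rowMeans(x)
  s <- sqrt(rowMeans((x - m)^2))
  (x - m) / s
}

#' Trapezoidal area under a curve
#'
#' @param y Numeric vector of curve values.
#' @param x Abscissae; defaults to the unit-spaced ordinal axis
#'   `0, 1, ..., length(y) - 1`.
#' @return Trapezoidal AUC.
#' @export
trapezoid_auc <- function(y, x = seq_along(y) - 1) {
  stopifnot(length(y) == length(x), length(y) >= 2L)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

#' Mean age-group trajectories, z-scored for clustering
#'
#' For each gene, averages expression over the samples of each age group
#' (pooling sexes unless `sex` is given) and z-scores the resulting
#' 6-point trajectory (population sd). Genes with a constant trajectory are
#' dropped with a warning.
#'
#' @param expr Expression matrix on the `tmm_cpm` (or `cpm`) scale.
#' @param samples Sample table.
#' @param genes Genes to include (typically the union-DEG list).
#' @param sex Optional: restrict to one sex.
#' @param tissue Tissue (default "vat").
#' @param zscore If `FALSE`, return raw group means instead.
#' @return Matrix of genes x age groups.
#' @export
mean_trajectories <- function(expr, samples, genes, sex = NULL, tissue = "vat",
                              zscore = TRUE) {
  samples <- validate_sample_table(samples)
  sub <- samples[samples$tissue == tissue & samples$sample_id %in% colnames(expr), ,
                 drop = FALSE]
  if (!is.null(sex)) sub <- sub[sub$sex == sex, , drop = FALSE]
  groups <- age_groups()
  if (!all(groups %in% sub$age_group))
    stop("every age group needs at least 1 sample")
  genes <- intersect(toupper(genes), rownames(expr))
  if (length(genes) == 0L) stop("none of the requested genes are in expr")
  mm <- vapply(groups, function(g) {
    ids <- sub$sample_id[sub$age_group == g]
    rowMeans(expr[genes, ids, drop = FALSE])
  }, numeric(length(genes)))
  if (!is.matrix(mm)) mm <- matrix(mm, nrow = 1L)
  dimnames(mm) <- list(genes, groups)
  if (!zscore) return(mm)
  z <- row_zscore(mm)
  const <- !is.finite(rowSums(z))
  if (any(const)) {
    warning(sum(const), " constant-trajectory gene(s) dropped: ",
            paste(utils::head(genes[const], 5L), collapse = ", "))
    z <- z[!const, , drop = FALSE]
  }
  z
}

# k-means++ greedy seeding: first center uniform, later centers sampled
# proportional to squared distance from the nearest chosen center.
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      pool <- setdiff(seq_len(n), idx[seq_len(j - 1L)])
      idx[j] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

#' K-means clustering of trajectories
#'
#' Euclidean k-means (Lloyd iterations) with greedy k-means++ seeding and
#' `restarts` independent starts; the solution with the lowest total
#' within-cluster sum of squares is kept. Restarts that end with an empty
#' cluster are counted as failed. Clusters are relabelled deterministically
#' `A, B, C, ...` by descending size, ties broken by the lexicographically
#' smallest member gene, so results are comparable across runs.
#'
#' @param traj Genes x age-groups matrix (typically z-scored; see
#'   [mean_trajectories()]).
#' @param k Number of clusters (default 11).
#' @param seed Integer seed making the clustering deterministic.
#' @param restarts Number of random restarts (default 50).
#' @return List of class `cluster_set`: `assignment` (named character vector
#'   gene -> label), `centroids` (label x age-group matrix), `sizes`, `k`,
#'   `tot_withinss`, and `gradient` (filled by [detect_gradients()]).
#' @export
kmeans_cluster <- function(traj, k = 11L, seed = 1L, restarts = 50L) {
  stopifnot(is.matrix(traj), nrow(traj) >= k, k >= 1L)
  if (anyNA(traj)) stop("traj contains missing values")
  set.seed(seed)
  best <- NULL
  failed <- 0L
  for (r in seq_len(restarts)) {
    centers <- .kmeanspp_centers(traj, k)
    fit <- tryCatch(
      withCallingHandlers(
        stats::kmeans(traj, centers = centers, iter.max = 100L,
                      algorithm = "Lloyd"),
        warning = function(w) {
          if (grepl("empty cluster", conditionMessage(w), fixed = TRUE))
            stop("empty cluster")
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit) || length(unique(fit$cluster)) < k) {
      failed <- failed + 1L
      next
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("all ", restarts, " k-means restarts failed (empty clusters)")
  # deterministic relabelling: descending size, ties by smallest member gene
  sizes <- tabulate(best$cluster, nbins = k)
  first_gene <- vapply(seq_len(k), function(j)
    min(rownames(traj)[best$cluster == j]), character(1L))
  ord <- order(-sizes, first_gene)
  labels <- if (k <= 26L) LETTERS[seq_len(k)] else sprintf("C%02d", seq_len(k))
  relabel <- character(k)
  relabel[ord] <- labels
  assignment <- relabel[best$cluster]
  names(assignment) <- rownames(traj)
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- labels
  structure(list(assignment = assignment,
                 centroids = centroids,
                 sizes = stats::setNames(sizes[ord], labels),
                 k = k,
                 tot_withinss = best$tot.withinss,
                 failed_restarts = failed,
                 gradient = NULL),
            class = "cluster_set")
}

#' Flag gradient (monotone) clusters
#'
#' A cluster is a gradient cluster when its centroid changes monotonically
#' across the ordered age groups, operationalized as Spearman correlation of
#' the centroid against the age-group index with `|rho| >= rho_min`.
#' Direction is the sign of rho.
#'
#' @param clusters A `cluster_set`.
#' @param rho_min Monotonicity threshold on `|rho|` (default 0.9).
#' @return The `cluster_set` with a `gradient` data.frame (cluster, rho,
#'   gradient flag, direction in {increasing, decreasing, none}).
#' @export
detect_gradients <- function(clusters, rho_min = 0.9) {
  stopifnot(inherits(clusters, "cluster_set"))
  cent <- clusters$centroids
  idx <- seq_len(ncol(cent))
  rho <- apply(cent, 1L, function(v) stats::cor(v, idx, method = "spearman"))
  grad <- is.finite(rho) & abs(rho) >= rho_min
  direction <- ifelse(!grad, "none", ifelse(rho > 0, "increasing", "decreasing"))
  clusters$gradient <- data.frame(cluster = rownames(cent), rho = rho,
                                  gradient = grad, direction = direction,
                                  stringsAsFactors = FALSE, row.names = NULL)
  clusters
}

#' Gradient-cluster membership of genes
#'
#' @param clusters A `cluster_set` with gradients detected.
#' @return Named character vector gene -> direction for genes in gradient
#'   clusters.
#' @export
gradient_members <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (is.null(clusters$gradient))
    stop("run detect_gradients() first")
  g <- clusters$gradient
  keep <- clusters$assignment %in% g$cluster[g$gradient]
  dir <- stats::setNames(g$direction, g$cluster)
  stats::setNames(dir[clusters$assignment[keep]], names(clusters$assignment)[keep])
}

#' Per-sex trajectory profiles, AUC and male/female AUC ratio
#'
#' For each gradient cluster and sex: every member gene's age-group mean
#' trajectory is min-max normalized to [0, 1]; the arithmetic average across
#' genes is the cluster's sex trajectory; its trapezoidal AUC is taken over
#' the unit-spaced age-group axis (0..5); the ratio is male AUC / female
#' AUC. Genes with a constant raw trajectory in a sex are mapped to the
#' midpoint 0.5. A cluster with no genes expressed in a sex yields a missing
#' AUC (and ratio).
#'
#' @param expr Expression matrix on the `tmm_cpm` (or `cpm`) scale.
#' @param samples Sample table; both sexes must be present.
#' @param clusters A `cluster_set` with gradients detected.
#' @param tissue Tissue (default "vat").
#' @return data.frame: cluster, sex, one column per age group, auc,
#'   auc_ratio_male_over_female.
#' @export
auc_ratio <- function(expr, samples, clusters, tissue = "vat") {
  stopifnot(inherits(clusters, "cluster_set"))
  if (is.null(clusters$gradient)) stop("run detect_gradients() first")
  samples <- validate_sample_table(samples)
  if (!all(c("male", "female") %in% samples$sex[samples$tissue == tissue]))
    stop("both sexes must be present")
  glabs <- clusters$gradient$cluster[clusters$gradient$gradient]
  if (length(glabs) == 0L) {
    warning("no gradient clusters")
    return(data.frame())
  }
  rows <- list()
  for (lab in glabs) {
    members <- names(clusters$assignment)[clusters$assignment == lab]
    auc_by_sex <- c(male = NA_real_, female = NA_real_)
    traj_by_sex <- list()
    for (sx in c("male", "female")) {
      mm <- mean_trajectories(expr, samples, members, sex = sx, tissue = tissue,
                              zscore = FALSE)
      expressed <- rowSums(mm) > 0
      if (!any(expressed)) {
        warning("cluster ", lab, " has no genes expressed in ", sx,
                "; AUC ratio undefined")
        traj_by_sex[[sx]] <- rep(NA_real_, ncol(mm))
        next
      }
      mm <- mm[expressed, , drop = FALSE]
      rng <- apply(mm, 1L, function(v) diff(range(v)))
      norm <- (mm - apply(mm, 1L, min)) / rng
      norm[rng == 0, ] <- 0.5
      avg <- colMeans(norm)
      traj_by_sex[[sx]] <- avg
      auc_by_sex[sx] <- trapezoid_auc(avg)
    }
    ratio <- auc_by_sex["male"] / auc_by_sex["female"]
    for (sx in c("male", "female")) {
      v <- traj_by_sex[[sx]]
      row <- data.frame(cluster = lab, sex = sx, stringsAsFactors = FALSE)
      for (j in seq_along(age_groups())) row[[age_groups()[j]]] <- v[j]
      row$auc <- auc_by_sex[[sx]]
      row$auc_ratio_male_over_female <- unname(ratio)
      rows[[paste(lab, sx)]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
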