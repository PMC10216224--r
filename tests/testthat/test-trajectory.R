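# Trajectory averaging, k-means clustering, gradient detection and AUC
# ratios.

test_that("trapezoid_auc matches hand-computed and pracma values", {
  expect_equal(trapezoid_auc(rep(1, 6)), 5)
  expect_equal(trapezoid_auc(c(0, 1)), 0.5)
  expect_equal(trapezoid_auc(c(0, 1, 0)), 1)
  skip_if_not_installed("pracma")
  set.seed(8)
  for (i in 1:10) {
    y <- rnorm(6)
    expect_equal(trapezoid_auc(y), pracma::trapz(0:5, y), tolerance = 1e-12)
  }
})

test_that("mean_trajectories averages by group and z-scores with population sd", {
  st <- flat_samples(n_per_group = 3)
  m <- matrix(0, 2, 18, dimnames = list(c("G1", "G2"), st$sample_id))
  # G1 alternates group means 1 and 3; G2 constant
  means <- rep(c(1, 3), 3)
  for (j in 1:6) m["G1", st$age_group == age_groups()[j]] <- means[j] + c(-1, 0, 1)
  m["G2", ] <- 7
  m <- viscage:::set_expr_scale(m, "tmm_cpm")
  raw <- mean_trajectories(m, st, c("G1", "G2"), zscore = FALSE)
  expect_equal(unname(raw["G1", ]), means)
  expect_warning(z <- mean_trajectories(m, st, c("G1", "G2")), "constant")
  expect_false("G2" %in% rownames(z))
  expect_equal(unname(z["G1", ]), (means - 2) / 1)  # population sd of (1,3)x3 = 1
  # permuting samples within groups changes nothing
  perm <- sample(18)
  z2 <- suppressWarnings(mean_trajectories(m[, perm], st, c("G1", "G2")))
  expect_equal(z, z2)
})

test_that("two-group z-score example uses the n-denominator convention", {
  x <- matrix(c(1, 3), 1, 2, dimnames = list("g", NULL))
  expect_equal(unname(viscage:::row_zscore(x)[1, ]), c(-1, 1),
               tolerance = 1e-12)
})

test_that("kmeans_cluster: K = 1 recovers total deviance; planted pairs are exact", {
  set.seed(10)
  x <- matrix(rnorm(60), 10, 6, dimnames = list(sprintf("g%02d", 1:10), NULL))
  cl1 <- kmeans_cluster(x, k = 1, seed = 1)
  grand <- colMeans(x)
  expect_equal(cl1$tot_withinss, sum(sweep(x, 2, grand)^2), tolerance = 1e-9)
  expect_identical(unname(unique(cl1$assignment)), "A")

  # two well-separated shapes: recovered exactly
  a <- matrix(rnorm(25 * 6, 0, 0.5), 25, 6)
  b <- matrix(rnorm(25 * 6, 10, 0.5), 25, 6)
  y <- rbind(a, b)
  rownames(y) <- sprintf("g%02d", 1:50)
  truth <- rep(c("lo", "hi"), each = 25)
  cl2 <- kmeans_cluster(y, k = 2, seed = 2)
  expect_equal(adjusted_rand(cl2$assignment, truth), 1)
})

test_that("kmeans_cluster is deterministic, a fixed point, and size-relabelled", {
  set.seed(11)
  x <- matrix(rnorm(80 * 6), 80, 6, dimnames = list(sprintf("g%02d", 1:80), NULL))
  cl_a <- kmeans_cluster(x, k = 4, seed = 9)
  cl_b <- kmeans_cluster(x, k = 4, seed = 9)
  expect_identical(cl_a$assignment, cl_b$assignment)
  expect_equal(cl_a$centroids, cl_b$centroids)
  # fixed point: every gene is nearest its own centroid
  d2 <- sapply(seq_len(nrow(cl_a$centroids)), function(j)
    rowSums((x - matrix(cl_a$centroids[j, ], nrow(x), 6, byrow = TRUE))^2))
  nearest <- rownames(cl_a$centroids)[apply(d2, 1, which.min)]
  expect_identical(unname(cl_a$assignment), nearest)
  # labels ordered by descending size
  expect_true(all(diff(unname(cl_a$sizes)) <= 0))
})

test_that("detect_gradients applies the Spearman monotonicity rule", {
  cent <- rbind(A = c(1, 2, 3, 4, 5, 6),
                B = c(0, 1, 0, 1, 0, 1),
                C = c(6, 5, 4, 3, 2, 1))
  fake <- structure(list(assignment = c(x = "A", y = "B", z = "C"),
                         centroids = cent, sizes = c(A = 1, B = 1, C = 1),
                         k = 3, gradient = NULL), class = "cluster_set")
  out <- detect_gradients(fake)
  g <- out$gradient
  expect_identical(g$direction, c("increasing", "none", "decreasing"))
  expect_equal(g$rho[1], 1)
  expect_equal(g$rho[2], cor(c(0, 1, 0, 1, 0, 1), 1:6, method = "spearman"))
  expect_lt(abs(g$rho[2]), 0.4)
  # adding a constant leaves rho unchanged; negation flips direction
  out2 <- detect_gradients(structure(
    list(assignment = fake$assignment, centroids = cent + 100,
         sizes = fake$sizes, k = 3, gradient = NULL), class = "cluster_set"))
  expect_equal(out2$gradient$rho, g$rho)
  out3 <- detect_gradients(structure(
    list(assignment = fake$assignment, centroids = -cent,
         sizes = fake$sizes, k = 3, gradient = NULL), class = "cluster_set"))
  expect_identical(out3$gradient$direction, c("decreasing", "none", "increasing"))
})

test_that("auc_ratio: symmetry gives 1; earlier male decline gives ratio < 1", {
  st <- rbind(flat_samples(2, sex = "male", prefix = "M"),
              flat_samples(2, sex = "female", prefix = "F"))
  male_curve <- c(10, 4, 2, 2, 2, 2)    # floor reached two groups earlier
  female_curve <- c(10, 8, 6, 4, 2, 2)
  m <- matrix(0, 2, nrow(st), dimnames = list(c("G1", "G2"), st$sample_id))
  for (j in 1:6) {
    sel_m <- st$sex == "male" & st$age_group == age_groups()[j]
    sel_f <- st$sex == "female" & st$age_group == age_groups()[j]
    m["G1", sel_m] <- male_curve[j];  m["G1", sel_f] <- male_curve[j]
    m["G2", sel_m] <- male_curve[j];  m["G2", sel_f] <- female_curve[j]
  }
  m <- viscage:::set_expr_scale(m, "tmm_cpm")
  mk_cl <- function(gene) structure(
    list(assignment = stats::setNames("A", gene),
         centroids = rbind(A = -(1:6)), sizes = c(A = 1), k = 1,
         gradient = data.frame(cluster = "A", rho = -1, gradient = TRUE,
                               direction = "decreasing")),
    class = "cluster_set")
  sym <- auc_ratio(m, st, mk_cl("G1"))
  expect_equal(unique(sym$auc_ratio_male_over_female), 1, tolerance = 1e-12)
  asym <- auc_ratio(m, st, mk_cl("G2"))
  # trapezoid oracle on the planted min-max-normalized curves
  auc_m <- trapezoid_auc((male_curve - 2) / 8)
  auc_f <- trapezoid_auc((female_curve - 2) / 8)
  expect_equal(unique(asym$auc_ratio_male_over_female), auc_m / auc_f,
               tolerance = 1e-12)
  expect_lt(unique(asym$auc_ratio_male_over_female), 1)
  # min-max normalization: values span [0, 1]
  vals <- unlist(asym[asym$sex == "male", age_groups()])
  expect_equal(range(vals), c(0, 1))
})

test_that("auc_ratio is invariant to affine rescaling of one sex", {
  sim <- small_sim(13)
  expr <- tmm_cpm(sim$vat_counts, tmm_factors(sim$vat_counts))
  traj <- mean_trajectories(expr, sim$samples,
                            rownames(expr)[1:60])
  cl <- detect_gradients(kmeans_cluster(traj, k = 3, seed = 5))
  base <- auc_ratio(expr, sim$samples, cl)
  expr2 <- expr
  male_ids <- sim$samples$sample_id[sim$samples$sex == "male" &
                                      sim$samples$tissue == "vat"]
  expr2[, male_ids] <- expr2[, male_ids] * 3 + 7
  expr2 <- viscage:::set_expr_scale(expr2, "tmm_cpm")
  again <- auc_ratio(expr2, sim$samples, cl)
  expect_equal(base$auc, again$auc, tolerance = 1e-9)
})
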