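# Empirical-Bayes moderation, the moderated two-group test, DEG union and
# the SASP profile.

test_that("trigamma_inverse inverts trigamma across scales", {
  y <- c(1e-4, 0.01, 0.5, 1, 3, 50, 1e4)
  expect_equal(trigamma_inverse(trigamma(y)), y, tolerance = 1e-8)
})

test_that("fit_moderation handles zero spread and matches the moment oracle", {
  fit <- fit_moderation(rep(2.5, 50), df = 3)
  expect_identical(fit$d0, Inf)
  expect_equal(fit$s02, 2.5, tolerance = 1e-12)
  expect_equal(unname(fit$posterior_var), rep(2.5, 50), tolerance = 1e-12)

  s2 <- c(1, 1, 1, 1, 1, 4, 4, 4, 4, 4)
  fit2 <- fit_moderation(s2, df = 3)
  oracle <- moderation_brute(s2, 3)
  expect_equal(fit2$d0, oracle$d0, tolerance = 1e-6)
  expect_equal(fit2$s02, oracle$s02, tolerance = 1e-6)

  skip_if_not_installed("limma")
  lf <- limma::fitFDist(s2, df1 = 3)
  expect_equal(fit2$d0, lf$df2, tolerance = 1e-6)
  expect_equal(fit2$s02, lf$scale, tolerance = 1e-6)

  expect_error(fit_moderation(rep(0, 20), df = 3), "degenerate")
})

test_that("fit_moderation recovers planted prior parameters", {
  set.seed(42)
  d0 <- 10; s02 <- 1; d <- 4
  sigma2 <- s02 * d0 / rchisq(20000, d0)
  s2 <- sigma2 * rchisq(20000, d) / d
  fit <- fit_moderation(s2, d)
  expect_lt(abs(fit$d0 - d0) / d0, 0.20)
  expect_lt(abs(fit$s02 - s02) / s02, 0.05)
})

test_that("moderated t collapses to the pooled t at d0 = 0 and to the prior at d0 -> Inf", {
  set.seed(7)
  x1 <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(letters[1:5], NULL))
  x2 <- matrix(rnorm(5 * 8, 1), 5, 8)
  mt0 <- moderated_t(x1, x2, d0 = 0, s02 = 1)
  for (g in 1:5) {
    tt <- t.test(x2[g, ], x1[g, ], var.equal = TRUE)
    expect_equal(mt0$t[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(mt0$p[g], tt$p.value, tolerance = 1e-12)
  }
  mt_inf <- moderated_t(x1, x2, d0 = Inf, s02 = 2)
  diff <- rowMeans(x2) - rowMeans(x1)
  expect_equal(mt_inf$t, unname(diff / sqrt(2 * (1 / 6 + 1 / 8))),
               tolerance = 1e-12)
})

test_that("constant genes give t = 0, p = 1", {
  x1 <- matrix(3, 4, 5, dimnames = list(paste0("g", 1:4), NULL))
  x2 <- matrix(3, 4, 5)
  x1[2, ] <- rnorm(5); x2[2, ] <- rnorm(5)  # keep the fit non-degenerate
  x1[3, ] <- rnorm(5); x2[3, ] <- rnorm(5)
  x1[4, ] <- rnorm(5); x2[4, ] <- rnorm(5)
  mt <- suppressWarnings(moderated_t(x1, x2))  # few genes: small-fit warning
  expect_equal(mt$t[1], 0)
  # moderation gives the constant gene positive posterior variance, so the
  # identical-groups gene is exactly null
  expect_equal(mt$p[1], 1, tolerance = 1e-12)
})

test_that("moderated_test agrees with limma on a two-group design", {
  skip_if_not_installed("limma")
  set.seed(21)
  sim <- simulate_two_group(n_genes = 300, n_per_group = 6, n_de = 30,
                            log2_fc = 1.5, seed = 21)
  e <- log10_cpm(sim$counts)
  st <- data.frame(sample_id = colnames(e), sex = "male",
                   age_group = rep(c("20-29", "70-79"), each = 6),
                   tissue = "vat")
  res <- moderated_test(e, st, sex = "male")
  design <- cbind(1, rep(0:1, each = 6))
  fit <- limma::eBayes(limma::lmFit(e, design))
  expect_equal(res$mod_t, fit$t[, 2], tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(res$p, fit$p.value[, 2], tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("moderated_test is invariant to sample order and gates significance", {
  sim <- small_sim(3)
  e <- log10_cpm(sim$vat_counts)
  res <- moderated_test(e, sim$samples, sex = "male")
  perm <- sample(ncol(e))
  res_perm <- moderated_test(e[, perm], sim$samples, sex = "male")
  expect_equal(res, res_perm)
  expect_identical(res$significant,
                   res$fdr < 0.05 & abs(res$log2_fc) >= 1)
  # BH within each contrast matches the brute-force definition
  for (ct in unique(res$contrast)[1:2]) {
    sub <- res[res$contrast == ct, ]
    expect_equal(sub$fdr, bh_brute(sub$p), tolerance = 1e-12)
  }
})

test_that("small contrast groups are skipped with a warning", {
  sim <- small_sim(5)
  st <- sim$samples
  vat_m <- st$sample_id[st$tissue == "vat" & st$sex == "male"]
  drop <- st$sample_id[st$tissue == "vat" & st$sex == "male" &
                         st$age_group == "70-79"][-1]
  keep <- setdiff(colnames(sim$vat_counts), drop)
  e <- log10_cpm(sim$vat_counts[, keep])
  expect_warning(res <- moderated_test(e, st[st$sample_id %in% keep, ],
                                       sex = "male"),
                 "70-79")
  expect_false("70-79_vs_20-29" %in% res$contrast)
})

test_that("deg_union de-duplicates across contrasts", {
  mk <- function(genes, contrast, sig = TRUE)
    data.frame(gene = genes, sex = "male", contrast = contrast,
               log2_fc = 2, mod_t = 5, p = 0.001, fdr = 0.01,
               significant = sig)
  none <- mk(c("A", "B"), "c1", sig = FALSE)
  expect_identical(deg_union(none), character(0))
  multi <- rbind(mk("A", "c1"), mk("A", "c2"), mk("A", "c3"))
  expect_identical(deg_union(multi), "A")
  disjoint <- rbind(mk(c("A", "B", "C"), "c1"), mk(c("D", "E", "F", "G"), "c2"))
  expect_identical(deg_union(disjoint), LETTERS[1:7])
})

test_that("sasp_profile keeps non-significant panel genes and stars hits", {
  res <- data.frame(
    gene = rep(c("TIMP2", "PLAT", "FAS"), each = 2), sex = "male",
    contrast = rep(c("c1", "c2"), 3),
    log2_fc = c(2, 2, 0.1, 0.2, 0.5, 0.1),
    mod_t = 1, p = 0.5,
    fdr = c(0.01, 0.2, 0.9, 0.8, 0.3, 0.4),
    significant = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  expect_warning(prof <- sasp_profile(res, c("TIMP2", "PLAT", "NOPE")),
                 "NOPE")
  expect_setequal(unique(prof$gene), c("TIMP2", "PLAT"))
  expect_true(all(prof$star[prof$gene == "TIMP2"]))
  expect_false(any(prof$star[prof$gene == "PLAT"]))
  expect_identical(nrow(prof[prof$gene == "PLAT", ]), 2L)
})
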