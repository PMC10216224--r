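# Independent brute-force oracles and shared fixtures. Each oracle is a
# deliberately naive re-derivation, kept separate from the package's code
# paths.

# Benjamini-Hochberg by the definition: sort, p * m / i, cumulative min from
# the largest rank, cap at 1, unsort.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  cur <- Inf
  for (i in m:1) {
    cur <- min(cur, ps[i] * m / i)
    adj[i] <- min(cur, 1)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Hypergeometric upper tail P[X >= k] by direct summation of the pmf.
hyper_brute <- function(k, m, n, N) {
  upper <- min(m, n)
  if (k > upper) return(0)
  i <- max(k, max(0, n - (N - m))):upper
  sum(choose(m, i) * choose(N - m, n - i)) / choose(N, n)
}

# TMM factor for one sample vs a reference, re-derived with plain loops.
tmm_brute_pair <- function(y, yr, n, nr, trim_m = 0.3, trim_a = 0.05) {
  keep <- which(y > 0 & yr > 0)
  M <- A <- w <- numeric(0)
  for (g in keep) {
    p <- y[g] / n; pr <- yr[g] / nr
    M <- c(M, log2(p / pr))
    A <- c(A, 0.5 * (log2(p) + log2(pr)))
    w <- c(w, 1 / ((n - y[g]) / (n * y[g]) + (nr - yr[g]) / (nr * yr[g])))
  }
  ng <- length(M)
  lo_m <- floor(ng * trim_m) + 1; hi_m <- ng + 1 - lo_m
  lo_a <- floor(ng * trim_a) + 1; hi_a <- ng + 1 - lo_a
  rM <- rank(M, ties.method = "first"); rA <- rank(A, ties.method = "first")
  sel <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  2^(sum(w[sel] * M[sel]) / sum(w[sel]))
}

# Moment-matching fit of the log-F variance prior, written independently:
# same moment equations, trigamma inverted by bisection.
moderation_brute <- function(s2, d) {
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(d / 2)
  if (evar <= 0) return(list(d0 = Inf, s02 = mean(s2)))
  lo <- 1e-6; hi <- 1e6
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > evar) lo <- mid else hi <- mid
  }
  y <- sqrt(lo * hi)
  list(d0 = 2 * y, s02 = exp(emean + digamma(y) - log(y)))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Down-scaled simulated study shared across tests.
small_sim <- function(seed = 11L) {
  simulate_study(sim_config(
    seed = seed, genes_total = 1500L, genes_per_template = 20L,
    vat_samples = list(male = c(6L, 6L, 8L, 10L, 10L, 4L),
                       female = c(5L, 5L, 6L, 8L, 8L, 3L)),
    liver_samples = list(male = c(3L, 3L, 4L, 5L, 5L, 2L),
                         female = c(2L, 2L, 3L, 4L, 4L, 2L)),
    sasp_size = 10L, background_edges = 100L))
}

# Minimal hand-built sample table: one sex, six groups, n per group.
flat_samples <- function(n_per_group = 5L, sex = "male", tissue = "vat",
                        prefix = "S") {
  data.frame(
    sample_id = sprintf("%s%03d", prefix, seq_len(6L * n_per_group)),
    sex = sex,
    age_group = rep(age_groups(), each = n_per_group),
    tissue = tissue,
    stringsAsFactors = FALSE)
}

# TPM-scale matrix from explicit values (bypasses count plumbing).
as_tpm <- function(values) viscage:::set_expr_scale(values, "tpm")
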