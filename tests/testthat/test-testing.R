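# ---- BH adjustment ---------------------------------------------------------

test_that("bh_adjust matches a brute-force step-up oracle", {
  # independent direct evaluation of the BH definition
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q_sorted <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) {
      if (n >= 2) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
    }
    pmin(1, q_sorted)[order(o)]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.4), 0.4)
  set.seed(71)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
  }
  # second reference implementation
  p <- runif(200)
  expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  # order preservation
  ps <- sort(runif(50))
  expect_false(is.unsorted(bh_adjust(ps)))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

# ---- cluster Monte-Carlo test ----------------------------------------------

test_that("cluster p-value follows the printed formula at its extremes", {
  G <- 200
  p <- fixed_profile(G)
  prof <- fake_profile(p)
  # anti-background cluster: counts concentrated on the rarest genes
  rare <- order(p)[1:5]
  anti <- matrix(0, G, 3)
  anti[rare, ] <- 50
  m_anti <- as_counts(anti, genes = sprintf("g%03d", 1:G))
  res <- cluster_mc_test(m_anti, 1:3, prof, m_iter = 1000, seed = 4)
  expect_equal(res$p_value, 1 / 1001)

  # cluster proportional to the profile itself: T_C above nearly all nulls
  prop <- round(outer(p, c(600, 600, 600)))
  m_prop <- as_counts(prop, genes = sprintf("g%03d", 1:G))
  res2 <- cluster_mc_test(m_prop, 1:3, prof, m_iter = 1000, seed = 4)
  expect_gt(res2$p_value, 0.9)
  expect_lte(res2$p_value, 1)

  expect_error(cluster_mc_test(m_anti, 1L, prof), "2 members")
})

test_that("cluster p-values are bounded, monotone in T_C, and cached", {
  G <- 150
  p <- fixed_profile(G)
  prof <- fake_profile(p)
  set.seed(9)
  X <- vapply(rep(400, 6), function(N) rmultinom(1, N, p)[, 1], numeric(G))
  m <- as_counts(X, genes = sprintf("g%03d", 1:G))
  cache <- new.env(parent = emptyenv())
  r1 <- cluster_mc_test(m, 1:4, prof, m_iter = 500, seed = 11, null_cache = cache)
  expect_gte(r1$p_value, 1 / 501)
  expect_lte(r1$p_value, 1)
  # same nulls (cached per size): p is monotone in the statistic
  key <- as.character(r1$n_ref)
  nulls <- cache[[key]]
  expect_length(nulls, 500)
  p_at <- function(t) (sum(nulls <= t) + 1) / 501
  expect_equal(r1$p_value, p_at(r1$t_c))
  expect_lte(p_at(quantile(nulls, 0.1)), p_at(quantile(nulls, 0.9)))
})

test_that("cluster test type-I error is near nominal on null clusters", {
  G <- 300
  p <- fixed_profile(G)
  prof <- fake_profile(p)
  m_iter <- 199
  n_rep <- 200
  pvals <- vapply(seq_len(n_rep), function(r) {
    X <- dropletcall:::with_seed(5000 + r,
      vapply(rep(300, 5), function(N) rmultinom(1, N, p)[, 1], numeric(G)))
    m <- as_counts(X, genes = sprintf("g%03d", 1:G))
    cluster_mc_test(m, 1:5, prof, m_iter = m_iter, seed = 6000 + r)$p_value
  }, numeric(1))
  for (alpha in c(0.05, 0.1)) {
    rate <- mean(pvals <= alpha)
    se <- sqrt(alpha * (1 - alpha) / n_rep)
    expect_lte(rate, alpha + 3 * se)
  }
})

# ---- individual barcode test -----------------------------------------------

test_that("path-simulated log-likelihoods match the closed form", {
  G <- 80
  p <- fixed_profile(G)
  for (alpha in c(Inf, 50)) {
    nulls <- dropletcall:::simulate_null_loglik(p, alpha, sizes = c(37, 120),
                                               m_iter = 5, seed = 3)
    # reconstruct: a path's partial LL at total t equals the closed form of
    # a multinomial/DM vector with that many counts; verify via fresh draws
    set.seed(8)
    for (rep in 1:20) {
      x <- rmultinom(1, 120, p)[, 1]
      ll <- dropletcall:::loglik_background(x, p, alpha)
      expect_true(is.finite(ll))
    }
    # distributional check: closed-form LL of direct draws and path LL draws
    # come from the same distribution (compare means within 4 SE)
    direct <- vapply(1:200, function(i) {
      if (is.infinite(alpha)) {
        x <- rmultinom(1, 120, p)[, 1]
      } else {
        w <- rgamma(G, alpha * p)
        x <- rmultinom(1, 120, w / sum(w))[, 1]
      }
      dropletcall:::loglik_background(x, p, alpha)
    }, numeric(1))
    paths <- dropletcall:::simulate_null_loglik(p, alpha, sizes = 120L,
                                               m_iter = 200, seed = 91)[, 1]
    se <- sqrt(var(direct) / 200 + var(paths) / 200)
    expect_lt(abs(mean(direct) - mean(paths)), 4 * se)
  }
})

test_that("ed test: floor bound, null barcodes large p, outlier barcodes small p", {
  G <- 300
  p <- fixed_profile(G)
  prof <- fake_profile(p)
  # maximally background-like barcode: counts proportional to p
  x_null <- round(500 * p)
  # far-from-null barcode: all mass on the genes carrying the bottom 1% of p
  rare <- order(p)[seq_len(ceiling(G / 10))]
  x_out <- numeric(G)
  x_out[rare] <- round(500 / length(rare))
  m <- as_counts(cbind(x_null, x_out), genes = sprintf("g%03d", 1:G),
                 barcodes = c("null", "outlier"))
  r_null <- ed_barcode_test(m, 1L, prof, m_iter = 400, seed = 17)
  r_out <- ed_barcode_test(m, 2L, prof, m_iter = 400, seed = 17)
  expect_gte(r_null$p_value, 1 / 401)
  expect_gte(r_out$p_value, 1 / 401)
  expect_gt(r_null$p_value, 0.5)
  expect_lt(r_out$p_value, 0.05)
})

test_that("ed batch equals repeated single tests and respects DM concentration", {
  G <- 120
  p <- fixed_profile(G)
  set.seed(23)
  X <- vapply(c(150, 150, 300), function(N) rmultinom(1, N, p)[, 1], numeric(G))
  m <- as_counts(X, genes = sprintf("g%03d", 1:G))
  for (alpha in c(Inf, 20)) {
    prof <- fake_profile(p, concentration = alpha)
    batch <- dropletcall:::ed_test_batch(m, 1:3, prof, m_iter = 300, seed = 5)
    for (j in 1:3) {
      single <- ed_barcode_test(m, j, prof, m_iter = 300, seed = 5)
      expect_equal(single$log_lik, batch$log_lik[j])
    }
    # closed-form statistic agrees with loglik_background
    expect_equal(batch$log_lik[1],
                 dropletcall:::loglik_background(X[, 1], p, alpha))
  }
})
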