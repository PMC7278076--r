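# ---- Dirichlet-multinomial / multinomial log-likelihoods -------------------

# Full log-likelihood (combinatorial terms included) of one count vector x
# with total n under the background profile p. alpha = Inf gives the
# multinomial limit; finite alpha the Dirichlet-multinomial.
loglik_background <- function(x, p, alpha = Inf) {
  nz <- which(x > 0)
  n <- sum(x)
  base <- lgamma(n + 1) - sum(lgamma(x[nz] + 1))
  if (is.infinite(alpha)) {
    base + sum(x[nz] * log(p[nz]))
  } else {
    base + lgamma(alpha) - lgamma(alpha + n) +
      sum(lgamma(x[nz] + alpha * p[nz]) - lgamma(alpha * p[nz]))
  }
}

# Null log-likelihood draws for many barcode sizes at once.
#
# Each Monte-Carlo iteration grows one background barcode a count at a time
# up to max(totals): under the compound representation a Dirichlet weight
# vector is drawn once (multinomial when alpha = Inf) and genes are sampled
# i.i.d. from it, so the partial counts at every intermediate total are a
# valid DM/multinomial draw of that size. The log-likelihood is accumulated
# incrementally, giving, per iteration, a null statistic for every
# requested size for the price of one path.
#
# Returns a m_iter x length(sizes) matrix; column j holds the null
# log-likelihoods for barcode total sizes[j] (sizes must be sorted).
simulate_null_loglik <- function(p, alpha, sizes, m_iter, seed) {
  stopifnot(!is.unsorted(sizes), all(sizes >= 1))
  G <- length(p)
  maxN <- max(sizes)
  logt <- log(seq_len(maxN))
  if (!is.infinite(alpha)) logat <- log(alpha + seq_len(maxN) - 1)
  out <- matrix(NA_real_, m_iter, length(sizes))
  with_seed(seed, {
    for (it in seq_len(m_iter)) {
      if (is.infinite(alpha)) {
        g <- sample.int(G, maxN, replace = TRUE, prob = p)
      } else {
        w <- rgamma(G, shape = alpha * p)
        if (sum(w) == 0) w[which.max(p)] <- 1
        g <- sample.int(G, maxN, replace = TRUE, prob = w)
      }
      o <- order(g)
      occ <- integer(maxN)
      occ[o] <- sequence(rle(g[o])$lengths)
      inc <- if (is.infinite(alpha)) {
        logt - log(occ) + log(p[g])
      } else {
        logt - log(occ) + log(alpha * p[g] + occ - 1) - logat
      }
      out[it, ] <- cumsum(inc)[sizes]
    }
  })
  out
}

# Null Pearson correlations with the profile p for many barcode sizes at
# once. Same incremental-path idea as simulate_null_loglik: genes are
# sampled i.i.d. from p, so the partial count vector after t draws is an
# exact multinomial(t, p) draw, and cor(x_t, p) only needs the running
# sums sum(x*p) and sum(x^2). Returns m_iter x length(sizes); sizes sorted.
simulate_null_cors <- function(p, sizes, m_iter, seed) {
  stopifnot(!is.unsorted(sizes), all(sizes >= 1))
  G <- length(p)
  maxN <- max(sizes)
  tvec <- seq_len(maxN)
  p_ss <- sum(p^2) - 1 / G
  out <- matrix(NA_real_, m_iter, length(sizes))
  with_seed(seed, {
    for (it in seq_len(m_iter)) {
      g <- sample.int(G, maxN, replace = TRUE, prob = p)
      o <- order(g)
      occ <- integer(maxN)
      occ[o] <- sequence(rle(g[o])$lengths)
      sxp <- cumsum(p[g])
      sx2 <- cumsum(2 * occ - 1)
      denom <- sqrt((sx2 - tvec^2 / G) * p_ss)
      cors <- (sxp - tvec / G) / denom
      cors[denom == 0] <- 0
      out[it, ] <- cors[sizes]
    }
  })
  out
}

# Pearson correlation of each sparse column with a dense vector p.
sparse_profile_cors <- function(X, p) {
  X <- as(X, "CsparseMatrix")
  G <- nrow(X)
  tot <- Matrix::colSums(X)
  sxp <- as.vector(Matrix::crossprod(X, p))
  sx2 <- Matrix::colSums(X^2)
  denom <- sqrt((sx2 - tot^2 / G) * (sum(p^2) - 1 / G))
  cors <- (sxp - tot / G) / denom
  cors[!is.finite(cors)] <- 0
  cors
}

# ---- Monte-Carlo tests -----------------------------------------------------

# Cluster statistic T_C (median member-to-profile Pearson correlation) and
# the reference size N supplying it. For an even cluster the median is the
# midpoint of the middle pair and N comes from the pair's lower-correlation
# member (the conservative choice: smaller barcodes give noisier nulls).
cluster_stat <- function(m, cluster, p) {
  X <- m[, cluster, drop = FALSE]
  cors <- sparse_profile_cors(X, p)
  totals <- Matrix::colSums(X)
  ord <- order(cors)
  k <- length(cors)
  if (k %% 2L == 1L) {
    mid <- ord[(k + 1L) %/% 2L]
    t_c <- cors[mid]
    n_ref <- totals[mid]
  } else {
    lo <- ord[k %/% 2L]
    t_c <- (cors[lo] + cors[ord[k %/% 2L + 1L]]) / 2
    n_ref <- totals[lo]
  }
  list(t_c = t_c, n_ref = as.integer(round(n_ref)))
}

#' Monte-Carlo test of a tight cluster against the background
#'
#' Computes the Pearson correlation of each cluster member's count vector
#' with the smoothed ambient profile and takes the median as the cluster
#' statistic T_C (a background-like cluster correlates highly with the
#' ambient profile, so small T_C is evidence for a real-cell cluster). M
#' null barcodes are drawn from a multinomial(N, ambient profile), N being
#' the total count of the barcode supplying T_C, and the p-value is the
#' add-one corrected fraction of null correlations at or below T_C:
#' p = (#\{cor* <= T_C\} + 1) / (M + 1).
#'
#' @param m count matrix.
#' @param cluster integer vector of barcode column indices (>= 2 members).
#' @param profile a [estimate_background_profile()] result.
#' @param m_iter Monte-Carlo iterations M (default 1000).
#' @param seed integer seed.
#' @param null_cache optional environment caching null correlations per
#'   distinct N within one pipeline run.
#' @return a `ClusterTestResult`: list with `cluster`, `t_c`, `n_ref`,
#'   `m_iter`, `p_value`.
#' @export
cluster_mc_test <- function(m, cluster, profile, m_iter = 1000, seed = 1L,
                            null_cache = NULL) {
  stopifnot(inherits(profile, "BackgroundProfile"))
  if (length(cluster) < 2L) stop("cluster must have at least 2 members", call. = FALSE)
  assert_scalar_number(m_iter, "m_iter", lower = 1)
  p <- profile$p_b0
  st <- cluster_stat(m, cluster, p)
  t_c <- st$t_c
  n_ref <- st$n_ref
  key <- as.character(n_ref)
  null_cors <- NULL
  if (!is.null(null_cache) && !is.null(null_cache[[key]])) {
    null_cors <- null_cache[[key]]
  }
  if (is.null(null_cors)) {
    null_cors <- with_seed(seed, {
      Xn <- rmultinom(m_iter, n_ref, p)
      nc <- as.vector(suppressWarnings(cor(Xn, p)))
      nc[is.na(nc)] <- 0
      nc
    })
    if (!is.null(null_cache)) null_cache[[key]] <- null_cors
  }
  p_value <- (sum(null_cors <= t_c) + 1) / (m_iter + 1)
  structure(
    list(cluster = cluster, t_c = t_c, n_ref = n_ref,
         m_iter = m_iter, p_value = p_value),
    class = "ClusterTestResult"
  )
}

# Batched individual-barcode test. Returns a data.frame with one row per
# requested barcode: log_lik, p_value.
ed_test_batch <- function(m, barcodes, profile, m_iter = 1000, seed = 1L) {
  stopifnot(inherits(profile, "BackgroundProfile"))
  p <- profile$p_b0
  alpha <- profile$concentration %||% Inf
  X <- as(m[, barcodes, drop = FALSE], "CsparseMatrix")
  totals <- as.integer(round(Matrix::colSums(X)))
  if (any(totals == 0)) stop("cannot test a zero-count barcode", call. = FALSE)
  # vectorized over the sparse slots; must agree with loglik_background()
  col_of <- rep.int(seq_along(barcodes), diff(X@p))
  gi <- X@i + 1L
  xv <- X@x
  per_entry <- if (is.infinite(alpha)) {
    xv * log(p[gi]) - lgamma(xv + 1)
  } else {
    lgamma(xv + alpha * p[gi]) - lgamma(alpha * p[gi]) - lgamma(xv + 1)
  }
  obs <- lgamma(totals + 1)
  if (!is.infinite(alpha)) obs <- obs + lgamma(alpha) - lgamma(alpha + totals)
  sums <- rowsum(per_entry, col_of, reorder = FALSE)
  obs[unique(col_of)] <- obs[unique(col_of)] + as.vector(sums)
  sizes <- sort(unique(totals))
  nulls <- simulate_null_loglik(p, alpha, sizes, m_iter, seed)
  pv <- numeric(length(barcodes))
  for (s in seq_along(sizes)) {
    sel <- which(totals == sizes[s])
    ns <- sort(nulls[, s])
    # more extreme = log-likelihood at or below the observed one
    pv[sel] <- (findInterval(obs[sel], ns) + 1) / (m_iter + 1)
  }
  data.frame(barcode_index = barcodes, total = totals,
             log_lik = obs, p_value = pv)
}

#' Individual-barcode test against the ambient background
#'
#' The classical empty-droplet test: the statistic is the
#' Dirichlet-multinomial log-likelihood of the barcode's counts under the
#' smoothed ambient profile at the estimated concentration (multinomial
#' when the concentration is infinite). M null barcodes of the same total
#' are simulated under that model and the add-one corrected fraction with a
#' log-likelihood at or below the observed one is the p-value.
#'
#' @param m count matrix.
#' @param barcode a single barcode column index.
#' @param profile a [estimate_background_profile()] result (its
#'   `concentration` field sets the null model).
#' @param m_iter Monte-Carlo iterations M (default 1000).
#' @param seed integer seed.
#' @return a `BarcodeTestResult`: list with `barcode`, `log_lik`, `p_value`.
#' @export
ed_barcode_test <- function(m, barcode, profile, m_iter = 1000, seed = 1L) {
  assert_scalar_number(m_iter, "m_iter", lower = 1)
  res <- ed_test_batch(m, barcode, profile, m_iter = m_iter, seed = seed)
  structure(
    list(barcode = barcode, log_lik = res$log_lik, p_value = res$p_value),
    class = "BarcodeTestResult"
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment: q_(i) = min over j >= i of p_(j) * m / j,
#' clipped at 1, returned in the input order.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return vector of adjusted q-values.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  n <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / seq(n, 1) * p_values[o]))[ro]
}
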