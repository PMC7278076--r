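#' Simple Good-Turing smoothing of pooled gene counts
#'
#' Gale & Sampson's Simple Good-Turing estimator applied to a vector of
#' pooled per-gene counts. Frequencies-of-frequencies are smoothed by a
#' log-log regression; the Turing estimate is used for low counts until it
#' stops differing significantly (at `conf` standard deviations) from the
#' smoothed estimate, after which the smoothed estimate takes over. The
#' total unseen-species mass N1/N is split evenly among zero-count genes,
#' so every returned probability is strictly positive whenever the input
#' has at least one singleton or no zeros.
#'
#' @param counts non-negative integer vector of pooled per-gene counts.
#' @param conf switch-rule width in standard deviations (default 1.96).
#' @param warn warn when the log-log regression slope exceeds -1 (the
#'   smoothing is then extrapolating outside its comfort zone).
#' @return probability vector over genes, summing to 1.
#' @export
good_turing_probs <- function(counts, conf = 1.96, warn = TRUE) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(round(counts))
  N <- sum(counts)
  if (N == 0) stop("cannot smooth an all-zero count vector", call. = FALSE)
  r <- sort(unique(counts[counts > 0]))
  n <- tabulate(match(counts[counts > 0], r), nbins = length(r))
  n0 <- sum(counts == 0L)
  P0 <- if (r[1L] == 1L) n[1L] / N else 0

  if (length(r) == 1L) {
    # single frequency class: no regression possible, fall back to ML
    rstar <- as.numeric(r)
  } else {
    # Z-transform: spread each frequency over its gap to the neighbours
    q <- c(0L, head(r, -1L))
    t <- c(tail(r, -1L), 2L * r[length(r)] - q[length(q)])
    Z <- n / (0.5 * (t - q))
    fit <- stats::lm.fit(cbind(1, log(r)), log(Z))
    b <- fit$coefficients[2L]
    if (b > -1 && warn) {
      warning("Good-Turing log-log slope > -1; smoothing may be unreliable")
    }
    lgt <- r * (1 + 1 / r)^(b + 1)
    rstar <- numeric(length(r))
    switched <- FALSE
    for (j in seq_along(r)) {
      nxt <- match(r[j] + 1L, r)
      if (!switched && !is.na(nxt)) {
        turing <- (r[j] + 1) * n[nxt] / n[j]
        sd_t <- (r[j] + 1) * sqrt(n[nxt] / n[j]^2 * (1 + n[nxt] / n[j]))
        if (abs(turing - lgt[j]) <= conf * sd_t) switched <- TRUE
        rstar[j] <- if (switched) lgt[j] else turing
      } else {
        switched <- TRUE
        rstar[j] <- lgt[j]
      }
    }
  }
  Nprime <- sum(n * rstar)
  prop_by_class <- (1 - P0) * rstar / Nprime

  p <- numeric(length(counts))
  pos <- counts > 0L
  p[pos] <- prop_by_class[match(counts[pos], r)]
  if (n0 > 0L) p[!pos] <- P0 / n0
  # if nothing was unseen, the P0 mass has nowhere to go: renormalize
  p / sum(p)
}

#' Locate the knee or inflection of a barcode-rank curve
#'
#' Landmarks are computed on the log10(total) versus log10(rank) curve of
#' distinct totals (rank of a total = number of barcodes with at least that
#' many counts), smoothed with a small running median. The inflection is
#' the point of steepest descent (minimum first derivative); the knee is
#' the point of minimum signed curvature. The search is restricted to
#' totals above `lower` so the low-count plateau cannot attract the
#' landmark; if that leaves too few points the restriction is relaxed.
#'
#' @param totals vector of per-barcode total counts.
#' @param mode `"knee"` or `"inflection"`.
#' @param lower ignore totals at or below this value when searching.
#' @return a single total count strictly between `min(totals)` and
#'   `max(totals)`, to be used as a threshold.
#' @export
find_thresholds <- function(totals, mode = c("knee", "inflection"), lower = 100) {
  mode <- match.arg(mode)
  totals <- totals[totals > 0]
  if (length(totals) < 3L) stop("too few positive barcodes to find a threshold", call. = FALSE)
  ut <- sort(unique(totals), decreasing = TRUE)
  if (length(ut) < 2L) stop("constant totals: no transition detectable", call. = FALSE)

  keep <- ut > lower
  if (sum(keep) < 3L) keep <- rep(TRUE, length(ut))
  ut_s <- ut[keep]
  if (length(ut_s) == 2L) {
    # two plateaus only: the transition is the geometric midpoint
    return(max(2, floor(sqrt(prod(as.numeric(ut_s))))))
  }
  rank_of <- vapply(ut_s, function(t) sum(totals >= t), numeric(1))
  x <- log10(rank_of)
  y <- log10(ut_s)
  w <- min(5L, length(y) - (1 - length(y) %% 2))
  if (w >= 3L) y <- runmed(y, w, endrule = "median")

  dx <- diff(x)
  dx[dx == 0] <- min(dx[dx > 0], 1e-8)
  d1 <- diff(y) / dx
  if (mode == "inflection") {
    j <- which.min(d1)           # steepest descent, between points j and j+1
    thr <- ut_s[j + 1L]
  } else {
    xm <- (x[-1] + x[-length(x)]) / 2
    dxm <- diff(xm)
    dxm[dxm == 0] <- min(dxm[dxm > 0], 1e-8)
    d2 <- diff(d1) / dxm
    curv <- d2 / (1 + ((d1[-1] + d1[-length(d1)]) / 2)^2)^1.5
    j <- which.min(curv)         # most negative signed curvature
    thr <- ut_s[j + 1L]
  }
  thr <- min(max(thr, min(totals) + 1), max(totals) - 1)
  as.numeric(thr)
}

#' Partition barcodes by total count
#'
#' Splits the barcodes of a count matrix into the background set B0
#' (total <= `lower`), the high-count set B2 (total > `upper`, retained as
#' cells without testing), and the candidate set B1 in between, which is
#' what the cluster and individual tests examine.
#'
#' @param m count matrix with no all-zero barcodes (see [drop_empty()]).
#' @param lower background threshold; a barcode whose total is less than or
#'   equal to it belongs to B0 (default 100).
#' @param upper high-count threshold, or `"auto"` to use the knee of the
#'   barcode-rank curve; a barcode must strictly exceed it to enter B2.
#' @return a `BarcodePartition`: list with `lower_threshold`,
#'   `upper_threshold`, and integer index vectors `b0`, `b1`, `b2`.
#' @export
partition_barcodes <- function(m, lower = 100, upper = "auto") {
  totals <- barcode_totals(m)
  if (any(totals == 0)) {
    stop("matrix contains all-zero barcodes; run drop_empty() first", call. = FALSE)
  }
  assert_scalar_number(lower, "lower", lower = 1)
  if (identical(upper, "auto")) {
    upper <- find_thresholds(totals, mode = "knee", lower = lower)
  }
  assert_scalar_number(upper, "upper")
  if (upper <= lower) stop("upper threshold must exceed lower threshold", call. = FALSE)
  b0 <- unname(which(totals <= lower))
  b2 <- unname(which(totals > upper))
  b1 <- unname(which(totals > lower & totals <= upper))
  if (length(b0) == 0L) {
    stop("no barcodes at or below the lower threshold: background unestimable",
         call. = FALSE)
  }
  structure(
    list(lower_threshold = lower, upper_threshold = upper,
         b0 = b0, b1 = b1, b2 = b2),
    class = "BarcodePartition"
  )
}

#' @export
print.BarcodePartition <- function(x, ...) {
  cat(sprintf(
    "BarcodePartition: thresholds (%g, %g]; |B0|=%d |B1|=%d |B2|=%d\n",
    x$lower_threshold, x$upper_threshold,
    length(x$b0), length(x$b1), length(x$b2)))
  invisible(x)
}

#' Estimate the smoothed ambient expression profile
#'
#' Pools the counts of the background barcodes B0 and applies Simple
#' Good-Turing smoothing so that every gene, including those unobserved in
#' the background, receives strictly positive probability. The high-count
#' profile from B2 is computed the same way; it is needed to calibrate the
#' cluster-tightness thresholds.
#'
#' @param m count matrix.
#' @param part a [partition_barcodes()] result.
#' @return a `BackgroundProfile`: list with `p_b0`, `p_b2` (NULL when B2 is
#'   empty) and `concentration` (Dirichlet-multinomial scale; `Inf` until
#'   [estimate_concentration()] is run, meaning the multinomial limit).
#' @export
estimate_background_profile <- function(m, part) {
  stopifnot(inherits(part, "BarcodePartition"))
  pooled0 <- Matrix::rowSums(m[, part$b0, drop = FALSE])
  if (sum(pooled0) == 0) stop("background barcodes have zero total mass", call. = FALSE)
  p_b0 <- good_turing_probs(pooled0, warn = FALSE)
  p_b2 <- NULL
  if (length(part$b2)) {
    pooled2 <- Matrix::rowSums(m[, part$b2, drop = FALSE])
    if (sum(pooled2) > 0) p_b2 <- good_turing_probs(pooled2, warn = FALSE)
  }
  structure(
    list(p_b0 = p_b0, p_b2 = p_b2, concentration = Inf),
    class = "BackgroundProfile"
  )
}

#' @export
print.BackgroundProfile <- function(x, ...) {
  cat(sprintf("BackgroundProfile over %d genes; concentration alpha = %s\n",
              length(x$p_b0), format(x$concentration)))
  invisible(x)
}

# Dirichlet-multinomial log-likelihood of sparse columns at scale alpha and
# mean profile p (combinatorial terms dropped: they are constant in alpha).
dm_loglik_alpha <- function(gene_idx, xval, totals, p, alpha) {
  sum(lgamma(xval + alpha * p[gene_idx])) - sum(lgamma(alpha * p[gene_idx])) +
    length(totals) * lgamma(alpha) - sum(lgamma(alpha + totals))
}

#' Estimate the Dirichlet-multinomial concentration of the background
#'
#' Maximizes the DM log-likelihood of the B0 barcode count vectors over the
#' scalar concentration alpha, holding the mean profile fixed at the
#' smoothed ambient profile. When the likelihood keeps rising to the search
#' bound, or the best finite alpha does not improve on the multinomial
#' limit by a chi-square(1) likelihood-ratio margin (no detectable
#' overdispersion), the `Inf` sentinel is returned (multinomial limit).
#'
#' @param m count matrix.
#' @param part a [partition_barcodes()] result with at least 2 B0 barcodes.
#' @param profile a [estimate_background_profile()] result.
#' @param bounds log10 search interval for alpha.
#' @return positive scalar alpha, or `Inf`.
#' @export
estimate_concentration <- function(m, part, profile, bounds = c(-2, 6)) {
  stopifnot(inherits(part, "BarcodePartition"), inherits(profile, "BackgroundProfile"))
  if (length(part$b0) < 2L) stop("need at least 2 background barcodes", call. = FALSE)
  X <- as(m[, part$b0, drop = FALSE], "CsparseMatrix")
  gene_idx <- X@i + 1L
  xval <- X@x
  totals <- Matrix::colSums(X)
  p <- profile$p_b0
  if (sum(p > 0) < 2L) return(Inf)  # one-gene profile: likelihood flat in alpha

  ll <- function(la) dm_loglik_alpha(gene_idx, xval, totals, p, 10^la)
  grid <- seq(bounds[1], bounds[2], length.out = 13L)
  vals <- vapply(grid, ll, numeric(1))
  k <- which.max(vals)
  if (k == length(grid)) return(Inf)
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  opt <- optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-4)
  if (opt$maximum >= bounds[2] - 0.05) return(Inf)
  # multinomial limit of the (constant-free) DM log-likelihood
  ll_inf <- sum(xval * log(p[gene_idx]))
  if (2 * (opt$objective - ll_inf) < stats::qchisq(0.95, df = 1)) return(Inf)
  10^opt$maximum
}

#' Shannon entropy of a probability vector (nats)
#'
#' @param p probability vector (non-negative, sums to 1).
#' @param tol tolerance for the sum-to-one check.
#' @return \eqn{-\sum p_i \log p_i} with \eqn{0 \log 0 = 0}.
#' @export
shannon_entropy <- function(p, tol = 1e-8) {
  if (any(p < 0)) stop("probabilities must be non-negative", call. = FALSE)
  if (abs(sum(p) - 1) > tol) stop("probabilities must sum to 1", call. = FALSE)
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}
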