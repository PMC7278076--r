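#' Group candidate barcodes by size
#'
#' Orders the B1 barcodes by non-decreasing total count and cuts them into
#' consecutive groups of `s` barcodes. When the last group holds fewer than
#' `s/2` barcodes it is merged into the previous one, so every group except
#' possibly the last has exactly `s` members and the last has between `s/2`
#' and `2s - 1`. Grouping by size keeps within-group totals comparable,
#' which reduces size-driven bias in the correlation clustering.
#'
#' @param b1_totals per-barcode totals of the B1 barcodes; names, when
#'   present, break ties deterministically.
#' @param s target group size (default 1000).
#' @return a `SizeGroups`: list with `group_size_s`, `order` (the sorting
#'   permutation) and `groups`, a list of integer index vectors into the
#'   input.
#' @export
group_by_size <- function(b1_totals, s = 1000) {
  n <- length(b1_totals)
  if (n < 1L) stop("no barcodes to group", call. = FALSE)
  assert_scalar_number(s, "s", lower = 2)
  ord <- if (is.null(names(b1_totals))) {
    order(b1_totals)
  } else {
    order(b1_totals, names(b1_totals))
  }
  k <- ceiling(n / s)
  grp <- pmin(((seq_len(n) - 1L) %/% s) + 1L, k)
  sizes <- tabulate(grp, k)
  if (k >= 2L && sizes[k] < s / 2) {
    grp[grp == k] <- k - 1L
    k <- k - 1L
  }
  groups <- split(ord, grp)
  names(groups) <- NULL
  structure(
    list(group_size_s = s, order = ord, groups = groups),
    class = "SizeGroups"
  )
}

# Pearson correlation matrix with a defined value for constant columns:
# identical constant pairs correlate at 1, otherwise 0.
safe_cor <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sds <- sqrt(pmax(0, (colSums(X^2) - n * mu^2) / (n - 1)))
  C <- suppressWarnings(cor(X))
  zv <- which(sds <= 1e-12)
  if (length(zv)) {
    for (j in zv) {
      same <- vapply(seq_len(ncol(X)),
                     function(k) isTRUE(all(X[, k] == X[, j])), logical(1))
      C[j, ] <- ifelse(same, 1, 0)
      C[, j] <- C[j, ]
    }
  }
  C[is.na(C)] <- 0
  C
}

#' Calibrate cluster-tightness thresholds from the data
#'
#' Simulates, for each size N in 100, 200, ..., 1000, a reference tight
#' cluster of `n_samples` multinomial(N, p*) draws, where p* is whichever
#' of the ambient profile and the high-count profile has larger Shannon
#' entropy (the higher-entropy profile is less dominated by a few genes and
#' therefore less outlier-driven). The threshold kappa for that size is the
#' average pairwise Pearson correlation of the simulated cluster: a real
#' cluster of barcodes must beat the correlation that pure sampling noise
#' around a common profile already achieves.
#'
#' @param profile a [estimate_background_profile()] result.
#' @param n_samples draws per reference cluster (default 100).
#' @param seed integer seed.
#' @return a `TightnessTable`: data.frame with columns `size`, `kappa` and
#'   `sd_pair` (the spread of pairwise correlations within the reference
#'   cluster, used by [extract_tight_clusters()] to guard against chance
#'   tightness); `n_samples` is carried as an attribute.
#' @export
calibrate_thresholds <- function(profile, n_samples = 100, seed = 1L) {
  stopifnot(inherits(profile, "BackgroundProfile"))
  assert_scalar_number(n_samples, "n_samples", lower = 2)
  p0 <- profile$p_b0
  if (length(p0) < 2L) stop("need at least 2 genes to calibrate", call. = FALSE)
  p2 <- profile$p_b2
  pstar <- p0
  if (!is.null(p2) && shannon_entropy(p2) > shannon_entropy(p0)) pstar <- p2
  sizes <- seq(100L, 1000L, by = 100L)
  stats <- with_seed(seed, vapply(sizes, function(N) {
    X <- rmultinom(n_samples, N, pstar)
    C <- safe_cor(X)
    ut <- C[upper.tri(C)]
    c(mean(ut), stats::sd(ut))
  }, numeric(2)))
  out <- data.frame(size = sizes, kappa = stats[1L, ], sd_pair = stats[2L, ])
  attr(out, "n_samples") <- n_samples
  class(out) <- c("TightnessTable", "data.frame")
  out
}

# Acceptance threshold for a candidate cluster of k members out of a group
# of n_group barcodes: kappa interpolated linearly at the cluster's median
# total (clamped to the calibrated range) plus a null envelope. Background
# barcodes are themselves draws around a common profile — exactly what the
# reference clusters simulate — so a bare mean-vs-mean comparison passes
# pure noise about half the time, and dendrogram nodes are additionally
# selected for above-average correlation. The envelope is scaled by the
# calibrated pairwise spread: a selection term 5.5 * (k/2)^(-1/4), the
# empirical upper envelope of how far the tightest k-node of a null
# dendrogram sits above the mean (about 5 sd for pairs, under 1 sd at the
# root; measured over null groups of 300-600 barcodes and inflated ~20%),
# with a mild sqrt(log n) growth for larger groups, plus a
# calibration-noise term 2 / sqrt(n_samples).
match_kappa <- function(table, member_totals, k = NULL, n_group = NULL) {
  target <- min(max(median(member_totals), min(table$size)), max(table$size))
  kap <- stats::approx(table$size, table$kappa, xout = target, rule = 2)$y
  if (is.null(k)) return(kap)
  sdp <- stats::approx(table$size, table$sd_pair, xout = target, rule = 2)$y
  n_samples <- attr(table, "n_samples") %||% 100
  selection <- 5.5 * (k / 2)^(-0.25) * sqrt(log(max(n_group, 3)) / log(600))
  margin <- sdp * (selection + 2 / sqrt(n_samples))
  list(kappa = kap, threshold = kap + margin)
}

#' Extract tight clusters from one size group
#'
#' Barcodes are clustered hierarchically with average linkage on the
#' distance 1 - Pearson correlation of their raw count vectors. The
#' dendrogram is walked from the root; a node is accepted as a tight
#' cluster when its leaves' average pairwise correlation exceeds the
#' calibrated kappa for its size (interpolated at the cluster's median
#' total count) plus a null envelope guarding against chance tightness
#' (see the package vignette), and accepted nodes are maximal (their
#' subtrees are not split further). Barcodes covered by no accepted node
#' are routed to individual testing.
#'
#' @param m count matrix.
#' @param group integer vector of barcode column indices forming one group.
#' @param table a [calibrate_thresholds()] result.
#' @return a `ClusterSet`: list with `tight_clusters` (each a list with
#'   `barcodes`, `avg_cor`, `kappa`, `threshold`) and `unclustered`
#'   (barcode indices).
#' @export
extract_tight_clusters <- function(m, group, table) {
  stopifnot(inherits(table, "TightnessTable"))
  if (length(group) < 2L) {
    return(structure(list(tight_clusters = list(), unclustered = group),
                     class = "ClusterSet"))
  }
  X <- as.matrix(m[, group, drop = FALSE])
  totals <- colSums(X)
  C <- safe_cor(X)
  hc <- stats::hclust(stats::as.dist(1 - C), method = "average")
  n <- length(group)

  # bottom-up pass: per merge node, member leaves and the sum of pairwise
  # correlations among them (S), so avg_cor is O(1) at each node
  members <- vector("list", n - 1L)
  S <- numeric(n - 1L)
  node_members <- function(k) if (k < 0L) -k else members[[k]]
  node_S <- function(k) if (k < 0L) 0 else S[k]
  for (k in seq_len(n - 1L)) {
    a <- hc$merge[k, 1L]; b <- hc$merge[k, 2L]
    ma <- node_members(a); mb <- node_members(b)
    members[[k]] <- c(ma, mb)
    S[k] <- node_S(a) + node_S(b) + sum(C[ma, mb])
  }

  accepted <- list()
  stack <- n - 1L
  singles <- integer(0)
  while (length(stack)) {
    k <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (k < 0L) { singles <- c(singles, -k); next }
    mem <- members[[k]]
    sz <- length(mem)
    avg <- S[k] / (sz * (sz - 1) / 2)
    kap <- match_kappa(table, totals[mem], k = sz, n_group = n)
    if (sz >= 2L && avg > kap$threshold) {
      accepted[[length(accepted) + 1L]] <-
        list(barcodes = group[mem], avg_cor = avg, kappa = kap$kappa,
             threshold = kap$threshold)
    } else {
      stack <- c(stack, hc$merge[k, 1L], hc$merge[k, 2L])
    }
  }
  structure(
    list(tight_clusters = accepted, unclustered = group[singles]),
    class = "ClusterSet"
  )
}

#' @export
print.ClusterSet <- function(x, ...) {
  cat(sprintf("ClusterSet: %d tight clusters (%d barcodes), %d unclustered\n",
              length(x$tight_clusters),
              sum(vapply(x$tight_clusters, function(cl) length(cl$barcodes), numeric(1))),
              length(x$unclustered)))
  invisible(x)
}
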