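#' Call cells with the cluster-based pipeline
#'
#' Full cell-calling pipeline for a droplet UMI count matrix. After
#' dropping all-zero genes/barcodes the barcodes are partitioned by total
#' count into background (B0), candidates (B1) and high-count cells (B2,
#' retained outright). The smoothed ambient profile and its
#' Dirichlet-multinomial concentration are estimated from B0. B1 barcodes
#' are grouped by size, each group is clustered on Pearson correlation, and
#' tight clusters (tighter than size-matched multinomial reference
#' clusters) are tested jointly against the background; members of
#' BH-significant clusters are retained. All remaining B1 barcodes —
#' unclustered ones and members of non-significant clusters — fall back to
#' the individual-barcode test with its own BH pass.
#'
#' @param m count matrix.
#' @param lower background threshold (default 100).
#' @param upper high-count threshold or `"auto"` (knee point, the default).
#' @param fdr target false discovery rate for both BH passes (default 0.01).
#' @param s size-group width (default 1000).
#' @param m_iter Monte-Carlo iterations per test (default 1000).
#' @param seed integer seed; the run is fully deterministic given it.
#' @return a `CellCalls`: list with `retained` (barcode ids), `results`
#'   (per-barcode data.frame: barcode, total, tier, provenance, statistic,
#'   p_value, q_value, retained), `partition`, `profile`, `kappa_table`,
#'   `clusters`, `fdr`, `seed`.
#' @export
run_cb2 <- function(m, lower = 100, upper = "auto", fdr = 0.01, s = 1000,
                    m_iter = 1000, seed = 1L) {
  assert_scalar_number(fdr, "fdr", lower = 1e-12, upper = 1 - 1e-12)
  m <- drop_empty(m)
  part <- partition_barcodes(m, lower = lower, upper = upper)
  profile <- estimate_background_profile(m, part)
  profile$concentration <- estimate_concentration(m, part, profile)
  seeds <- derive_seeds(seed, 3L)

  totals <- barcode_totals(m)
  res <- data.frame(
    barcode = colnames(m), total = as.numeric(totals),
    tier = "B1", provenance = NA_character_,
    statistic = NA_real_, p_value = NA_real_, q_value = NA_real_,
    retained = FALSE, stringsAsFactors = FALSE
  )
  res$tier[part$b0] <- "B0"
  res$tier[part$b2] <- "B2"
  res$provenance[part$b2] <- "high_count"
  res$retained[part$b2] <- TRUE

  kappa_table <- calibrate_thresholds(profile, seed = seeds[1L])
  clusters <- list()
  individual <- integer(0)

  if (length(part$b1)) {
    b1_totals <- totals[part$b1]
    names(b1_totals) <- colnames(m)[part$b1]
    sg <- group_by_size(b1_totals, s = s)
    for (g in sg$groups) {
      cs <- extract_tight_clusters(m, part$b1[g], kappa_table)
      clusters <- c(clusters, cs$tight_clusters)
      individual <- c(individual, cs$unclustered)
    }

    if (length(clusters)) {
      # one shared pool of incremental null paths serves every cluster size
      stats <- lapply(clusters, function(cl) {
        cluster_stat(m, cl$barcodes, profile$p_b0)
      })
      sizes <- sort(unique(vapply(stats, `[[`, integer(1), "n_ref")))
      null_cors <- simulate_null_cors(profile$p_b0, sizes, m_iter, seeds[2L])
      cache <- new.env(parent = emptyenv())
      for (s_i in seq_along(sizes)) {
        cache[[as.character(sizes[s_i])]] <- null_cors[, s_i]
      }
      tests <- lapply(seq_along(clusters), function(i) {
        cluster_mc_test(m, clusters[[i]]$barcodes, profile,
                        m_iter = m_iter, seed = seeds[2L],
                        null_cache = cache)
      })
      cl_p <- vapply(tests, `[[`, numeric(1), "p_value")
      cl_q <- bh_adjust(cl_p)
      for (i in seq_along(clusters)) {
        clusters[[i]]$t_c <- tests[[i]]$t_c
        clusters[[i]]$n_ref <- tests[[i]]$n_ref
        clusters[[i]]$p_value <- cl_p[i]
        clusters[[i]]$q_value <- cl_q[i]
        idx <- clusters[[i]]$barcodes
        res$statistic[idx] <- tests[[i]]$t_c
        res$p_value[idx] <- cl_p[i]
        res$q_value[idx] <- cl_q[i]
        if (cl_q[i] <= fdr) {
          res$provenance[idx] <- "cluster_test"
          res$retained[idx] <- TRUE
        } else {
          individual <- c(individual, idx)
        }
      }
    }

    if (length(individual)) {
      ind <- ed_test_batch(m, individual, profile,
                           m_iter = m_iter, seed = seeds[3L])
      ind$q_value <- bh_adjust(ind$p_value)
      hit <- ind$q_value <= fdr
      idx <- ind$barcode_index
      res$statistic[idx] <- ind$log_lik
      res$p_value[idx] <- ind$p_value
      res$q_value[idx] <- ind$q_value
      res$provenance[idx[hit]] <- "individual_test"
      res$retained[idx[hit]] <- TRUE
      res$provenance[idx[!hit]] <- NA_character_
    }
  }

  structure(
    list(retained = res$barcode[res$retained],
         results = res,
         partition = part,
         profile = profile,
         kappa_table = kappa_table,
         clusters = clusters,
         fdr = fdr, seed = seed),
    class = "CellCalls"
  )
}

#' Call cells with the individual-barcode test only
#'
#' Baseline pipeline: the same partition and background model as
#' [run_cb2()], but every B1 barcode is tested individually and a single
#' BH pass is applied. Useful for comparing the power gain of the
#' cluster-based test.
#'
#' @inheritParams run_cb2
#' @return a `CellCalls` (see [run_cb2()]); `clusters` is empty.
#' @export
run_ed <- function(m, lower = 100, upper = "auto", fdr = 0.01,
                   m_iter = 1000, seed = 1L) {
  assert_scalar_number(fdr, "fdr", lower = 1e-12, upper = 1 - 1e-12)
  m <- drop_empty(m)
  part <- partition_barcodes(m, lower = lower, upper = upper)
  profile <- estimate_background_profile(m, part)
  profile$concentration <- estimate_concentration(m, part, profile)
  seeds <- derive_seeds(seed, 3L)

  totals <- barcode_totals(m)
  res <- data.frame(
    barcode = colnames(m), total = as.numeric(totals),
    tier = "B1", provenance = NA_character_,
    statistic = NA_real_, p_value = NA_real_, q_value = NA_real_,
    retained = FALSE, stringsAsFactors = FALSE
  )
  res$tier[part$b0] <- "B0"
  res$tier[part$b2] <- "B2"
  res$provenance[part$b2] <- "high_count"
  res$retained[part$b2] <- TRUE

  if (length(part$b1)) {
    ind <- ed_test_batch(m, part$b1, profile, m_iter = m_iter, seed = seeds[3L])
    ind$q_value <- bh_adjust(ind$p_value)
    hit <- ind$q_value <= fdr
    idx <- ind$barcode_index
    res$statistic[idx] <- ind$log_lik
    res$p_value[idx] <- ind$p_value
    res$q_value[idx] <- ind$q_value
    res$provenance[idx[hit]] <- "individual_test"
    res$retained[idx[hit]] <- TRUE
  }

  structure(
    list(retained = res$barcode[res$retained],
         results = res,
         partition = part,
         profile = profile,
         kappa_table = NULL,
         clusters = list(),
         fdr = fdr, seed = seed),
    class = "CellCalls"
  )
}

#' @export
print.CellCalls <- function(x, ...) {
  prov <- table(x$results$provenance[x$results$retained])
  cat(sprintf("CellCalls: %d barcodes retained (FDR target %g)\n",
              length(x$retained), x$fdr))
  for (nm in names(prov)) cat(sprintf("  %s: %d\n", nm, prov[[nm]]))
  invisible(x)
}

#' Remove retained barcodes dominated by mitochondrial expression
#'
#' Damaged or dying cells leak cytoplasmic RNA and are left with a high
#' mitochondrial fraction; they differ from the ambient background and so
#' are (correctly) retained by the tests, but are rarely wanted downstream.
#' This post-filter drops retained barcodes whose mitochondrial fraction is
#' at or above `threshold`.
#'
#' @param m the count matrix the calls were made on.
#' @param calls a `CellCalls` object.
#' @param mito_prefix character vector of gene-symbol prefixes identifying
#'   mitochondrial genes, matched case-insensitively (default `"MT-"`).
#' @param threshold removal threshold on the mitochondrial fraction;
#'   a barcode at exactly the threshold is removed (default 0.40).
#' @return the updated `CellCalls`.
#' @export
filter_mito <- function(m, calls, mito_prefix = "MT-", threshold = 0.40) {
  stopifnot(inherits(calls, "CellCalls"))
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  symbols <- attr(m, "gene_symbols") %||% rownames(m)
  is_mito <- Reduce(`|`, lapply(toupper(mito_prefix), function(pre) {
    startsWith(toupper(symbols), pre)
  }))
  if (!any(is_mito)) return(calls)
  keep_bc <- intersect(calls$retained, colnames(m))
  mito_frac <- Matrix::colSums(m[is_mito, keep_bc, drop = FALSE]) /
    Matrix::colSums(m[, keep_bc, drop = FALSE])
  drop <- keep_bc[mito_frac >= threshold]
  calls$retained <- setdiff(calls$retained, drop)
  calls$results$retained[calls$results$barcode %in% drop] <- FALSE
  calls$mito_filter <- list(prefix = mito_prefix, threshold = threshold,
                            removed = drop)
  calls
}
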