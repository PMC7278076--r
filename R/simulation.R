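# Build a sparse matrix column-wise from per-barcode sampled gene units.
# gene_units: integer vector of gene indices; bc_of_unit: parallel barcode
# index per unit.
units_to_sparse <- function(gene_units, bc_of_unit, n_genes, n_barcodes) {
  Matrix::sparseMatrix(
    i = gene_units, j = bc_of_unit, x = 1,
    dims = c(n_genes, n_barcodes), use.last.ij = FALSE
  )
}

# Multinomial draws with per-barcode totals from one shared profile,
# returned sparse. Sampling units i.i.d. from p and slicing them per
# barcode is exactly a multinomial per barcode.
rmultinom_sparse <- function(totals, p) {
  total_units <- sum(totals)
  g <- sample.int(length(p), total_units, replace = TRUE, prob = p)
  j <- rep.int(seq_along(totals), totals)
  units_to_sparse(g, j, length(p), length(totals))
}

#' Generate a synthetic droplet experiment
#'
#' Stand-in for a real 10x input dataset: a small number of correlated cell
#' subpopulations riding on an ambient multinomial background. Each cell
#' type has its own sparse expression profile (an independent Dirichlet
#' draw, so types are mutually distinct); the ambient profile is the equal
#' mixture of the type profiles, mimicking a soup of lysed cell contents.
#' Individual cells draw their own profile from a Dirichlet centred on
#' their type (concentration `cell_alpha`, inducing within-type correlation
#' with biological variability) and totals are log-normal around
#' `cell_scale`; ambient barcodes are multinomial with log-normal totals
#' around `ambient_scale`, so most fall at or below the conventional
#' background threshold of 100. The resulting barcode-rank curve shows the
#' plateau-cliff-tail shape that knee/inflection detection expects.
#'
#' @param n_genes number of genes (default 3000).
#' @param n_cell_types number of cell subpopulations (default 3).
#' @param n_cells number of real-cell barcodes (default 6000).
#' @param n_ambient number of ambient barcodes (default 20000).
#' @param seed integer seed.
#' @param cell_scale median real-cell total UMI count (default 5000).
#' @param ambient_scale median ambient total UMI count (default 50).
#' @param cell_alpha Dirichlet concentration of cells around their type
#'   profile (default 200; smaller = noisier cells).
#' @return a count matrix; cells come first in column order (barcode ids
#'   `cell-*`, then `amb-*`), but no downstream step uses that.
#' @export
generate_synthetic_input <- function(n_genes = 3000, n_cell_types = 3,
                                     n_cells = 6000, n_ambient = 20000,
                                     seed = 1L, cell_scale = 5000,
                                     ambient_scale = 50, cell_alpha = 200) {
  stopifnot(n_genes >= 2, n_cell_types >= 1, n_cells >= 1, n_ambient >= 1)
  with_seed(seed, {
    type_p <- vapply(seq_len(n_cell_types), function(t) {
      w <- rgamma(n_genes, shape = 0.1)
      w / sum(w)
    }, numeric(n_genes))
    ambient_p <- rowMeans(type_p)

    cell_type <- sample.int(n_cell_types, n_cells, replace = TRUE)
    cell_totals <- pmax(1L, as.integer(round(
      stats::rlnorm(n_cells, log(cell_scale), 0.35))))
    blocks <- split(seq_len(n_cells), ceiling(seq_len(n_cells) / 500))
    cell_cols <- lapply(blocks, function(ix) {
      cols <- vapply(ix, function(i) {
        w <- rgamma(n_genes, shape = cell_alpha * type_p[, cell_type[i]])
        if (sum(w) == 0) w <- type_p[, cell_type[i]]
        rmultinom(1L, cell_totals[i], w)[, 1L]
      }, numeric(n_genes))
      as(Matrix::Matrix(cols, sparse = TRUE), "CsparseMatrix")
    })
    cells <- do.call(cbind, cell_cols)

    amb_totals <- pmax(1L, as.integer(round(
      stats::rlnorm(n_ambient, log(ambient_scale), 0.6))))
    ambient <- rmultinom_sparse(amb_totals, ambient_p)

    counts <- cbind(cells, ambient)
    make_count_matrix(
      counts,
      gene_ids = sprintf("gene-%05d", seq_len(n_genes)),
      barcode_ids = c(sprintf("cell-%06d", seq_len(n_cells)),
                      sprintf("amb-%06d", seq_len(n_ambient)))
    )
  })
}

#' Binomial downsampling of a count vector
#'
#' Each individual count unit is retained independently with probability
#' `1 - remove_rate`, so the output total is Binomial(total, 1 - remove_rate).
#'
#' @param x non-negative integer count vector.
#' @param remove_rate fraction of counts to remove, in [0, 1].
#' @param seed integer seed (NULL = use current RNG state).
#' @return thinned count vector of the same length.
#' @export
downsample_counts <- function(x, remove_rate, seed = NULL) {
  assert_scalar_number(remove_rate, "remove_rate", lower = 0, upper = 1)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (remove_rate == 0) return(x)
  with_seed(seed, {
    nz <- which(x > 0)
    x[nz] <- rbinom(length(nz), size = as.integer(round(x[nz])),
                    prob = 1 - remove_rate)
    x
  })
}

# Thin every stored entry of a sparse matrix at once.
downsample_matrix <- function(m, remove_rate, seed = NULL) {
  if (remove_rate == 0) return(m)
  with_seed(seed, {
    m <- as(m, "CsparseMatrix")
    m@x <- as.numeric(rbinom(length(m@x), size = as.integer(round(m@x)),
                             prob = 1 - remove_rate))
    Matrix::drop0(m)
  })
}

#' Shuffle a random fraction of gene positions within a count vector
#'
#' Selects `round(fraction * length(x))` gene positions uniformly at random
#' and permutes the counts among them. The multiset of counts — and hence
#' the barcode total — is preserved; only which genes carry them changes,
#' making the vector less similar to any fixed profile.
#'
#' @param x count vector.
#' @param fraction fraction of gene positions to shuffle, in [0, 1].
#' @param seed integer seed (NULL = use current RNG state).
#' @return shuffled count vector.
#' @export
shuffle_gene_fraction <- function(x, fraction, seed = NULL) {
  assert_scalar_number(fraction, "fraction", lower = 0, upper = 1)
  n_sel <- round(fraction * length(x))
  if (n_sel < 2) return(x)
  with_seed(seed, {
    idx <- sample.int(length(x), n_sel)
    x[idx] <- x[idx][sample.int(n_sel)]
    x
  })
}

#' Default simulation configuration
#'
#' @param n_per_group simulated real cells per size group (default 2000).
#' @param downsample_g2 removal rate for small cells (default 0.90).
#' @param downsample_g15 removal rate for medium cells (default 0.50).
#' @param shuffle_fraction gene fraction shuffled per real cell in the
#'   shuffled design only (default 0.10).
#' @param seed integer seed.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_per_group = 2000, downsample_g2 = 0.90,
                       downsample_g15 = 0.50, shuffle_fraction = 0.10,
                       seed = 1L) {
  stopifnot(n_per_group >= 1)
  assert_scalar_number(downsample_g2, "downsample_g2", 0, 1)
  assert_scalar_number(downsample_g15, "downsample_g15", 0, 1)
  assert_scalar_number(shuffle_fraction, "shuffle_fraction", 0, 1)
  structure(
    list(n_per_group = n_per_group, downsample_g2 = downsample_g2,
         downsample_g15 = downsample_g15,
         shuffle_fraction = shuffle_fraction, seed = seed),
    class = "SimConfig"
  )
}

#' Simulate a labelled dataset from an input experiment (design IA)
#'
#' The inflection point of the input's barcode-rank curve divides low-count
#' from high-count barcodes. Background barcodes are regenerated one per
#' below-inflection input barcode: a multinomial draw of that barcode's
#' total from the Good-Turing-smoothed pooled low-range profile. Real cells
#' are sampled from the high-count barcodes: `n_per_group` copied unchanged
#' (G1, large), `n_per_group` thinned by 50% (G1.5, medium) and
#' `n_per_group` thinned by 90% (G2, small). The three sets are drawn
#' without replacement within a set and independently across sets. Truth
#' labels accompany every barcode for power/FDR scoring.
#'
#' @param input count matrix of a (real or synthetic) droplet experiment.
#' @param config a [sim_config()].
#' @return a `SimDataset`: list with `matrix`, `truth` (data.frame:
#'   barcode, label, source_total), `seed`, `config`.
#' @export
simulate_sim_ia <- function(input, config = sim_config()) {
  stopifnot(inherits(config, "SimConfig"))
  totals <- barcode_totals(input)
  infl <- find_thresholds(totals, mode = "inflection")
  low <- which(totals <= infl)
  high <- which(totals > infl)
  n <- config$n_per_group
  if (length(high) < 3 * n) {
    stop(sprintf("need at least %d high-count barcodes, found %d",
                 3 * n, length(high)), call. = FALSE)
  }
  if (!length(low)) stop("no below-inflection barcodes in input", call. = FALSE)

  seeds <- derive_seeds(config$seed, 5L)
  pooled_low <- Matrix::rowSums(input[, low, drop = FALSE])
  p_low <- good_turing_probs(pooled_low, warn = FALSE)

  bg <- with_seed(seeds[1L], rmultinom_sparse(as.integer(totals[low]), p_low))
  g1_src <- with_seed(seeds[2L], sample(high, n))
  g15_src <- with_seed(seeds[3L], sample(high, n))
  g2_src <- with_seed(seeds[4L], sample(high, n))

  g1 <- input[, g1_src, drop = FALSE]
  g15 <- downsample_matrix(input[, g15_src, drop = FALSE],
                           config$downsample_g15, seed = seeds[5L])
  g2 <- downsample_matrix(input[, g2_src, drop = FALSE],
                          config$downsample_g2, seed = seeds[5L] %% 1000003L + 1L)

  counts <- cbind(bg, g1, g15, g2)
  ids <- c(sprintf("bg-%06d", seq_along(low)),
           sprintf("g1-%06d", seq_len(n)),
           sprintf("g15-%06d", seq_len(n)),
           sprintf("g2-%06d", seq_len(n)))
  mat <- make_count_matrix(counts, rownames(input), ids,
                           gene_symbols = attr(input, "gene_symbols"))
  truth <- data.frame(
    barcode = ids,
    label = c(rep("background", length(low)), rep("G1", n),
              rep("G1.5", n), rep("G2", n)),
    source_total = c(as.numeric(totals[low]), as.numeric(totals[g1_src]),
                     as.numeric(totals[g15_src]), as.numeric(totals[g2_src])),
    stringsAsFactors = FALSE
  )
  structure(
    list(matrix = mat, truth = truth, seed = config$seed, config = config,
         inflection = infl),
    class = "SimDataset"
  )
}

#' Simulate a labelled dataset with per-cell gene shuffling (design IB)
#'
#' Identical to [simulate_sim_ia()] — same seeds, so the background and the
#' sampled source barcodes match a paired IA run — except that a fraction
#' of gene positions (default 10%) is shuffled within every simulated real
#' cell, moving real cells further from the background profile while
#' preserving their totals. Background barcodes are not shuffled.
#'
#' @inheritParams simulate_sim_ia
#' @return a `SimDataset` (see [simulate_sim_ia()]).
#' @export
simulate_sim_ib <- function(input, config = sim_config()) {
  ds <- simulate_sim_ia(input, config)
  frac <- config$shuffle_fraction
  real <- which(ds$truth$label != "background")
  shuffle_seeds <- derive_seeds(ds$seed + 211L, length(real))
  mat <- as(ds$matrix, "CsparseMatrix")
  dense_cols <- as.matrix(mat[, real, drop = FALSE])
  for (j in seq_along(real)) {
    dense_cols[, j] <- shuffle_gene_fraction(dense_cols[, j], frac,
                                             seed = shuffle_seeds[j])
  }
  mat[, real] <- Matrix::Matrix(dense_cols, sparse = TRUE)
  mat <- Matrix::drop0(mat)
  ds$matrix <- make_count_matrix(mat, rownames(ds$matrix), colnames(ds$matrix),
                                 gene_symbols = attr(ds$matrix, "gene_symbols"))
  ds$design <- "IB"
  ds
}

#' Score cell calls against simulation truth
#'
#' @param calls a `CellCalls` (or a character vector of retained barcodes).
#' @param truth a `SimDataset` or its `truth` data.frame.
#' @return an `EvalMetrics`: list with `power_g1`, `power_g15`, `power_g2`,
#'   `empirical_fdr` (called background barcodes over total calls; 0 when
#'   nothing is called) and `n_called`.
#' @export
evaluate_calls <- function(calls, truth) {
  retained <- if (inherits(calls, "CellCalls")) calls$retained else calls
  tr <- if (inherits(truth, "SimDataset")) truth$truth else truth
  stopifnot(is.data.frame(tr), all(c("barcode", "label") %in% names(tr)))
  unknown <- setdiff(retained, tr$barcode)
  if (length(unknown)) {
    stop("calls contain barcodes absent from the truth table: ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  called <- tr$barcode %in% retained
  pow <- function(lab) {
    in_g <- tr$label == lab
    if (!any(in_g)) return(NA_real_)
    sum(called & in_g) / sum(in_g)
  }
  n_called <- sum(called)
  fdr <- if (n_called == 0) 0 else
    sum(called & tr$label == "background") / n_called
  structure(
    list(power_g1 = pow("G1"), power_g15 = pow("G1.5"), power_g2 = pow("G2"),
         empirical_fdr = fdr, n_called = n_called),
    class = "EvalMetrics"
  )
}

#' @export
print.EvalMetrics <- function(x, ...) {
  cat(sprintf(
    "EvalMetrics: power G1=%.3f G1.5=%.3f G2=%.3f; empirical FDR=%.4f (%d called)\n",
    x$power_g1, x$power_g15, x$power_g2, x$empirical_fdr, x$n_called))
  invisible(x)
}
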