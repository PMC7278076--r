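# Shared fixtures, all generated in code.

# Small deterministic sparse matrix from a dense definition.
as_counts <- function(dense, genes = NULL, barcodes = NULL) {
  dense <- as.matrix(dense)
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(dense)))
  barcodes <- barcodes %||% sprintf("b%02d", seq_len(ncol(dense)))
  dropletcall:::make_count_matrix(
    Matrix::Matrix(dense, sparse = TRUE), genes, barcodes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A background profile object without running the estimation pipeline.
fake_profile <- function(p_b0, p_b2 = NULL, concentration = Inf) {
  structure(list(p_b0 = p_b0, p_b2 = p_b2, concentration = concentration),
            class = "BackgroundProfile")
}

# Skewed but strictly positive probability vector, deterministic.
fixed_profile <- function(n_genes, seed = 99) {
  dropletcall:::with_seed(seed, {
    w <- rgamma(n_genes, shape = 0.3) + 1e-4
    w / sum(w)
  })
}

# A small droplet-like input used by several suites: keeps runtime low while
# preserving the plateau-cliff-tail rank curve.
small_input <- function(seed = 7) {
  generate_synthetic_input(n_genes = 400, n_cell_types = 2, n_cells = 300,
                           n_ambient = 2500, seed = seed,
                           cell_scale = 2000, ambient_scale = 40)
}
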