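# ---- synthetic input generator ---------------------------------------------

test_that("synthetic input has a detectable knee and sensible partition", {
  m <- small_input(seed = 3)
  tot <- barcode_totals(m)
  knee <- find_thresholds(tot, "knee")
  expect_gt(knee, min(tot))
  expect_lt(knee, max(tot))
  part <- partition_barcodes(drop_empty(m))
  expect_gt(length(part$b0), 0)
  expect_gt(length(part$b1), 0)
  expect_gt(length(part$b2), 0)
})

test_that("within-type correlation exceeds between-type correlation", {
  m <- generate_synthetic_input(n_genes = 300, n_cell_types = 2, n_cells = 60,
                                n_ambient = 50, seed = 12)
  X <- as.matrix(m[, 1:60])
  # types are assigned at generation; recover them from the profile blocks
  C <- suppressWarnings(cor(X))
  hc <- stats::cutree(stats::hclust(stats::as.dist(1 - C)), k = 2)
  within <- mean(C[outer(hc, hc, "==") & upper.tri(C)])
  between <- mean(C[outer(hc, hc, "!=") & upper.tri(C)])
  expect_gt(within, between)
})

test_that("generator is deterministic given seed", {
  a <- generate_synthetic_input(n_genes = 100, n_cells = 30, n_ambient = 40, seed = 9)
  b <- generate_synthetic_input(n_genes = 100, n_cells = 30, n_ambient = 40, seed = 9)
  expect_identical(as.matrix(a), as.matrix(b))
  c <- generate_synthetic_input(n_genes = 100, n_cells = 30, n_ambient = 40, seed = 10)
  expect_false(identical(as.matrix(a), as.matrix(c)))
})

# ---- downsampling ----------------------------------------------------------

test_that("downsampling obeys binomial thinning moments", {
  x <- rep(100, 100)  # total 10000
  expect_identical(downsample_counts(x, 0, seed = 1), x)
  expect_identical(downsample_counts(x, 1, seed = 1), rep(0, 100))
  totals <- vapply(1:25, function(s) sum(downsample_counts(x, 0.9, seed = s)),
                   numeric(1))
  expect_lt(abs(mean(totals) - 1000), 5 * sqrt(10000 * 0.1 * 0.9 / 25))
  expect_error(downsample_counts(c(-1, 2), 0.5), "non-negative")
})

test_that("per-entry thinning is Binomial(count, rate): chi-square GOF", {
  # one gene with count 6, thinned at keep rate 0.5, over 1000 seeds
  draws <- vapply(1:1000, function(s) downsample_counts(c(6), 0.5, seed = s),
                  numeric(1))
  obs <- tabulate(draws + 1, nbins = 7)
  expected <- dbinom(0:6, 6, 0.5) * 1000
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.99, df = 6))
})

# ---- gene shuffling --------------------------------------------------------

test_that("shuffle preserves the count multiset and selects the exact fraction", {
  x <- c(5, 0, 0, 2, 7, 1, 0, 0, 3, 9)
  expect_identical(shuffle_gene_fraction(x, 0, seed = 1), x)
  s1 <- shuffle_gene_fraction(x, 1, seed = 2)
  expect_identical(sort(s1), sort(x))
  expect_identical(sum(s1), sum(x))
  # fraction 0.1 of 3000 genes -> exactly 300 positions may move
  x2 <- seq_len(3000)
  s2 <- shuffle_gene_fraction(x2, 0.1, seed = 3)
  expect_identical(sort(s2), sort(x2))
  expect_lte(sum(s2 != x2), 300)
  expect_gt(sum(s2 != x2), 250)  # nearly all selected positions move
})

# ---- SIM IA ----------------------------------------------------------------

test_that("design IA emits exact group sizes and matched background", {
  inp <- small_input(seed = 21)
  cfg <- sim_config(n_per_group = 80, seed = 5)
  ds <- simulate_sim_ia(inp, cfg)
  expect_equal(sum(ds$truth$label == "G1"), 80)
  expect_equal(sum(ds$truth$label == "G1.5"), 80)
  expect_equal(sum(ds$truth$label == "G2"), 80)
  tot_in <- barcode_totals(inp)
  low <- which(tot_in <= ds$inflection)
  bg <- ds$truth[ds$truth$label == "background", ]
  expect_equal(nrow(bg), length(low))
  # background totals equal the below-inflection input totals, one for one
  expect_equal(unname(barcode_totals(ds$matrix)[bg$barcode]),
               unname(as.numeric(tot_in[low])))
  expect_equal(bg$source_total, unname(as.numeric(tot_in[low])))
  # G1 columns are verbatim copies of their source barcodes
  g1_tot <- barcode_totals(ds$matrix)[ds$truth$barcode[ds$truth$label == "G1"]]
  expect_equal(unname(g1_tot), ds$truth$source_total[ds$truth$label == "G1"])
})

test_that("design IA downsampling hits its thinning expectations", {
  inp <- small_input(seed = 22)
  ratios <- vapply(1:3, function(r) {
    ds <- simulate_sim_ia(inp, sim_config(n_per_group = 100, seed = 30 + r))
    g2 <- ds$truth[ds$truth$label == "G2", ]
    sum(barcode_totals(ds$matrix)[g2$barcode]) / sum(g2$source_total)
  }, numeric(1))
  # keep rate 0.10; 3 replicates x 100 cells of ~2000 counts
  expect_lt(abs(mean(ratios) - 0.10), 0.005)
  expect_error(simulate_sim_ia(small_input(), sim_config(n_per_group = 5000)),
               "high-count")
})

# ---- SIM IB ----------------------------------------------------------------

test_that("design IB shuffles real cells only and conserves totals", {
  inp <- small_input(seed = 23)
  cfg <- sim_config(n_per_group = 60, seed = 8)
  ia <- simulate_sim_ia(inp, cfg)
  ib <- simulate_sim_ib(inp, cfg)
  expect_identical(ia$truth$barcode, ib$truth$barcode)
  # totals unchanged everywhere; background columns bit-identical
  expect_equal(unname(barcode_totals(ia$matrix)),
               unname(barcode_totals(ib$matrix)))
  bg <- ia$truth$barcode[ia$truth$label == "background"]
  expect_equal(as.matrix(ia$matrix[, bg]), as.matrix(ib$matrix[, bg]))
  # real cells differ (some shuffled gene carries a different count)
  real <- ia$truth$barcode[ia$truth$label != "background"]
  expect_false(identical(as.matrix(ia$matrix[, real]),
                         as.matrix(ib$matrix[, real])))
})

test_that("design IB real cells sit farther from the ambient profile", {
  inp <- small_input(seed = 24)
  cfg <- sim_config(n_per_group = 60, seed = 9)
  ia <- simulate_sim_ia(inp, cfg)
  ib <- simulate_sim_ib(inp, cfg)
  low_profile <- good_turing_probs(
    Matrix::rowSums(inp[, barcode_totals(inp) <= ia$inflection]), warn = FALSE)
  real <- ia$truth$barcode[ia$truth$label != "background"]
  cor_ia <- dropletcall:::sparse_profile_cors(ia$matrix[, real], low_profile)
  cor_ib <- dropletcall:::sparse_profile_cors(ib$matrix[, real], low_profile)
  expect_lt(mean(cor_ib), mean(cor_ia))
})

# ---- evaluation ------------------------------------------------------------

test_that("evaluate_calls arithmetic and edge conventions", {
  truth <- data.frame(
    barcode = c(sprintf("c%02d", 1:6), sprintf("b%02d", 1:4)),
    label = c(rep(c("G1", "G1.5", "G2"), each = 2), rep("background", 4)),
    stringsAsFactors = FALSE
  )
  perfect <- evaluate_calls(sprintf("c%02d", 1:6), truth)
  expect_equal(c(perfect$power_g1, perfect$power_g15, perfect$power_g2),
               c(1, 1, 1))
  expect_equal(perfect$empirical_fdr, 0)

  one_bad <- evaluate_calls(c(sprintf("c%02d", 1:6), "b01", truth$barcode[7]), truth)
  expect_equal(one_bad$empirical_fdr, 1 / 7)

  none <- evaluate_calls(character(0), truth)
  expect_equal(none$empirical_fdr, 0)
  expect_equal(none$power_g1, 0)

  # order invariance and unknown-barcode error
  shuf <- evaluate_calls(rev(sprintf("c%02d", 1:6)), truth[sample(1:10), ])
  expect_equal(shuf$power_g2, 1)
  expect_error(evaluate_calls("zz", truth), "absent")
})
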