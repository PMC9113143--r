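test_that("spectrum bins VAFs into 19 half-open bins with a closed top bin", {
  empty <- vaf_spectrum(numeric(0))
  expect_length(empty$counts, 19)
  expect_true(all(empty$counts == 0))

  sp <- vaf_spectrum(c(0.07, 0.52, 0.98, 1.0))
  want <- rep(0, 19)
  want[1] <- 1   # [0.05, 0.10)
  want[10] <- 1  # [0.50, 0.55)
  want[19] <- 2  # [0.95, 1.00] closed: 0.98 and 1.0
  expect_equal(sp$counts, want)
  expect_equal(sp$bin_edges, (1:20) * 0.05)

  # sub-threshold VAFs are excluded; boundary 0.05 is included
  expect_equal(sum(vaf_spectrum(c(0.049, 0.05, 0.0))$counts), 1)
})

test_that("raw spectrum counts sum to the number of detectable VAFs and are
           permutation invariant", {
  set.seed(5)
  v <- runif(200)
  expect_equal(sum(vaf_spectrum(v)$counts), sum(v >= 0.05))
  expect_equal(vaf_spectrum(v)$counts, vaf_spectrum(rev(v))$counts)
  expect_equal(vaf_spectrum(sample(v))$counts, vaf_spectrum(v)$counts)
})

test_that("per-cell-mean normalization divides by n_cells and validates it", {
  v <- c(0.2, 0.4, 0.6)
  sp <- vaf_spectrum(v, n_cells = 10, normalization = "per_cell_mean")
  expect_equal(sum(sp$counts), 0.3)
  expect_error(vaf_spectrum(v, n_cells = 0, normalization = "per_cell_mean"),
               "n_cells")
  expect_error(vaf_spectrum(v, normalization = "per_cell_mean"), "n_cells")
  expect_error(vaf_spectrum(c(-0.1, 0.5)), "\\[0, 1\\]")
})

make_cvm <- function(df, cells) {
  structure(list(vaf = df, cells = cells), class = "cell_variant_matrix")
}

test_that("per-cell burden counts defined positive VAFs, matching a naive loop", {
  vaf <- tibble::tibble(
    cell_id = c("c1", "c1", "c1", "c2", "c3"),
    cell_type = "B",
    variant_id = c("v1", "v2", "v3", "v1", "v2"),
    site = 1L, ref = "A", alt = "G",
    vaf = c(0, 0.2, 0.9, 0.5, 0))
  cells <- tibble::tibble(cell_id = c("c1", "c2", "c3", "c4"),
                          cell_type = "B", mean_depth = 50)
  burden <- per_cell_burden(make_cvm(vaf, cells))
  # naive loop oracle
  want <- vapply(cells$cell_id, function(cc) {
    sum(vaf$vaf[vaf$cell_id == cc] > 0)
  }, numeric(1))
  expect_equal(burden$n_variants[match(cells$cell_id, burden$cell_id)],
               unname(want))
  expect_equal(burden$n_variants[burden$cell_id == "c4"], 0)
})

test_that("homoplasmic and dominant fractions nest correctly", {
  vaf <- tibble::tibble(
    cell_id = c("c1", "c2", "c3", "c4"),
    cell_type = "B", variant_id = "v", site = 1L, ref = "A", alt = "G",
    vaf = c(1.0, 0.96, 0.6, 0.2))
  cells <- tibble::tibble(cell_id = paste0("c", 1:10), cell_type = "B",
                          mean_depth = 50)
  fr <- homoplasmic_dominant_fractions(make_cvm(vaf, cells))
  expect_equal(fr$homoplasmic_fraction, 0.2)  # c1, c2 of 10
  expect_equal(fr$dominant_fraction, 0.3)     # c1, c2, c3
  expect_gte(fr$dominant_fraction, fr$homoplasmic_fraction)
  none <- homoplasmic_dominant_fractions(make_cvm(vaf[0, ], cells))
  expect_equal(none$homoplasmic_fraction, 0)
  expect_equal(none$dominant_fraction, 0)
})

test_that("copy-number proxy is mito over total reads with per-type medians", {
  cells <- tibble::tibble(cell_id = c("a", "b", "c"),
                          cell_type = c("B", "B", "NK"),
                          mito_reads = c(5000, 0, 3000),
                          total_reads = c(50000, 10000, 50000))
  cn <- relative_copy_number(cells)
  expect_equal(cn$per_cell$copy_number_proxy, c(0.1, 0, 0.06))
  expect_equal(cn$per_type$median_proxy[cn$per_type$cell_type == "B"], 0.05)
  cells$total_reads[1] <- 0
  expect_error(relative_copy_number(cells), "total_reads")
})

test_that("NK baseline scales to 60% of the B/T baseline", {
  expect_equal(baseline_copy_number("NK"), 300)
  expect_equal(baseline_copy_number("B"), 500)
  expect_equal(baseline_copy_number("T"), 500)
})

test_that("early-fixed progenitor variants are excluded before spectra", {
  vaf <- tibble::tibble(
    cell_id = rep(c("p1", "p2", "b1"), each = 2),
    cell_type = rep(c("HSC", "HSC", "B"), each = 2),
    variant_id = rep(c("fixed", "low"), 3),
    site = rep(c(10L, 20L), 3), ref = "A",
    alt = rep(c("G", "C"), 3),
    vaf = c(0.99, 0.2, 0.98, 0.2, 0.97, 0.2))
  cells <- tibble::tibble(cell_id = c("p1", "p2", "b1"),
                          cell_type = c("HSC", "HSC", "B"), mean_depth = 50)
  out <- exclude_early_fixed(make_cvm(vaf, cells),
                             progenitor_types = "HSC")
  expect_setequal(unique(out$vaf$variant_id), "low")
  # naive recount oracle on the surviving variant set
  frac_fixed <- tapply(vaf$vaf[vaf$cell_type == "HSC"] > 0.9,
                       vaf$variant_id[vaf$cell_type == "HSC"], mean)
  expect_setequal(unique(out$vaf$variant_id),
                  names(frac_fixed)[frac_fixed <= 0.5])
  expect_warning(exclude_early_fixed(make_cvm(vaf, cells),
                                     progenitor_types = "CLP"),
                 "no progenitor")
})
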