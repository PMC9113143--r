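small_types <- function(n = 10) {
  tibble::tibble(label = "B", n_cells = n, baseline_copy_number = 500)
}

test_that("a signal-free spec yields only reference reads and an empty truth", {
  cohort <- generate_cohort(cohort_spec(cell_types = small_types(5),
                                        depth_mean = 20, seed = 3))
  expect_equal(nrow(cohort$truth$variants), 0)
  expect_true(all(cohort$matrix$counts$alt_fwd == 0))
  expect_true(all(cohort$matrix$counts$alt_rev == 0))
  expect_true(all(is.na(cohort$matrix$counts$alt)))
})

test_that("planted germline variants appear near VAF 1 in every cell", {
  germ <- tibble::tibble(site = 100L, alt = "T")
  if (mt_ref_base(100L) == "T") germ$alt <- "C"
  cohort <- generate_cohort(cohort_spec(cell_types = small_types(20),
                                        depth_mean = 100,
                                        germline_variants = germ, seed = 5))
  at100 <- cohort$matrix$counts[cohort$matrix$counts$site == 100, ]
  expect_equal(nrow(at100), 20)
  vaf <- (at100$alt_fwd + at100$alt_rev) /
    (at100$ref_fwd + at100$ref_rev + at100$alt_fwd + at100$alt_rev)
  expect_true(all(vaf > 0.95))
  expect_equal(cohort$truth$variants$class, "germline")
})

test_that("somatic alt fractions track the planted VAF within binomial noise", {
  site <- 5000L
  alt <- setdiff(c("A", "C", "G", "T"), c(mt_ref_base(site), "T", "A"))[1]
  som <- tibble::tibble(site = site, alt = alt, vaf = 0.5, n_carriers = 100L)
  cohort <- generate_cohort(cohort_spec(cell_types = small_types(100),
                                        depth_mean = 200,
                                        somatic_vafs = som, seed = 11))
  rows <- cohort$matrix$counts[cohort$matrix$counts$site == site &
                                 !is.na(cohort$matrix$counts$alt), ]
  alt_n <- sum(rows$alt_fwd + rows$alt_rev)
  depth <- sum(rows$ref_fwd + rows$ref_rev + rows$alt_fwd + rows$alt_rev)
  # pooled binomial: 3 standard errors around p = 0.5
  se <- sqrt(0.25 / depth)
  expect_lt(abs(alt_n / depth - 0.5), 3 * se)
})

test_that("counts conserve depth and strand split per (cell, site)", {
  cohort <- generate_cohort(cohort_spec(
    cell_types = small_types(10), depth_mean = 50,
    somatic_vafs = tibble::tibble(site = 2000L,
                                  alt = setdiff(c("A", "C", "G", "T"),
                                                c(mt_ref_base(2000L), "T",
                                                  "A"))[1],
                                  vaf = 0.3, n_carriers = 10L),
    seed = 2))
  cc <- cohort$matrix$counts
  expect_true(all(cc$ref_fwd >= 0 & cc$ref_rev >= 0 &
                    cc$alt_fwd >= 0 & cc$alt_rev >= 0))
  expect_false(any(duplicated(paste(cc$cell_id, cc$site))))
  # mito_reads equals the column sums of the count table per cell
  per_cell <- tapply(cc$ref_fwd + cc$ref_rev + cc$alt_fwd + cc$alt_rev,
                     cc$cell_id, sum)
  expect_equal(as.numeric(per_cell[cohort$matrix$cells$cell_id]),
               as.numeric(cohort$matrix$cells$mito_reads))
})

test_that("identical seeds reproduce the cohort exactly, different seeds do not", {
  spec1 <- cohort_spec(cell_types = small_types(5), depth_mean = 30,
                       n_damage_sites = 3, seed = 21)
  spec2 <- cohort_spec(cell_types = small_types(5), depth_mean = 30,
                       n_damage_sites = 3, seed = 21)
  spec3 <- cohort_spec(cell_types = small_types(5), depth_mean = 30,
                       n_damage_sites = 3, seed = 22)
  c1 <- generate_cohort(spec1)
  c2 <- generate_cohort(spec2)
  c3 <- generate_cohort(spec3)
  expect_identical(c1$matrix$counts, c2$matrix$counts)
  expect_identical(c1$truth, c2$truth)
  expect_false(identical(c1$matrix$counts, c3$matrix$counts))
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(cohort_spec(germline_variants = tibble::tibble(site = 20000L,
                                                              alt = "A")),
               "germline_variants")
  expect_error(cohort_spec(error_rate = -0.1), "error_rate")
  expect_error(cohort_spec(cell_types = tibble::tibble(
    label = "B", n_cells = 0, baseline_copy_number = 500)), "n_cells")
  expect_error(
    cohort_spec(somatic_vafs = tibble::tibble(site = 10L, alt = "A",
                                              vaf = 1.5, n_carriers = 1L)),
    "somatic_vafs")
})

test_that("somatic plants may not use damage-type substitutions", {
  # find a G site and try to plant G>T
  gsite <- as.integer(regexpr("G", synthetic_mt_genome(), fixed = TRUE))
  spec <- cohort_spec(cell_types = small_types(5),
                      somatic_vafs = tibble::tibble(site = gsite, alt = "T",
                                                    vaf = 0.5,
                                                    n_carriers = 2L))
  expect_error(generate_cohort(spec), "G>T")
})

test_that("simulate_site_counts honors depth, VAF extremes and errors", {
  set.seed(7)
  z <- simulate_site_counts(0, 50, strand_fwd = 0.5)
  expect_equal(sum(z), 50)
  expect_equal(unname(z["alt_fwd"] + z["alt_rev"]), 0)
  o <- simulate_site_counts(1, 40, strand_fwd = 0.5)
  expect_equal(unname(o["alt_fwd"] + o["alt_rev"]), 40)
  expect_equal(unname(o["ref_fwd"] + o["ref_rev"]), 0)
  big <- simulate_site_counts(0.5, 1e5, strand_fwd = 0.5)
  expect_lt(abs((big["alt_fwd"] + big["alt_rev"]) / 1e5 - 0.5), 0.005)
  expect_error(simulate_site_counts(0.5, -1), "depth")
})

test_that("with zero error rates every alt read traces to a planted variant", {
  som <- tibble::tibble(site = 7777L,
                        alt = setdiff(c("A", "C", "G", "T"),
                                      c(mt_ref_base(7777L), "T", "A"))[1],
                        vaf = 0.4, n_carriers = 5L)
  cohort <- generate_cohort(cohort_spec(cell_types = small_types(10),
                                        depth_mean = 60, somatic_vafs = som,
                                        seed = 31))
  alt_sites <- unique(cohort$matrix$counts$site[
    cohort$matrix$counts$alt_fwd + cohort$matrix$counts$alt_rev > 0])
  expect_true(all(alt_sites %in% cohort$truth$variants$site))
})
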