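test_that("candidate calling applies the per-cell depth/alt/VAF thresholds", {
  acm <- make_acm(list(
    crow("c1", 5000, "A", "G", ref_n = 6, alt_n = 2),    # depth 8, VAF 0.25
    crow("c2", 6000, "A", "G", ref_n = 5, alt_n = 2),    # depth 7: below
    crow("c3", 7000, "A", "G", ref_n = 991, alt_n = 9),  # VAF 0.009: below
    crow("c4", 8000, "A", "G", ref_n = 7, alt_n = 1)))   # 1 alt read: below
  cand <- call_candidates(acm)
  expect_equal(cand$site, 5000L)
  expect_equal(cand$n_cells_candidate, 1L)
})

test_that("empty matrix gives an empty candidate set, not an error", {
  acm <- make_acm(list(crow("c1", 100, "A", ref_n = 10)))
  expect_equal(nrow(call_candidates(acm)), 0)
})

test_that("germline detection uses pooled VAF and the shared-cell rule", {
  # pooled VAF 0.95 -> germline by bulk rule
  bulk <- make_acm(lapply(1:10, function(i) {
    crow(paste0("c", i), 1000, "A", "G", ref_n = 5, alt_n = 95)
  }))
  g <- identify_germline(bulk)
  expect_equal(g$site, 1000L)
  expect_equal(g$rule, "bulk")

  # per-cell VAF 0.95 in 95% of covered cells, pooled dragged to ~0.86 by one
  # deep wild-type cell -> germline by shared-cell rule
  rows <- lapply(1:19, function(i) {
    crow(paste0("c", i), 2000, "A", "G", ref_n = 5, alt_n = 95)
  })
  rows[[20]] <- crow("c20", 2000, "A", "G", ref_n = 200, alt_n = 0)
  shared <- identify_germline(make_acm(rows))
  expect_equal(shared$site, 2000L)
  expect_true(shared$pooled_vaf < 0.90)
  expect_equal(shared$rule, "shared_cells")

  # pooled VAF 0.40 in every cell -> somatic-like, not germline
  low <- make_acm(lapply(1:10, function(i) {
    crow(paste0("c", i), 3000, "A", "G", ref_n = 60, alt_n = 40)
  }))
  expect_equal(nrow(identify_germline(low)), 0)
})

test_that("blacklists remove homopolymer sites and damage substitutions", {
  calls <- tibble::tibble(site = c(309L, 5000L, 10304L),
                          ref = c("C", "G", "G"),
                          alt = c("T", "T", "A"))
  kept <- apply_blacklists(calls)
  # 309 is a blacklisted position; G>T is a damage substitution; G>A survives
  expect_equal(kept$site, 10304L)
})

test_that("confidence filters demand 20x depth, 2 alt reads and strand balance", {
  cfg <- filter_config()
  acm <- make_acm(list(
    crow("c1", 1000, "A", "G", ref_n = 9, alt_n = 10),              # depth 19
    crow("c2", 2000, "A", "G", ref_n = 40, alt_n = 10, alt_fwd = 9), # f = 0.9
    crow("c3", 3000, "A", "G", ref_n = 40, alt_n = 10, alt_fwd = 5), # f = 0.5
    crow("c4", 4000, "A", "G", ref_n = 40, alt_n = 10, alt_fwd = 3))) # f = 0.3
  calls <- tibble::tibble(site = c(1000L, 2000L, 3000L, 4000L),
                          ref = "A", alt = "G")
  conf <- apply_confidence_filters(calls, acm, cfg)
  # f = 0.30 exactly fails the strict bound; only the balanced cell passes
  expect_equal(conf$site, 3000L)
  expect_equal(conf$n_cells_confident, 1L)
})

test_that("VAF recounting respects the 8x constraint and counts missing cells", {
  acm <- make_acm(list(
    crow("c1", 5000, "A", "G", ref_n = 40, alt_n = 10, alt_fwd = 5),
    crow("c2", 5000, "A", "G", ref_n = 6, alt_n = 6),   # 6 alt / 12 total
    crow("c3", 5000, "A", ref_n = 7),                    # depth 7: missing
    crow("c4", 5000, "A", ref_n = 30)))                  # 0 alt / 30
  calls <- apply_confidence_filters(
    tibble::tibble(site = 5000L, ref = "A", alt = "G"), acm, filter_config())
  cvm <- recount_vaf(calls, acm, filter_config())
  v <- cvm$vaf[order(cvm$vaf$cell_id), ]
  expect_equal(v$cell_id, c("c1", "c2", "c4"))
  expect_equal(v$vaf[v$cell_id == "c2"], 0.5)
  expect_equal(v$vaf[v$cell_id == "c4"], 0)
})

test_that("cell filtering drops cells at mean depth <= 10x", {
  # mean depth over all 16,569 sites: plant enough reads in a few rows
  deep_reads <- 16569 * 11   # mean 11
  shallow_reads <- 16569 * 9 # mean 9
  acm <- make_acm(list(
    crow("deep", 1, "A", ref_n = deep_reads),
    crow("shallow", 1, "A", ref_n = shallow_reads)))
  cvm <- recount_vaf(tibble::tibble(site = integer(0), ref = character(0),
                                    alt = character(0),
                                    cell_types = list()),
                     acm, filter_config())
  kept <- filter_cells(cvm)
  expect_equal(kept$cells$cell_id, "deep")
  expect_warning(filter_cells(structure(list(
    vaf = cvm$vaf, cells = cvm$cells[cvm$cells$cell_id == "shallow", ]),
    class = "cell_variant_matrix")), "mean-depth")
})

test_that("cascade recovers planted somatic truth and rejects artifacts", {
  set.seed(1)
  free <- setdiff(1:16569, default_site_blacklist())
  som_sites <- sort(sample(free, 30))
  som <- tibble::tibble(
    site = som_sites,
    alt = mitobottleneck:::random_alt(mt_ref_base(som_sites),
                                      avoid_damage = TRUE),
    vaf = runif(30, 0.05, 1), n_carriers = 10L)
  germ_sites <- sort(sample(setdiff(free, som_sites), 4))
  germ <- tibble::tibble(
    site = germ_sites,
    alt = mitobottleneck:::random_alt(mt_ref_base(germ_sites),
                                      avoid_damage = TRUE))
  cohort <- generate_cohort(cohort_spec(
    cell_types = tibble::tibble(label = "B", n_cells = 80,
                                baseline_copy_number = 500),
    depth_mean = 70, germline_variants = germ, somatic_vafs = som,
    artifact_sites = default_site_blacklist(), n_damage_sites = 8,
    seed = 77))
  res <- call_somatic_variants(cohort$matrix)
  truth <- cohort$truth$variants
  som_truth <- truth[truth$class == "somatic", ]
  expect_gte(mean(som_truth$site %in% res$variants$site), 0.95)
  bad <- truth[truth$class %in% c("artifact", "damage_error"), ]
  expect_equal(sum(bad$site %in% res$variants$site), 0)
  germ_truth <- truth[truth$class == "germline", ]
  expect_true(all(germ_truth$site %in% res$germline$site))
  # final somatic set disjoint from germline and blacklists
  expect_length(intersect(res$variants$site, res$germline$site), 0)
  expect_length(intersect(res$variants$site, default_site_blacklist()), 0)
})

test_that("cascade is deterministic and monotone in min_site_depth", {
  set.seed(9)
  free <- setdiff(1:16569, default_site_blacklist())
  sites <- sort(sample(free, 12))
  som <- tibble::tibble(
    site = sites,
    alt = mitobottleneck:::random_alt(mt_ref_base(sites),
                                      avoid_damage = TRUE),
    vaf = runif(12, 0.1, 0.9), n_carriers = 6L)
  cohort <- generate_cohort(cohort_spec(
    cell_types = tibble::tibble(label = "B", n_cells = 30,
                                baseline_copy_number = 500),
    depth_mean = 30, somatic_vafs = som, seed = 13))
  r1 <- call_somatic_variants(cohort$matrix)
  r2 <- call_somatic_variants(cohort$matrix)
  expect_identical(r1$variants, r2$variants)
  expect_identical(r1$cvm$vaf, r2$cvm$vaf)
  n_by_depth <- vapply(c(10, 20, 40, 80), function(d) {
    nrow(call_somatic_variants(cohort$matrix,
                               filter_config(min_site_depth = d))$variants)
  }, numeric(1))
  expect_true(all(diff(n_by_depth) <= 0))
})
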