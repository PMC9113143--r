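test_that("codon substitution enumeration matches the mitochondrial code", {
  # TTA (Leu): synonymous partners are TTG (Leu) and CTA (Leu) only
  counts <- codon_site_counts("TTA")
  expect_equal(unname(counts["SY"]), 2)
  expect_equal(unname(counts["NS"]), 7)
  expect_error(codon_site_counts("TNA"), "ambiguous")
})

test_that("every codon conserves NS + SY = 9", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  for (codon in codons) {
    expect_equal(sum(codon_site_counts(codon)), 9)
  }
})

test_that("potential-site totals are additive and doubling doubles them", {
  one <- count_potential_sites(c(g1 = "TTAGCT"))
  two <- count_potential_sites(c(g1 = "TTAGCTTTAGCT"))
  expect_equal(two$N, 2 * one$N)
  expect_equal(two$S, 2 * one$S)
  expect_equal(one$N + one$S, 9 * 2)
  expect_error(count_potential_sites(c(g = "TTN")), "ambiguous")
})

test_that("classification handles SY, NS and the TGA = Trp rule in context", {
  # custom reference with known codons at the start of ND1 (plus strand)
  ann <- mt_annotation()
  nd1 <- ann[ann$gene == "ND1", ]
  g <- synthetic_mt_genome()
  custom <- paste0(substring(g, 1, nd1$start - 1), "TTA",
                   substring(g, nd1$start + 3, 16569))
  s <- nd1$start
  # third position TTA -> TTG: Leu -> Leu, synonymous
  sy <- classify_substitution(s + 2L, "A", "G", ann, custom)
  expect_equal(sy$effect, "SY")
  expect_equal(sy$gene, "ND1")
  # second position TTA -> TGA: Leu -> Trp under the mito code (NS, and
  # specifically not a stop)
  ns <- classify_substitution(s + 1L, "T", "G", ann, custom)
  expect_equal(ns$effect, "NS")
  # non-coding control region
  loop <- classify_substitution(100L, mt_ref_base(100L), "A", ann,
                                synthetic_mt_genome())
  expect_equal(loop$region, "loop")
  expect_true(is.na(loop$effect))
  # ref mismatch is an error naming the site
  wrong <- setdiff(c("A", "C", "G", "T"), mt_ref_base(100L))[1]
  expect_error(classify_substitution(100L, wrong, "T"), "100")
})

test_that("classification agrees with a Biostrings translation oracle", {
  ann <- mt_annotation()
  genome <- synthetic_mt_genome()
  cds_tbl <- ann[ann$region == "coding" & ann$strand == "+", ]
  set.seed(19)
  for (i in sample(nrow(cds_tbl), 4)) {
    g <- cds_tbl[i, ]
    len3 <- ((g$end - g$start + 1) %/% 3) * 3
    p <- g$start + sample.int(len3, 1) - 1L
    ref <- mt_ref_base(p, genome)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[sample.int(3, 1)]
    got <- classify_substitution(p, ref, alt, ann, genome)
    got <- got$effect[got$gene == g$gene]
    # oracle: translate the whole CDS before and after with Biostrings
    cds <- substring(genome, g$start, g$start + len3 - 1L)
    mutated <- cds
    substring(mutated, p - g$start + 1L, p - g$start + 1L) <- alt
    tr <- function(x) as.character(Biostrings::translate(
      Biostrings::DNAString(x), genetic.code = mt_genetic_code()))
    expect_equal(got, if (tr(cds) == tr(mutated)) "SY" else "NS")
  }
})

test_that("minus-strand classification uses the reverse complement", {
  ann <- mt_annotation()
  genome <- synthetic_mt_genome()
  nd6 <- ann[ann$gene == "ND6", ]
  len3 <- ((nd6$end - nd6$start + 1) %/% 3) * 3
  set.seed(23)
  p <- nd6$end - sample.int(len3, 1) + 1L
  ref <- mt_ref_base(p, genome)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  got <- classify_substitution(p, ref, alt, ann, genome)
  got <- got$effect[got$gene == "ND6"]
  cds <- mitobottleneck:::revcomp(substring(genome, nd6$start, nd6$end))
  cds <- substring(cds, 1, len3)
  offset <- nd6$end - p + 1L
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  mutated <- cds
  substring(mutated, offset, offset) <- comp[[alt]]
  tr <- function(x) as.character(Biostrings::translate(
    Biostrings::DNAString(x), genetic.code = mt_genetic_code()))
  expect_equal(got, if (tr(cds) == tr(mutated)) "SY" else "NS")
})

test_that("dN/dS arithmetic and degenerate cases behave", {
  fake_potential <- list(N = 70, S = 20, per_gene = NULL)
  variants <- tibble::tibble(
    site = rep(16100L, 9), ref = mt_ref_base(16100L), alt = "A",
    vaf = runif(9))
  # use the loop site so classification yields no coding effects: n = s = 0
  res <- compute_dnds(variants, strata = c(0, 1),
                      potential = fake_potential)
  expect_equal(res$n, 0)
  expect_equal(res$s, 0)
  expect_true(is.na(res$dnds))
  # direct arithmetic: n = 7, N = 70, s = 2, S = 20 -> ratio exactly 1
  expect_equal((7 / 70) / (2 / 20), 1)
})

test_that("uniform random coding substitutions give dN/dS near 1", {
  ann <- mt_annotation()
  genome <- synthetic_mt_genome()
  potential <- count_potential_sites(mt_cds_sequences(genome, ann))
  set.seed(37)
  # sample single-nucleotide substitutions uniformly over CDS positions
  cds_tbl <- ann[ann$region == "coding", ]
  pool <- unlist(lapply(seq_len(nrow(cds_tbl)), function(i) {
    len3 <- ((cds_tbl$end[i] - cds_tbl$start[i] + 1) %/% 3) * 3
    if (cds_tbl$strand[i] == "+") {
      cds_tbl$start[i]:(cds_tbl$start[i] + len3 - 1)
    } else {
      (cds_tbl$end[i] - len3 + 1):cds_tbl$end[i]
    }
  }))
  m <- 600
  sites <- sample(pool, m, replace = TRUE)
  refs <- mt_ref_base(sites, genome)
  alts <- vapply(refs, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                          1), character(1))
  variants <- tibble::tibble(site = sites, ref = refs, alt = alts,
                             vaf = runif(m))
  res <- compute_dnds(variants, strata = c(0, 1), ann = ann,
                      genome = genome, potential = potential)
  # binomial CI: expected NS fraction is N / (N + S); dnds -> 1
  p_ns <- potential$N / (potential$N + potential$S)
  tot <- res$n + res$s
  se <- sqrt(p_ns * (1 - p_ns) / tot)
  expect_lt(abs(res$n / tot - p_ns), 4 * se)
  expect_gt(res$dnds, 0.75)
  expect_lt(res$dnds, 1.35)
})

test_that("VAF-by-region keys partition the variant set", {
  set.seed(41)
  sites <- c(100L, 700L, 3500L, 16100L)  # loop, rRNA, coding, loop
  variants <- tibble::tibble(site = sites, ref = mt_ref_base(sites),
                             alt = vapply(mt_ref_base(sites), function(r) {
                               setdiff(c("A", "C", "G", "T"), r)[1]
                             }, character(1)),
                             vaf = c(0.98, 0.5, 0.2, 0.1))
  out <- vaf_by_region(variants)
  expect_equal(nrow(out), 4)
  expect_setequal(out$region[out$site %in% c(100L, 16100L)], "loop")
  expect_equal(out$region[out$site == 700L], "rRNA")
  expect_true(out$category[out$site == 3500L] %in% c("SY", "NS"))
  expect_equal(sum(table(out$category)), nrow(variants))
})
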