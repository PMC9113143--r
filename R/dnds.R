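#' Classify substitutions by region and coding effect
#'
#' Assigns each substitution its genomic region (`loop`, `tRNA`, `rRNA`,
#' `coding`) and, for coding positions, the effect under the vertebrate
#' mitochondrial genetic code: synonymous (`SY`) if the amino acid is
#' unchanged, nonsynonymous (`NS`) otherwise (stop gain/loss counts as NS;
#' note TGA = Trp and AGA/AGG = stop in this code). Minus-strand genes (ND6)
#' are classified on the reverse complement. Positions inside overlapping
#' genes yield one row per gene context, flagged via `overlapping`.
#'
#' @param site Integer vector of 1-based positions.
#' @param ref,alt Reference and alternate bases on the heavy (+) strand; `ref`
#'   must match the reference sequence at `site`.
#' @param ann Annotation tibble from [mt_annotation()].
#' @param genome Reference sequence string.
#' @param code Genetic code (named character over codons).
#' @return Tibble with one row per (substitution, gene context): `site`,
#'   `ref`, `alt`, `region`, `gene`, `effect` (`SY`/`NS`/NA for non-coding),
#'   `overlapping`.
#' @export
#' @examples
#' ann <- mt_annotation()
#' classify_substitution(16000L, mt_ref_base(16000L), "A", ann)
classify_substitution <- function(site, ref, alt, ann = mt_annotation(),
                                  genome = synthetic_mt_genome(),
                                  code = mt_genetic_code()) {
  stopifnot(length(site) == length(ref), length(ref) == length(alt),
            all(site >= 1), all(site <= MT_GENOME_LENGTH))
  true_ref <- mt_ref_base(site, genome)
  bad <- which(ref != true_ref)
  if (length(bad) > 0) {
    stop("ref allele mismatch with the reference sequence at site(s): ",
         paste(site[head(bad, 5)], collapse = ", "))
  }
  cds <- ann[ann$region == "coding", ]
  out <- lapply(seq_along(site), function(i) {
    p <- site[i]
    hits <- cds[cds$start <= p & cds$end >= p, ]
    if (nrow(hits) == 0) {
      region <- ann$region[ann$start <= p & ann$end >= p][1]
      return(tibble(site = p, ref = ref[i], alt = alt[i], region = region,
                    gene = ann$gene[ann$start <= p & ann$end >= p][1],
                    effect = NA_character_, overlapping = FALSE))
    }
    dplyr::bind_rows(lapply(seq_len(nrow(hits)), function(h) {
      g <- hits[h, ]
      eff <- codon_effect(p, ref[i], alt[i], g, genome, code)
      tibble(site = p, ref = ref[i], alt = alt[i], region = "coding",
             gene = g$gene, effect = eff, overlapping = nrow(hits) > 1)
    }))
  })
  dplyr::bind_rows(out)
}

# Effect of a heavy-strand substitution on one CDS. Positions in a trimmed
# trailing partial codon alter no complete codon and get NA (excluded from
# observed counts, matching their exclusion from the potential-site totals).
codon_effect <- function(p, ref, alt, gene_row, genome, code) {
  if (gene_row$strand == "+") {
    offset <- p - gene_row$start            # 0-based within CDS
    cds_ref <- ref
    cds_alt <- alt
  } else {
    offset <- gene_row$end - p
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    cds_ref <- comp[[ref]]
    cds_alt <- comp[[alt]]
  }
  len <- gene_row$end - gene_row$start + 1L
  if (offset >= (len %/% 3L) * 3L) return(NA_character_)
  codon_i <- offset %/% 3L
  pos_in <- offset %% 3L
  codon_start <- if (gene_row$strand == "+") {
    gene_row$start + codon_i * 3L
  } else {
    gene_row$end - codon_i * 3L - 2L
  }
  codon <- substring(genome, codon_start, codon_start + 2L)
  if (gene_row$strand == "-") codon <- revcomp(codon)
  stopifnot(substring(codon, pos_in + 1L, pos_in + 1L) == cds_ref)
  mutated <- codon
  substring(mutated, pos_in + 1L, pos_in + 1L) <- cds_alt
  if (code[[codon]] == code[[mutated]]) "SY" else "NS"
}

#' Per-codon substitution-site counts
#'
#' Enumerates all 9 single-nucleotide substitutions of a codon and classifies
#' each as synonymous or nonsynonymous; NS + SY = 9 for every codon.
#'
#' @param codon Three-letter codon string over `ACGT`.
#' @param code Genetic code.
#' @return Named numeric vector `c(NS =, SY =)`.
#' @export
#' @examples
#' codon_site_counts("TTA") # S = 2 (TTG, CTA), N = 7 under the mito code
codon_site_counts <- function(codon, code = mt_genetic_code()) {
  stopifnot(nchar(codon) == 3)
  if (!grepl("^[ACGT]{3}$", codon)) {
    stop("codon contains ambiguous bases: ", codon)
  }
  aa <- code[[codon]]
  ns <- 0L
  sy <- 0L
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"),
                      substring(codon, pos, pos))) {
      mutated <- codon
      substring(mutated, pos, pos) <- b
      if (code[[mutated]] == aa) sy <- sy + 1L else ns <- ns + 1L
    }
  }
  c(NS = ns, SY = sy)
}

#' Count potential nonsynonymous and synonymous sites
#'
#' Enumerates, over every codon of every CDS, all possible single-nucleotide
#' substitutions and totals the nonsynonymous (`N`) and synonymous (`S`)
#' ones. This is substitution enumeration: N + S = 9 x (number of codons).
#'
#' @param cds_seqs Named character vector of CDS sequences (lengths divisible
#'   by 3, no ambiguous bases), e.g. from [mt_cds_sequences()].
#' @param code Genetic code.
#' @return List with totals `N` and `S` and a `per_gene` tibble.
#' @export
count_potential_sites <- function(cds_seqs = mt_cds_sequences(),
                                  code = mt_genetic_code()) {
  per_gene <- lapply(names(cds_seqs), function(g) {
    s <- cds_seqs[[g]]
    if (!grepl("^[ACGT]*$", s)) {
      stop("CDS ", g, " contains ambiguous bases")
    }
    stopifnot(nchar(s) %% 3 == 0)
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    counts <- vapply(codons, codon_site_counts, numeric(2), code = code)
    tibble(gene = g, n_codons = length(codons),
           N = sum(counts["NS", ]), S = sum(counts["SY", ]))
  }) |> dplyr::bind_rows()
  list(N = sum(per_gene$N), S = sum(per_gene$S), per_gene = per_gene)
}

#' dN/dS per heteroplasmy stratum
#'
#' Counts observed nonsynonymous (`n`) and synonymous (`s`) substitutions per
#' VAF stratum and normalizes them by the genome-wide potential site totals:
#' `dN = n/N`, `dS = s/S`, ratio `dN/dS` (reported as NA, not infinity, when
#' `s = 0`). Variants in overlapping genes contribute once per gene context,
#' matching the enumeration of potential sites over every CDS.
#'
#' @param variants Tibble with `site`, `ref`, `alt` and `vaf` (the per-variant
#'   heteroplasmy used for stratification, e.g. the maximum or mean cell VAF).
#' @param strata Numeric breaks over `[0, 1]` partitioning VAF into
#'   categories (default `c(0, 0.1, 0.9, 1)`).
#' @param ann,genome,code Annotation, reference and genetic code.
#' @param potential Optional precomputed [count_potential_sites()] result.
#' @return Tibble with one row per stratum: `stratum`, `n`, `s`, `N`, `S`,
#'   `dN`, `dS`, `dnds`.
#' @export
compute_dnds <- function(variants, strata = c(0, 0.1, 0.9, 1),
                         ann = mt_annotation(),
                         genome = synthetic_mt_genome(),
                         code = mt_genetic_code(),
                         potential = NULL) {
  stopifnot(all(c("site", "ref", "alt", "vaf") %in% names(variants)),
            length(strata) >= 2, strata[1] >= 0,
            strata[length(strata)] <= 1)
  if (is.null(potential)) {
    potential <- count_potential_sites(mt_cds_sequences(genome, ann), code)
  }
  labels <- sprintf("(%g,%g]", strata[-length(strata)], strata[-1])
  if (nrow(variants) == 0) {
    return(tibble(stratum = labels, n = 0L, s = 0L,
                  N = potential$N, S = potential$S,
                  dN = 0, dS = 0, dnds = NA_real_))
  }
  uniq <- variants |> dplyr::distinct(.data$site, .data$ref, .data$alt)
  cls_u <- classify_substitution(uniq$site, uniq$ref, uniq$alt,
                                 ann, genome, code) |>
    dplyr::filter(!is.na(.data$effect))
  # one row per observed substitution occurrence per gene context
  cls <- variants |>
    dplyr::select("site", "alt", "vaf") |>
    dplyr::inner_join(cls_u, by = c("site", "alt"),
                      relationship = "many-to-many") |>
    dplyr::mutate(stratum = cut(.data$vaf, breaks = strata, labels = labels,
                                include.lowest = TRUE))
  tibble(stratum = labels) |>
    dplyr::left_join(
      cls |>
        dplyr::group_by(.data$stratum) |>
        dplyr::summarise(n = sum(.data$effect == "NS"),
                         s = sum(.data$effect == "SY"), .groups = "drop") |>
        dplyr::mutate(stratum = as.character(.data$stratum)),
      by = "stratum") |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n),
                  s = ifelse(is.na(.data$s), 0L, .data$s),
                  N = potential$N, S = potential$S,
                  dN = .data$n / .data$N, dS = .data$s / .data$S,
                  dnds = ifelse(.data$s > 0, .data$dN / .data$dS, NA_real_))
}

#' VAF distributions by genomic region and coding effect
#'
#' Keys every variant's VAF by its region label for non-coding positions and
#' by `SY`/`NS` for coding positions, the stratification behind the
#' region-wise comparison of homoplasmic-mutation proportions.
#'
#' @param cvm A `cell_variant_matrix` (per-cell VAFs are pooled over cells),
#'   or a tibble with `site`, `ref`, `alt`, `vaf`.
#' @param ann,genome,code Annotation, reference and genetic code.
#' @return Tibble with `site`, `ref`, `alt`, `vaf`, `region`, `effect` and
#'   `category` (region for non-coding, SY/NS for coding).
#' @export
vaf_by_region <- function(cvm, ann = mt_annotation(),
                          genome = synthetic_mt_genome(),
                          code = mt_genetic_code()) {
  variants <- if (inherits(cvm, "cell_variant_matrix")) {
    cvm$vaf |> dplyr::filter(.data$vaf > 0) |>
      dplyr::select("site", "ref", "alt", "vaf")
  } else {
    tibble::as_tibble(cvm)[, c("site", "ref", "alt", "vaf")]
  }
  if (nrow(variants) == 0) {
    return(tibble(site = integer(0), ref = character(0), alt = character(0),
                  vaf = numeric(0), region = character(0),
                  effect = character(0), category = character(0)))
  }
  keys <- classify_substitution(unique(variants$site),
                                mt_ref_base(unique(variants$site), genome),
                                variants$alt[match(unique(variants$site),
                                                   variants$site)],
                                ann, genome, code) |>
    dplyr::group_by(.data$site) |>
    dplyr::slice(1) |>   # one classification per site; overlaps flagged there
    dplyr::ungroup() |>
    dplyr::select("site", "region", "effect")
  variants |>
    dplyr::left_join(keys, by = "site") |>
    dplyr::mutate(category = ifelse(.data$region == "coding", .data$effect,
                                    .data$region))
}
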