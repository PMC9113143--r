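#' Per-cell strand-resolved allele-count matrix
#'
#' The observed-data object every stage of the pipeline consumes: one row per
#' (cell, site) with strand-resolved reference and alternate read counts, plus
#' per-cell metadata. At most one alternate allele per site.
#'
#' @param counts Tibble with `cell_id`, `site` (1..16,569), `ref`, `alt`
#'   (NA where no alternate allele was observed), `ref_fwd`, `ref_rev`,
#'   `alt_fwd`, `alt_rev`.
#' @param cells Tibble with `cell_id`, `cell_type`, `mito_reads`,
#'   `total_reads`; `cell_id` unique.
#' @return Object of class `allele_count_matrix`.
#' @export
allele_count_matrix <- function(counts, cells) {
  req <- c("cell_id", "site", "ref", "alt", "ref_fwd", "ref_rev",
           "alt_fwd", "alt_rev")
  stopifnot(all(req %in% names(counts)),
            all(c("cell_id", "cell_type", "mito_reads", "total_reads")
                %in% names(cells)))
  if (anyDuplicated(cells$cell_id)) stop("cell_ids must be unique")
  num <- counts[, c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")]
  if (nrow(counts) > 0) {
    stopifnot(all(as.matrix(num) >= 0),
              all(counts$site >= 1), all(counts$site <= MT_GENOME_LENGTH))
    if (!all(counts$cell_id %in% cells$cell_id)) {
      stop("counts reference cell_ids absent from cell metadata")
    }
  }
  structure(list(counts = tibble::as_tibble(counts),
                 cells = tibble::as_tibble(cells)),
            class = "allele_count_matrix")
}

#' @export
print.allele_count_matrix <- function(x, ...) {
  cat(sprintf("allele_count_matrix: %d cells, %d count rows, %d cell types\n",
              nrow(x$cells), nrow(x$counts),
              length(unique(x$cells$cell_type))))
  invisible(x)
}

#' Positions blacklisted for homopolymer/reference artifacts
#'
#' rCRS positions prone to misalignment around the 302-315 and 513-525
#' homopolymer tracts and the 3107 reference `N`; any call at these positions
#' is removed.
#'
#' @return Integer vector of 13 positions.
#' @export
default_site_blacklist <- function() {
  c(302L, 309L, 311L, 312L, 313L, 316L,
    514L, 515L, 523L, 524L,
    3106L, 3109L, 3110L)
}

#' Filter-cascade configuration
#'
#' Houses every threshold of the five-step somatic-variant filter cascade.
#'
#' @param candidate_min_vaf,candidate_min_depth,candidate_min_alt_reads
#'   Candidate-calling thresholds per cell (defaults 0.01, 8, 2).
#' @param bulk_germline_vaf Pooled-VAF threshold above which a variant is
#'   germline (default 0.90, exclusive).
#' @param shared_cell_fraction A variant at per-cell VAF >
#'   `bulk_germline_vaf` in more than this fraction of covered cells is also
#'   germline (default 0.90).
#' @param site_blacklist Blacklisted positions (default
#'   [default_site_blacklist()]).
#' @param substitution_blacklist Substitution types removed as DNA-damage
#'   errors (default `G>T` and `C>A`).
#' @param min_site_depth,min_alt_reads Confidence thresholds: site depth >=
#'   20 and alt reads >= 2 in at least one cell.
#' @param strand_low,strand_high Open interval the forward-strand fraction of
#'   alt reads must fall in (defaults 0.30, 0.70; boundary values fail).
#' @param recount_min_depth Minimum site depth for a recounted per-cell VAF to
#'   be defined (default 8).
#' @param min_cell_mean_depth Cells at mean mtDNA depth <= this are dropped
#'   (default 10).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(candidate_min_vaf = 0.01,
                          candidate_min_depth = 8,
                          candidate_min_alt_reads = 2,
                          bulk_germline_vaf = 0.90,
                          shared_cell_fraction = 0.90,
                          site_blacklist = default_site_blacklist(),
                          substitution_blacklist = c("G>T", "C>A"),
                          min_site_depth = 20,
                          min_alt_reads = 2,
                          strand_low = 0.30,
                          strand_high = 0.70,
                          recount_min_depth = 8,
                          min_cell_mean_depth = 10) {
  fracs <- c(candidate_min_vaf = candidate_min_vaf,
             bulk_germline_vaf = bulk_germline_vaf,
             shared_cell_fraction = shared_cell_fraction,
             strand_low = strand_low, strand_high = strand_high)
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad) > 0) {
    stop("filter_config fractions must lie in [0, 1]: ",
         paste(bad, collapse = ", "))
  }
  if (strand_low >= strand_high) stop("strand_low must be < strand_high")
  structure(as.list(environment()), class = "filter_config")
}

site_depth <- function(counts) {
  counts$ref_fwd + counts$ref_rev + counts$alt_fwd + counts$alt_rev
}

alt_reads <- function(counts) {
  counts$alt_fwd + counts$alt_rev
}

#' Step 0: call candidate variants per cell
#'
#' A (site, alt) is a candidate if in at least one cell the site depth is at
#' least `candidate_min_depth`, the alt read count at least
#' `candidate_min_alt_reads`, and the alt fraction at least
#' `candidate_min_vaf`; candidates are unioned over cells.
#'
#' @param matrix An [allele_count_matrix()].
#' @param cfg A [filter_config()].
#' @return Tibble (`variant_call_set`) with `site`, `ref`, `alt` and
#'   `n_cells_candidate`.
#' @export
call_candidates <- function(matrix, cfg = filter_config()) {
  stopifnot(inherits(matrix, "allele_count_matrix"))
  matrix$counts |>
    dplyr::filter(!is.na(.data$alt)) |>
    dplyr::mutate(depth = site_depth(dplyr::pick(dplyr::everything())),
                  alt_n = alt_reads(dplyr::pick(dplyr::everything()))) |>
    dplyr::filter(.data$depth >= cfg$candidate_min_depth,
                  .data$alt_n >= cfg$candidate_min_alt_reads,
                  .data$alt_n / .data$depth >= cfg$candidate_min_vaf) |>
    dplyr::count(.data$site, .data$ref, .data$alt,
                 name = "n_cells_candidate") |>
    dplyr::arrange(.data$site)
}

#' Step 1: identify germline variants
#'
#' Germline variants are (a) variants whose pooled ("bulk") alt fraction over
#' all cells exceeds `bulk_germline_vaf`, and (b) variants at per-cell VAF
#' above that threshold in more than `shared_cell_fraction` of covered cells
#' (cells with at least `recount_min_depth` at the site; cells with undefined
#' VAF cannot vote).
#'
#' @inheritParams call_candidates
#' @return Tibble with `site`, `alt`, `pooled_vaf`, `shared_fraction`, `rule`.
#' @export
identify_germline <- function(matrix, cfg = filter_config()) {
  stopifnot(inherits(matrix, "allele_count_matrix"))
  counts <- matrix$counts |>
    dplyr::mutate(depth = site_depth(dplyr::pick(dplyr::everything())),
                  alt_n = alt_reads(dplyr::pick(dplyr::everything())))
  site_alts <- counts |>
    dplyr::filter(!is.na(.data$alt)) |>
    dplyr::distinct(.data$site, valt = .data$alt)
  # Pool over every cell covering the site, not just alt-bearing cells:
  # a private near-fixed variant must not masquerade as bulk germline.
  per_cell <- counts |>
    dplyr::inner_join(site_alts, by = "site",
                      relationship = "many-to-many") |>
    dplyr::mutate(alt_n = ifelse(!is.na(.data$alt) &
                                   .data$alt == .data$valt,
                                 .data$alt_n, 0L))
  stats <- per_cell |>
    dplyr::group_by(.data$site, alt = .data$valt) |>
    dplyr::summarise(
      pooled_vaf = sum(.data$alt_n) / sum(.data$depth),
      shared_fraction = {
        cov <- .data$depth >= cfg$recount_min_depth
        if (any(cov)) {
          mean(.data$alt_n[cov] / .data$depth[cov] > cfg$bulk_germline_vaf)
        } else 0
      },
      .groups = "drop")
  stats |>
    dplyr::filter(.data$pooled_vaf > cfg$bulk_germline_vaf |
                    .data$shared_fraction > cfg$shared_cell_fraction) |>
    dplyr::mutate(rule = ifelse(.data$pooled_vaf > cfg$bulk_germline_vaf,
                                "bulk", "shared_cells"))
}

#' Step 2: remove blacklisted sites and damage substitutions
#'
#' Drops every call at a blacklisted position (homopolymer/misalignment
#' artifacts) and every call whose substitution type is blacklisted (G>T and
#' C>A oxidative-damage errors, by default).
#'
#' @param calls A variant call tibble with `site`, `ref`, `alt`.
#' @param cfg A [filter_config()].
#' @return The calls with blacklisted rows removed.
#' @export
apply_blacklists <- function(calls, cfg = filter_config()) {
  calls |>
    dplyr::filter(!(.data$site %in% cfg$site_blacklist),
                  !(paste0(.data$ref, ">", .data$alt) %in%
                      cfg$substitution_blacklist))
}

#' Step 3: depth, alt-read and strand-balance confidence filters
#'
#' Keeps a variant only if in at least one cell the site depth is >=
#' `min_site_depth` (20x), the alt reads >= `min_alt_reads`, and the
#' forward-strand fraction `f` of alt reads satisfies
#' `strand_low < f < strand_high` (strictly).
#'
#' @inheritParams apply_blacklists
#' @param matrix An [allele_count_matrix()].
#' @return The confident calls with `cell_types` (list-column of cell types
#'   in which the variant had at least one confident cell) and
#'   `n_cells_confident`.
#' @export
apply_confidence_filters <- function(calls, matrix, cfg = filter_config()) {
  stopifnot(inherits(matrix, "allele_count_matrix"))
  if (nrow(calls) == 0) {
    return(calls |> dplyr::mutate(n_cells_confident = integer(0),
                                  cell_types = list()))
  }
  evidence <- matrix$counts |>
    dplyr::inner_join(calls |> dplyr::select("site", "alt"),
                      by = c("site", "alt")) |>
    dplyr::left_join(matrix$cells |> dplyr::select("cell_id", "cell_type"),
                     by = "cell_id") |>
    dplyr::mutate(depth = site_depth(dplyr::pick(dplyr::everything())),
                  alt_n = alt_reads(dplyr::pick(dplyr::everything())),
                  f_fwd = ifelse(.data$alt_n > 0,
                                 .data$alt_fwd / .data$alt_n, NA_real_)) |>
    dplyr::filter(.data$depth >= cfg$min_site_depth,
                  .data$alt_n >= cfg$min_alt_reads,
                  .data$f_fwd > cfg$strand_low,
                  .data$f_fwd < cfg$strand_high)
  confident <- evidence |>
    dplyr::group_by(.data$site, .data$alt) |>
    dplyr::summarise(n_cells_confident = dplyr::n(),
                     cell_types = list(unique(.data$cell_type)),
                     .groups = "drop")
  calls |>
    dplyr::inner_join(confident, by = c("site", "alt"))
}

#' Step 4: recount VAF in all cells of the same cell type
#'
#' For every confident variant and every cell of a cell type in which the
#' variant was confidently observed, the VAF is recounted as
#' `alt / (alt + ref)` wherever the site depth is at least
#' `recount_min_depth`; below that, the VAF is missing (the cell does not
#' appear for that variant).
#'
#' @param calls Confident calls from [apply_confidence_filters()].
#' @param matrix An [allele_count_matrix()].
#' @param cfg A [filter_config()].
#' @return Object of class `cell_variant_matrix`: list with `vaf` (long
#'   tibble `cell_id`, `cell_type`, `variant_id`, `site`, `ref`, `alt`,
#'   `vaf`) and `cells` (per-cell metadata with `mean_depth` over all
#'   16,569 sites).
#' @export
recount_vaf <- function(calls, matrix, cfg = filter_config()) {
  stopifnot(inherits(matrix, "allele_count_matrix"))
  cells <- matrix$cells |>
    dplyr::left_join(
      matrix$counts |>
        dplyr::group_by(.data$cell_id) |>
        dplyr::summarise(total_depth = sum(site_depth(
          dplyr::pick(dplyr::everything()))), .groups = "drop"),
      by = "cell_id") |>
    dplyr::mutate(mean_depth = ifelse(is.na(.data$total_depth), 0,
                                      .data$total_depth / MT_GENOME_LENGTH)) |>
    dplyr::select(-"total_depth")

  if (nrow(calls) == 0) {
    vaf <- tibble(cell_id = character(0), cell_type = character(0),
                  variant_id = character(0), site = integer(0),
                  ref = character(0), alt = character(0), vaf = numeric(0))
    return(structure(list(vaf = vaf, cells = cells),
                     class = "cell_variant_matrix"))
  }
  scope <- calls |>
    dplyr::select("site", "ref", "alt", "cell_types") |>
    tidyr::unnest("cell_types") |>
    dplyr::rename(cell_type = "cell_types")
  vaf <- matrix$counts |>
    dplyr::left_join(matrix$cells |> dplyr::select("cell_id", "cell_type"),
                     by = "cell_id") |>
    dplyr::inner_join(scope |> dplyr::select("site", "cell_type"),
                      by = c("site", "cell_type")) |>
    dplyr::mutate(depth = site_depth(dplyr::pick(dplyr::everything()))) |>
    dplyr::filter(.data$depth >= cfg$recount_min_depth) |>
    dplyr::left_join(scope |> dplyr::select("site", "ref", "alt") |>
                       dplyr::distinct(),
                     by = "site", suffix = c("", ".call")) |>
    dplyr::mutate(
      alt_n = ifelse(!is.na(.data$alt) & .data$alt == .data$alt.call,
                     alt_reads(dplyr::pick(dplyr::everything())), 0L),
      vaf = .data$alt_n / .data$depth,
      variant_id = sprintf("%d%s>%s", .data$site, .data$ref.call,
                           .data$alt.call)) |>
    dplyr::select("cell_id", "cell_type", "variant_id", "site",
                  ref = "ref.call", alt = "alt.call", "vaf")
  structure(list(vaf = vaf, cells = cells), class = "cell_variant_matrix")
}

#' @export
print.cell_variant_matrix <- function(x, ...) {
  cat(sprintf("cell_variant_matrix: %d cells, %d variants, %d defined VAFs\n",
              nrow(x$cells), length(unique(x$vaf$variant_id)), nrow(x$vaf)))
  invisible(x)
}

#' Step 5: drop low-coverage cells
#'
#' Only cells with mean mtDNA site depth above `min_cell_mean_depth` (10x)
#' are considered for further analysis.
#'
#' @param cvm A `cell_variant_matrix` from [recount_vaf()].
#' @param cfg A [filter_config()].
#' @return The `cell_variant_matrix` restricted to retained cells.
#' @export
filter_cells <- function(cvm, cfg = filter_config()) {
  stopifnot(inherits(cvm, "cell_variant_matrix"))
  keep <- cvm$cells$mean_depth > cfg$min_cell_mean_depth
  if (!any(keep)) {
    warning("all cells fall below the mean-depth threshold; empty result")
  }
  cvm$cells <- cvm$cells[keep, ]
  cvm$vaf <- cvm$vaf |> dplyr::filter(.data$cell_id %in% cvm$cells$cell_id)
  cvm
}

#' Full somatic-variant filter cascade
#'
#' Runs the five-step cascade in order: candidate calling, germline removal,
#' site/substitution blacklists, depth/alt/strand confidence filters, per-cell
#' VAF recounting, and cell-depth filtering. The final somatic set is
#' disjoint from the germline set and from both blacklists (asserted on every
#' run).
#'
#' @param matrix An [allele_count_matrix()].
#' @param cfg A [filter_config()].
#' @return List with `variants` (final somatic calls), `germline` (the
#'   germline set), `candidates` (pre-filter candidates) and `cvm` (the
#'   recounted, cell-filtered `cell_variant_matrix`).
#' @export
call_somatic_variants <- function(matrix, cfg = filter_config()) {
  candidates <- call_candidates(matrix, cfg)
  germline <- identify_germline(matrix, cfg)
  calls <- candidates |>
    dplyr::anti_join(germline, by = c("site", "alt"))
  calls <- apply_blacklists(calls, cfg)
  calls <- apply_confidence_filters(calls, matrix, cfg)
  cvm <- recount_vaf(calls, matrix, cfg)
  cvm <- filter_cells(cvm, cfg)

  stopifnot(
    !any(paste(calls$site, calls$alt) %in%
           paste(germline$site, germline$alt)),
    !any(calls$site %in% cfg$site_blacklist),
    !any(paste0(calls$ref, ">", calls$alt) %in% cfg$substitution_blacklist))

  list(variants = calls, germline = germline, candidates = candidates,
       cvm = cvm)
}
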