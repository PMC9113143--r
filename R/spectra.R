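#' Spectrum bin edges
#'
#' The 20 edges 0.05, 0.10, ..., 1.00 defining the 19 VAF bins used as the
#' summary-statistic vector throughout the package.
#'
#' @return Numeric vector of length 20.
#' @export
spectrum_bin_edges <- function() {
  (1:20) * 0.05
}

#' VAF spectrum (allele-frequency spectrum)
#'
#' Bins variant allele frequencies into 19 bins of width 0.05 from 0.05 to 1.
#' Bin i covers `[0.05 * i, 0.05 * (i + 1))` for i < 19; the last bin is the
#' closed interval `[0.95, 1]`, so homoplasmic VAF = 1 variants are counted.
#' VAFs below 0.05 are excluded (undetectable at typical per-cell depth).
#'
#' @param vafs Numeric vector of VAFs in `[0, 1]`.
#' @param n_cells Number of cells the VAFs came from; required for
#'   `normalization = "per_cell_mean"`.
#' @param normalization `"raw"` (counts) or `"per_cell_mean"` (counts divided
#'   by `n_cells`, making spectra comparable across cohort sizes).
#' @param cell_type Optional label carried along for plotting/faceting.
#' @return Object of class `vaf_spectrum`: list with `counts` (length 19),
#'   `bin_edges`, `normalization`, `n_cells`, `cell_type`.
#' @export
#' @examples
#' vaf_spectrum(c(0.07, 0.52, 0.98, 1.0))$counts
vaf_spectrum <- function(vafs, n_cells = NULL,
                         normalization = c("raw", "per_cell_mean"),
                         cell_type = NA_character_) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(vafs) || length(vafs) == 0)
  if (length(vafs) > 0 && (any(vafs < 0) || any(vafs > 1))) {
    stop("vafs must lie in [0, 1]")
  }
  edges <- spectrum_bin_edges()
  v <- vafs[vafs >= edges[1]]
  # index of the largest edge <= v; v = 1 falls in bin 19 (closed top bin)
  idx <- pmin(findInterval(v, edges), 19L)
  counts <- as.numeric(tabulate(idx, nbins = 19L))
  if (normalization == "per_cell_mean") {
    if (is.null(n_cells) || n_cells <= 0) {
      stop("per_cell_mean normalization requires n_cells > 0")
    }
    counts <- counts / n_cells
  }
  structure(list(counts = counts, bin_edges = edges,
                 normalization = normalization,
                 n_cells = if (is.null(n_cells)) NA_integer_ else n_cells,
                 cell_type = cell_type),
            class = "vaf_spectrum")
}

#' @export
print.vaf_spectrum <- function(x, ...) {
  cat(sprintf("VAF spectrum (%s%s): 19 bins, edges 0.05..1.00\n",
              x$normalization,
              if (is.na(x$cell_type)) "" else paste0(", ", x$cell_type)))
  print(setNames(round(x$counts, 4),
                 sprintf("[%.2f,%.2f%s", x$bin_edges[1:19],
                         x$bin_edges[2:20],
                         c(rep(")", 18), "]"))))
  invisible(x)
}

#' Per-cell somatic mutation burden
#'
#' Number of somatic variants with a defined, positive VAF in each cell.
#'
#' @param cvm A `cell_variant_matrix` (see [recount_vaf()]).
#' @return Tibble with `cell_id`, `cell_type`, `n_variants`.
#' @export
per_cell_burden <- function(cvm) {
  stopifnot(inherits(cvm, "cell_variant_matrix"))
  counts <- cvm$vaf |>
    dplyr::filter(.data$vaf > 0) |>
    dplyr::count(.data$cell_id, name = "n_variants")
  cvm$cells |>
    dplyr::select("cell_id", "cell_type") |>
    dplyr::left_join(counts, by = "cell_id") |>
    dplyr::mutate(n_variants = ifelse(is.na(.data$n_variants), 0L,
                                      .data$n_variants))
}

#' Homoplasmic and dominant mutation fractions per cell type
#'
#' Fraction of cells carrying at least one homoplasmic variant
#' (VAF >= `homoplasmic_threshold`, operationalizing "VAF of ~1") and at
#' least one dominant variant (VAF > `dominant_threshold`, i.e. VAF > 50%
#' within a single cell).
#'
#' @param cvm A `cell_variant_matrix`.
#' @param homoplasmic_threshold VAF threshold for homoplasmy (default 0.95,
#'   the top spectrum bin).
#' @param dominant_threshold VAF threshold for dominance (default 0.5,
#'   exclusive).
#' @return Tibble with `cell_type`, `n_cells`, `homoplasmic_fraction`,
#'   `dominant_fraction`.
#' @export
homoplasmic_dominant_fractions <- function(cvm, homoplasmic_threshold = 0.95,
                                           dominant_threshold = 0.5) {
  stopifnot(inherits(cvm, "cell_variant_matrix"),
            homoplasmic_threshold > 0, homoplasmic_threshold <= 1,
            dominant_threshold > 0, dominant_threshold <= 1)
  flags <- cvm$vaf |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      homoplasmic = any(.data$vaf >= homoplasmic_threshold),
      dominant = any(.data$vaf > dominant_threshold),
      .groups = "drop")
  cvm$cells |>
    dplyr::left_join(flags, by = "cell_id") |>
    dplyr::mutate(homoplasmic = !is.na(.data$homoplasmic) & .data$homoplasmic,
                  dominant = !is.na(.data$dominant) & .data$dominant) |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     homoplasmic_fraction = mean(.data$homoplasmic),
                     dominant_fraction = mean(.data$dominant),
                     .groups = "drop")
}

#' Relative mtDNA copy-number proxy
#'
#' Per-cell fraction of sequencing reads mapped to the mitochondrial genome
#' over total reads, a dimensionless proxy for relative mtDNA copy number.
#'
#' @param cells Tibble with `cell_id`, `cell_type`, `mito_reads`,
#'   `total_reads`.
#' @return List with `per_cell` (tibble adding `copy_number_proxy`) and
#'   `per_type` (tibble of per-cell-type medians).
#' @export
relative_copy_number <- function(cells) {
  stopifnot(all(c("cell_id", "cell_type", "mito_reads", "total_reads")
                %in% names(cells)))
  if (any(cells$total_reads <= 0)) {
    bad <- cells$cell_id[cells$total_reads <= 0]
    stop("total_reads must be > 0; offending cells: ",
         paste(head(bad, 5), collapse = ", "))
  }
  per_cell <- cells |>
    dplyr::mutate(copy_number_proxy = .data$mito_reads / .data$total_reads)
  per_type <- per_cell |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(median_proxy = stats::median(.data$copy_number_proxy),
                     .groups = "drop")
  list(per_cell = per_cell, per_type = per_type)
}

#' Baseline mtDNA copy number per lineage
#'
#' B and T lymphocytes use the baseline of ~500 copies per cell; NK cells
#' show ~60% of the B/T relative copy number, so their baseline is scaled to
#' `500 * 0.6 = 300`.
#'
#' @param cell_type One of `"B"`, `"T"`, `"NK"` (other labels fall back to
#'   `baseline`).
#' @param baseline Baseline copies for B/T (default 500).
#' @param nk_scale NK relative copy-number scale (default 0.6).
#' @return Numeric baseline copy number.
#' @export
#' @examples
#' baseline_copy_number("NK") # 300
baseline_copy_number <- function(cell_type, baseline = 500, nk_scale = 0.6) {
  ifelse(cell_type == "NK", baseline * nk_scale, baseline)
}

#' Exclude variants fixed early in progenitors
#'
#' Somatic mutations that arose before the bottleneck and are already fixed in
#' the progenitor population carry no information about the bottleneck; they
#' are removed before spectrum computation. A variant is deemed early-fixed if
#' it is homoplasmic (VAF > `fixed_vaf`) in more than `fixed_cell_fraction` of
#' the progenitor cells in which it has a defined VAF.
#'
#' @param cvm A `cell_variant_matrix`.
#' @param progenitor_types Character vector of cell-type labels counted as
#'   progenitors (e.g. `c("HSC", "LMPP", "CLP")`).
#' @param fixed_vaf Homoplasmy threshold (default 0.90).
#' @param fixed_cell_fraction Fraction of progenitor cells above which the
#'   variant is excluded (default 0.50).
#' @return The `cell_variant_matrix` with early-fixed variants removed.
#' @export
exclude_early_fixed <- function(cvm, progenitor_types,
                                fixed_vaf = 0.90, fixed_cell_fraction = 0.50) {
  stopifnot(inherits(cvm, "cell_variant_matrix"))
  prog_cells <- cvm$cells$cell_id[cvm$cells$cell_type %in% progenitor_types]
  if (length(prog_cells) == 0) {
    warning("no progenitor-labeled cells present; exclude_early_fixed is a no-op")
    return(cvm)
  }
  fixed <- cvm$vaf |>
    dplyr::filter(.data$cell_id %in% prog_cells) |>
    dplyr::group_by(.data$site, .data$alt) |>
    dplyr::summarise(frac_fixed = mean(.data$vaf > fixed_vaf),
                     .groups = "drop") |>
    dplyr::filter(.data$frac_fixed > fixed_cell_fraction)
  cvm$vaf <- cvm$vaf |>
    dplyr::anti_join(fixed, by = c("site", "alt"))
  cvm
}
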