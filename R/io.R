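#' Write a cohort to disk
#'
#' Writes the long strand-resolved count table (gzip TSV), the cell metadata
#' TSV and, if provided, the truth tables. Round-trips losslessly through
#' [read_cohort()].
#'
#' @param matrix An [allele_count_matrix()].
#' @param path Output directory (created if absent).
#' @param truth Optional truth list from [generate_cohort()].
#' @return The paths written, invisibly.
#' @export
write_cohort <- function(matrix, path, truth = NULL) {
  stopifnot(inherits(matrix, "allele_count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- c(counts = file.path(path, "counts.tsv.gz"),
             cells = file.path(path, "cells.tsv"))
  readr::write_tsv(matrix$counts, files["counts"], progress = FALSE)
  readr::write_tsv(matrix$cells, files["cells"], progress = FALSE)
  if (!is.null(truth)) {
    files["truth_variants"] <- file.path(path, "truth_variants.tsv")
    files["truth_cell_vafs"] <- file.path(path, "truth_cell_vafs.tsv")
    readr::write_tsv(truth$variants, files["truth_variants"], progress = FALSE)
    readr::write_tsv(truth$cell_vafs, files["truth_cell_vafs"],
                     progress = FALSE)
  }
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Directory containing `counts.tsv.gz` and `cells.tsv`.
#' @return List with `matrix` and (if present on disk) `truth`.
#' @export
read_cohort <- function(path) {
  counts <- readr::read_tsv(
    file.path(path, "counts.tsv.gz"), show_col_types = FALSE,
    progress = FALSE,
    col_types = readr::cols(cell_id = "c", site = "i", ref = "c", alt = "c",
                            ref_fwd = "i", ref_rev = "i", alt_fwd = "i",
                            alt_rev = "i"))
  cells <- readr::read_tsv(
    file.path(path, "cells.tsv"), show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(cell_id = "c", cell_type = "c",
                            mito_reads = "d", total_reads = "d"))
  out <- list(matrix = allele_count_matrix(counts, cells))
  tv <- file.path(path, "truth_variants.tsv")
  if (file.exists(tv)) {
    out$truth <- list(
      variants = readr::read_tsv(tv, show_col_types = FALSE,
                                 progress = FALSE),
      cell_vafs = readr::read_tsv(file.path(path, "truth_cell_vafs.tsv"),
                                  show_col_types = FALSE, progress = FALSE))
  }
  out
}

#' Write final variant calls as VCF
#'
#' One sites-only record per final somatic variant on contig `chrM`
#' (rCRS coordinates), with filter provenance in INFO.
#'
#' @param variants Tibble with `site`, `ref`, `alt` and optionally
#'   `n_cells_candidate` / `n_cells_confident`.
#' @param path Output `.vcf` file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=chrM,length=%d>", MT_GENOME_LENGTH),
    "##INFO=<ID=NCAND,Number=1,Type=Integer,Description=\"Cells passing candidate thresholds\">",
    "##INFO=<ID=NCONF,Number=1,Type=Integer,Description=\"Cells passing confidence filters\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- vapply(seq_len(nrow(variants)), function(i) {
    parts <- character(0)
    if ("n_cells_candidate" %in% names(variants)) {
      parts <- c(parts, sprintf("NCAND=%d", variants$n_cells_candidate[i]))
    }
    if ("n_cells_confident" %in% names(variants)) {
      parts <- c(parts, sprintf("NCONF=%d", variants$n_cells_confident[i]))
    }
    if (length(parts) == 0) "." else paste(parts, collapse = ";")
  }, character(1))
  records <- sprintf("chrM\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
                     variants$site,
                     sprintf("%d%s>%s", variants$site, variants$ref,
                             variants$alt),
                     variants$ref, variants$alt, info)
  writeLines(c(header, records), path)
  invisible(path)
}

#' Write a spectrum as TSV
#'
#' @param spectrum A [vaf_spectrum()] object.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "vaf_spectrum"))
  readr::write_tsv(spectrum_as_tibble(spectrum), path, progress = FALSE)
  invisible(path)
}

#' Spectrum as a tibble
#'
#' @param spectrum A [vaf_spectrum()] object.
#' @return Tibble with `bin`, `vaf_low`, `vaf_high`, `count`.
#' @export
spectrum_as_tibble <- function(spectrum) {
  tibble(bin = 1:19,
         vaf_low = spectrum$bin_edges[1:19],
         vaf_high = spectrum$bin_edges[2:20],
         count = spectrum$counts,
         normalization = spectrum$normalization,
         cell_type = spectrum$cell_type)
}

#' Read a spectrum TSV written by [write_spectrum()]
#'
#' @param path TSV path.
#' @return A [vaf_spectrum()] object.
#' @export
read_spectrum <- function(path) {
  tb <- readr::read_tsv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(bin = "i", vaf_low = "d", vaf_high = "d",
                            count = "d", normalization = "c",
                            cell_type = "c"))
  structure(list(counts = tb$count, bin_edges = spectrum_bin_edges(),
                 normalization = tb$normalization[1],
                 n_cells = NA_integer_,
                 cell_type = tb$cell_type[1]),
            class = "vaf_spectrum")
}
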