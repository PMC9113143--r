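#' Mitochondrial genome annotation
#'
#' Region map of the 16,569-bp human mtDNA coordinate system: control-region /
#' non-coding loops, tRNA genes, the two rRNA genes and the 13 protein-coding
#' genes, with strand. Coordinates follow the standard rCRS gene map, including
#' the ATP8/ATP6 and ND4L/ND4 overlaps. Intervals are 1-based and inclusive.
#'
#' @return A tibble with columns `start`, `end`, `region`
#'   (`loop`/`tRNA`/`rRNA`/`coding`), `gene` and `strand` (`+`/`-`).
#' @export
#' @examples
#' ann <- mt_annotation()
#' subset(ann, region == "coding")
mt_annotation <- function() {
  path <- system.file("extdata", "mt_annotation.tsv", package = "mitobottleneck")
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(ann$start >= 1L), all(ann$end <= MT_GENOME_LENGTH),
            all(ann$start <= ann$end))
  ann
}

#' Synthetic mitochondrial reference sequence
#'
#' A deterministic, randomly generated 16,569-bp nucleotide sequence used as a
#' stand-in reference for the rCRS coordinate system. It is *synthetic*: gene
#' coordinates are real, the base composition is uniform random, and no codon
#' in it corresponds to the true human mtDNA sequence. All synthetic cohorts in
#' this package draw their reference alleles from it, so reference bases are
#' internally consistent across the generator, the variant pipeline and the
#' dN/dS annotation; analyses of real data must substitute the true rCRS
#' sequence via the `genome` arguments.
#'
#' @return A single character string of length 16,569 over `ACGT`.
#' @export
synthetic_mt_genome <- function() {
  if (!is.null(.mt_cache$genome)) {
    return(.mt_cache$genome)
  }
  # Isolated RNG stream so the reference is identical regardless of user seed.
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(166569L)
  genome <- paste(sample(c("A", "C", "G", "T"), MT_GENOME_LENGTH, replace = TRUE),
                  collapse = "")
  .mt_cache$genome <- genome
  genome
}

.mt_cache <- new.env(parent = emptyenv())

#' Reference base at mtDNA positions
#'
#' @param sites Integer vector of 1-based positions in 1..16,569.
#' @param genome Reference sequence string; defaults to the bundled synthetic
#'   reference.
#' @return Character vector of single bases.
#' @export
mt_ref_base <- function(sites, genome = synthetic_mt_genome()) {
  stopifnot(all(sites >= 1L), all(sites <= MT_GENOME_LENGTH))
  substring(genome, sites, sites)
}

#' Vertebrate mitochondrial genetic code
#'
#' Codon-to-amino-acid map (NCBI translation table 2), in which TGA encodes
#' Trp and AGA/AGG are stop codons. Stops are reported as `*`.
#'
#' @return Named character vector over all 64 codons.
#' @export
mt_genetic_code <- function() {
  Biostrings::getGeneticCode("2")
}

#' Extract coding sequences from a reference
#'
#' Pulls each protein-coding gene's sequence from the reference in reading
#' orientation (reverse-complemented for minus-strand genes, i.e. ND6) and
#' trims any incomplete trailing codon, mirroring the polyadenylation-completed
#' stops of several mitochondrial mRNAs.
#'
#' @param genome Reference sequence string.
#' @param ann Annotation tibble from [mt_annotation()].
#' @return Named character vector of CDS sequences, lengths divisible by 3.
#' @export
mt_cds_sequences <- function(genome = synthetic_mt_genome(), ann = mt_annotation()) {
  cds <- ann[ann$region == "coding", ]
  seqs <- vapply(seq_len(nrow(cds)), function(i) {
    s <- substring(genome, cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") s <- revcomp(s)
    substring(s, 1L, (nchar(s) %/% 3L) * 3L)
  }, character(1))
  setNames(seqs, cds$gene)
}

revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Genomic region at mtDNA positions
#'
#' Looks up the region label for each position. Positions covered by two
#' overlapping protein-coding genes are `coding`; a position is labelled with
#' the first matching interval in annotation order otherwise.
#'
#' @inheritParams mt_ref_base
#' @param ann Annotation tibble from [mt_annotation()].
#' @return Character vector of region labels (`loop`, `tRNA`, `rRNA`, `coding`).
#' @export
mt_region_at <- function(sites, ann = mt_annotation()) {
  stopifnot(all(sites >= 1L), all(sites <= MT_GENOME_LENGTH))
  vapply(sites, function(p) {
    hit <- ann$region[ann$start <= p & ann$end >= p]
    if (any(hit == "coding")) "coding" else hit[1]
  }, character(1))
}
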