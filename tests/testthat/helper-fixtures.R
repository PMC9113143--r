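# Shared fixtures: tiny hand-built count matrices and an independent pure-R
# Wright-Fisher reference implementation used as the oracle for the compiled
# simulator.

# Build an allele_count_matrix from a compact row description.
# rows: list of lists with cell, site, ref, alt, rf, rr, af, ar
make_acm <- function(rows, cell_types = NULL) {
  counts <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(cell_id = r$cell, site = as.integer(r$site),
                   ref = r$ref, alt = if (is.null(r$alt)) NA_character_ else r$alt,
                   ref_fwd = as.integer(r$rf), ref_rev = as.integer(r$rr),
                   alt_fwd = as.integer(r$af), alt_rev = as.integer(r$ar))
  }))
  ids <- unique(counts$cell_id)
  if (is.null(cell_types)) cell_types <- setNames(rep("B", length(ids)), ids)
  cells <- tibble::tibble(
    cell_id = ids,
    cell_type = unname(cell_types[ids]),
    mito_reads = vapply(ids, function(i) {
      sum(counts[counts$cell_id == i,
                 c("ref_fwd", "ref_rev", "alt_fwd", "alt_rev")])
    }, numeric(1)),
    total_reads = 1e5)
  allele_count_matrix(counts, cells)
}

# Count row helper with balanced strands.
crow <- function(cell, site, ref, alt = NULL, ref_n = 0, alt_n = 0,
                 alt_fwd = NULL) {
  af <- if (is.null(alt_fwd)) floor(alt_n / 2) else alt_fwd
  list(cell = cell, site = site, ref = ref, alt = alt,
       rf = floor(ref_n / 2), rr = ref_n - floor(ref_n / 2),
       af = af, ar = alt_n - af)
}

# --- independent pure-R Wright-Fisher reference ------------------------------
# Deliberately written as a naive loop, sharing no code with the package's
# compiled core.

ref_wf_step <- function(counts, n_cur, n_next, u) {
  if (length(counts) > 0) {
    counts <- stats::rbinom(length(counts), n_next, counts / n_cur)
    counts <- counts[counts > 0]
  }
  c(counts, rep(1, stats::rpois(1, u * n_next)))
}

ref_wf_lineage <- function(N0, alpha, Td, Ta, u) {
  n <- N0
  counts <- numeric(0)
  for (t in seq_len(Ta)) {
    nn <- if (t <= Td) {
      round(alpha * n)
    } else if (t == Ta) {
      N0
    } else {
      n
    }
    counts <- ref_wf_step(counts, n, nn, u)
    n <- nn
  }
  counts / n
}

ref_bin_spectrum <- function(vafs) {
  v <- vafs[vafs >= 0.05]
  tabulate(pmin(findInterval(v, (1:20) * 0.05), 19), nbins = 19)
}
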